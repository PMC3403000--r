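label	assay	mean	sem	n	group
BMP9	orientation_angle_deg	37.7	1.6	31	bmp
BMP7	orientation_angle_deg	35.0	1.9	22	bmp
BMP4	orientation_angle_deg	30.6	1.2	14	bmp
BMP2	orientation_angle_deg	26.8	1.6	20	bmp
GDF6	orientation_angle_deg	18.8	2.1	22	bmp
BMP5	orientation_angle_deg	16.1	1.8	28	bmp
DSL1	orientation_angle_deg	11.8	2.8	15	bmp
BMP6	orientation_angle_deg	7.0	2.2	24	bmp
GDF5	orientation_angle_deg	6.6	2.2	20	bmp
GDF7	orientation_angle_deg	3.7	1.5	19	bmp
TGFB3	orientation_angle_deg	-2.1	1.6	11	other
TGFB2	orientation_angle_deg	0.56	2.8	9	other
ACTA	orientation_angle_deg	-6.0	1.2	21	other
pMT23	orientation_angle_deg	-3.5	1.6	14	control
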