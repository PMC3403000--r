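label	assay	mean	sem	n	group
BMP6_WT	orientation_angle_deg	7.8	1.1	11	native
BMP6_Q48R	orientation_angle_deg	28.1	1.9	22	chimera
BMP7_WT	orientation_angle_deg	29.3	2.7	11	native
BMP6_Q48S	orientation_angle_deg	32.5	1.4	4	chimera
BMP6_Q48E	orientation_angle_deg	27.0	2.1	3	chimera
BMP6_Q48A	orientation_angle_deg	40.0	2.4	8	chimera
BMP7_R48Q	orientation_angle_deg	19.0	2.9	16	chimera
pMT23	orientation_angle_deg	-4.8	1.1	6	control
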