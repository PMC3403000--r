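label	assay	mean	sem	n	group
BMP9	induction_percent	203	26	11	bmp
BMP7	induction_percent	174	33	6	bmp
BMP4	induction_percent	175	26	10	bmp
BMP2	induction_percent	158	14	11	bmp
GDF6	induction_percent	173	15	4	bmp
BMP5	induction_percent	184	31	7	bmp
DSL1	induction_percent	205	29	7	bmp
BMP6	induction_percent	153	18	7	bmp
GDF5	induction_percent	198	20	12	bmp
GDF7	induction_percent	215	18	14	bmp
TGFB3	induction_percent	-8	6	10	other
TGFB2	induction_percent	-1	4	9	other
ACTA	induction_percent	-5	7	16	other
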