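label	assay	mean	sem	n	group
BMP6_WT	induction_percent	228	13	11	native
BMP6_Q48R	induction_percent	252	14	16	chimera
BMP7_WT	induction_percent	289	19	8	native
BMP6_Q48S	induction_percent	241	22	4	chimera
BMP6_Q48E	induction_percent	290	22	5	chimera
BMP7_R48Q	induction_percent	274	21	11	chimera
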