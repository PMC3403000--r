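label	assay	mean	sem	n	group
rBMP7	collapse_percent	36.7	0.3	2	recombinant
BMP7_WT	collapse_percent	40.7	4.0	2	native
BMP6_WT	collapse_percent	11.5	2.3	2	native
BMP6_N65Y	collapse_percent	13.3	4.9	2	chimera
BMP6_Y98T	collapse_percent	20.4	3.1	2	chimera
BMP6_Q48R	collapse_percent	49.8	4.5	2	chimera
BMP6_Q48A	collapse_percent	46.8	5.0	2	chimera
BMP7_R48Q	collapse_percent	26.7	5.7	2	chimera
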