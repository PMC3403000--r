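label	assay	mean	sem	n	group
control	growth_cone_area_um2	114.3	10.7	2	control
BMP7	growth_cone_area_um2	79.5	7.4	2	bmp
BMP6	growth_cone_area_um2	127.4	11.9	2	bmp
GDF7	growth_cone_area_um2	122.4	11.7	2	bmp
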