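id	tier	notes
BMP9	robust
BMP7	robust
BMP4	robust
BMP2	robust
GDF6	intermediate
BMP5	intermediate
DSL1	intermediate	chick dorsalin-1
BMP6	none
GDF5	none
GDF7	none
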