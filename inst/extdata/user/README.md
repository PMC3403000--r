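# User-supplied sequences

The real-data worked example needs the mature-domain amino-acid sequences
of the mouse BMP family (BMP2, BMP4, BMP5, BMP6, BMP7, BMP9, GDF5, GDF6,
GDF7 and chick dorsalin-1). The package deliberately ships no copies and no
download code: fetch them yourself from a reference protein database
(e.g. UniProt), trim each entry to its mature region starting two residues
upstream of the first conserved cysteine, and save them here as

    bmp_mature_mouse.fasta

with FASTA ids matching `inst/extdata/bmp_phenotypes.tsv` (BMP7, BMP6,
BMP5, ... DSL1 for dorsalin-1). If the file is installed with the package,
the worked-example acceptance test and the vignette's real-data section
will pick it up; otherwise they report it as unavailable.
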