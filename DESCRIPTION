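Package: bmporient
Title: Determinants of BMP Axon-Orienting Activity from Comparative
    Sequence Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies candidate specificity-determining residues in
    near-identical protein families by anchored mature-domain alignment,
    conservative-substitution classification and a phenotype-stratified
    residue-elimination filter, with neighbor-joining dendrograms and
    reconstruction of two-sample t-tests and one-way ANOVA from published
    group summary statistics (mean, SEM, n). Developed around the mouse
    BMP family, where the mature domains of BMP6 and BMP7 are 95% similar
    yet only BMP7 orients dorsal interneuron axons; a simulator generates
    seeded protein families with planted discriminative columns and
    per-tier Gaussian assay measurements so the whole pipeline is testable
    without external sequence downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    ape,
    jsonlite,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
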