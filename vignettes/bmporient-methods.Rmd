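---
title: "Methods: anchored family comparison, the elimination filter, and summary-statistic inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: anchored family comparison, the elimination filter, and summary-statistic inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bmporient)
```

This vignette is the package's account of its own methods: what each stage
assumes, which parameters matter and why they default as they do, what the
simulator does and does not emulate, and where the published numbers and
the formal rules part ways.

## 1. The procedure and its assumptions

The package targets one specific analytical situation: a protein family so
similar (≥ 90% pairwise identity, here ~95–97%) that a qualitative
phenotype splitting the family can be mapped onto individual alignment
columns deterministically, without statistical column scoring. The mouse
BMP family is the motivating case — BMP7 orients dorsal interneuron axons,
BMP6 does not, BMP5 is intermediate — and the procedure's product is a
short list of candidate specificity-determining positions for residue-swap
experiments. The key assumptions:

* the mature domains are alignable essentially without ambiguity (the
  center-star alignment below is only defensible in this regime);
* the phenotype tiers supplied with the sequences are trustworthy labels,
  not quantities to be estimated;
* a single residue (or a few) can carry the phenotype difference, so
  elimination by counter-example across the active set is meaningful.

None of these hold for divergent families; this is not a general
motif-discovery tool.

## 2. Anchored numbering

All coordinates are 1-based along a reference record (default BMP7),
starting two residues upstream of the first conserved cysteine of the
mature domain, i.e. the anchoring cysteine itself is position 3. The
anchor is the left-most alignment column that is cysteine in every row
with no gaps; if no such column exists the alignment refuses to anchor
(an error, not a guess). When several all-cysteine columns exist the
left-most wins, by definition of "first". Inputs that begin upstream of
the canonical start can be cut with `trim_to_anchor()`; positions upstream
of the start are then numbered ≤ 0 until trimmed. Per-record numbering
maps (each sequence's own coordinates at every non-gap cell) are kept
alongside, since the literature reports positions in both frames (e.g.
Arg47 of BMP5 corresponds to reference position 48).

## 3. The conservation scheme

"Conservative substitution" has no universal definition, and the choice is
load-bearing here: the published comparison treats Gln↔Arg (position 48),
Asn↔Tyr (65), Tyr↔Thr (98) and Lys↔Glu as *non-conservative*, while
substitution-matrix conventions (BLOSUM62 score > 0, Clustal "strong"
groups) would call Gln↔Arg conservative and delete the decisive position
48 from the analysis. The default scheme is therefore a deliberately fine
partition into eight physicochemical classes —

\{A,G,I,L,V\}, \{S,T\}, \{N,Q\}, \{D,E\}, \{H,K,R\}, \{F,W,Y\}, \{C,M\}, \{P\}

— which reproduces every classification the reference analysis states
while keeping obviously homologous exchanges (D/E, K/R, S/T, I/V)
conservative. The scheme is a first-class object
(`conservation_scheme()`), so users can substitute a coarser partition;
the filter, similarity and distance computations all take it as an
argument. Classification is symmetric, reflexive (`identical`), and any
pair involving a gap is classified `gap` and excluded from similarity
denominators (the gap count is reported separately). This gap-excluded
denominator is a choice: the published 95%/97% figures do not state their
denominator, and mature domains differ slightly in length.

## 4. Alignment

The published alignment came from a commercial GUI whose algorithm is
unspecified; for families this similar the alignment is
method-insensitive, so the package uses the simplest construction that is
provably adequate in this regime: optimal pairwise global
(Needleman–Wunsch) alignment of every sequence against a center sequence
(the one with maximal mean pairwise identity), merged by gap propagation
(center-star). Pairwise scoring is BLOSUM62 with affine gap costs, open 10
and extend 0.5 in score units. The tests assert that on indel-free
families the result is exactly the column stacking of the inputs, that
ungapping any row reproduces its input byte-for-byte, and that a
single-indel pair matches a brute-force enumeration of all global
alignments under the same scoring. A guide-tree progressive aligner would
add complexity without changing any in-scope result.

## 5. The elimination filter

Given the non-orienting reference `x`, orienting reference `y` and active
set `R` (robust-tier records; intermediate-tier records join only with
`include_intermediate = TRUE`, mirroring the original analysis which
filtered against *robustly* orienting members only), every column gets one
audit row:

* `not_different` — pair class identical/conservative, or a gap in either
  reference (gap columns are never candidates);
* `eliminated_shared_identical` — some member of `R` carries exactly `x`'s
  residue (the "shared by another orienting BMP" rule);
* `eliminated_conservative_with_active` — some member of `R` carries a
  residue conservative with `x`'s (the rule that removes position 36,
  where BMP2/BMP9 carry a conservative variant of BMP6's residue);
* `retained` — a candidate.

Both elimination rules are applied uniformly at every column; position 60
needs no special-casing because sharing (BMP9's Lys60) eliminates it.
Candidates are reported in ascending reference position. Enlarging `R`
can only add elimination evidence, so candidate sets are monotone
non-increasing in the active set — a property test, and the reason
`candidate_stability()` (leave-one-active-out) can only *add* candidates.
The symmetric filter (testing `y`'s residues against non-orienting
members) is not implemented; the original analysis ran the filter in one
direction only.

## 6. Dendrogram

Distances are `1 − sim/100` with conservation-aware similarity by default
(a documented `measure = "identity"` switch uses strict identity), and the
tree is standard neighbor joining. Two numerical choices: taxa are sorted
lexicographically before agglomeration so output is independent of input
order, and negative branch lengths — a known NJ artifact on non-additive
matrices — are clamped to zero with the deficit moved to the sibling
branch, preserving leaf-to-leaf path lengths through the parent. On
additive matrices no clamping triggers and generating-tree path lengths
are recovered to < 1e-9 (tested). No bootstrap, no likelihood methods:
the dendrogram's analytical role here is only the coarse observation that
close relatives can differ in phenotype.

## 7. Statistics from printed summaries

Explant assay results are published as `mean ± SEM (n)` per group, so the
inference layer reconstructs classical tests exactly from those triples:
group SD = SEM·√n; pooled-variance Student t (default, matching the
published "Student's t tests") with `n_a + n_b − 2` df, Welch by flag;
one-way fixed-effects ANOVA with between-SS from n-weighted deviations
about the weighted grand mean and within-SS `Σ(nᵢ−1)·SDᵢ²`. Whenever
summaries are computed from raw samples these equal `t.test()` /
`aov()` on the raw data to 1e-12 (oracle tests), and for two groups
F = t² (algebraic identity, tested). All tests are two-tailed with
α = 0.05 by default; no multiple-testing correction is applied, matching
the published reporting (a Bonferroni adjustment would be trivial to add
at the `classify_activity()` call site by passing a smaller α).

The three-tier classifier formalizes the published narrative grouping:
`none` if not significantly different from control, `robust` if different
from control but not from the top group, `intermediate` otherwise. Running
it on the printed summaries exposes real inconsistencies rather than
hiding them:

* BMP6 (7.0 ± 2.2°, n = 24) vs control (−3.5 ± 1.6°, n = 14) gives
  p ≈ 0.002 under any standard two-sample test, although the narrative
  calls BMP6 "not different from control";
* BMP4 and BMP2 differ from top-group BMP9 at p < 0.01, so the formal rule
  places them in the intermediate tier although the narrative groups all
  four strong BMPs together.

The package's position is that these are properties of the printed
summaries, not bugs to patch: `classify_activity()` returns the full
p-value table, and `run_pipeline()` warns when computed tiers disagree
with supplied phenotype labels. Similarly, the growth-cone-area and
collapse-percentage tables are shipped with `n = 2` (the stated number of
experiments) because the per-group replication unit is ambiguous in the
source; their p-values are not recomputed, only their means are used
(percent-change: 114.3 → 79.5 μm² is a 30.4% reduction).

## 8. The simulator: what it emulates and what it does not

`generate_family()` draws a root sequence (cysteine fixed at position 3),
mutates it independently per lineage at a background per-site rate, and
plants phenotype-linked residues: one shared residue across all
active/intermediate lineages, a cross-class residue in inactive lineages.
Defaults are fixed study conditions, chosen once:

| parameter | default | rationale |
|---|---|---|
| length | 139 | approximate mature-domain length implied by the reference numbering |
| planted positions | 48, 65, 98 | the real candidate set, so synthetic and real frames coincide |
| background rate | 0.015/site/lineage | two lineages ≈ 3% divergence ≈ the 95–97% similarity band |
| topology | star | adequate at this identity level; no clade structure is needed by any in-scope analysis |
| indel rate | 0 | keeps the zero-gap invariant testable; when enabled, indels avoid the anchor neighborhood |

Background mutations can collide with the filter rules (create a spurious
candidate column); the generator does not prevent this — it *logs* it in
ground truth (`truth$collisions`, via a literal per-column application of
the rules), so tests can assert exact recovery on collision-free families
and exact predictability of the discrepancies otherwise.

`generate_assays()` draws Gaussian measurements per tier (defaults
32 ± 6° robust, 16 ± 5° intermediate, 5 ± 5° none, −3 ± 4° control,
n = 12 per group — inside the published n range of 3–31) and summarizes
them as mean/SEM/n. What the simulator does **not** emulate: phylogenetic
covariance among lineages, realistic substitution processes (no rate
heterogeneity, no exchangeability bias), indel length distributions,
non-Gaussian assay error, or correlation between explants. Passing tests
on synthetic data therefore certify the *logic* of the pipeline — exact
recovery under the generative assumptions — not robustness to real
evolutionary noise.

One structural consequence worth stating plainly: with the default
"none" tier at 5 ± 5° against control at −3 ± 4°, a significance-based
rule has near-full power at n = 12 to detect the 8° offset, so simulated
"none" groups are systematically reported as weakly active — exactly the
behaviour the printed BMP6/GDF5/GDF7 summaries show. The test suite
asserts high recovery for robust/intermediate tiers and asserts (rather
than fights) the weak-tier flagging.

## 9. Problem sizes and determinism

Validation runs use deliberately desk-scale sizes: 100 seeded families for
planted-candidate recovery, 200 for monotonicity, 50 random cases for the
raw-data statistical oracles, 500 replicates for the power check. All
randomness flows through explicit integer seeds (`family_spec(seed=)`,
`assay_sim_spec(seed=)`); identical specs produce byte-identical output
files, and `run_pipeline()` re-runs reproduce byte-identical report JSON.

## 10. Known limitations

* The real-sequence worked example requires user-supplied FASTA (the
  package ships no reference sequences and no fetching code); until it is
  provided, the 95%/97%/8-difference/{48,65,98} checks run only in their
  synthetic analogue.
* Center-star alignment is inadequate outside the near-identical regime
  and the package makes no attempt to detect misalignment beyond the
  conserved-cysteine anchor requirement.
* The filter is deterministic and label-driven: a single mislabelled tier
  changes the candidate set, which is why `candidate_stability()` exists.
* Summary-statistic tests inherit the rounding of the printed means/SEMs;
  recomputed p-values should be compared to printed ones with an absolute
  tolerance of about 0.02.
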