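# Independent oracles used across the suite. These deliberately do not call
# the package code paths they are checking.

blosum62 <- local({
  data("BLOSUM62", package = "Biostrings", envir = environment())
  BLOSUM62
})

# Score a gapped alignment row pair with BLOSUM62 and affine gap costs
# (gap of length L costs open + ext * L), matching the package's stated
# alignment scoring.
score_gapped_pair <- function(a, b, open = 10, ext = 0.5) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  stopifnot(length(ca) == length(cb))
  s <- 0
  in_gap <- FALSE
  for (k in seq_along(ca)) {
    if (ca[k] == "-" || cb[k] == "-") {
      s <- s - ext - if (in_gap) 0 else open
      in_gap <- TRUE
    } else {
      s <- s + blosum62[ca[k], cb[k]]
      in_gap <- FALSE
    }
  }
  s
}

# Enumerate every global alignment of two short sequences and return the
# optimal score plus all optimal alignments. Exponential; only for tiny
# inputs.
enumerate_alignments <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  out <- list()
  rec <- function(i, j, ra, rb) {
    if (i > length(ca) && j > length(cb)) {
      out[[length(out) + 1]] <<- c(paste(ra, collapse = ""),
                                   paste(rb, collapse = ""))
      return(invisible())
    }
    if (i <= length(ca) && j <= length(cb)) {
      rec(i + 1, j + 1, c(ra, ca[i]), c(rb, cb[j]))
    }
    if (i <= length(ca)) rec(i + 1, j, c(ra, ca[i]), c(rb, "-"))
    if (j <= length(cb)) rec(i, j + 1, c(ra, "-"), c(rb, cb[j]))
  }
  rec(1, 1, character(0), character(0))
  scores <- vapply(out, function(al) score_gapped_pair(al[1], al[2]),
                   numeric(1))
  list(best_score = max(scores),
       best = out[scores == max(scores)])
}

# Literal re-implementation of the elimination filter over ungapped,
# equal-length sequences: enumerate columns, apply the rules as written.
brute_force_candidates <- function(seqs, tiers, inactive, active_ref,
                                   scheme = default_scheme(),
                                   active_ids = NULL) {
  mat <- do.call(rbind, strsplit(unname(seqs), ""))
  rownames(mat) <- names(seqs)
  if (is.null(active_ids)) {
    active_ids <- names(seqs)[tiers == "robust"]
  }
  active_ids <- setdiff(union(active_ids, active_ref), inactive)
  keep <- integer(0)
  for (p in seq_len(ncol(mat))) {
    ri <- mat[inactive, p]
    ra <- mat[active_ref, p]
    if (classify_pair(ri, ra, scheme) != "nonconservative") next
    elim <- FALSE
    for (id in active_ids) {
      cls <- classify_pair(ri, mat[id, p], scheme)
      if (cls %in% c("identical", "conservative")) { elim <- TRUE; break }
    }
    if (!elim) keep <- c(keep, p)
  }
  keep
}

# A tiny concrete family used in several tests: equal-length sequences so
# alignment is trivially the column stacking and positions equal columns.
tiny_family <- function() {
  protein_family(
    id = c("ACT_A", "ACT_B", "ACT_C", "INACT"),
    sequence = c(
      "AACKDLFGHRSTW",
      "AACKDLFGHRSTW",
      "AACKELFGHRSTW",   # E at 5 (conservative with D of ACT_A/B)
      "AACQDLFGYRSTW"    # Q at 4 (cross-class to K), Y at 9 (cross-class to H)
    ),
    tier = c("robust", "robust", "robust", "none")
  )
}

summ_from_raw <- function(x, label = "g", assay = "orientation_angle_deg") {
  assay_summary(label, assay, mean(x), stats::sd(x) / sqrt(length(x)),
                length(x))
}
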