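anchored <- function(records, ref) find_anchor(align_family(records,
                                                            reference_id = ref))

test_that("identical references yield zero nonconservative audits", {
  rec <- protein_family(c("a", "b", "c"),
                        c("AACRDEF", "AACRDEF", "AACRDEF"),
                        tier = c("robust", "robust", "none"))
  aln <- anchored(rec, "a")
  d <- difference_positions(aln, "c", "a")
  expect_equal(nrow(d), 7)                       # audit covers every column
  expect_equal(sum(d$pair_class == "nonconservative"), 0)
  rep <- call_candidates(aln, "c", "a")
  expect_length(rep$candidates, 0)
})

test_that("audits cover each alignment column exactly once", {
  fam <- generate_family(family_spec(seed = 21))
  aln <- anchored(fam$records, "ACT01")
  d <- difference_positions(aln, "INA01", "ACT01")
  expect_identical(d$column, seq_len(ncol(aln$mat)))
})

test_that("planted nonconservative columns are counted exactly", {
  fam <- generate_family(family_spec(seed = 2, rate = 0))
  aln <- anchored(fam$records, "ACT01")
  d <- difference_positions(aln, "INA01", "ACT01")
  expect_identical(d$ref_position[d$pair_class == "nonconservative"],
                   fam$truth$planted_positions)
})

test_that("the elimination filter matches a literal brute-force oracle", {
  set.seed(99)
  aas <- c("A", "D", "K", "N", "S", "F", "C", "P", "E", "R")
  for (i in 1:30) {
    n <- sample(4:6, 1)
    L <- sample(12:30, 1)
    root <- sample(setdiff(aas, "C"), L, replace = TRUE)
    root[3] <- "C"   # single conserved cysteine fixes numbering at columns
    seqs <- replicate(n, {   # near-identical family: few point mutations
      s <- root
      hit <- setdiff(which(stats::runif(L) < 0.1), 1:3)
      s[hit] <- vapply(s[hit], function(x) sample(setdiff(aas, c(x, "C")), 1), "")
      paste(s, collapse = "")
    })
    ids <- sprintf("P%02d", seq_len(n))
    tiers <- c(rep("robust", n - 1), "none")
    rec <- protein_family(ids, seqs, tier = tiers)
    aln <- anchored(rec, ids[1])
    got <- call_candidates(aln, ids[n], ids[1])$candidates
    want <- brute_force_candidates(stats::setNames(seqs, ids), tiers,
                                   inactive = ids[n], active_ref = ids[1])
    expect_identical(as.integer(got), as.integer(want))
  }
})

test_that("verdicts separate sharing from conservative-equivalence", {
  # INACT vs ACT_A differ nonconservatively at 4 (Q/K) and 9 (Y/H)
  rec <- tiny_family()
  aln <- anchored(rec, "ACT_A")
  rep <- call_candidates(aln, "INACT", "ACT_A")
  expect_identical(rep$candidates, c(4L, 9L))
  expect_true(all(rep$audits$verdict[rep$audits$ref_position %in% c(4, 9)] ==
                    "retained"))

  # give one active member the inactive residue at 4 -> sharing eliminates
  rec2 <- rec
  rec2$sequence[3] <- "AACQELFGHRSTW"
  aln2 <- anchored(rec2, "ACT_A")
  rep2 <- call_candidates(aln2, "INACT", "ACT_A")
  expect_identical(rep2$candidates, 9L)
  a4 <- rep2$audits[which(rep2$audits$ref_position == 4), ]
  expect_equal(a4$verdict, "eliminated_shared_identical")
  expect_equal(a4$evidence[[1]], "ACT_C")

  # give it instead an amide neighbour (N) -> conservative-equivalence
  rec3 <- rec
  rec3$sequence[3] <- "AACNELFGHRSTW"
  aln3 <- anchored(rec3, "ACT_A")
  rep3 <- call_candidates(aln3, "INACT", "ACT_A")
  expect_identical(rep3$candidates, 9L)
  a4 <- rep3$audits[which(rep3$audits$ref_position == 4), ]
  expect_equal(a4$verdict, "eliminated_conservative_with_active")
})

test_that("candidates shrink (never grow) as the active set grows", {
  set.seed(31)
  for (i in 1:40) {
    fam <- generate_family(family_spec(seed = 1000 + i, n_active = 5,
                                       rate = 0.02))
    aln <- anchored(fam$records, "ACT01")
    acts <- sprintf("ACT%02d", 1:5)
    prev <- NULL
    for (k in 2:5) {
      cand <- call_candidates(aln, "INA01", "ACT01",
                              active_ids = acts[1:k])$candidates
      if (!is.null(prev)) expect_true(all(cand %in% prev))
      prev <- cand
    }
  }
})

test_that("intermediate-tier records join the active set only on request", {
  rec <- tiny_family()
  rec$tier[3] <- "intermediate"        # ACT_C leaves the default active set
  rec$sequence[3] <- "AACQELFGHRSTW"   # shares Q at 4 with INACT
  aln <- anchored(rec, "ACT_A")
  expect_identical(call_candidates(aln, "INACT", "ACT_A")$candidates,
                   c(4L, 9L))
  expect_identical(
    call_candidates(aln, "INACT", "ACT_A",
                    include_intermediate = TRUE)$candidates,
    9L
  )
})

test_that("leave-one-active-out keeps originals and can add candidates", {
  rec <- tiny_family()
  rec$sequence[3] <- "AACQELFGHRSTW"   # ACT_C alone eliminates position 4
  aln <- anchored(rec, "ACT_A")
  rep <- call_candidates(aln, "INACT", "ACT_A")
  expect_identical(rep$candidates, 9L)
  st <- candidate_stability(rep, aln)
  expect_true(all(st$status[st$candidate == 9] == "retained"))
  gained <- st[st$status == "gained", ]
  expect_identical(gained$dropped, "ACT_C")
  expect_identical(gained$candidate, 4L)

  # dropping the only co-active member leaves the filter undefined
  rec2 <- protein_family(c("ACT_A", "ACT_B", "INACT"),
                         c("AACKDLF", "AACKDLF", "AACQDLF"),
                         tier = c("robust", "robust", "none"))
  aln2 <- anchored(rec2, "ACT_A")
  rep2 <- call_candidates(aln2, "INACT", "ACT_A")
  st2 <- candidate_stability(rep2, aln2)
  expect_identical(unique(st2$status), "undefined")
})

test_that("planted candidates are stable under every leave-one-out", {
  fam <- generate_family(family_spec(seed = 77, rate = 0))
  aln <- anchored(fam$records, "ACT01")
  rep <- call_candidates(aln, "INA01", "ACT01")
  expect_identical(rep$candidates, fam$truth$planted_positions)
  st <- candidate_stability(rep, aln)
  expect_true(all(st$status == "retained"))
  expect_setequal(unique(st$candidate), fam$truth$planted_positions)
})
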