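#' Specify a synthetic near-identical protein family
#'
#' The generator emulates the structure the elimination filter assumes: a
#' family of ~95–97% similar mature domains in which a small set of planted
#' columns carries phenotype-linked residues. A shared root sequence (with
#' the anchoring cysteine fixed at position 3) is mutated independently per
#' lineage at a background rate, excluding the anchor and planted columns.
#' At each planted column every active-tier (and intermediate-tier)
#' sequence receives one residue and the inactive reference a residue from
#' a different conservation class, so by construction the planted columns
#' survive the filter.
#'
#' @param seed Integer RNG seed.
#' @param n_active,n_inactive,n_intermediate Tier counts (robust / none /
#'   intermediate).
#' @param length Sequence length; default 139 (approximate BMP mature
#'   domain).
#' @param rate Per-site, per-lineage background substitution probability;
#'   default 0.015, which yields ~97% pairwise similarity at default
#'   settings.
#' @param planted_positions Planted discriminative columns (1-based root
#'   coordinates); default `c(48, 65, 98)`.
#' @param indel_rate Per-site, per-lineage indel probability (default 0;
#'   indels avoid the first five columns so anchoring is preserved).
#' @param scheme Conservation scheme used to pick cross-class residues.
#' @return A `synthetic_family_spec` list.
#' @export
family_spec <- function(seed = 1L, n_active = 5L, n_inactive = 1L,
                        n_intermediate = 0L, length = 139L, rate = 0.015,
                        planted_positions = c(48L, 65L, 98L),
                        indel_rate = 0, scheme = default_scheme()) {
  if (length < 5) stop("sequence length must be at least 5")
  if (any(planted_positions < 1 | planted_positions > length)) {
    stop("planted positions must lie in [1, length]")
  }
  if (any(planted_positions <= 3)) {
    stop("planted positions must lie downstream of the anchor (position 3)")
  }
  if (rate < 0 || rate > 1 || indel_rate < 0 || indel_rate > 1) {
    stop("rates must be in [0, 1]")
  }
  if (n_active < 1 || n_inactive < 1) {
    stop("need at least one active and one inactive lineage")
  }
  if (length(scheme$classes) < 2) {
    stop("scheme must have at least two classes to plant cross-class residues")
  }
  structure(
    list(seed = as.integer(seed), n_active = as.integer(n_active),
         n_inactive = as.integer(n_inactive),
         n_intermediate = as.integer(n_intermediate),
         length = as.integer(length), rate = rate,
         planted_positions = sort(as.integer(planted_positions)),
         indel_rate = indel_rate, scheme = scheme),
    class = "synthetic_family_spec"
  )
}

#' Generate a synthetic protein family with planted discriminative columns
#'
#' @param spec A [family_spec()].
#' @return A list of class `synthetic_family`:
#'   * `records` — a [protein_family()] tibble (active ids `ACT01...`,
#'     intermediate `INT01...`, inactive `INA01...`; the references are
#'     `ACT01` and `INA01`);
#'   * `phenotypes` — tibble `id`, `tier`;
#'   * `truth` — list with `planted_positions`, `active_residues`,
#'     `inactive_residues`, `expected_candidates` (literal application of
#'     the filter rules to the generated sequences; meaningful only when
#'     `indel_rate = 0`) and `collisions` (background-created candidate
#'     columns beyond the planted set).
#' @export
generate_family <- function(spec) {
  stopifnot(inherits(spec, "synthetic_family_spec"))
  set.seed(spec$seed)
  L <- spec$length
  scheme <- spec$scheme
  planted <- spec$planted_positions

  root <- sample(AA_ALPHABET_20, L, replace = TRUE)
  root[1:2] <- sample(setdiff(AA_ALPHABET_20, "C"), 2, replace = TRUE)
  root[3] <- "C"

  ids <- c(sprintf("ACT%02d", seq_len(spec$n_active)),
           if (spec$n_intermediate > 0) sprintf("INT%02d", seq_len(spec$n_intermediate)),
           sprintf("INA%02d", seq_len(spec$n_inactive)))
  tiers <- c(rep("robust", spec$n_active),
             rep("intermediate", spec$n_intermediate),
             rep("none", spec$n_inactive))

  # planted residues: all active/intermediate share X; inactive lineages get
  # a residue from a different conservation class than X
  active_res <- character(length(planted))
  inactive_res <- character(length(planted))
  for (k in seq_along(planted)) {
    x <- sample(setdiff(AA_ALPHABET_20, "C"), 1)
    other <- AA_ALPHABET_20[scheme$class_of[AA_ALPHABET_20] != scheme$class_of[x]]
    other <- setdiff(other, "C")
    if (!length(other)) stop("scheme leaves no cross-class residue available")
    active_res[k] <- x
    inactive_res[k] <- sample(other, 1)
  }

  frozen <- c(3L, planted)           # never hit by background substitution
  seqs <- character(length(ids))
  for (i in seq_along(ids)) {
    s <- root
    hit <- which(stats::runif(L) < spec$rate)
    hit <- setdiff(hit, frozen)
    for (p in hit) {
      pool <- setdiff(AA_ALPHABET_20, s[p])
      if (p <= 2) pool <- setdiff(pool, "C")  # keep the anchor left-most
      s[p] <- sample(pool, 1)
    }
    s[planted] <- if (tiers[i] == "none") inactive_res else active_res
    if (spec$indel_rate > 0) {
      s <- apply_indels(s, spec$indel_rate)
    }
    seqs[i] <- paste(s, collapse = "")
  }

  records <- protein_family(ids, seqs, tier = tiers, species = "synthetic")

  truth <- list(planted_positions = planted,
                root = paste(root, collapse = ""),
                active_residues = active_res,
                inactive_residues = inactive_res,
                expected_candidates = NA,
                collisions = NA)
  if (spec$indel_rate == 0) {
    expected <- scan_candidate_columns(
      do.call(rbind, strsplit(seqs, "")), ids, tiers, scheme
    )
    truth$expected_candidates <- expected
    truth$collisions <- setdiff(expected, planted)
  }

  structure(list(records = records,
                 phenotypes = tibble::tibble(id = ids, tier = tiers),
                 truth = truth, spec = spec),
            class = "synthetic_family")
}

# literal per-column application of the elimination rules to ungapped,
# equal-length sequences; used for generator ground truth
scan_candidate_columns <- function(mat, ids, tiers, scheme) {
  rownames(mat) <- ids
  inactive <- ids[tiers == "none"][1]
  active_set <- ids[tiers == "robust"]
  active_ref <- active_set[1]
  out <- integer(0)
  for (p in seq_len(ncol(mat))) {
    cls <- classify_pair(mat[inactive, p], mat[active_ref, p], scheme)
    if (cls != "nonconservative") next
    act <- mat[active_set, p]
    if (any(act == mat[inactive, p])) next
    if (any(classify_pair(rep(mat[inactive, p], length(act)), act,
                          scheme) == "conservative")) next
    out <- c(out, p)
  }
  out
}

apply_indels <- function(s, indel_rate) {
  out <- character(0)
  for (p in seq_along(s)) {
    if (p > 5 && stats::runif(1) < indel_rate) {
      if (stats::runif(1) < 0.5) next                     # deletion
      out <- c(out, s[p], sample(AA_ALPHABET_20, 1))      # insertion after
    } else {
      out <- c(out, s[p])
    }
  }
  out
}

#' Write a synthetic family to disk
#'
#' @param fam A `synthetic_family`.
#' @param dir Output directory (created if needed); writes `family.fasta`,
#'   `phenotypes.tsv` and `truth.json`.
#' @return `dir`, invisibly.
#' @export
write_synthetic_family <- function(fam, dir) {
  stopifnot(inherits(fam, "synthetic_family"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_family_fasta(fam$records, file.path(dir, "family.fasta"))
  utils::write.table(fam$phenotypes, file.path(dir, "phenotypes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(fam$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Specify simulated assay measurements per activity tier
#'
#' Defaults emulate the published orientation-angle structure: robust
#' responders around 32 +/- 6 degrees, intermediate 16 +/- 5, weak/none
#' 5 +/- 5 and control -3 +/- 4, with 12 measurements per group.
#'
#' @param seed Integer RNG seed.
#' @param assay Assay kind (see [assay_summary()]).
#' @param tier_mean,tier_sd Named numeric vectors over
#'   `robust`, `intermediate`, `none`, `control`.
#' @param n Measurements per group; scalar or named vector like
#'   `tier_mean`.
#' @return An `assay_sim_spec` list.
#' @export
assay_sim_spec <- function(seed = 1L, assay = "orientation_angle_deg",
                           tier_mean = c(robust = 32, intermediate = 16,
                                         none = 5, control = -3),
                           tier_sd = c(robust = 6, intermediate = 5,
                                       none = 5, control = 4),
                           n = 12L) {
  if (any(tier_sd <= 0)) stop("tier sds must be > 0")
  if (length(n) == 1) n <- stats::setNames(rep(n, length(tier_mean)), names(tier_mean))
  if (any(n < 2)) stop("group sizes must be >= 2")
  structure(list(seed = as.integer(seed), assay = assay,
                 tier_mean = tier_mean, tier_sd = tier_sd,
                 n = stats::setNames(as.integer(round(n)), names(n))),
            class = "assay_sim_spec")
}

#' Simulate raw assay measurements and their group summaries
#'
#' Draws per-group Gaussian measurements with tier-specific mean and SD,
#' then summarizes each group as (mean, SEM, n) exactly as figure legends
#' report them. A `control` group is always appended.
#'
#' @param sim_spec An [assay_sim_spec()].
#' @param phenotypes Tibble `id`, `tier` naming the treatment groups.
#' @return List with `raw` (tibble `label`, `tier`, `value`) and
#'   `summaries` (tibble `label`, `assay`, `mean`, `sem`, `n`, `tier`).
#' @export
generate_assays <- function(sim_spec, phenotypes) {
  stopifnot(inherits(sim_spec, "assay_sim_spec"))
  set.seed(sim_spec$seed)
  groups <- rbind(as.data.frame(phenotypes[, c("id", "tier")]),
                  data.frame(id = "control", tier = "control"))
  raw <- list()
  summaries <- list()
  for (i in seq_len(nrow(groups))) {
    tier <- groups$tier[i]
    if (!tier %in% names(sim_spec$tier_mean)) {
      stop("no simulation parameters for tier: ", tier)
    }
    ni <- sim_spec$n[[tier]]
    v <- stats::rnorm(ni, sim_spec$tier_mean[[tier]], sim_spec$tier_sd[[tier]])
    raw[[i]] <- tibble::tibble(label = groups$id[i], tier = tier, value = v)
    summaries[[i]] <- tibble::tibble(
      label = groups$id[i], assay = sim_spec$assay,
      mean = mean(v), sem = stats::sd(v) / sqrt(ni), n = ni, tier = tier
    )
  }
  list(raw = do.call(rbind, raw), summaries = do.call(rbind, summaries))
}
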