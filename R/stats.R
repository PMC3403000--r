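#' Build an assay summary group
#'
#' Group-level summary of one treatment in one assay, as printed in figure
#' legends: label, assay kind, mean, standard error of the mean and group
#' size.
#'
#' @param label Group label (e.g. `"BMP7"`).
#' @param assay One of `"orientation_angle_deg"`, `"growth_cone_area_um2"`,
#'   `"collapse_percent"`, `"induction_percent"`.
#' @param mean,sem Group mean and SEM in assay units (`sem >= 0`).
#' @param n Positive integer group size.
#' @return A one-row tibble of class `assay_summary`.
#' @export
assay_summary <- function(label, assay, mean, sem, n) {
  assay <- match.arg(assay, c("orientation_angle_deg", "growth_cone_area_um2",
                              "collapse_percent", "induction_percent"))
  if (sem < 0) stop("sem must be >= 0")
  if (n < 1 || n != round(n)) stop("n must be a positive integer")
  out <- tibble::tibble(label = label, assay = assay, mean = mean,
                        sem = sem, n = as.integer(n))
  class(out) <- c("assay_summary", class(out))
  out
}

#' Read a table of assay summaries
#'
#' @param path TSV with header columns `label`, `assay`, `mean`, `sem`,
#'   `n`; extra columns are kept.
#' @return A tibble.
#' @export
read_assay_summaries <- function(path) {
  if (!file.exists(path)) stop("assay summary file not found: ", path)
  x <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- setdiff(c("label", "assay", "mean", "sem", "n"), names(x))
  if (length(need)) stop("assay table lacks column(s): ", paste(need, collapse = ", "))
  tibble::as_tibble(x)
}

#' Path to a packaged reference assay-summary table
#'
#' The package ships TSV transcriptions of the published group summaries
#' (mean, SEM, n) for the mouse BMP explant assays it targets:
#' `"bmp_orientation_angles"`, `"bmp_induction"`, `"growth_cone_areas"`,
#' `"chimera_collapse"`, `"chimera_orientation_angles"`,
#' `"chimera_induction"`, plus the phenotype table `"bmp_phenotypes"`.
#'
#' @param name Table name as above.
#' @return File path inside the installed package.
#' @export
bmp_assay_path <- function(name = c("bmp_orientation_angles", "bmp_induction",
                                    "growth_cone_areas", "chimera_collapse",
                                    "chimera_orientation_angles",
                                    "chimera_induction", "bmp_phenotypes")) {
  name <- match.arg(name)
  p <- system.file("extdata", paste0(name, ".tsv"), package = "bmporient")
  if (!nzchar(p)) stop("packaged table not found: ", name)
  p
}

sd_from_sem <- function(sem, n) sem * sqrt(n)

#' Two-sample t-test reconstructed from group summaries
#'
#' Rebuilds the two-sample t statistic from (mean, SEM, n) per group.
#' The pooled (Student) variant reconstructs each group SD as
#' `sem * sqrt(n)`, pools variances with `n - 1` weights and uses
#' `n_a + n_b - 2` degrees of freedom; the Welch variant uses
#' `t = diff / sqrt(sem_a^2 + sem_b^2)` with Welch-Satterthwaite degrees of
#' freedom. P-values are two-tailed.
#'
#' @param a,b One-row data frames (or named lists) with `mean`, `sem`, `n`
#'   and optionally `assay` and `label`.
#' @param variant `"pooled"` (default) or `"welch"`.
#' @return A `summary_test` list: `statistic`, `df`, `p`, `method`,
#'   `estimate` (mean difference a - b).
#' @examples
#' a <- assay_summary("BMP5", "orientation_angle_deg", 16.1, 1.8, 28)
#' b <- assay_summary("BMP6", "orientation_angle_deg", 7.0, 2.2, 24)
#' ttest_from_summary(a, b)$p  # ~0.0022
#' @export
ttest_from_summary <- function(a, b, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  a <- as.list(a); b <- as.list(b)
  if (!is.null(a$assay) && !is.null(b$assay) && !identical(a$assay, b$assay)) {
    stop("groups measure different assays: ", a$assay, " vs ", b$assay)
  }
  if (a$n < 2 || b$n < 2) stop("both groups need n >= 2")
  diff <- a$mean - b$mean
  if (variant == "pooled") {
    va <- sd_from_sem(a$sem, a$n)^2
    vb <- sd_from_sem(b$sem, b$n)^2
    df <- a$n + b$n - 2
    sp2 <- ((a$n - 1) * va + (b$n - 1) * vb) / df
    se <- sqrt(sp2 * (1 / a$n + 1 / b$n))
    method <- "Two-sample t-test from summaries (pooled variance)"
  } else {
    se <- sqrt(a$sem^2 + b$sem^2)
    df <- (a$sem^2 + b$sem^2)^2 /
      (a$sem^4 / (a$n - 1) + b$sem^4 / (b$n - 1))
    method <- "Welch two-sample t-test from summaries"
  }
  tstat <- if (se == 0) {
    if (diff == 0) 0 else sign(diff) * Inf
  } else diff / se
  p <- 2 * stats::pt(-abs(tstat), df)
  structure(list(statistic = tstat, df = df, p = p, method = method,
                 estimate = diff,
                 labels = c(a$label %||% "a", b$label %||% "b")),
            class = "summary_test")
}

#' One-way ANOVA reconstructed from group summaries
#'
#' Fixed-effects one-way ANOVA from (mean, SEM, n) per group: the
#' between-group sum of squares is the n-weighted squared deviation of the
#' group means about the weighted grand mean; the within-group sum of
#' squares is `sum((n_i - 1) * (sem_i * sqrt(n_i))^2)`. The p-value is the
#' upper tail of the F distribution.
#'
#' @param groups Data frame with columns `mean`, `sem`, `n` (one row per
#'   group; optional `assay` must be constant).
#' @return A `summary_test` list with `statistic` (F), `df` (numerator,
#'   denominator), `p` and `method`.
#' @export
anova_from_summary <- function(groups) {
  groups <- as.data.frame(groups)
  if (nrow(groups) < 2) stop("ANOVA needs at least 2 groups")
  if ("assay" %in% names(groups) && length(unique(groups$assay)) > 1) {
    stop("groups measure different assays")
  }
  if (any(groups$n < 2)) stop("every group needs n >= 2")
  k <- nrow(groups)
  N <- sum(groups$n)
  grand <- sum(groups$n * groups$mean) / N
  ssb <- sum(groups$n * (groups$mean - grand)^2)
  ssw <- sum((groups$n - 1) * sd_from_sem(groups$sem, groups$n)^2)
  df1 <- k - 1
  df2 <- N - k
  msb <- ssb / df1
  msw <- ssw / df2
  f <- if (msw == 0) { if (msb == 0) 0 else Inf } else msb / msw
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  structure(list(statistic = f, df = c(df1, df2), p = p,
                 method = "One-way ANOVA from summaries",
                 estimate = c(ss_between = ssb, ss_within = ssw)),
            class = "summary_test")
}

#' @export
print.summary_test <- function(x, ...) {
  cat(x$method, "\n")
  if (length(x$df) == 2) {
    cat(sprintf("  F(%g, %g) = %.4f, p = %.4g\n", x$df[1], x$df[2],
                x$statistic, x$p))
  } else {
    cat(sprintf("  t(%g) = %.4f, p = %.4g\n", x$df, x$statistic, x$p))
  }
  invisible(x)
}

#' Percent change of a treated mean relative to control
#'
#' Positive values are reductions: `100 * (control - treated) / control`.
#'
#' @param treated_mean,control_mean Group means; `control_mean` must be
#'   positive.
#' @return Signed percentage.
#' @examples
#' percent_change(79.5, 114.3)  # 30.4% reduction in growth-cone area
#' @export
percent_change <- function(treated_mean, control_mean) {
  if (any(control_mean <= 0)) stop("control mean must be > 0")
  100 * (control_mean - treated_mean) / control_mean
}

#' Fold change implied by a percent increase over control
#'
#' @param pct_over_control Percent increase relative to control
#'   (>= -100); e.g. induction of 174% over control is a 2.74-fold level.
#' @return Fold change `1 + pct/100`.
#' @export
fold_from_percent_increase <- function(pct_over_control) {
  if (any(pct_over_control < -100)) stop("percent increase cannot be below -100")
  1 + pct_over_control / 100
}

#' Classify activity tiers from orientation-angle summaries
#'
#' Formalizes a three-tier decision rule over group summaries: a group is
#' `none` when it is not significantly different from the control group at
#' level `alpha` (two-tailed t from summaries); `robust` when it differs
#' from control but not from the strongest (top) group; `intermediate`
#' when it differs from both. The full p-value table is returned so
#' borderline calls can be audited.
#'
#' @param groups Data frame of summaries (`label`, `mean`, `sem`, `n`),
#'   excluding the control row if `control` is supplied separately.
#' @param control One-row summary of the control group.
#' @param top_group One-row summary of the strongest responder used as the
#'   upper anchor.
#' @param alpha Two-tailed significance level (default 0.05).
#' @param variant Passed to [ttest_from_summary()].
#' @return A tibble `label`, `p_vs_control`, `p_vs_top`, `tier`.
#' @export
classify_activity <- function(groups, control, top_group, alpha = 0.05,
                              variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  groups <- as.data.frame(groups)
  control <- as.list(control)
  top_group <- as.list(top_group)
  res <- lapply(seq_len(nrow(groups)), function(i) {
    g <- as.list(groups[i, ])
    p_ctrl <- ttest_from_summary(g, control, variant)$p
    p_top <- if (identical(g$label, top_group$label)) 1 else {
      ttest_from_summary(g, top_group, variant)$p
    }
    tier <- if (p_ctrl >= alpha) "none"
      else if (p_top >= alpha) "robust"
      else "intermediate"
    tibble::tibble(label = g$label, p_vs_control = p_ctrl,
                   p_vs_top = p_top, tier = tier)
  })
  do.call(rbind, res)
}
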