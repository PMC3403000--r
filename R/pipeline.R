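#' Build a pipeline configuration
#'
#' Collects paths, references and flags for [run_pipeline()]. A config may
#' also be loaded from a YAML or JSON file with [read_pipeline_config()];
#' arguments given here override file values.
#'
#' @param fasta Path to the family FASTA.
#' @param phenotypes Path to the phenotype TSV (`id`, `tier`).
#' @param assays Optional path to an assay summary TSV (`label`, `assay`,
#'   `mean`, `sem`, `n`); enables the statistics section of the report.
#' @param out_dir Output directory for the report bundle.
#' @param inactive_id,active_id References for the elimination filter.
#' @param reference_id Numbering reference (default `active_id`).
#' @param control_label,top_label Group labels used by
#'   [classify_activity()] when `assays` is given.
#' @param alpha Significance level.
#' @param include_intermediate,trim_to_anchor,welch Logical flags.
#' @param seed Integer seed recorded in the report (the pipeline itself is
#'   deterministic; the seed matters when the config points at simulated
#'   inputs).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(fasta, phenotypes, assays = NULL,
                            out_dir = "bmporient-out",
                            inactive_id = "BMP6", active_id = "BMP7",
                            reference_id = NULL,
                            control_label = "pMT23", top_label = NULL,
                            alpha = 0.05, include_intermediate = FALSE,
                            trim_to_anchor = FALSE, welch = FALSE,
                            seed = 1L) {
  structure(list(fasta = fasta, phenotypes = phenotypes, assays = assays,
                 out_dir = out_dir, inactive_id = inactive_id,
                 active_id = active_id,
                 reference_id = reference_id %||% active_id,
                 control_label = control_label, top_label = top_label,
                 alpha = alpha,
                 include_intermediate = isTRUE(include_intermediate),
                 trim_to_anchor = isTRUE(trim_to_anchor),
                 welch = isTRUE(welch), seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path Config file; keys as in [pipeline_config()].
#' @param ... Overrides applied on top of the file values.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, ...) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  over <- list(...)
  vals[names(over)] <- over
  do.call(pipeline_config, vals)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage: %s] %s", name, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full comparative-analysis pipeline
#'
#' Executes read, align, anchor, similarity, tree, candidate-calling
#' and (optionally) assay statistics, writing a report bundle to
#' `config$out_dir`: aligned FASTA, a numbered alignment table, similarity
#' and distance TSVs, a newick dendrogram, the candidate audit TSV/JSON,
#' statistics TSVs, plus `report.md` and `report.json` echoing the
#' headline outputs. When the phenotype table assigns tiers and assay
#' summaries are supplied, computed tiers are compared against the
#' supplied ones and mismatches are surfaced as a warning (not an error):
#' published tier narratives are not always consistent with their own
#' printed summary statistics.
#'
#' @param config A [pipeline_config()] or path to a YAML/JSON config file.
#' @return The report as a list, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)

  fam <- stage("read", {
    if (!file.exists(config$fasta)) stop("FASTA not found: ", config$fasta)
    if (!is.null(config$phenotypes) && !file.exists(config$phenotypes)) {
      stop("phenotype file not found: ", config$phenotypes)
    }
    read_family(config$fasta, config$phenotypes)
  })
  aln <- stage("align", align_family(fam, reference_id = config$reference_id))
  aln <- stage("anchor", {
    a <- find_anchor(aln)
    if (config$trim_to_anchor) trim_to_anchor(a) else a
  })
  stage("write-alignment", {
    write_alignment_fasta(aln, out("alignment.fasta"))
    write_alignment_table(aln, out("alignment.txt"))
  })

  sim <- stage("similarity", similarity_matrix(aln))
  stage("write-similarity", {
    utils::write.table(cbind(id = rownames(sim), as.data.frame(round(sim, 2))),
                       out("similarity.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  })

  tree <- NULL
  newick <- NA_character_
  if (nrow(fam) >= 3) {
    tree <- stage("tree", neighbor_joining(distance_from_alignment(aln)))
    stage("write-tree", {
      write_distance_tsv(distance_from_alignment(aln), out("distance.tsv"))
      write_newick(tree, out("tree.nwk"))
    })
    newick <- ape::write.tree(tree)
  }

  report_cand <- stage("candidates", {
    rep <- call_candidates(aln, config$inactive_id, config$active_id,
                           include_intermediate = config$include_intermediate)
    write_candidate_report(rep, out("candidates.tsv"), out("candidates.json"))
    rep
  })
  diffs <- report_cand$audits
  n_noncons <- sum(diffs$pair_class == "nonconservative")

  stats_block <- NULL
  if (!is.null(config$assays)) {
    stats_block <- stage("stats", {
      gs <- read_assay_summaries(config$assays)
      variant <- if (config$welch) "welch" else "pooled"
      labs <- gs$label
      tt <- list()
      for (i in seq_len(nrow(gs) - 1)) {
        for (j in seq((i + 1), nrow(gs))) {
          r <- ttest_from_summary(gs[i, ], gs[j, ], variant)
          tt[[length(tt) + 1]] <- tibble::tibble(
            a = labs[i], b = labs[j], t = r$statistic, df = r$df, p = r$p
          )
        }
      }
      ttab <- do.call(rbind, tt)
      utils::write.table(ttab, out("ttests.tsv"), sep = "\t", quote = FALSE,
                         row.names = FALSE)
      av <- anova_from_summary(gs[gs$label != config$control_label, ])
      tiers <- NULL
      if (!is.null(config$control_label) &&
          config$control_label %in% labs) {
        ctrl <- gs[gs$label == config$control_label, ]
        rest <- gs[gs$label != config$control_label, ]
        top_lab <- config$top_label %||% rest$label[which.max(rest$mean)]
        tiers <- classify_activity(rest, ctrl,
                                   gs[gs$label == top_lab, ],
                                   alpha = config$alpha, variant = variant)
        utils::write.table(tiers, out("tiers.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        ph <- tryCatch(read_phenotypes(config$phenotypes), error = function(e) NULL)
        if (!is.null(ph)) {
          cmp <- merge(tiers, ph, by.x = "label", by.y = "id")
          bad <- cmp$label[cmp$tier.x != cmp$tier.y & cmp$tier.y != "unknown"]
          if (length(bad)) {
            warning("computed tier disagrees with supplied phenotype for: ",
                    paste(bad, collapse = ", "),
                    " (summary statistics may contradict the narrative tier)")
          }
        }
      }
      list(ttests = ttab, anova = list(F = av$statistic, df = av$df, p = av$p),
           tiers = tiers)
    })
  }

  report <- list(
    config = unclass(config),
    n_records = nrow(fam),
    anchor_column = aln$anchor_column,
    similarity = round(sim, 4),
    nonconservative_difference_count = n_noncons,
    candidates = report_cand$candidates,
    active_set = report_cand$active_set,
    tree_newick = newick,
    stats = if (!is.null(stats_block)) {
      list(anova = stats_block$anova, tiers = stats_block$tiers)
    }
  )
  stage("report", {
    jsonlite::write_json(report, out("report.json"), auto_unbox = TRUE,
                         pretty = TRUE, digits = NA, force = TRUE)
    writeLines(render_report_md(report, report_cand), out("report.md"))
  })
  invisible(report)
}

render_report_md <- function(report, cand) {
  lines <- c(
    "# Comparative BMP family analysis",
    "",
    sprintf("- records: %d", report$n_records),
    sprintf("- anchor column: %d (reference position 3)", report$anchor_column),
    sprintf("- non-conservative differences (%s vs %s): %d",
            cand$inactive_reference, cand$active_reference,
            report$nonconservative_difference_count),
    sprintf("- candidate determinant positions: %s",
            if (length(report$candidates)) {
              paste(report$candidates, collapse = ", ")
            } else "(none)"),
    sprintf("- active set: %s", paste(report$active_set, collapse = ", ")),
    "",
    "## Pairwise percent similarity", ""
  )
  sim <- report$similarity
  lines <- c(lines,
             paste0("| | ", paste(colnames(sim), collapse = " | "), " |"),
             paste0("|", paste(rep("---", ncol(sim) + 1), collapse = "|"), "|"))
  for (i in seq_len(nrow(sim))) {
    lines <- c(lines, paste0("| ", rownames(sim)[i], " | ",
                             paste(sprintf("%.1f", sim[i, ]), collapse = " | "),
                             " |"))
  }
  if (!is.null(report$stats)) {
    lines <- c(lines, "", "## Assay statistics", "",
               sprintf("- one-way ANOVA: F(%g, %g) = %.4f, p = %.4f",
                       report$stats$anova$df[1], report$stats$anova$df[2],
                       report$stats$anova$F, report$stats$anova$p))
    if (!is.null(report$stats$tiers)) {
      t <- report$stats$tiers
      lines <- c(lines, "", "| group | p vs control | p vs top | tier |",
                 "|---|---|---|---|",
                 sprintf("| %s | %.4g | %.4g | %s |",
                         t$label, t$p_vs_control, t$p_vs_top, t$tier))
    }
  }
  if (!is.na(report$tree_newick)) {
    lines <- c(lines, "", "## Dendrogram (newick)", "", "```",
               report$tree_newick, "```")
  }
  lines
}
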