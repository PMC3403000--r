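#' Audit every alignment column for differences between two references
#'
#' Compares the residues of an inactive (non-orienting) reference and an
#' active (orienting) reference at every alignment column and classifies
#' the substitution under the conservation scheme. Columns where either
#' reference has a gap are classified `gap`.
#'
#' @param alignment An anchored `mature_alignment` (see [find_anchor()]).
#' @param inactive_id,active_id Record ids of the two references
#'   (e.g. `"BMP6"` and `"BMP7"`).
#' @param scheme A [conservation_scheme()].
#' @return A tibble with one row per alignment column: `column` (alignment
#'   column index), `ref_position` (reference numbering; `NA` at
#'   reference-row gaps), `inactive`, `active` (the two residues) and
#'   `pair_class`.
#' @export
difference_positions <- function(alignment, inactive_id, active_id,
                                 scheme = default_scheme()) {
  stopifnot(inherits(alignment, "mature_alignment"))
  if (is.na(alignment$anchor_column)) alignment <- find_anchor(alignment)
  for (id in c(inactive_id, active_id)) {
    if (!id %in% rownames(alignment$mat)) stop("id not in alignment: ", id)
  }
  a <- alignment$mat[inactive_id, ]
  b <- alignment$mat[active_id, ]
  tibble::tibble(
    column = seq_along(a),
    ref_position = alignment$ref_position,
    inactive = unname(a),
    active = unname(b),
    pair_class = classify_pair(a, b, scheme)
  )
}

#' Call candidate determinant positions by phenotype-stratified elimination
#'
#' Implements the residue-elimination filter: starting from the columns at
#' which the inactive reference differs non-conservatively from the active
#' reference, a column is eliminated if the inactive reference's residue is
#' (i) identical to the residue of any robustly active family member at
#' that column (`eliminated_shared_identical`), or (ii) a conservative
#' substitution of any such residue (`eliminated_conservative_with_active`).
#' Surviving columns are the candidate determinants of the phenotype.
#'
#' @inheritParams difference_positions
#' @param include_intermediate Also admit intermediate-tier records into
#'   the active comparison set (default `FALSE`: the filter is run against
#'   robust-tier records only).
#' @param active_ids Optional explicit active comparison set, overriding
#'   tier-based selection. Must contain at least one id besides
#'   `inactive_id`.
#' @return An object of class `candidate_report`: list with
#'   `inactive_reference`, `active_reference`, `active_set`, `audits` (the
#'   per-column tibble of [difference_positions()] extended with `verdict`
#'   and list-column `evidence`), and `candidates` (ascending reference
#'   positions of retained columns).
#' @export
call_candidates <- function(alignment, inactive_id, active_id,
                            scheme = default_scheme(),
                            include_intermediate = FALSE,
                            active_ids = NULL) {
  stopifnot(inherits(alignment, "mature_alignment"))
  if (is.na(alignment$anchor_column)) alignment <- find_anchor(alignment)
  if (is.null(active_ids)) {
    tiers <- c("robust", if (include_intermediate) "intermediate")
    active_ids <- alignment$records$id[alignment$records$tier %in% tiers]
    active_ids <- union(active_ids, active_id)
  } else {
    missing <- setdiff(active_ids, rownames(alignment$mat))
    if (length(missing)) stop("active id(s) not in alignment: ",
                              paste(missing, collapse = ", "))
  }
  active_ids <- setdiff(active_ids, inactive_id)
  if (length(setdiff(active_ids, active_id)) < 1) {
    stop("active set must contain at least one record besides ", active_id)
  }

  audits <- difference_positions(alignment, inactive_id, active_id, scheme)
  verdict <- rep("not_different", nrow(audits))
  evidence <- vector("list", nrow(audits))
  for (i in which(audits$pair_class == "nonconservative")) {
    res_in <- audits$inactive[i]
    act_res <- stats::setNames(alignment$mat[active_ids, audits$column[i]],
                               active_ids)
    act_res <- act_res[act_res != GAP_CHAR]
    if (!length(act_res)) {
      verdict[i] <- "retained"
      next
    }
    shared <- names(act_res)[act_res == res_in]
    if (length(shared)) {
      verdict[i] <- "eliminated_shared_identical"
      evidence[[i]] <- shared
      next
    }
    conserv <- names(act_res)[
      classify_pair(rep(res_in, length(act_res)), act_res, scheme) == "conservative"
    ]
    if (length(conserv)) {
      verdict[i] <- "eliminated_conservative_with_active"
      evidence[[i]] <- conserv
    } else {
      verdict[i] <- "retained"
    }
  }
  audits$verdict <- verdict
  audits$evidence <- evidence

  cand <- sort(audits$ref_position[audits$verdict == "retained"])
  structure(
    list(
      inactive_reference = inactive_id,
      active_reference = active_id,
      active_set = sort(active_ids),
      scheme = scheme$name,
      audits = audits,
      candidates = as.integer(cand)
    ),
    class = "candidate_report"
  )
}

#' @export
print.candidate_report <- function(x, ...) {
  cat(sprintf("Candidate determinant positions: %s vs %s\n",
              x$inactive_reference, x$active_reference))
  cat("  active set:", paste(x$active_set, collapse = ", "), "\n")
  nd <- table(x$audits$verdict)
  cat("  columns:", paste(sprintf("%s=%d", names(nd), nd), collapse = ", "), "\n")
  cat("  candidates:", if (length(x$candidates)) {
    paste(x$candidates, collapse = ", ")
  } else "(none)", "\n")
  invisible(x)
}

#' Leave-one-active-out stability of candidate positions
#'
#' Re-runs the elimination filter with each active-set member removed in
#' turn. Removing a member can only remove elimination evidence, so every
#' original candidate is retained and new candidates may appear; the
#' function reports both.
#'
#' @param report A `candidate_report` from [call_candidates()].
#' @param alignment The anchored alignment the report was computed from.
#' @param scheme A [conservation_scheme()]; should match the report.
#' @return A tibble with columns `dropped` (the removed active-set member),
#'   `candidate` (reference position), and `status`: `"retained"` for an
#'   original candidate that survives, `"gained"` for a new candidate, or
#'   `"undefined"` when dropping the member leaves no valid active set.
#' @export
candidate_stability <- function(report, alignment, scheme = default_scheme()) {
  stopifnot(inherits(report, "candidate_report"))
  out <- list()
  for (drop_id in setdiff(report$active_set, report$active_reference)) {
    reduced <- setdiff(report$active_set, drop_id)
    res <- tryCatch(
      call_candidates(alignment,
                      inactive_id = report$inactive_reference,
                      active_id = report$active_reference,
                      scheme = scheme, active_ids = reduced),
      error = function(e) NULL
    )
    if (is.null(res)) {
      out[[drop_id]] <- tibble::tibble(
        dropped = drop_id,
        candidate = if (length(report$candidates)) report$candidates else NA_integer_,
        status = "undefined"
      )
      next
    }
    status <- c(
      stats::setNames(rep("retained", length(report$candidates)),
                      report$candidates)[
                        as.character(intersect(report$candidates, res$candidates))],
      stats::setNames(rep("gained", length(setdiff(res$candidates, report$candidates))),
                      setdiff(res$candidates, report$candidates))
    )
    out[[drop_id]] <- tibble::tibble(
      dropped = drop_id,
      candidate = as.integer(names(status)),
      status = unname(status)
    )
  }
  do.call(rbind, out)
}

#' Write a candidate report as TSV (audits) and JSON (summary)
#'
#' @param report A `candidate_report`.
#' @param tsv_path,json_path Output paths; `NULL` skips that output.
#' @export
write_candidate_report <- function(report, tsv_path = NULL, json_path = NULL) {
  if (!is.null(tsv_path)) {
    audits <- report$audits
    audits$evidence <- vapply(audits$evidence, function(e) {
      paste(e, collapse = ",")
    }, character(1))
    utils::write.table(audits, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(inactive_reference = report$inactive_reference,
           active_reference = report$active_reference,
           active_set = report$active_set,
           scheme = report$scheme,
           candidates = report$candidates),
      json_path, auto_unbox = TRUE, pretty = TRUE
    )
  }
  invisible(report)
}
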