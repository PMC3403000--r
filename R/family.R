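#' Build a protein family table
#'
#' A protein family is a tibble with one row per mature-domain sequence and
#' columns `id`, `species`, `sequence` and `tier`. Tiers describe axon
#' orienting activity: `robust`, `intermediate`, `none` or `unknown`.
#'
#' @param id Character vector of unique short labels (e.g. `"BMP7"`).
#' @param sequence Character vector of ungapped amino-acid strings over the
#'   20-letter alphabet. Lowercase input is uppercased; ambiguity codes
#'   (B, J, O, U, X, Z) are rejected.
#' @param tier Activity tier per record; defaults to `"unknown"`.
#' @param species Free-text species per record.
#' @return A tibble of class `protein_family`.
#' @export
protein_family <- function(id, sequence, tier = "unknown", species = "") {
  id <- as.character(id)
  sequence <- toupper(as.character(sequence))
  tier <- rep_len(as.character(tier), length(id))
  species <- rep_len(as.character(species), length(id))
  if (length(id) != length(sequence)) {
    stop("`id` and `sequence` must have the same length")
  }
  if (anyDuplicated(id)) {
    stop("duplicate record id(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  if (any(!nzchar(sequence))) {
    stop("empty sequence for record(s): ", paste(id[!nzchar(sequence)], collapse = ", "))
  }
  for (i in seq_along(sequence)) {
    chars <- strsplit(sequence[i], "", fixed = TRUE)[[1]]
    bad <- which(!chars %in% AA_ALPHABET_20)
    if (length(bad)) {
      stop(sprintf("illegal residue '%s' at position %d of record '%s'",
                   chars[bad[1]], bad[1], id[i]))
    }
  }
  bad_tier <- setdiff(unique(tier), c("robust", "intermediate", "none", "unknown"))
  if (length(bad_tier)) {
    stop("unknown activity tier(s): ", paste(bad_tier, collapse = ", "))
  }
  out <- tibble::tibble(id = id, species = species, sequence = sequence, tier = tier)
  class(out) <- c("protein_family", class(out))
  out
}

#' Read a protein family from FASTA plus a phenotype table
#'
#' Reads mature-domain amino-acid sequences from FASTA and attaches activity
#' tiers from a tab-separated phenotype table with header columns `id`,
#' `tier` (and optionally `species`, `notes`). FASTA records missing from
#' the phenotype table get `tier = "unknown"` with a warning.
#'
#' @param fasta_path Path to a FASTA file of ungapped amino-acid sequences.
#' @param phenotype_path Optional path to the phenotype TSV; `NULL` leaves
#'   all tiers `"unknown"`.
#' @return A [protein_family()] tibble in FASTA order.
#' @export
read_family <- function(fasta_path, phenotype_path = NULL) {
  if (!file.exists(fasta_path)) stop("FASTA file not found: ", fasta_path)
  aa <- Biostrings::readAAStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(aa))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA id(s): ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  tier <- rep("unknown", length(ids))
  species <- rep("", length(ids))
  if (!is.null(phenotype_path)) {
    ph <- read_phenotypes(phenotype_path)
    hit <- match(ids, ph$id)
    missing <- ids[is.na(hit)]
    if (length(missing)) {
      warning("no phenotype entry for: ", paste(missing, collapse = ", "),
              "; tier set to 'unknown'")
    }
    tier[!is.na(hit)] <- ph$tier[hit[!is.na(hit)]]
    if ("species" %in% names(ph)) {
      species[!is.na(hit)] <- ph$species[hit[!is.na(hit)]]
    }
  }
  protein_family(id = ids, sequence = as.character(aa), tier = tier,
                 species = species)
}

#' Read a phenotype table
#'
#' @param path TSV with header columns `id` and `tier`; extra columns are
#'   kept.
#' @return A tibble with at least `id` and `tier`.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("phenotype file not found: ", path)
  ph <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE)
  need <- setdiff(c("id", "tier"), names(ph))
  if (length(need)) {
    stop("phenotype table lacks column(s): ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(ph$id)) stop("duplicate id(s) in phenotype table")
  tibble::as_tibble(ph)
}

#' Write a protein family to FASTA
#'
#' @param records A [protein_family()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_family_fasta <- function(records, path) {
  aa <- Biostrings::AAStringSet(stats::setNames(records$sequence, records$id))
  Biostrings::writeXStringSet(aa, filepath = path, width = 60)
  invisible(path)
}
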