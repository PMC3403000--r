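#' @keywords internal
AA_ALPHABET_20 <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

GAP_CHAR <- "-"

#' Define a conservation scheme
#'
#' A conservation scheme is a partition of the 20 standard amino acids into
#' disjoint physicochemical classes. Two distinct residues in the same class
#' are treated as a conservative substitution; residues in different classes
#' are non-conservative. The scheme drives both percent-similarity
#' computation and the residue-elimination filter.
#'
#' @param name Short label for the scheme.
#' @param classes Named list of character vectors; together the vectors must
#'   contain each of the 20 standard amino acids exactly once.
#' @return An object of class `conservation_scheme`: a list with elements
#'   `name`, `classes` and `class_of` (a named lookup vector mapping each
#'   residue to its class label).
#' @examples
#' sch <- default_scheme()
#' classify_pair("Q", "R", sch)  # non-conservative
#' @export
conservation_scheme <- function(name, classes) {
  if (is.null(names(classes)) || any(!nzchar(names(classes)))) {
    names(classes) <- paste0("class", seq_along(classes))
  }
  members <- toupper(unlist(classes, use.names = FALSE))
  if (anyDuplicated(members)) {
    stop("conservation scheme classes overlap: ",
         paste(unique(members[duplicated(members)]), collapse = ", "))
  }
  missing <- setdiff(AA_ALPHABET_20, members)
  extra <- setdiff(members, AA_ALPHABET_20)
  if (length(missing)) {
    stop("conservation scheme does not cover: ", paste(missing, collapse = ", "))
  }
  if (length(extra)) {
    stop("conservation scheme contains non-standard symbols: ",
         paste(extra, collapse = ", "))
  }
  class_of <- stats::setNames(
    rep(names(classes), lengths(classes)),
    toupper(unlist(classes, use.names = FALSE))
  )
  structure(
    list(name = name, classes = lapply(classes, toupper), class_of = class_of),
    class = "conservation_scheme"
  )
}

#' Default fine-grained physicochemical conservation scheme
#'
#' Partitions the amino acids into eight classes: small/aliphatic
#' \{A,G,I,L,V\}, hydroxyl \{S,T\}, amide \{N,Q\}, acidic \{D,E\}, basic
#' \{H,K,R\}, aromatic \{F,W,Y\}, sulfur-containing \{C,M\} and proline
#' \{P\}. These fine classes deliberately score Gln/Arg, Asn/Tyr, Tyr/Thr
#' and Lys/Glu exchanges as non-conservative — the classifications required
#' to reproduce the BMP6/BMP7 comparison — whereas coarser schemes built on
#' positive substitution-matrix scores would call Gln/Arg conservative.
#'
#' @return A `conservation_scheme`.
#' @export
default_scheme <- function() {
  conservation_scheme(
    name = "fine-physicochemical",
    classes = list(
      aliphatic = c("A", "G", "I", "L", "V"),
      hydroxyl  = c("S", "T"),
      amide     = c("N", "Q"),
      acidic    = c("D", "E"),
      basic     = c("H", "K", "R"),
      aromatic  = c("F", "W", "Y"),
      sulfur    = c("C", "M"),
      proline   = "P"
    )
  )
}

#' @export
print.conservation_scheme <- function(x, ...) {
  cat("Conservation scheme:", x$name, "\n")
  for (nm in names(x$classes)) {
    cat(sprintf("  %-10s {%s}\n", nm, paste(x$classes[[nm]], collapse = ",")))
  }
  invisible(x)
}

#' Classify a substitution between two aligned residues
#'
#' @param a,b Character vectors of single residues (or the gap symbol `-`).
#'   Recycled to a common length.
#' @param scheme A [conservation_scheme()].
#' @return Character vector over \{"identical", "conservative",
#'   "nonconservative", "gap"\}. The classification is symmetric in `a`
#'   and `b`, and any pair involving a gap is classified `"gap"`.
#' @examples
#' classify_pair(c("A", "Q", "N", "-"), c("A", "R", "Q", "K"), default_scheme())
#' @export
classify_pair <- function(a, b, scheme = default_scheme()) {
  stopifnot(inherits(scheme, "conservation_scheme"))
  a <- toupper(as.character(a))
  b <- toupper(as.character(b))
  n <- max(length(a), length(b))
  a <- rep_len(a, n)
  b <- rep_len(b, n)
  bad <- setdiff(unique(c(a, b)), c(AA_ALPHABET_20, GAP_CHAR))
  if (length(bad)) {
    stop("unknown residue symbol(s): ", paste(bad, collapse = ", "))
  }
  out <- character(n)
  is_gap <- a == GAP_CHAR | b == GAP_CHAR
  out[is_gap] <- "gap"
  same <- !is_gap & a == b
  out[same] <- "identical"
  rest <- !is_gap & !same
  same_class <- scheme$class_of[a[rest]] == scheme$class_of[b[rest]]
  out[rest] <- ifelse(same_class, "conservative", "nonconservative")
  out
}
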