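#' Distance matrix from an aligned family
#'
#' Converts pairwise percent similarity (or identity) into a distance:
#' `d = 1 - similarity/100`, giving values in \[0, 1\] with zero diagonal.
#'
#' @inheritParams similarity_matrix
#' @return Symmetric numeric matrix with zero diagonal, attribute
#'   `measure`.
#' @export
distance_from_alignment <- function(alignment, scheme = default_scheme(),
                                    measure = c("similarity", "identity")) {
  measure <- match.arg(measure)
  if (nrow(alignment$mat) < 3) {
    stop("distance matrix needs at least 3 records")
  }
  d <- 1 - similarity_matrix(alignment, scheme, measure) / 100
  diag(d) <- 0
  attr(d, "measure") <- measure
  d
}

#' Neighbor-joining dendrogram from a distance matrix
#'
#' Standard neighbor-joining agglomeration (via [ape::nj()]) over a
#' symmetric distance matrix, with taxa ordered lexicographically before
#' joining so the output is deterministic under label permutation, and
#' with any negative branch length clamped to zero, the deficit being moved
#' to the sibling branch so leaf-to-leaf path lengths through the parent
#' node are preserved.
#'
#' @param d Symmetric numeric matrix with zero diagonal and row/column
#'   names, or the result of [distance_from_alignment()].
#' @return An unrooted `phylo` tree (package \pkg{ape}).
#' @export
neighbor_joining <- function(d) {
  d <- as.matrix(d)
  if (is.null(rownames(d))) stop("distance matrix must have labelled taxa")
  if (nrow(d) != ncol(d) || max(abs(d - t(d))) > 1e-8) {
    stop("distance matrix must be symmetric")
  }
  if (any(diag(d) != 0)) stop("distance matrix must have a zero diagonal")
  if (nrow(d) < 3) stop("neighbor joining needs at least 3 taxa")
  ord <- order(rownames(d))
  d <- d[ord, ord]
  tr <- ape::nj(d)
  # clamp negative branches; push the deficit onto the sibling branch
  repeat {
    neg <- which(tr$edge.length < -1e-12)
    if (!length(neg)) break
    e <- neg[1]
    parent <- tr$edge[e, 1]
    sib <- setdiff(which(tr$edge[, 1] == parent), e)
    deficit <- tr$edge.length[e]
    tr$edge.length[e] <- 0
    if (length(sib)) {
      tr$edge.length[sib[1]] <- tr$edge.length[sib[1]] + deficit
    }
  }
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Serialize a tree to a newick file
#'
#' @param tree A `phylo` object.
#' @param path Output path.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Write a distance matrix as TSV
#'
#' @param d Matrix from [distance_from_alignment()].
#' @param path Output path.
#' @export
write_distance_tsv <- function(d, path) {
  utils::write.table(cbind(id = rownames(d), as.data.frame(d)), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
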