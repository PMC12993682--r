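#' Read a rooted Newick tree
#'
#' Thin wrapper over [ape::read.tree()] that enforces the invariants the
#' turnover metrics rely on: unique tip labels, branch lengths present,
#' finite and non-negative.
#'
#' @param path file containing a single Newick string.
#' @return an `ape::phylo` tree; a single-tip tree is accepted but
#'   carries attribute `usable_for_distances = FALSE`.
#' @export
read_newick <- function(path) {
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stop("Newick parse error in ", path,
                                            ": ", conditionMessage(e)))
  if (is.null(tree)) stop("Newick parse error in ", path)
  if (inherits(tree, "multiPhylo")) stop("expected a single tree in ", path)
  tree$tip.label <- trimws(tree$tip.label)
  if (anyDuplicated(tree$tip.label)) stop("duplicate tip labels in ", path)
  if (is.null(tree$edge.length)) stop("tree has no branch lengths: ", path)
  if (anyNA(tree$edge.length) || any(!is.finite(tree$edge.length))) {
    stop("non-finite branch length in ", path)
  }
  if (any(tree$edge.length < 0)) stop("negative branch length in ", path)
  attr(tree, "usable_for_distances") <- length(tree$tip.label) >= 2L
  tree
}

#' Cophenetic (patristic) distances between tree tips
#'
#' Distance between two tips is the sum of branch lengths along the path
#' connecting them.  Computed once per analysis; the permutation null
#' acts on this matrix, never on the tree.
#'
#' @param tree an `ape::phylo` tree with >= 2 tips and branch lengths.
#' @return symmetric numeric matrix with zero diagonal, tip labels as
#'   dimnames.
#' @export
cophenetic_distances <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (length(tree$tip.label) < 2L) stop("need >= 2 tips for distances")
  d <- ape::cophenetic.phylo(tree)
  d[tree$tip.label, tree$tip.label]
}

validate_distance_matrix <- function(d, tol = 1e-12) {
  if (!is.matrix(d) || nrow(d) != ncol(d)) stop("distance matrix must be square")
  if (is.null(rownames(d)) || !identical(rownames(d), colnames(d))) {
    stop("distance matrix must carry matching row/column ids")
  }
  if (max(abs(d - t(d))) > tol) stop("distance matrix not symmetric")
  if (max(abs(diag(d))) > tol) stop("distance matrix diagonal not zero")
  if (any(d < 0)) stop("negative distances")
  invisible(d)
}

#' Tip-label permutation of a distance matrix
#'
#' The null model behind the beta nearest taxon index: taxon identities
#' are shuffled across the tips of the phylogeny while abundances stay
#' attached to their identifiers.  Implemented as a joint row/column
#' permutation of the cophenetic matrix, which is equivalent and avoids
#' re-traversing the tree for each of the (typically 999) replicates.
#'
#' @param dist square patristic distance matrix with id dimnames.
#' @param seed integer seed; the permutation is deterministic given it.
#' @return matrix of identical dimnames whose values have been jointly
#'   permuted; the multiset of off-diagonal entries is unchanged.
#' @export
permute_taxa <- function(dist, seed) {
  validate_distance_matrix(dist)
  ids <- rownames(dist)
  perm <- with_seed(seed, sample.int(length(ids)))
  out <- dist[perm, perm, drop = FALSE]
  dimnames(out) <- list(ids, ids)
  out
}

#' Serialize a distance matrix as square CSV
#' @param d square distance matrix with id dimnames.
#' @param path output path.
#' @export
write_distance_matrix <- function(d, path) {
  validate_distance_matrix(d)
  df <- data.frame(id = rownames(d), d, check.names = FALSE)
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a square-CSV distance matrix written by [write_distance_matrix()]
#' @param path input path.
#' @export
read_distance_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  ids <- df[[1L]]
  m <- vapply(df[, -1L, drop = FALSE], as.numeric, numeric(nrow(df)))
  if (nrow(df) == 1L) m <- matrix(m, 1L, dimnames = list(NULL, names(df)[-1L]))
  rownames(m) <- ids
  validate_distance_matrix(m)
  m
}
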