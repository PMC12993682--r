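row_mins <- function(m) {
  m[cbind(seq_len(nrow(m)), max.col(-m, ties.method = "first"))]
}

# core betaMNTD kernel used by both the public function and the
# permutation null: ia/ib index present taxa, wa/wb are their relative
# weights (already summing to 1).
beta_mntd_kernel <- function(D, ia, ib, wa, wb) {
  d <- D[ia, ib, drop = FALSE]
  0.5 * (sum(wa * row_mins(d)) + sum(wb * row_mins(t(d))))
}

#' Abundance-weighted beta mean nearest taxon distance
#'
#' For every taxon present in one community, the patristic distance to
#' its nearest relative present in the other community, averaged with
#' abundance weights and symmetrized:
#' \deqn{0.5 [ \sum_i f_{ik} \min_j \Delta_{ij} + \sum_j f_{jm} \min_i \Delta_{ij} ]}
#' with minima over taxa present in the opposite community.  A taxon
#' present in both communities is its own nearest neighbor (distance 0)
#' unless `conspecifics = FALSE`.
#'
#' @param f_k,f_m abundance vectors named by taxon, each covering the
#'   taxon set of `dist`; renormalized to sum 1 internally.
#' @param dist patristic distance matrix over the same taxa.
#' @param conspecifics include shared taxa in the nearest-taxon minima
#'   (default `TRUE`, the convention of abundance-weighted betaMNTD).
#' @return non-negative scalar, at most the largest off-diagonal distance.
#' @export
beta_mntd <- function(f_k, f_m, dist, conspecifics = TRUE) {
  validate_distance_matrix(dist)
  ids <- rownames(dist)
  if (!setequal(names(f_k), ids) || !setequal(names(f_m), ids)) {
    stop("abundance vectors and distance matrix index different taxon sets")
  }
  f_k <- f_k[ids]
  f_m <- f_m[ids]
  if (all(f_k == 0) || all(f_m == 0)) stop("empty community")
  D <- dist
  if (!conspecifics) {
    shared <- which(f_k > 0 & f_m > 0)
    if (length(shared)) D[cbind(shared, shared)] <- Inf
  }
  ia <- which(f_k > 0)
  ib <- which(f_m > 0)
  beta_mntd_kernel(D, ia, ib, f_k[ia] / sum(f_k), f_m[ib] / sum(f_m))
}

#' All-pairs observed betaMNTD
#'
#' @param matrix a `community_matrix` harmonized with `dist`.
#' @param dist patristic distance matrix over the matrix's taxa.
#' @inheritParams beta_mntd
#' @return symmetric samples x samples matrix of observed betaMNTD.
#' @export
beta_mntd_matrix <- function(matrix, dist, conspecifics = TRUE) {
  stopifnot(inherits(matrix, "community_matrix"))
  vals <- matrix$values[, rownames(dist), drop = FALSE]
  n <- nrow(vals)
  out <- matrix(0, n, n, dimnames = list(rownames(vals), rownames(vals)))
  for (k in seq_len(n - 1L)) {
    for (m in (k + 1L):n) {
      out[k, m] <- out[m, k] <-
        beta_mntd(vals[k, ], vals[m, ], dist, conspecifics = conspecifics)
    }
  }
  out
}

#' Bray-Curtis dissimilarity matrix
#'
#' `BC(k,m) = sum |x_ik - x_im| / sum (x_ik + x_im)`, computed with
#' [vegan::vegdist()]; identical for relative abundances and for
#' pseudocounts after row normalization.
#'
#' @param matrix a `community_matrix` (any mode) with no all-zero rows.
#' @return symmetric samples x samples matrix with zero diagonal, values
#'   in `[0, 1]`.
#' @export
bray_curtis_matrix <- function(matrix) {
  stopifnot(inherits(matrix, "community_matrix"))
  vals <- matrix$values
  if (any(rowSums(vals) == 0)) stop("all-zero sample row")
  as.matrix(vegan::vegdist(vals, method = "bray"))
}

#' Pairwise squared Pearson correlation between samples
#'
#' Replicate-similarity screen: for each sample pair, taxa whose
#' abundance exceeds `min_abundance` are retained (by default judged on
#' the maximum over the two samples compared), abundances are optionally
#' Hellinger-transformed, and the squared Pearson correlation is
#' reported.
#'
#' @param matrix relative-mode `community_matrix`.
#' @param min_abundance relative-abundance filter threshold (e.g. 0.001
#'   for the ">0.1%" screen, 0.0002 for low-abundance taxa).
#' @param transform `"hellinger"` (default) or `"none"`.
#' @param filter `"max"` (default) keeps taxa exceeding the threshold in
#'   either compared sample; `"mean"` uses their mean.
#' @return symmetric samples x samples matrix of R-squared values with
#'   unit diagonal.
#' @export
pairwise_r2 <- function(matrix, min_abundance = 0.001,
                        transform = c("hellinger", "none"),
                        filter = c("max", "mean")) {
  stopifnot(inherits(matrix, "community_matrix"))
  transform <- match.arg(transform)
  filter <- match.arg(filter)
  if (matrix$mode != "relative") stop("pairwise_r2 requires relative mode")
  vals <- matrix$values / rowSums(matrix$values)
  n <- nrow(vals)
  out <- matrix(1, n, n, dimnames = list(rownames(vals), rownames(vals)))
  for (k in seq_len(n - 1L)) {
    for (m in (k + 1L):n) {
      screen <- if (filter == "max") {
        pmax(vals[k, ], vals[m, ])
      } else {
        (vals[k, ] + vals[m, ]) / 2
      }
      keep <- screen > min_abundance
      if (sum(keep) < 2L) {
        stop(sprintf("fewer than 2 taxa above %g for pair (%s, %s)",
                     min_abundance, rownames(vals)[k], rownames(vals)[m]))
      }
      a <- vals[k, keep]
      b <- vals[m, keep]
      if (transform == "hellinger") {
        a <- sqrt(a)
        b <- sqrt(b)
      }
      out[k, m] <- out[m, k] <- stats::cor(a, b)^2
    }
  }
  out
}

#' Write pairwise metrics in long format
#'
#' @param metrics named list of square sample x sample matrices.
#' @param path output CSV with columns sample_a, sample_b, metric, value.
#' @export
write_pairwise_long <- function(metrics, path) {
  rows <- do.call(rbind, lapply(names(metrics), function(name) {
    m <- metrics[[name]]
    idx <- which(upper.tri(m), arr.ind = TRUE)
    data.frame(sample_a = rownames(m)[idx[, 1L]],
               sample_b = colnames(m)[idx[, 2L]],
               metric = name, value = m[idx],
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
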