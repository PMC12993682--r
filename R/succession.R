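#' Read a long-format physicochemical phase table
#'
#' CSV with columns `digester,phase,parameter,value`; one value per
#' (digester, phase, parameter).  Returned in wide form (one row per
#' digester x phase) for ANOVA across phases with digesters as
#' replicates.
#'
#' @param path CSV path.
#' @return data.frame with columns digester, phase, and one column per
#'   parameter.
#' @export
read_phase_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("digester", "phase", "parameter", "value")
  if (!all(need %in% names(df))) {
    stop("phase table needs columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(df[, c("digester", "phase", "parameter")])) {
    stop("duplicate (digester, phase, parameter) rows")
  }
  if (!is.numeric(df$value)) stop("non-numeric value column")
  wide <- stats::reshape(df, idvar = c("digester", "phase"),
                         timevar = "parameter", direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  if ("pH" %in% names(wide) && any(wide$pH <= 0 | wide$pH >= 14)) {
    stop("pH outside (0, 14)")
  }
  conc <- setdiff(names(wide), c("digester", "phase", "pH"))
  if (any(as.matrix(wide[conc]) < 0, na.rm = TRUE)) stop("negative concentration")
  rownames(wide) <- NULL
  wide[order(wide$digester, wide$phase), ]
}

#' Fisher's log-series alpha
#'
#' The unique `alpha > 0` solving `S = alpha * log(1 + N/alpha)` for
#' richness `S` and total count `N`, found by bracketed root-finding to
#' `|f| < 1e-10`.
#'
#' @param S observed richness.
#' @param N total individuals.
#' @return alpha, or `NA` (with a warning) in the degenerate S = N = 1
#'   case where the equation has no finite root.
#' @export
fisher_alpha <- function(S, N) {
  if (S < 1 || N < S) stop("need 1 <= S <= N")
  if (S == N) {
    # S = N: alpha -> infinity (every individual a singleton); S = N = 1
    # in particular is undefined.
    warning("Fisher's alpha undefined when S = N")
    return(NA_real_)
  }
  f <- function(a) a * log(1 + N / a) - S
  lo <- 1e-10
  hi <- 1
  while (f(hi) < 0) hi <- hi * 2
  r <- stats::uniroot(f, c(lo, hi), tol = 1e-14)
  if (abs(f(r$root)) > 1e-10) stop("Fisher's alpha root-finding failed")
  r$root
}

#' Alpha diversity indices for one sample
#'
#' @param counts non-negative integer abundance vector (pseudocounts).
#' @return list with `shannon` (H = -sum p log p, natural log), `simpson`
#'   (D = sum p^2, the concentration form), `inv_simpson` (1/D), and
#'   `fisher_alpha`.
#' @export
alpha_diversity <- function(counts) {
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  counts <- counts[counts > 0]
  if (!length(counts)) stop("zero community")
  N <- sum(counts)
  S <- length(counts)
  p <- counts / N
  D <- sum(p^2)
  list(shannon = -sum(p * log(p)),
       simpson = D,
       inv_simpson = 1 / D,
       fisher_alpha = if (S == 1L && N == 1L) {
         warning("Fisher's alpha undefined for a single singleton")
         NA_real_
       } else if (S == N) {
         warning("Fisher's alpha undefined when S = N")
         NA_real_
       } else {
         fisher_alpha(S, N)
       })
}

#' One-way analysis of variance
#'
#' Classical fixed-effects ANOVA via [stats::aov()], with explicit
#' handling of the degenerate cases the F table cannot express: zero
#' within-group variance with distinct means gives `F = Inf, p = 0`
#' (flagged), and completely constant data give `F = 0, p = 1`.
#'
#' @param groups list of numeric vectors, one per group.
#' @return list with `F`, `p`, `df_between`, `df_within`, and logical
#'   `degenerate`.
#' @export
one_way_anova <- function(groups) {
  if (length(groups) < 2L) stop("need >= 2 groups")
  if (any(lengths(groups) < 1L)) stop("empty group")
  if (sum(lengths(groups) - 1L) < 1L) stop("no within-group degrees of freedom")
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  df_b <- nlevels(g) - 1L
  df_w <- length(y) - nlevels(g)
  means <- tapply(y, g, mean)
  ssw <- sum((y - means[g])^2)
  if (ssw == 0) {
    if (all(abs(y - mean(y)) == 0)) {
      return(list(F = 0, p = 1, df_between = df_b, df_within = df_w,
                  degenerate = TRUE))
    }
    return(list(F = Inf, p = 0, df_between = df_b, df_within = df_w,
                degenerate = TRUE))
  }
  tab <- stats::anova(stats::aov(y ~ g))
  list(F = tab[["F value"]][1L], p = tab[["Pr(>F)"]][1L],
       df_between = tab[["Df"]][1L], df_within = tab[["Df"]][2L],
       degenerate = FALSE)
}

#' Tukey's honestly significant difference test
#'
#' Post-hoc pairwise comparisons after a one-way ANOVA, using the
#' studentized range distribution with the omnibus mean square within.
#'
#' @param groups list of numeric vectors, one per group (>= 2 values
#'   each); names are used as group labels.
#' @param alpha familywise significance level (default 0.05).
#' @return data.frame with group_a, group_b, difference (mean_b -
#'   mean_a), q, p_adj, significant.
#' @export
tukey_hsd <- function(groups, alpha = 0.05) {
  if (length(groups) < 2L) stop("need >= 2 groups")
  if (any(lengths(groups) < 2L)) stop("each group needs >= 2 values")
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  k <- nlevels(g)
  df_w <- length(y) - k
  means <- tapply(y, g, mean)
  ns <- tapply(y, g, length)
  msw <- sum((y - means[g])^2) / df_w
  pairs <- utils::combn(names(groups), 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1L, j]
    b <- pairs[2L, j]
    diff <- means[[b]] - means[[a]]
    se <- sqrt(msw / 2 * (1 / ns[[a]] + 1 / ns[[b]]))
    if (msw == 0) {
      q <- if (diff == 0) 0 else Inf
      p <- if (diff == 0) 1 else 0
    } else {
      q <- abs(diff) / se
      p <- stats::ptukey(q, k, df_w, lower.tail = FALSE)
    }
    data.frame(group_a = a, group_b = b, difference = diff, q = q,
               p_adj = p, significant = p < alpha,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-feature phase-peak test with BH-FDR
#'
#' For every taxon/feature: a one-way ANOVA of (optionally
#' Hellinger-transformed) abundance across phases, Benjamini-Hochberg
#' adjustment across features, and the phase in which the mean abundance
#' peaks.  Digesters serve as within-phase replicates.
#'
#' @param matrix relative-mode `community_matrix` with `sample_meta`
#'   carrying a `phase` column (or pass `phases` explicitly).
#' @param phases optional character vector of per-sample phases.
#' @param fdr_q FDR threshold (default 0.05).
#' @param transform `"hellinger"` (default) or `"none"`.
#' @return data.frame: feature, peak_phase, p_raw, p_adj, significant.
#'   Peak phases are judged on untransformed abundances; features that
#'   are constant across samples get p = 1.
#' @export
phase_peak_test <- function(matrix, phases = NULL, fdr_q = 0.05,
                            transform = c("hellinger", "none")) {
  stopifnot(inherits(matrix, "community_matrix"))
  transform <- match.arg(transform)
  if (is.null(phases)) {
    if (is.null(matrix$sample_meta)) stop("no phases given and no sample_meta")
    phases <- matrix$sample_meta$phase
  }
  phases <- factor(phases)
  if (any(table(phases) < 2L)) stop("each phase needs >= 2 samples")
  vals <- matrix$values / rowSums(matrix$values)
  test_vals <- if (transform == "hellinger") sqrt(vals) else vals
  p_raw <- vapply(seq_len(ncol(vals)), function(i) {
    x <- test_vals[, i]
    if (max(x) - min(x) <= 1e-12 * max(abs(x), 1)) return(1)
    res <- one_way_anova(split(x, phases))
    res$p
  }, numeric(1L))
  p_adj <- stats::p.adjust(p_raw, method = "BH")
  peak <- levels(phases)[apply(
    do.call(rbind, lapply(split(seq_len(nrow(vals)), phases),
                          function(idx) colMeans(vals[idx, , drop = FALSE]))),
    2L, which.max)]
  data.frame(feature = colnames(vals), peak_phase = peak,
             p_raw = p_raw, p_adj = p_adj,
             significant = p_adj < fdr_q,
             stringsAsFactors = FALSE)
}

#' Permutation tests of group separation (PERMANOVA / ANOSIM)
#'
#' One-factor PERMANOVA (pseudo-F from the within/between squared
#' distance decomposition, via [vegan::adonis2()]) or ANOSIM (rank-based
#' R, via [vegan::anosim()]).  p-values include the observed statistic
#' in the null, `p = (1 + #permuted >= observed) / (1 + permutations)`,
#' and are deterministic given the seed.
#'
#' @param dist square distance matrix over samples.
#' @param labels group label per sample (>= 2 groups of >= 2).
#' @param method `"permanova"` or `"anosim"`.
#' @param permutations number of label permutations (default 999).
#' @param seed integer seed.
#' @return list with `statistic` (pseudo-F or R) and `p`.
#' @export
group_significance <- function(dist, labels,
                               method = c("permanova", "anosim"),
                               permutations = 999L, seed = 1L) {
  method <- match.arg(method)
  validate_distance_matrix(dist, tol = 1e-8)
  labels <- factor(labels)
  if (length(labels) != nrow(dist)) stop("one label per sample required")
  if (nlevels(labels) < 2L) stop("need >= 2 groups")
  if (any(table(labels) < 2L)) stop("every group needs >= 2 samples")
  d <- stats::as.dist(dist)
  if (method == "permanova") {
    fit <- with_seed(seed, vegan::adonis2(d ~ labels,
                                          permutations = permutations))
    list(statistic = fit$F[1L], p = fit$`Pr(>F)`[1L])
  } else {
    fit <- with_seed(seed, vegan::anosim(d, labels,
                                         permutations = permutations))
    list(statistic = unname(fit$statistic), p = fit$signif)
  }
}

#' Principal coordinates analysis (classical MDS)
#'
#' Gower double-centering followed by eigendecomposition.  Negative
#' eigenvalues (possible for non-Euclidean dissimilarities such as
#' Bray-Curtis) are reported but excluded from the proportion-explained
#' denominator, which sums positive eigenvalues only.
#'
#' @param dist square symmetric distance matrix with zero diagonal.
#' @return list with `coordinates` (samples x positive axes, ordered by
#'   descending eigenvalue), `eigenvalues` (all, descending), and
#'   `proportion_explained` (per positive axis).
#' @export
pcoa <- function(dist) {
  validate_distance_matrix(dist, tol = 1e-8)
  n <- nrow(dist)
  fit <- suppressWarnings(stats::cmdscale(stats::as.dist(dist),
                                          k = n - 1L, eig = TRUE))
  eig <- fit$eig
  pos <- eig > max(eig, 0) * 1e-12
  coords <- fit$points
  if (!is.null(coords) && ncol(coords) > 0) {
    colnames(coords) <- paste0("Axis", seq_len(ncol(coords)))
  }
  pos_eig <- eig[pos]
  list(coordinates = coords,
       eigenvalues = eig,
       proportion_explained = if (length(pos_eig)) pos_eig / sum(pos_eig)
                              else numeric(0))
}

#' UPGMA (average-linkage) hierarchical clustering
#'
#' Heights are recorded as the raw average-linkage distance at each
#' merge (not halved), so a perfectly ultrametric input is reproduced
#' exactly by the dendrogram's cophenetic distances.
#'
#' @param dist square distance matrix over >= 2 items.
#' @return object of class `hclust`; convert with [ape::as.phylo()] for
#'   Newick export.
#' @export
upgma_cluster <- function(dist) {
  validate_distance_matrix(dist, tol = 1e-8)
  if (nrow(dist) < 2L) stop("need >= 2 items")
  stats::hclust(stats::as.dist(dist), method = "average")
}

#' Percent reduction between two values
#'
#' `100 * (start - end) / start`; the reporting layer rounds half-up to
#' the nearest integer percent (see `round_half_up`).
#'
#' @param start positive baseline value.
#' @param end final value.
#' @return percent reduction (negative if the value increased).
#' @export
percent_reduction <- function(start, end) {
  if (any(start <= 0)) stop("start must be positive")
  100 * (start - end) / start
}

#' Round half away from zero
#'
#' Deterministic half-up rounding for reported integer percentages
#' (base `round()` rounds half to even).
#'
#' @param x numeric vector.
#' @param digits decimal places (default 0).
#' @return rounded vector.
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}
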