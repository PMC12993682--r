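process_labels <- c("variable_selection", "homogeneous_selection",
                    "dispersal_limitation", "homogenizing_dispersal",
                    "undominated")

#' Beta nearest taxon index (betaNTI) for every sample pair
#'
#' Standardizes observed betaMNTD against a null ensemble in which taxon
#' identities are shuffled across the tips of the phylogeny:
#' \deqn{\beta NTI = (\beta MNTD_{obs} - mean(\beta MNTD_{null})) / sd(\beta MNTD_{null})}
#' with the sample standard deviation (n-1 denominator).  `|betaNTI| > 2`
#' marks deterministic assembly; the sign marks more (+) or less (-)
#' phylogenetic turnover than expected under the null.
#'
#' Randomization is driven by one root seed; each sample pair gets its
#' own derived stream, so results are independent of pair order.
#'
#' @param matrix relative-mode `community_matrix`, harmonized with `dist`.
#' @param dist patristic distance matrix over the matrix's taxa.
#' @param reps null replicates (default 999; must be >= 99).
#' @param seed integer root seed.
#' @param conspecifics passed to [beta_mntd()].
#' @param keep_nulls retain the per-pair null vectors (default `FALSE`).
#' @param degenerate what to do when every tip shuffle yields the same
#'   betaMNTD (e.g. a star phylogeny, or a pair sharing every present
#'   taxon): `"error"` (default) or `"zero"`, which records betaNTI = 0
#'   for identical-support pairs -- zero turnover carries no selection
#'   signal, the stochastic side of the decision rule.
#' @return data.frame with one row per unordered sample pair: `sample_a`,
#'   `sample_b`, `beta_mntd_obs`, `null_mean`, `null_sd`, `beta_nti`.
#'   With `keep_nulls`, the null vectors are attached as attribute
#'   `nulls` (a named list).
#' @export
beta_nti <- function(matrix, dist, reps = 999L, seed = 1L,
                     conspecifics = TRUE, keep_nulls = FALSE,
                     degenerate = c("error", "zero")) {
  degenerate <- match.arg(degenerate)
  stopifnot(inherits(matrix, "community_matrix"))
  validate_distance_matrix(dist)
  reps <- as.integer(reps)
  if (reps < 99L) stop("reps must be >= 99")
  ids <- rownames(dist)
  if (!all(ids %in% taxon_ids(matrix)) ||
      length(ids) != length(taxon_ids(matrix))) {
    stop("matrix and distance matrix must share one taxon set; harmonize first")
  }
  vals <- matrix$values[, ids, drop = FALSE]
  vals <- vals / rowSums(vals)
  n <- nrow(vals)
  if (n < 2L) stop("need >= 2 samples")
  ntax <- length(ids)
  pairs <- utils::combn(n, 2L)
  res <- vector("list", ncol(pairs))
  nulls <- if (keep_nulls) vector("list", ncol(pairs)) else NULL
  for (p in seq_len(ncol(pairs))) {
    k <- pairs[1L, p]
    m <- pairs[2L, p]
    fk <- vals[k, ]
    fm <- vals[m, ]
    D <- dist
    if (!conspecifics) {
      shared <- which(fk > 0 & fm > 0)
      if (length(shared)) D[cbind(shared, shared)] <- Inf
    }
    ia <- which(fk > 0)
    ib <- which(fm > 0)
    wa <- fk[ia]
    wb <- fm[ib]
    obs <- beta_mntd_kernel(D, ia, ib, wa, wb)
    pair_ids <- sort(c(rownames(vals)[k], rownames(vals)[m]))
    null_vals <- with_seed(
      derive_seed(seed, "beta_nti", pair_ids[1L], pair_ids[2L]),
      vapply(seq_len(reps), function(r) {
        perm <- sample.int(ntax)
        beta_mntd_kernel(D, perm[ia], perm[ib], wa, wb)
      }, numeric(1L))
    )
    s <- stats::sd(null_vals)
    if (s < 1e-12) {
      if (degenerate == "error" || abs(obs - mean(null_vals)) > 1e-12) {
        stop("degenerate null distribution for pair (",
             rownames(vals)[k], ", ", rownames(vals)[m],
             "): all tip shuffles give identical betaMNTD")
      }
      # identical-support pair: zero turnover observed and under every
      # shuffle -- no phylogenetic signal, record betaNTI = 0
      bnti <- 0
    } else {
      bnti <- (obs - mean(null_vals)) / s
    }
    res[[p]] <- data.frame(sample_a = rownames(vals)[k],
                           sample_b = rownames(vals)[m],
                           beta_mntd_obs = obs,
                           null_mean = mean(null_vals),
                           null_sd = s,
                           beta_nti = bnti,
                           stringsAsFactors = FALSE)
    if (keep_nulls) {
      nulls[[p]] <- null_vals
      names(nulls)[p] <- paste(rownames(vals)[k], rownames(vals)[m], sep = "|")
    }
  }
  out <- do.call(rbind, res)
  if (keep_nulls) attr(out, "nulls") <- nulls
  out
}

# one null community: S species drawn without replacement with
# probability ~ occupancy, 1 individual each, remaining N-S individuals
# multinomial with probability ~ summed relative abundance.
rc_null_community <- function(ntax, S, N, occ_prob, ab_prob) {
  chosen <- sample.int(ntax, S, prob = occ_prob)
  x <- numeric(ntax)
  x[chosen] <- 1
  if (N > S) {
    x[chosen] <- x[chosen] +
      stats::rmultinom(1L, N - S, prob = ab_prob[chosen])[, 1L]
  }
  x
}

#' Abundance-based Raup-Crick Bray-Curtis (RCbray)
#'
#' Partitions non-selection processes (drift vs dispersal) by comparing
#' the observed Bray-Curtis dissimilarity of each sample pair against
#' pairs of null communities that preserve each sample's richness and
#' total abundance.  Null communities draw species with probability
#' proportional to occupancy across the whole sample set (the
#' metacommunity), then fill to the observed total with probability
#' proportional to summed relative abundance.  The score is
#' \deqn{RC_{bray} = 2 [ (n_{<} + 0.5 n_{=}) / reps - 0.5 ] \in [-1, 1]}
#' where `n_<`/`n_=` count null pairs less dissimilar than / equal to the
#' observed pair (tie tolerance 1e-12).  `RCbray > +0.95` indicates
#' dispersal limitation with drift, `< -0.95` homogenizing dispersal.
#'
#' @param matrix pseudocount-mode `community_matrix` with >= 2 samples;
#'   the full sample set defines the metacommunity.
#' @param reps null replicates (default 999).
#' @param seed integer root seed; per-pair streams are derived from it.
#' @param keep_nulls retain per-pair null Bray-Curtis vectors.
#' @param pairs optional 2-column matrix/data.frame of sample ids
#'   restricting which pairs are scored; all samples still define the
#'   metacommunity.  Default: every unordered pair.
#' @return data.frame with one row per scored pair: `sample_a`,
#'   `sample_b`, `bray_obs`, `rc_bray`.
#' @export
raup_crick_bray <- function(matrix, reps = 999L, seed = 1L,
                            keep_nulls = FALSE, pairs = NULL) {
  stopifnot(inherits(matrix, "community_matrix"))
  if (matrix$mode != "pseudocount") {
    stop("raup_crick_bray requires pseudocounts; see to_pseudocounts()")
  }
  reps <- as.integer(reps)
  if (reps < 99L) stop("reps must be >= 99")
  counts <- matrix$values
  n <- nrow(counts)
  if (n < 2L) stop("need >= 2 samples to define a metacommunity")
  ntax <- ncol(counts)
  occ_prob <- colSums(counts > 0)
  ab_prob <- colSums(counts / rowSums(counts))
  S <- rowSums(counts > 0)
  N <- rowSums(counts)
  if (any(S > ntax)) stop("richness exceeds species pool")
  if (any(N < S)) stop("total abundance below richness")
  bray <- function(x, y) sum(abs(x - y)) / sum(x + y)
  if (is.null(pairs)) {
    pairs <- utils::combn(n, 2L)
  } else {
    pairs <- as.matrix(pairs)
    if (ncol(pairs) != 2L) stop("'pairs' must have two columns")
    idx <- matrix(match(pairs, rownames(counts)), ncol = 2L)
    if (anyNA(idx)) stop("'pairs' names samples absent from the matrix")
    pairs <- t(idx)
  }
  res <- vector("list", ncol(pairs))
  nulls <- if (keep_nulls) vector("list", ncol(pairs)) else NULL
  for (p in seq_len(ncol(pairs))) {
    k <- pairs[1L, p]
    m <- pairs[2L, p]
    obs <- bray(counts[k, ], counts[m, ])
    pair_ids <- sort(c(rownames(counts)[k], rownames(counts)[m]))
    null_bc <- with_seed(
      derive_seed(seed, "rc_bray", pair_ids[1L], pair_ids[2L]),
      vapply(seq_len(reps), function(r) {
        bray(rc_null_community(ntax, S[k], N[k], occ_prob, ab_prob),
             rc_null_community(ntax, S[m], N[m], occ_prob, ab_prob))
      }, numeric(1L))
    )
    n_lt <- sum(null_bc < obs - 1e-12)
    n_eq <- sum(abs(null_bc - obs) <= 1e-12)
    rc <- 2 * ((n_lt + 0.5 * n_eq) / reps - 0.5)
    res[[p]] <- data.frame(sample_a = rownames(counts)[k],
                           sample_b = rownames(counts)[m],
                           bray_obs = obs, rc_bray = rc,
                           stringsAsFactors = FALSE)
    if (keep_nulls) {
      nulls[[p]] <- null_bc
      names(nulls)[p] <- paste(rownames(counts)[k], rownames(counts)[m], sep = "|")
    }
  }
  out <- do.call(rbind, res)
  if (keep_nulls) attr(out, "nulls") <- nulls
  out
}

#' Classify a sample pair into an assembly process
#'
#' The five-way decision rule over the (betaNTI, RCbray) plane:
#' `betaNTI > +2` variable selection; `betaNTI < -2` homogeneous
#' selection; otherwise (stochastic side) `RCbray > +0.95` dispersal
#' limitation, `RCbray < -0.95` homogenizing dispersal, and anything
#' else undominated.  Boundaries count to the stochastic/undominated
#' side (`|betaNTI| = 2` is stochastic, `|RCbray| = 0.95` undominated).
#' RCbray is ignored (and may be `NA`) when selection dominates.
#'
#' @param beta_nti numeric vector of betaNTI values.
#' @param rc_bray numeric vector of RCbray values in `[-1, 1]`.
#' @return character vector of process labels.
#' @export
classify_process <- function(beta_nti, rc_bray = NA_real_) {
  n <- max(length(beta_nti), length(rc_bray))
  beta_nti <- rep_len(beta_nti, n)
  rc_bray <- rep_len(rc_bray, n)
  if (any(!is.finite(beta_nti))) stop("non-finite betaNTI")
  stoch <- abs(beta_nti) <= 2
  if (any(stoch & !is.finite(rc_bray))) {
    stop("non-finite RCbray for a stochastic-side pair")
  }
  if (any(stoch & (rc_bray < -1 | rc_bray > 1))) stop("RCbray outside [-1, 1]")
  out <- character(n)
  out[beta_nti > 2] <- "variable_selection"
  out[beta_nti < -2] <- "homogeneous_selection"
  out[stoch & rc_bray > 0.95] <- "dispersal_limitation"
  out[stoch & rc_bray < -0.95] <- "homogenizing_dispersal"
  out[out == ""] <- "undominated"
  out
}

#' Full assembly inference for one community matrix
#'
#' Convenience chain: betaNTI on the relative matrix, RCbray on its
#' pseudocount version, and the per-pair process classification.
#'
#' @param matrix relative-mode `community_matrix` harmonized with `dist`.
#' @param dist patristic distance matrix.
#' @param reps null replicates for both nulls.
#' @param seed root seed.
#' @param depth pseudocount depth for the RCbray null.
#' @param conspecifics passed to [beta_mntd()].
#' @return data.frame: sample_a, sample_b, beta_mntd_obs, beta_nti,
#'   bray_obs, rc_bray, process.
#' @export
infer_assembly <- function(matrix, dist, reps = 999L, seed = 1L,
                           depth = 10000L, conspecifics = TRUE) {
  bn <- beta_nti(matrix, dist, reps = reps, seed = seed,
                 conspecifics = conspecifics, degenerate = "zero")
  rc <- raup_crick_bray(to_pseudocounts(matrix, depth = depth),
                        reps = reps, seed = seed)
  out <- merge(bn[, c("sample_a", "sample_b", "beta_mntd_obs", "beta_nti")],
               rc, by = c("sample_a", "sample_b"), sort = FALSE)
  out$process <- classify_process(out$beta_nti, out$rc_bray)
  out
}

#' Aggregate assembly results over phase pairs
#'
#' Collects, for each unordered pair of successional phases, all
#' cross-phase sample pairs (9 for 3 digesters x 2 phases), and reports
#' mean and median betaNTI, mean RCbray, the per-pair labels, and a
#' consensus classification computed from the means.  Within-phase pairs
#' are excluded from aggregates.
#'
#' @param results data.frame from [infer_assembly()] (needs sample_a,
#'   sample_b, beta_nti, rc_bray, process).
#' @param sample_meta data.frame with sample_id, digester, phase.
#' @return data.frame with one row per phase pair: phase_a, phase_b,
#'   n_pairs, mean_beta_nti, median_beta_nti, mean_rc_bray, consensus,
#'   plus label counts as a list column `labels`.
#' @export
phase_pair_summary <- function(results, sample_meta) {
  need <- c("sample_id", "phase")
  if (!all(need %in% names(sample_meta))) {
    stop("sample_meta needs columns sample_id and phase")
  }
  phase_of <- stats::setNames(as.character(sample_meta$phase),
                              sample_meta$sample_id)
  if (!all(c(results$sample_a, results$sample_b) %in% names(phase_of))) {
    stop("results contain samples absent from sample_meta")
  }
  phases <- sort(unique(phase_of))
  counts <- table(phase_of)
  if (any(counts == 0)) stop("phase with no samples")
  results$phase_a <- phase_of[results$sample_a]
  results$phase_b <- phase_of[results$sample_b]
  pp <- utils::combn(phases, 2L)
  rows <- lapply(seq_len(ncol(pp)), function(j) {
    pa <- pp[1L, j]
    pb <- pp[2L, j]
    sel <- (results$phase_a == pa & results$phase_b == pb) |
      (results$phase_a == pb & results$phase_b == pa)
    sub <- results[sel, , drop = FALSE]
    if (!nrow(sub)) stop("no cross-phase pairs for (", pa, ", ", pb, ")")
    mb <- mean(sub$beta_nti)
    mr <- mean(sub$rc_bray)
    data.frame(phase_a = pa, phase_b = pb, n_pairs = nrow(sub),
               mean_beta_nti = mb, median_beta_nti = stats::median(sub$beta_nti),
               mean_rc_bray = mr,
               consensus = classify_process(mb, mr),
               labels = I(list(table(factor(sub$process, levels = process_labels)))),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
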