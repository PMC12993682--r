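test_that("betaNTI is deterministic, seed-stream stable, and flags degenerate nulls", {
  tree <- simulate_yule_tree(10, seed = 5)
  cm <- random_community(tree, n_samples = 2L, seed = 14)
  d <- cophenetic_distances(tree)
  a <- beta_nti(cm, d, reps = 199, seed = 3)
  b <- beta_nti(cm, d, reps = 199, seed = 3)
  expect_identical(a, b)
  expect_named(a, c("sample_a", "sample_b", "beta_mntd_obs", "null_mean",
                    "null_sd", "beta_nti"))

  # star phylogeny: every shuffle yields identical betaMNTD
  star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1);")
  vals <- matrix(c(1, 0, 0, 0, 0, 0, 1, 0), 2, 4, byrow = TRUE,
                 dimnames = list(c("S1", "S2"), star$tip.label))
  expect_error(
    beta_nti(community_matrix(vals, mode = "relative"),
             cophenetic_distances(star), reps = 99, seed = 1),
    "degenerate null")

  expect_error(beta_nti(cm, d, reps = 10, seed = 1), "reps must be >= 99")
})

test_that("betaNTI is invariant to sample order and taxon relabeling", {
  tree <- simulate_yule_tree(12, seed = 9)
  cm <- random_community(tree, n_samples = 3L, seed = 4)
  d <- cophenetic_distances(tree)
  res <- beta_nti(cm, d, reps = 199, seed = 8)
  # reversing sample order leaves each pair's value unchanged
  rev_cm <- subset_samples(cm, rev(sample_ids(cm)))
  res_rev <- beta_nti(rev_cm, d, reps = 199, seed = 8)
  key <- function(df) {
    k <- apply(df[, c("sample_a", "sample_b")], 1L, function(r) paste(sort(r), collapse = "|"))
    stats::setNames(df$beta_nti, k)
  }
  expect_equal(key(res_rev)[names(key(res))], key(res))

  # relabeling taxa (consistently in matrix and distances) changes nothing
  perm <- sample(taxon_ids(cm))
  relab <- stats::setNames(paste0("x", seq_along(perm)), perm)
  vals2 <- cm$values
  colnames(vals2) <- relab[colnames(vals2)]
  d2 <- d
  dimnames(d2) <- list(relab[rownames(d)], relab[colnames(d)])
  res2 <- beta_nti(community_matrix(vals2, mode = "relative", normalize = FALSE),
                   d2[colnames(vals2), colnames(vals2)], reps = 199, seed = 8)
  expect_equal(res2$beta_nti, res$beta_nti, tolerance = 1e-12)
})

test_that("doubling null replicates barely moves betaNTI", {
  tree <- simulate_yule_tree(20, seed = 13)
  cm <- random_community(tree, n_samples = 2L, seed = 31)
  d <- cophenetic_distances(tree)
  b1 <- beta_nti(cm, d, reps = 999, seed = 5)$beta_nti
  b2 <- beta_nti(cm, d, reps = 1998, seed = 6)$beta_nti
  expect_lt(abs(b1 - b2), 0.3)
})

test_that("raup-crick boundaries behave: identical and disjoint pairs", {
  # identical non-empty communities: no null pair can be more similar
  set.seed(44)
  row <- as.integer(rpois(40, 4))
  row[row == 0] <- 1L
  vals <- rbind(S1 = row, S2 = row)
  colnames(vals) <- paste0("t", 1:40)
  cm <- community_matrix(vals, mode = "pseudocount")
  rc <- raup_crick_bray(cm, reps = 199, seed = 1)
  expect_equal(rc$rc_bray, -1)
  expect_equal(rc$bray_obs, 0)

  # disjoint communities from a shared 50-species pool: obs BC = 1 while
  # null pairs almost always share species, so RC approaches +1
  vals2 <- matrix(0L, 2, 50, dimnames = list(c("S1", "S2"), paste0("t", 1:50)))
  set.seed(9)
  vals2[1L, 1:15] <- as.integer(rpois(15, 5) + 1L)
  vals2[2L, 16:30] <- as.integer(rpois(15, 5) + 1L)
  cm2 <- community_matrix(vals2, mode = "pseudocount")
  rc2 <- raup_crick_bray(cm2, reps = 999, seed = 2)
  expect_equal(rc2$bray_obs, 1)
  expect_gte(rc2$rc_bray, 0.9)
  expect_lte(rc2$rc_bray, 1)

  expect_error(raup_crick_bray(community_matrix(vals / sum(vals),
                                                mode = "relative"),
                               reps = 99, seed = 1), "pseudocount")
})

test_that("raup-crick is monotone in observed dissimilarity against a fixed null", {
  tree <- simulate_yule_tree(30, seed = 3)
  cm <- to_pseudocounts(random_community(tree, n_samples = 4L, seed = 77),
                        depth = 500)
  rc <- raup_crick_bray(cm, reps = 299, seed = 9, keep_nulls = TRUE)
  nulls <- attr(rc, "nulls")
  for (i in seq_len(nrow(rc))) {
    null_bc <- nulls[[i]]
    score <- function(obs) {
      2 * ((sum(null_bc < obs - 1e-12) + 0.5 * sum(abs(null_bc - obs) <= 1e-12)) /
             length(null_bc) - 0.5)
    }
    grid <- seq(0, 1, by = 0.1)
    expect_true(all(diff(vapply(grid, score, numeric(1L))) >= 0))
    expect_true(rc$rc_bray[i] >= -1 && rc$rc_bray[i] <= 1)
  }
})

test_that("process classification partitions the plane with stated boundaries", {
  expect_equal(classify_process(2.60, NA), "variable_selection")
  expect_equal(classify_process(-2.5, 0), "homogeneous_selection")
  expect_equal(classify_process(0.3, 0.97), "dispersal_limitation")
  expect_equal(classify_process(0.3, -0.97), "homogenizing_dispersal")
  expect_equal(classify_process(0.3, 0.2), "undominated")
  # boundary conventions: |betaNTI| = 2 is stochastic, |RC| = 0.95 undominated
  expect_equal(classify_process(2, 0), "undominated")
  expect_equal(classify_process(-2, 0.95), "undominated")
  expect_equal(classify_process(2, 0.951), "dispersal_limitation")

  grid <- expand.grid(b = seq(-4, 4, by = 0.25), r = seq(-1, 1, by = 0.05))
  labels <- classify_process(grid$b, grid$r)
  expect_true(all(labels %in% c("variable_selection", "homogeneous_selection",
                                "dispersal_limitation", "homogenizing_dispersal",
                                "undominated")))
  expect_length(labels, nrow(grid))
  expect_error(classify_process(NaN, 0), "non-finite")
  expect_error(classify_process(0, 2), "outside")
})

test_that("phase-pair aggregation collects the 9 cross-phase pairs and a consensus", {
  samples <- paste0(rep(c("D1", "D2", "D3"), each = 3), rep(c("P1", "P2", "P3"), 3))
  meta <- data.frame(sample_id = samples,
                     digester = rep(c("D1", "D2", "D3"), each = 3),
                     phase = rep(c("P1", "P2", "P3"), 3))
  pairs <- t(utils::combn(samples, 2))
  res <- data.frame(sample_a = pairs[, 1], sample_b = pairs[, 2],
                    beta_nti = 2.6, rc_bray = 0.5)
  res$process <- classify_process(res$beta_nti, res$rc_bray)
  agg <- phase_pair_summary(res, meta)
  expect_equal(nrow(agg), 3L)
  expect_true(all(agg$n_pairs == 9L))
  expect_equal(sum(agg$n_pairs), 27L)
  expect_true(all(agg$mean_beta_nti == 2.6))
  expect_true(all(agg$consensus == "variable_selection"))

  # symmetric betaNTI values cancel into an undominated consensus while
  # per-pair labels are retained
  res2 <- res
  res2$beta_nti <- rep_len(c(3, -3), nrow(res2))
  res2$rc_bray <- 0
  res2$process <- classify_process(res2$beta_nti, res2$rc_bray)
  agg2 <- phase_pair_summary(res2, meta)
  expect_true(all(agg2$consensus == "undominated"))
  expect_true(all(vapply(agg2$labels, function(t) sum(t) == 9, logical(1L))))
})
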