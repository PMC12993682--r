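test_that("alpha diversity matches closed forms and the fisher-alpha root", {
  u <- alpha_diversity(rep(100L, 4L))
  expect_equal(u$shannon, log(4))
  expect_equal(u$simpson, 0.25)
  expect_equal(u$inv_simpson, 4)

  single <- alpha_diversity(c(7L, 0L))
  expect_equal(single$shannon, 0)
  expect_equal(single$simpson, 1)
  expect_equal(single$inv_simpson, 1)

  # S = 10, N = 100: alpha solves alpha*log(1 + 100/alpha) = 10
  a <- fisher_alpha(10, 100)
  expect_equal(a, 2.76629, tolerance = 1e-5)
  expect_lt(abs(a * log(1 + 100 / a) - 10), 1e-10)
  expect_equal(a, vegan::fisher.alpha(c(rep(1, 9), 91)), tolerance = 1e-4)

  expect_warning(alpha_diversity(c(1L, 0L)), "undefined")
  expect_error(alpha_diversity(integer(0)), "zero community")

  # H <= log(S) with equality only when uniform; inv_simpson <= S
  set.seed(2)
  for (i in 1:10) {
    x <- rpois(12, 30) + 1L
    d <- alpha_diversity(x)
    expect_lte(d$shannon, log(12) + 1e-12)
    expect_lte(d$inv_simpson, 12 + 1e-12)
  }
})

test_that("one-way ANOVA reproduces hand sums of squares and degenerate cases", {
  res <- one_way_anova(list(c(0, 1), c(2, 3), c(4, 5)))
  expect_equal(res$F, 16)
  expect_equal(res$df_between, 2L)
  expect_equal(res$df_within, 3L)
  expect_equal(res$p, stats::pf(16, 2, 3, lower.tail = FALSE))

  same <- one_way_anova(list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3)))
  expect_equal(same$F, 0)

  const <- one_way_anova(list(c(1, 1), c(1, 1)))
  expect_equal(const$F, 0)
  expect_equal(const$p, 1)

  sep <- one_way_anova(list(c(1, 1), c(2, 2)))
  expect_equal(sep$F, Inf)
  expect_equal(sep$p, 0)
  expect_true(sep$degenerate)

  # two groups: F equals the squared pooled-variance t statistic
  set.seed(7)
  for (i in 1:5) {
    a <- rnorm(6); b <- rnorm(5, mean = 1)
    f <- one_way_anova(list(a, b))$F
    t2 <- stats::t.test(a, b, var.equal = TRUE)$statistic^2
    expect_equal(f, unname(t2), tolerance = 1e-10)
  }

  # brute-force oracle on random instances
  set.seed(11)
  for (i in 1:10) {
    g <- lapply(1:3, function(j) rnorm(3 + j))
    y <- unlist(g); gm <- mean(y)
    ssb <- sum(lengths(g) * (vapply(g, mean, 1) - gm)^2)
    ssw <- sum(unlist(lapply(g, function(x) (x - mean(x))^2)))
    fo <- (ssb / 2) / (ssw / (length(y) - 3))
    expect_equal(one_way_anova(g)$F, fo, tolerance = 1e-10)
  }
})

test_that("tukey hsd ranks pairs by mean difference and matches TukeyHSD", {
  g <- list(a = c(0, 1), b = c(2, 3), c = c(4, 5))
  th <- tukey_hsd(g)
  expect_equal(th$group_a[which.max(th$q)], "a")
  expect_equal(th$group_b[which.max(th$q)], "c")
  # q = |diff| / sqrt(MSW/n) for equal n
  msw <- 0.5
  expect_equal(th$q[th$group_a == "a" & th$group_b == "c"],
               4 / sqrt(msw / 2), tolerance = 1e-12)

  # agree with stats::TukeyHSD on a seeded instance
  set.seed(5)
  g2 <- list(x = rnorm(5), y = rnorm(5, 1), z = rnorm(5, 2))
  th2 <- tukey_hsd(g2)
  y <- unlist(g2)
  grp <- factor(rep(names(g2), each = 5))
  ref <- stats::TukeyHSD(stats::aov(y ~ grp))$grp
  for (i in seq_len(nrow(th2))) {
    key <- paste0(th2$group_b[i], "-", th2$group_a[i])
    expect_equal(th2$p_adj[i], ref[key, "p adj"], tolerance = 1e-8)
    expect_equal(th2$difference[i], ref[key, "diff"], tolerance = 1e-12)
  }

  ident <- tukey_hsd(list(a = c(1, 2), b = c(1, 2)))
  expect_false(any(ident$significant))
})

test_that("BH adjustment follows the step-up procedure and preserves order", {
  p <- c(0.01, 0.02, 0.04, 0.8)
  adj <- stats::p.adjust(p, method = "BH")
  expect_equal(adj, c(0.04, 0.04, 0.04 * 4 / 3, 0.8), tolerance = 1e-12)
  set.seed(3)
  praw <- runif(50)
  padj <- stats::p.adjust(praw, method = "BH")
  expect_true(all(diff(padj[order(praw)]) >= -1e-15))
})

test_that("phase-peak tests find separated features and respect constants", {
  vals <- matrix(0.01, 9, 4,
                 dimnames = list(paste0("s", 1:9), paste0("f", 1:4)))
  phases <- rep(c("P1", "P2", "P3"), each = 3)
  vals[phases == "P1", 1] <- 0.5   # f1 peaks in P1
  vals[phases == "P2", 2] <- 0.3   # f2 peaks in P2
  cm <- community_matrix(vals, mode = "relative")
  res <- phase_peak_test(cm, phases = phases)
  expect_equal(res$peak_phase[res$feature == "f1"], "P1")
  expect_equal(res$peak_phase[res$feature == "f2"], "P2")
  expect_true(res$significant[res$feature == "f1"])
  # a feature that stays constant after row normalization gets p = 1
  vals2 <- cbind(0.8 * vals / rowSums(vals), f5 = 0.2)
  res2 <- phase_peak_test(community_matrix(vals2, mode = "relative",
                                           normalize = FALSE),
                          phases = phases, transform = "none")
  expect_equal(res2$p_raw[res2$feature == "f5"], 1)
  expect_false(res2$significant[res2$feature == "f5"])
})

test_that("phase-peak false discoveries stay near the nominal FDR on null data", {
  hits <- 0; total <- 0
  for (s in 1:20) {
    set.seed(400 + s)
    vals <- matrix(rexp(9 * 30), 9, 30,
                   dimnames = list(paste0("s", 1:9), paste0("f", 1:30)))
    cm <- community_matrix(vals, mode = "relative")
    res <- phase_peak_test(cm, phases = rep(c("P1", "P2", "P3"), each = 3))
    hits <- hits + sum(res$significant)
    total <- total + nrow(res)
  }
  expect_lte(hits / total, 0.05 + 0.05)
})

test_that("permanova and anosim separate disjoint groups and are seeded", {
  d <- matrix(1, 6, 6, dimnames = list(paste0("s", 1:6), paste0("s", 1:6)))
  diag(d) <- 0
  d[1:3, 1:3] <- 0.01; d[4:6, 4:6] <- 0.01; diag(d) <- 0
  labels <- rep(c("a", "b"), each = 3)
  an <- group_significance(d, labels, method = "anosim", permutations = 199, seed = 4)
  expect_equal(an$statistic, 1)
  # with 6 samples the exact 3|3 split recurs in ~10% of label
  # permutations, so the minimum attainable p is about 0.1
  expect_lte(an$p, 0.12)
  pm <- group_significance(d, labels, method = "permanova", permutations = 199, seed = 4)
  expect_gt(pm$statistic, 10)
  expect_equal(pm, group_significance(d, labels, method = "permanova",
                                      permutations = 199, seed = 4))
  expect_gte(pm$p, 1 / 200)  # +1 smoothing keeps p attainable

  expect_error(group_significance(d, c("a", rep("b", 5)), "permanova"),
               "every group needs >= 2")
})

test_that("pcoa reproduces collinear geometry and euclidean distances", {
  pts <- c(0, 1, 2)
  d <- as.matrix(stats::dist(pts))
  dimnames(d) <- list(paste0("s", 1:3), paste0("s", 1:3))
  fit <- pcoa(d)
  rec <- as.matrix(stats::dist(fit$coordinates[, 1]))
  expect_lt(max(abs(rec - d)), 1e-9)
  expect_lt(abs(fit$eigenvalues[2]), 1e-9)
  expect_equal(sum(fit$proportion_explained), 1)

  # euclidean input: non-negative eigenvalues, distances reproduced
  set.seed(9)
  x <- matrix(rnorm(5 * 3), 5)
  de <- as.matrix(stats::dist(x))
  dimnames(de) <- list(paste0("s", 1:5), paste0("s", 1:5))
  fe <- pcoa(de)
  expect_true(all(fe$eigenvalues > -1e-9))
  rec2 <- as.matrix(stats::dist(fe$coordinates))
  expect_lt(max(abs(rec2 - de)), 1e-8)

  dd <- de; dd[1, 2] <- dd[1, 2] + 1
  expect_error(pcoa(dd), "symmetric")
})

test_that("upgma merges by hand-computed average linkage and fixes ultrametric input", {
  d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  hc <- upgma_cluster(d)
  expect_equal(sort(hc$height), c(2, 4))
  coph <- as.matrix(stats::cophenetic(hc))
  expect_equal(coph[rownames(d), colnames(d)], d)

  # permuting input order yields the same merge heights
  ord <- c("C", "A", "B")
  hc2 <- upgma_cluster(d[ord, ord])
  expect_equal(sort(hc2$height), sort(hc$height))
})

test_that("percent reduction reproduces the printed COD arithmetic", {
  expect_equal(percent_reduction(27595.16, 3959.78), 85.65045, tolerance = 1e-5)
  expect_equal(round_half_up(percent_reduction(27595.16, 3959.78)), 86)
  expect_equal(round_half_up(percent_reduction(25457.29, 4316.09)), 83)
  expect_equal(percent_reduction(5, 5), 0)
  expect_error(percent_reduction(0, 1), "positive")
  expect_equal(round_half_up(0.5), 1)
  expect_equal(round_half_up(-0.5), -1)
  expect_equal(round_half_up(85.65), 86)
})
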