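# Small fixtures built in code; no binary files.

# three-tip tree used throughout: ((A:1,B:1):1,C:2);
fixture_tree3 <- function() ape::read.tree(text = "((A:1,B:1):1,C:2);")

fixture_dist3 <- function() cophenetic_distances(fixture_tree3())

# random relative community over the taxa of a tree
random_community <- function(tree, n_samples = 2L, seed = 1L) {
  taxa <- tree$tip.label
  set.seed(seed)
  vals <- matrix(stats::rexp(n_samples * length(taxa)), n_samples,
                 dimnames = list(paste0("S", seq_len(n_samples)), taxa))
  # sparsify: drop ~half the entries
  vals[matrix(stats::runif(length(vals)) < 0.5, nrow(vals))] <- 0
  vals[rowSums(vals) == 0, 1L] <- 1
  community_matrix(vals, mode = "relative")
}

# brute-force betaMNTD oracle: explicit double loop over present taxa
beta_mntd_oracle <- function(f_k, f_m, dist) {
  ids <- rownames(dist)
  f_k <- f_k[ids] / sum(f_k[ids])
  f_m <- f_m[ids] / sum(f_m[ids])
  pk <- which(f_k > 0)
  pm <- which(f_m > 0)
  term_k <- 0
  for (i in pk) {
    best <- Inf
    for (j in pm) best <- min(best, dist[i, j])
    term_k <- term_k + f_k[i] * best
  }
  term_m <- 0
  for (j in pm) {
    best <- Inf
    for (i in pk) best <- min(best, dist[j, i])
    term_m <- term_m + f_m[j] * best
  }
  as.numeric(0.5 * (term_k + term_m))
}

write_tsv_fixture <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
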