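#' Simulate a Yule (pure-birth) phylogeny
#'
#' Tree grown tip-by-tip with exponential waiting times, then rescaled
#' to total height 1, so trait-diffusion rates and selection widths are
#' expressed per unit tree height.
#'
#' @param n_taxa number of tips (>= 2).
#' @param seed integer seed; the Newick string is deterministic given it.
#' @return ultrametric `ape::phylo` tree of height 1 with tips
#'   `t1..tn`.
#' @export
simulate_yule_tree <- function(n_taxa, seed = 1L) {
  n_taxa <- as.integer(n_taxa)
  if (n_taxa < 2L) stop("n_taxa must be >= 2")
  tree <- with_seed(seed, ape::rphylo(n_taxa, birth = 1, death = 0))
  depths <- ape::node.depth.edgelength(tree)
  height <- max(depths[seq_len(n_taxa)])
  tree$edge.length <- tree$edge.length / height
  tree
}

#' Evolve a neutral trait by Brownian motion
#'
#' Plain BM along the branches of the given tree: tip variance is
#' `bm_sigma^2 * depth` and the covariance between two tips equals
#' `bm_sigma^2` times their shared branch length, so closely related
#' tips carry similar values.
#'
#' @param tree `ape::phylo` tree with branch lengths.
#' @param bm_sigma diffusion rate (trait units per square-root unit
#'   branch length).
#' @param seed integer seed.
#' @return named numeric vector of tip trait values (root value 0).
#' @export
evolve_trait_bm <- function(tree, bm_sigma = 1, seed = 1L) {
  stopifnot(inherits(tree, "phylo"))
  if (bm_sigma < 0) stop("bm_sigma must be >= 0")
  if (bm_sigma == 0) {
    return(stats::setNames(rep(0, length(tree$tip.label)), tree$tip.label))
  }
  with_seed(seed, ape::rTraitCont(tree, model = "BM", sigma = bm_sigma,
                                  root.value = 0))
}

#' Habitat-commitment transform of a phylogeny
#'
#' Rescales node depths so that trait evolution on the transformed tree
#' behaves as Brownian motion until lineages commit to a habitat at
#' relative depth `commit_depth`, after which the trait is nearly frozen
#' within each clade (a small `residual` rate keeps tip values
#' distinct).  This concentrates niche variance between intermediate-age
#' clades -- the strong phylogenetic niche conservatism under which
#' environmental filtering leaves a nearest-taxon signature.
#'
#' @param tree ultrametric `ape::phylo` tree.
#' @param commit_depth relative depth (0-1) at which niches freeze.
#' @param residual residual diffusion fraction after commitment.
#' @return tree with transformed branch lengths (same topology/labels).
#' @export
conserve_niche_tree <- function(tree, commit_depth = 0.6, residual = 0.02) {
  stopifnot(inherits(tree, "phylo"))
  if (commit_depth <= 0 || commit_depth > 1) stop("commit_depth must be in (0, 1]")
  n <- length(tree$tip.label)
  depth <- ape::node.depth.edgelength(tree)
  depth <- depth / max(depth[seq_len(n)])
  tdepth <- pmin(depth, commit_depth) + residual * depth
  tree$edge.length <- tdepth[tree$edge[, 2L]] - tdepth[tree$edge[, 1L]]
  tree
}

#' Evolve a multivariate conserved niche
#'
#' Draws `k` independent Brownian traits on the habitat-commitment
#' transform of the tree.  Several independent conserved axes make the
#' niche clade-specific: unrelated clades rarely converge on all axes
#' at once, so a Gaussian product kernel around any one species' niche
#' selects an (approximately) monophyletic neighborhood.
#'
#' @param tree ultrametric `ape::phylo` tree.
#' @param k number of niche axes (default 5).
#' @param bm_sigma per-axis diffusion rate.
#' @param seed integer seed (one derived stream per axis).
#' @param commit_depth,residual passed to [conserve_niche_tree()].
#' @return tips x k matrix of niche positions.
#' @export
evolve_niche_traits <- function(tree, k = 5L, bm_sigma = 1, seed = 1L,
                                commit_depth = 0.6, residual = 0.02) {
  ntree <- conserve_niche_tree(tree, commit_depth, residual)
  out <- vapply(seq_len(k), function(j) {
    evolve_trait_bm(ntree, bm_sigma = bm_sigma,
                    seed = derive_seed(seed, "niche_axis", j))
  }, numeric(length(tree$tip.label)))
  rownames(out) <- tree$tip.label
  out
}

# Gaussian product kernel over niche axes; sel_width recycled per axis.
# Returns list(w = weights, z2 = squared niche distance in width units).
niche_weights <- function(traits, env, sel_width) {
  if (is.null(dim(traits))) traits <- cbind(traits)
  env <- rep_len(env, ncol(traits))
  sel_width <- rep_len(sel_width, ncol(traits))
  z <- sweep(sweep(traits, 2L, env), 2L, sel_width, "/")
  z[!is.finite(z)] <- 0  # sel_width = Inf disables an axis
  z2 <- rowSums(z^2)
  list(w = exp(-z2 / 2), z2 = z2)
}

#' Assemble samples under a selection/dispersal/drift regime
#'
#' Generative model, per sample `s`:
#' \enumerate{
#'   \item Metacommunity abundances `lambda_i ~ lognormal(0, 1)` (one
#'     draw per scenario).
#'   \item Selection: Gaussian product kernel `w_i = exp(-z2_i / 2)`
#'     where `z2_i` is the squared niche distance between species `i`
#'     and the sample's environment in units of `sel_width`
#'     (`sel_width = Inf` disables selection).
#'   \item Drift: per-sample lognormal jitter `eta ~ lognormal(0,
#'     drift_sigma)` on realized abundances.
#'   \item Establishment: with `lottery = TRUE` (selection regimes) each
#'     sample recruits only a disjoint-leaning half of the suitable
#'     candidate set (`z2 < 9`), emulating lottery/priority effects
#'     among ecologically equivalent species; with `occupancy_pool <
#'     n_taxa` (dispersal limitation) each sample is restricted to a
#'     disjoint-leaning random block of the whole pool.
#'   \item Dispersal: `round(mix * depth)` individuals come from one
#'     shared immigrant pool (a single multinomial realization of the
#'     metacommunity, identical for every sample) -- shared realized
#'     individuals are what make communities more similar than any
#'     independent assembly.
#'   \item Sampling drift: the remaining individuals are one multinomial
#'     draw from the sample's expected proportions.
#' }
#'
#' @param scenario list with fields n_samples, sel_width, env (vector,
#'   or samples x axes matrix), mix, depth, occupancy_pool, drift_sigma,
#'   lottery, seed.
#' @param tree phylogeny whose tips are the species pool.
#' @param traits niche positions: named vector (one axis) or tips x k
#'   matrix from [evolve_niche_traits()].
#' @return pseudocount-mode `community_matrix` (samples `S1..Sn`).
#' @export
assemble_regime_samples <- function(scenario, tree, traits) {
  taxa <- tree$tip.label
  if (is.null(dim(traits))) {
    if (!setequal(names(traits), taxa)) stop("traits must be indexed by tree tips")
    traits <- cbind(traits[taxa])
    rownames(traits) <- taxa
  } else {
    if (!setequal(rownames(traits), taxa)) stop("traits must be indexed by tree tips")
    traits <- traits[taxa, , drop = FALSE]
  }
  n_taxa <- length(taxa)
  ns <- scenario$n_samples
  env <- scenario$env
  if (is.null(dim(env))) {
    env <- matrix(rep_len(env, ns * ncol(traits)), nrow = ns)
  } else if (nrow(env) != ns) {
    env <- env[rep_len(seq_len(nrow(env)), ns), , drop = FALSE]
  }
  mix <- scenario$mix
  if (mix < 0 || mix > 1) stop("mix must lie in [0, 1]")
  drift_sigma <- if (is.null(scenario$drift_sigma)) 1 else scenario$drift_sigma
  lottery <- isTRUE(scenario$lottery)
  pool_size <- scenario$occupancy_pool
  if (is.null(pool_size)) pool_size <- n_taxa
  if (pool_size < 2L) stop("occupancy_pool must be >= 2")
  with_seed(derive_seed(scenario$seed, "assemble"), {
    lambda <- stats::rlnorm(n_taxa, 0, 1)
    p_meta <- lambda / sum(lambda)
    n_immigrant <- as.integer(round(mix * scenario$depth))
    immigrants <- if (n_immigrant > 0L) {
      stats::rmultinom(1L, n_immigrant, p_meta)[, 1L]
    } else {
      integer(n_taxa)
    }
    # one shuffled taxon order shared by all samples: consecutive blocks
    # give disjoint-leaning establishment sets
    pool_order <- sample.int(n_taxa)
    counts <- matrix(0L, ns, n_taxa,
                     dimnames = list(paste0("S", seq_len(ns)), taxa))
    for (s in seq_len(ns)) {
      nw <- niche_weights(traits, env[s, ], scenario$sel_width)
      eta <- if (drift_sigma > 0) stats::rlnorm(n_taxa, 0, drift_sigma) else 1
      p <- lambda * eta * nw$w
      if (lottery) {
        suitable <- which(nw$z2 < 9)
        if (length(suitable) < 10L) {
          # isolated niche: fall back to the best-suited species
          suitable <- order(nw$z2)[seq_len(min(10L, n_taxa))]
        }
        cand <- pool_order[pool_order %in% suitable]
        half <- max(2L, as.integer(ceiling(length(cand) / 2)))
        idx <- cand[((s - 1L) * half + seq_len(half) - 1L) %% length(cand) + 1L]
        keep <- numeric(n_taxa)
        keep[idx] <- 1
        p <- p * keep
      } else if (pool_size < n_taxa) {
        idx <- pool_order[((s - 1L) * pool_size + seq_len(pool_size) - 1L) %% n_taxa + 1L]
        keep <- numeric(n_taxa)
        keep[idx] <- 1
        p <- p * keep
      }
      if (sum(p) == 0) stop("no taxon has positive recruitment probability")
      p <- p / sum(p)
      own <- stats::rmultinom(1L, scenario$depth - n_immigrant, p)[, 1L]
      counts[s, ] <- immigrants + own
    }
    community_matrix(counts, mode = "pseudocount")
  })
}

regime_defaults <- function(regime, n_taxa, traits, seed) {
  sd_axis <- apply(traits, 2L, stats::sd)
  n_tips <- nrow(traits)
  # environments anchored at real species' niches: a random resident and
  # the resident most distant from it in niche space (contrast pair)
  anchor <- derive_seed(seed, "env") %% n_tips + 1L
  zd <- sweep(sweep(traits, 2L, traits[anchor, ]), 2L, sd_axis, "/")
  contrast <- which.max(rowSums(zd^2))
  env_one <- traits[anchor, , drop = FALSE]
  env_two <- traits[c(anchor, contrast), , drop = FALSE]
  base <- list(drift_sigma = 1, lottery = FALSE, occupancy_pool = n_taxa)
  over <- switch(regime,
    variable_selection = list(sel_width = 0.3 * sd_axis, env = env_two,
                              mix = 0, depth = 5000L),
    homogeneous_selection = list(sel_width = 0.3 * sd_axis, env = env_one,
                                 mix = 0, depth = 5000L, lottery = TRUE),
    homogenizing_dispersal = list(sel_width = Inf, env = 0,
                                  mix = 0.95, depth = 5000L),
    dispersal_limitation = list(sel_width = Inf, env = 0,
                                mix = 0, depth = 200L,
                                occupancy_pool = max(2L, n_taxa %/% 4L)),
    undominated = list(sel_width = 2 * sqrt(ncol(traits)) * sd_axis,
                       env = env_one, mix = 0.3, depth = 2000L,
                       drift_sigma = 0.25),
    stop("unknown regime: ", regime)
  )
  base[names(over)] <- over
  base
}

#' Generate a ready-to-analyze scenario under one assembly regime
#'
#' Builds a Yule tree, a multivariate conserved niche
#' ([evolve_niche_traits()]), and a community matrix assembled under the
#' named regime with documented default parameters.  Environments are
#' anchored at real species' niche positions: selection regimes filter
#' around the niche of a randomly chosen resident (homogeneous) or of a
#' contrasting resident pair (variable selection, undominated).
#'
#' @param regime one of `"variable_selection"`, `"homogeneous_selection"`,
#'   `"homogenizing_dispersal"`, `"dispersal_limitation"`,
#'   `"undominated"`.
#' @param seed integer root seed; tree, niche, and assembly each get a
#'   derived stream.
#' @param n_taxa species-pool size (default 150).
#' @param n_samples samples to assemble (default 6).
#' @param bm_sigma per-axis trait diffusion rate (default 1).
#' @param n_niche_axes independent conserved niche axes (default 5).
#' @param commit_depth habitat-commitment depth for niche conservatism
#'   (default 0.6).
#' @param overrides named list overriding any scenario field (sel_width,
#'   env, mix, depth, occupancy_pool, drift_sigma, lottery).
#' @return list with elements `tree`, `matrix` (pseudocount
#'   `community_matrix`), `traits` (tips x axes), and `scenario`.
#' @export
generate_scenario <- function(regime, seed = 1L, n_taxa = 150L,
                              n_samples = 6L, bm_sigma = 1,
                              n_niche_axes = 5L, commit_depth = 0.6,
                              overrides = list()) {
  regime <- match.arg(regime, process_labels)
  if (n_taxa < 3L) stop("n_taxa must be >= 3")
  tree <- simulate_yule_tree(n_taxa, seed = derive_seed(seed, "tree"))
  traits <- evolve_niche_traits(tree, k = n_niche_axes, bm_sigma = bm_sigma,
                                seed = derive_seed(seed, "traits"),
                                commit_depth = commit_depth)
  params <- regime_defaults(regime, n_taxa, traits, seed)
  params[names(overrides)] <- overrides
  scenario <- c(list(regime = regime, n_taxa = as.integer(n_taxa),
                     n_samples = as.integer(n_samples),
                     bm_sigma = bm_sigma,
                     n_niche_axes = as.integer(n_niche_axes),
                     commit_depth = commit_depth,
                     seed = as.integer(seed)),
                params)
  if (scenario$depth < scenario$occupancy_pool) {
    stop("depth must be >= occupancy_pool so every presence is representable")
  }
  mat <- assemble_regime_samples(scenario, tree, traits)
  list(tree = tree, matrix = mat, traits = traits, scenario = scenario)
}

#' Write a scenario bundle to a directory
#'
#' Emits `tree.nwk`, `abundance.tsv`, `meta.csv`, and `scenario.json`
#' (all generative parameters plus the seed), so a scenario round-trips
#' through the package's own readers.
#'
#' @param bundle output of [generate_scenario()].
#' @param dir output directory (created if missing).
#' @export
write_scenario <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ape::write.tree(bundle$tree, file.path(dir, "tree.nwk"))
  write_abundance_table(bundle$matrix, file.path(dir, "abundance.tsv"))
  utils::write.csv(data.frame(sample_id = sample_ids(bundle$matrix)),
                   file.path(dir, "meta.csv"), row.names = FALSE, quote = FALSE)
  sc <- bundle$scenario
  sc$env <- if (is.null(dim(sc$env))) sc$env else apply(sc$env, 1L, list)
  sc$sel_width <- unname(sc$sel_width)
  jsonlite::write_json(lapply(sc, unname),
                       file.path(dir, "scenario.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}

#' Parameter-recovery experiment for one regime
#'
#' Generates `n_pairs` independent scenarios under the regime, scores
#' the first sample pair of each with betaNTI and RCbray (the whole
#' scenario sample set serves as the RCbray metacommunity), and
#' classifies it.  Recovery of the generating regime as the modal label
#' validates the whole inference chain end to end.  A pair whose
#' communities share every present taxon carries no phylogenetic
#' turnover signal (its betaNTI null is degenerate); such pairs fall to
#' the stochastic side with betaNTI recorded as 0.
#'
#' @param regime generating process label.
#' @param n_pairs scenarios (= scored pairs) to draw (default 20).
#' @param reps null replicates (default 999).
#' @param seed root seed.
#' @param n_taxa,n_samples scenario dimensions.
#' @return data.frame with one row per pair: scenario_seed, beta_nti,
#'   rc_bray, process.
#' @export
regime_recovery <- function(regime, n_pairs = 20L, reps = 999L, seed = 1L,
                            n_taxa = 150L, n_samples = 6L) {
  rows <- lapply(seq_len(n_pairs), function(i) {
    sc_seed <- derive_seed(seed, "recovery", regime, i)
    bundle <- generate_scenario(regime, seed = sc_seed, n_taxa = n_taxa,
                                n_samples = n_samples)
    dist <- cophenetic_distances(bundle$tree)
    rel <- community_matrix(bundle$matrix$values, mode = "relative")
    pair <- sample_ids(rel)[1:2]
    bn <- beta_nti(subset_samples(rel, pair), dist, reps = reps,
                   seed = sc_seed, degenerate = "zero")$beta_nti[1L]
    rc <- raup_crick_bray(bundle$matrix, reps = reps, seed = sc_seed,
                          pairs = matrix(pair, ncol = 2L))
    data.frame(scenario_seed = sc_seed, beta_nti = bn,
               rc_bray = rc$rc_bray[1L],
               process = classify_process(bn, rc$rc_bray[1L]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Restrict a community matrix to a subset of samples
#'
#' @param x a `community_matrix`.
#' @param ids sample identifiers to keep.
#' @return a `community_matrix` over the selected samples.
#' @export
subset_samples <- function(x, ids) {
  stopifnot(inherits(x, "community_matrix"))
  if (!all(ids %in% sample_ids(x))) stop("unknown sample id(s)")
  meta <- x$sample_meta
  if (!is.null(meta)) meta <- meta[meta$sample_id %in% ids, , drop = FALSE]
  community_matrix(x$values[ids, , drop = FALSE], mode = x$mode,
                   sample_meta = meta, normalize = FALSE,
                   transformed = x$transformed)
}
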