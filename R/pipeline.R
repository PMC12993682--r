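#' Default run configuration
#'
#' @param reps permutation/null replicates (>= 99).
#' @param seed root seed for every random stream.
#' @param depth pseudocount depth for the RCbray null and diversity.
#' @param bnti_threshold deterministic/stochastic split on `|betaNTI|`.
#' @param rc_threshold dispersal split on `|RCbray|`.
#' @param fdr_q FDR threshold for phase-peak tests.
#' @param abundance_filter,low_abundance_filter relative-abundance
#'   screens used by the similarity analyses (defaults 0.001 and 0.0002,
#'   i.e. the 0.1% and 0.02% cutoffs).
#' @return named list of configuration values.
#' @export
run_config <- function(reps = 999L, seed = 1L, depth = 10000L,
                       bnti_threshold = 2, rc_threshold = 0.95,
                       fdr_q = 0.05, abundance_filter = 0.001,
                       low_abundance_filter = 2e-4) {
  if (reps < 99L) stop("reps must be >= 99")
  if (bnti_threshold <= 0 || rc_threshold <= 0 || fdr_q <= 0) {
    stop("thresholds must be positive")
  }
  list(reps = as.integer(reps), seed = as.integer(seed),
       depth = as.integer(depth), bnti_threshold = bnti_threshold,
       rc_threshold = rc_threshold, fdr_q = fdr_q,
       abundance_filter = abundance_filter,
       low_abundance_filter = low_abundance_filter)
}

write_csv6 <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1L))
  df[num] <- lapply(df[num], signif, digits = 6L)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the full assembly + succession analysis
#'
#' Chains harmonization, betaNTI, RCbray, process classification,
#' phase-pair aggregation, alpha diversity, phase-peak tests, PCoA, and
#' UPGMA clustering, writing tidy CSV outputs and a machine-readable run
#' manifest into `out_dir`.
#'
#' @param matrix relative-mode `community_matrix` (with `sample_meta`
#'   carrying digester/phase for the phase-level outputs).
#' @param tree `ape::phylo` phylogeny covering (a superset of) the taxa.
#' @param config list from [run_config()].
#' @param out_dir output directory (created if missing).
#' @return invisibly, a list with the main result tables.
#' @export
run_full_analysis <- function(matrix, tree, config = run_config(),
                              out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- "harmonize"
  res <- tryCatch({
    harm <- harmonize_taxa(matrix, tree)
    utils::write.csv(
      data.frame(sample_id = names(harm$report$dropped_abundance),
                 dropped_abundance = harm$report$dropped_abundance,
                 row.names = NULL),
      file.path(out_dir, "harmonization_report.csv"), row.names = FALSE)
    dist <- cophenetic_distances(harm$tree)

    stage <- "assembly"
    assembly <- infer_assembly(harm$matrix, dist, reps = config$reps,
                               seed = config$seed, depth = config$depth)
    write_csv6(assembly, file.path(out_dir, "assembly_pairs.csv"))

    meta <- harm$matrix$sample_meta
    phase_summary <- NULL
    if (!is.null(meta) && length(unique(meta$phase)) >= 2L) {
      stage <- "phase_aggregation"
      phase_summary <- phase_pair_summary(assembly, meta)
      write_csv6(phase_summary[, setdiff(names(phase_summary), "labels")],
                 file.path(out_dir, "assembly_phase_pairs.csv"))
    }

    stage <- "diversity"
    counts <- to_pseudocounts(harm$matrix, depth = config$depth)
    div <- do.call(rbind, lapply(sample_ids(counts), function(s) {
      d <- suppressWarnings(alpha_diversity(counts$values[s, ]))
      data.frame(sample_id = s, shannon = d$shannon, simpson = d$simpson,
                 inv_simpson = d$inv_simpson, fisher_alpha = d$fisher_alpha)
    }))
    write_csv6(div, file.path(out_dir, "alpha_diversity.csv"))

    peaks <- NULL
    if (!is.null(meta) && all(table(meta$phase) >= 2L)) {
      stage <- "phase_peaks"
      peaks <- phase_peak_test(harm$matrix, fdr_q = config$fdr_q)
      write_csv6(peaks, file.path(out_dir, "phase_peaks.csv"))
    }

    stage <- "ordination"
    bc <- bray_curtis_matrix(harm$matrix)
    ord <- pcoa(bc)
    write_csv6(data.frame(sample_id = rownames(ord$coordinates),
                          ord$coordinates, check.names = FALSE),
               file.path(out_dir, "pcoa_coordinates.csv"))
    write_csv6(data.frame(axis = seq_along(ord$eigenvalues),
                          eigenvalue = ord$eigenvalues),
               file.path(out_dir, "pcoa_eigenvalues.csv"))

    stage <- "clustering"
    hc <- upgma_cluster(bc)
    ape::write.tree(ape::as.phylo(hc), file.path(out_dir, "upgma_dendrogram.nwk"))

    stage <- "manifest"
    manifest <- list(
      package = "adassembly",
      version = as.character(utils::packageVersion("adassembly")),
      config = config,
      n_samples = nrow(harm$matrix$values),
      n_taxa = ncol(harm$matrix$values),
      dropped_taxa = harm$report$dropped_taxa,
      rc_null = "abundance-based (richness and total abundance fixed at observed; metacommunity = all samples)")
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    list(assembly = assembly, phase_summary = phase_summary,
         diversity = div, peaks = peaks, ordination = ord,
         dendrogram = hc, harmonization = harm$report)
  }, error = function(e) {
    writeLines(paste0("FAILED at stage '", stage, "': ", conditionMessage(e)),
               file.path(out_dir, "FAILED"))
    stop("run_full_analysis failed at stage '", stage, "': ",
         conditionMessage(e), call. = FALSE)
  })
  invisible(res)
}
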