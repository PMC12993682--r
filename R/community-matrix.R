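#' Construct a community matrix
#'
#' The central container of the package: a samples x taxa abundance table
#' with an abundance mode and optional per-sample metadata (digester,
#' phase).  Relative-mode matrices are row-normalized so each sample sums
#' to 1; pseudocount-mode matrices hold non-negative integers.
#'
#' @param values numeric matrix, samples in rows, taxa in columns, with
#'   unique dimnames on both margins.
#' @param mode `"relative"` or `"pseudocount"`.
#' @param sample_meta optional data.frame with columns `sample_id`,
#'   `digester`, `phase`; one row per sample.
#' @param normalize for relative mode, renormalize rows to sum to 1
#'   (default `TRUE`).  Ignored in pseudocount mode.
#' @param transformed logical flag marking matrices whose rows are no
#'   longer on the simplex (e.g. after [hellinger_transform()]).
#' @return an object of class `community_matrix`: a list with elements
#'   `values`, `mode`, `sample_meta`, `transformed`.
#' @export
community_matrix <- function(values, mode = c("relative", "pseudocount"),
                             sample_meta = NULL, normalize = TRUE,
                             transformed = FALSE) {
  mode <- match.arg(mode)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("'values' must be a numeric matrix (samples x taxa)")
  }
  if (nrow(values) == 0L) stop("no samples")
  if (ncol(values) == 0L) stop("no taxa")
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("'values' must carry sample (row) and taxon (column) names")
  }
  rownames(values) <- trimws(rownames(values))
  colnames(values) <- trimws(colnames(values))
  if (anyDuplicated(rownames(values))) stop("duplicate sample identifiers")
  if (anyDuplicated(colnames(values))) stop("duplicate taxon identifiers")
  if (anyNA(values)) stop("missing values in abundance table")
  if (any(values < 0)) stop("negative abundances")
  if (mode == "relative") {
    rs <- rowSums(values)
    if (any(rs == 0)) {
      stop("empty sample: ", paste(rownames(values)[rs == 0], collapse = ", "))
    }
    if (normalize && !transformed) values <- values / rs
  } else {
    if (any(values != round(values))) {
      stop("pseudocount mode requires non-negative integers")
    }
  }
  if (!is.null(sample_meta)) {
    sample_meta <- as.data.frame(sample_meta)
    need <- c("sample_id", "digester", "phase")
    miss <- setdiff(need, names(sample_meta))
    if (length(miss)) stop("sample_meta lacks columns: ", paste(miss, collapse = ", "))
    if (!all(rownames(values) %in% sample_meta$sample_id)) {
      stop("sample_meta does not cover all samples")
    }
    sample_meta <- sample_meta[match(rownames(values), sample_meta$sample_id), , drop = FALSE]
    rownames(sample_meta) <- NULL
  }
  structure(
    list(values = values, mode = mode, sample_meta = sample_meta,
         transformed = isTRUE(transformed)),
    class = "community_matrix"
  )
}

#' @export
print.community_matrix <- function(x, ...) {
  cat(sprintf("community_matrix: %d samples x %d taxa, mode=%s%s\n",
              nrow(x$values), ncol(x$values), x$mode,
              if (x$transformed) " (transformed)" else ""))
  if (!is.null(x$sample_meta)) {
    cat("phases:", paste(unique(x$sample_meta$phase), collapse = " "), "\n")
  }
  invisible(x)
}

#' @export
dim.community_matrix <- function(x) dim(x$values)

sample_ids <- function(x) rownames(x$values)
taxon_ids <- function(x) colnames(x$values)

#' Read a TSV abundance table
#'
#' @param path TSV file; first row and first column hold identifiers.
#' @param orientation `"samples_rows"` (default) or `"taxa_rows"`.
#' @param mode abundance mode of the result; relative tables are
#'   row-normalized.
#' @param sample_meta optional metadata forwarded to [community_matrix()].
#' @return a `community_matrix` in samples x taxa orientation.
#' @export
read_abundance_table <- function(path, orientation = c("samples_rows", "taxa_rows"),
                                 mode = c("relative", "pseudocount"),
                                 sample_meta = NULL) {
  orientation <- match.arg(orientation)
  mode <- match.arg(mode)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = "character", comment.char = "")
  if (nrow(df) == 0L || ncol(df) < 2L) stop("no samples: empty table in ", path)
  ids <- trimws(df[[1L]])
  if (anyDuplicated(ids)) stop("duplicate identifiers in first column of ", path)
  body <- df[, -1L, drop = FALSE]
  num <- suppressWarnings(vapply(body, as.numeric, numeric(nrow(body))))
  if (nrow(body) == 1L) num <- matrix(num, nrow = 1L, dimnames = list(NULL, colnames(body)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric cell in %s at row '%s', column '%s'",
                 path, ids[bad[["row"]]], colnames(body)[bad[["col"]]]))
  }
  rownames(num) <- ids
  if (orientation == "taxa_rows") num <- t(num)
  community_matrix(num, mode = mode, sample_meta = sample_meta)
}

#' Write a community matrix as TSV
#'
#' Inverse of [read_abundance_table()] (samples_rows orientation);
#' identifiers and values round-trip losslessly.
#' @param x a `community_matrix`.
#' @param path output path.
#' @export
write_abundance_table <- function(x, path) {
  stopifnot(inherits(x, "community_matrix"))
  df <- data.frame(sample_id = rownames(x$values), x$values,
                   check.names = FALSE)
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

metaphlan_rank_prefixes <- c(kingdom = "k__", phylum = "p__", class = "c__",
                             order = "o__", family = "f__", genus = "g__",
                             species = "s__", strain = "t__")

#' Read a MetaPhlAn-style merged profile
#'
#' Merged profiles list one clade per row (`k__...|p__...|...|s__...`) and
#' one sample per column, with relative abundances on a 0-100 scale.  A
#' leading `#` comment block and an optional NCBI-taxid second column
#' (header containing "taxid") are both tolerated, since merged-profile
#' dialects vary between versions.
#'
#' @param path merged profile TSV.
#' @param rank taxonomic rank to extract; rows whose deepest rank is
#'   exactly `rank` are kept (for species: contains `s__`, no `t__`).
#' @param sample_meta optional metadata forwarded to [community_matrix()].
#' @return a relative-mode `community_matrix`; taxon ids are the names
#'   after the rank prefix, values are divided by 100 and renormalized.
#' @export
read_metaphlan_merged <- function(path, rank = "species", sample_meta = NULL) {
  rank <- match.arg(rank, names(metaphlan_rank_prefixes)[1:7])
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (!length(lines)) stop("no rows in ", path)
  con <- textConnection(lines)
  on.exit(close(con))
  df <- utils::read.delim(con, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = "character")
  # taxid column dialect: drop a second column whose header mentions taxid
  if (ncol(df) >= 2L && grepl("taxid", tolower(names(df)[2L]))) {
    df <- df[, -2L, drop = FALSE]
  }
  clade <- df[[1L]]
  prefix <- metaphlan_rank_prefixes[[rank]]
  deeper <- metaphlan_rank_prefixes[match(rank, names(metaphlan_rank_prefixes)) + 1L]
  keep <- grepl(prefix, clade, fixed = TRUE) &
    !(if (is.na(deeper)) FALSE else grepl(deeper, clade, fixed = TRUE))
  if (!any(keep)) stop("no rows at rank '", rank, "' in ", path)
  df <- df[keep, , drop = FALSE]
  taxa <- sub(paste0(".*", metaphlan_rank_prefixes[[rank]]), "", df[[1L]])
  vals <- vapply(df[, -1L, drop = FALSE], as.numeric, numeric(nrow(df)))
  if (nrow(df) == 1L) {
    vals <- matrix(vals, nrow = 1L, dimnames = list(NULL, names(df)[-1L]))
  }
  if (anyNA(vals)) stop("non-numeric abundance in ", path)
  if (any(vals < 0 | vals > 100)) stop("abundance outside [0,100] in ", path)
  m <- t(vals) / 100
  colnames(m) <- taxa
  community_matrix(m, mode = "relative", sample_meta = sample_meta)
}

#' Harmonize a community matrix with a phylogeny
#'
#' Taxa absent from the tree (or tips absent from the matrix) are removed
#' so the two objects share one taxon set, the standard preparation for
#' phylogenetic turnover metrics.  Relative rows are renormalized by
#' default and the dropped abundance is reported per sample.
#'
#' @param matrix a `community_matrix`.
#' @param tree an `ape::phylo` tree whose tip labels are taxon ids.
#' @param renormalize renormalize relative rows after dropping taxa
#'   (default `TRUE`).
#' @return list with elements `matrix`, `tree`, and `report`
#'   (`dropped_taxa`, `dropped_tips`, `dropped_abundance` per sample).
#' @export
harmonize_taxa <- function(matrix, tree, renormalize = TRUE) {
  stopifnot(inherits(matrix, "community_matrix"), inherits(tree, "phylo"))
  taxa <- taxon_ids(matrix)
  tips <- trimws(tree$tip.label)
  tree$tip.label <- tips
  shared <- intersect(taxa, tips)
  if (!length(shared)) stop("no shared taxa between matrix and tree")
  dropped_taxa <- setdiff(taxa, shared)
  dropped_tips <- setdiff(tips, shared)
  vals <- matrix$values
  dropped_abundance <- if (length(dropped_taxa)) {
    rowSums(vals[, dropped_taxa, drop = FALSE]) / rowSums(vals)
  } else {
    stats::setNames(rep(0, nrow(vals)), rownames(vals))
  }
  vals <- vals[, shared, drop = FALSE]
  if (any(rowSums(vals) == 0)) {
    stop("sample(s) lost all taxa during harmonization: ",
         paste(rownames(vals)[rowSums(vals) == 0], collapse = ", "))
  }
  out_mat <- community_matrix(vals, mode = matrix$mode,
                              sample_meta = matrix$sample_meta,
                              normalize = matrix$mode == "relative" && renormalize,
                              transformed = matrix$transformed)
  out_tree <- if (length(dropped_tips)) ape::keep.tip(tree, shared) else tree
  list(matrix = out_mat, tree = out_tree,
       report = list(dropped_taxa = dropped_taxa, dropped_tips = dropped_tips,
                     dropped_abundance = dropped_abundance,
                     renormalized = isTRUE(renormalize)))
}

#' Hellinger transform
#'
#' Replaces each relative abundance by its square root, moderating the
#' influence of dominant taxa in downstream distances and correlations.
#' Output rows no longer sum to 1; the result is flagged `transformed`.
#'
#' @param matrix relative-mode `community_matrix`.
#' @return transformed `community_matrix` with values in `[0, 1]`.
#' @export
hellinger_transform <- function(matrix) {
  stopifnot(inherits(matrix, "community_matrix"))
  if (matrix$mode != "relative") {
    stop("hellinger_transform requires a relative-mode matrix; normalize first")
  }
  vals <- matrix$values / rowSums(matrix$values)
  community_matrix(sqrt(vals), mode = "relative",
                   sample_meta = matrix$sample_meta, transformed = TRUE)
}

#' Convert relative abundances to pseudocounts
#'
#' Count-like data are needed by the Raup-Crick null and by Fisher's
#' alpha; profile tables are relative.  Each row is scaled by `depth` and
#' rounded; taxa with positive relative abundance that would round to 0
#' are floored to 1 so presence/absence is preserved exactly.
#'
#' @param matrix relative-mode `community_matrix`.
#' @param depth individuals per sample (default 10000, which keeps 0.02%
#'   taxa as >= 2 counts).
#' @return pseudocount-mode `community_matrix`.
#' @export
to_pseudocounts <- function(matrix, depth = 10000L) {
  stopifnot(inherits(matrix, "community_matrix"))
  if (matrix$mode != "relative") stop("to_pseudocounts requires relative mode")
  depth <- as.integer(depth)
  if (depth < 1L) stop("depth must be positive")
  rel <- matrix$values / rowSums(matrix$values)
  richness <- rowSums(rel > 0)
  if (any(depth < richness)) {
    stop("depth ", depth, " cannot represent all presences (max richness ",
         max(richness), ")")
  }
  counts <- round(rel * depth)
  counts[rel > 0 & counts == 0] <- 1
  community_matrix(counts, mode = "pseudocount",
                   sample_meta = matrix$sample_meta)
}
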