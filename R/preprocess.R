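#' Preprocessing configuration
#'
#' @param window_half half-width of the promoter CpG window in bp; CpGs in
#'   `[tss - window_half, tss + window_half)` form a gene's CpG cluster
#'   (default 2000, i.e. "within 2 kb" of the promoter).
#' @param expr_target_sum library-size normalisation target:
#'   `"median_library"` (default, the median library size across cells) or a
#'   fixed positive number.
#' @param minmax_fit where min-max statistics are fitted inside
#'   cross-validation: `"train_only"` (default, no leakage from held-out
#'   cells) or `"all"`.
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(window_half = 2000,
                              expr_target_sum = "median_library",
                              minmax_fit = c("train_only", "all")) {
  stopifnot(window_half > 0)
  minmax_fit <- match.arg(minmax_fit)
  structure(list(window_half = as.integer(window_half),
                 expr_target_sum = expr_target_sum,
                 minmax_fit = minmax_fit),
            class = "preprocess_config")
}

#' Drop genes with zero counts in every cell
#'
#' @param expr an expression [omics_matrix()] of raw counts.
#' @return The matrix restricted to genes with at least one nonzero count.
#' @export
filter_zero_genes <- function(expr) {
  stopifnot(inherits(expr, "omics_matrix"), expr$omics_kind == "expression")
  keep <- colSums(expr$values != 0) > 0
  if (!any(keep)) stop("filter_zero_genes: empty expression matrix ",
                       "(all genes lack counts)")
  omics_matrix(expr$values[, keep, drop = FALSE],
               expr$features[keep, , drop = FALSE], "expression")
}

#' Library-size normalise and log-transform expression counts
#'
#' Each cell's counts are scaled to a common library size and
#' log-transformed: `log1p(count * target / library_size)`. The default
#' target is the median library size across cells.
#'
#' @param expr an expression [omics_matrix()] of raw counts (zero genes
#'   already removed).
#' @param config a [preprocess_config()].
#' @return The normalised [omics_matrix()].
#' @export
normalize_expression <- function(expr, config = preprocess_config()) {
  stopifnot(inherits(expr, "omics_matrix"), expr$omics_kind == "expression")
  lib <- rowSums(expr$values)
  if (any(lib == 0)) {
    stop("normalize_expression: cell(s) with library size 0: ",
         paste(utils::head(expr$cells[lib == 0], 5), collapse = ", "))
  }
  target <- config$expr_target_sum
  if (identical(target, "median_library")) target <- stats::median(lib)
  stopifnot(is.numeric(target), target > 0)
  vals <- log1p(expr$values * (target / lib))
  omics_matrix(vals, expr$features, "expression")
}

#' Group CpG sites into promoter windows
#'
#' For each annotated gene, the promoter CpG cluster is the set of CpG
#' sites within `window_half` bp of the TSS, i.e. inside the half-open
#' window `[tss - window_half, tss + window_half)`. A CpG may belong to
#' several genes' clusters; genes with no in-window CpG yield no cluster.
#'
#' @param meth a methylation [site_matrix()].
#' @param ann a [gene_annotation()].
#' @param config a [preprocess_config()] (supplies `window_half`).
#' @return A tibble with one row per cluster: `gene_id`, `chrom`,
#'   `window_start`, `window_end`, and a list-column `member_sites` of site
#'   indices into `meth$sites`.
#' @export
build_cpg_clusters <- function(meth, ann, config = preprocess_config()) {
  stopifnot(inherits(meth, "site_matrix"), meth$omics_kind == "methylation")
  w <- config$window_half
  win_start <- pmax(ann$tss - w, 0L)
  win_end <- ann$tss + w
  if (nrow(ann) == 0 || nrow(meth$sites) == 0) {
    return(tibble::tibble(gene_id = character(), chrom = character(),
                          window_start = integer(), window_end = integer(),
                          member_sites = list()))
  }
  # half-open intervals on the 0-based scale; IRanges is 1-based inclusive
  windows <- GenomicRanges::GRanges(
    ann$chrom, IRanges::IRanges(start = win_start + 1L, end = win_end))
  cpgs <- GenomicRanges::GRanges(
    meth$sites$chrom,
    IRanges::IRanges(start = meth$sites$start + 1L, end = meth$sites$start + 1L))
  hits <- GenomicRanges::findOverlaps(windows, cpgs, ignore.strand = TRUE)
  members <- split(S4Vectors::subjectHits(hits), S4Vectors::queryHits(hits))
  gidx <- as.integer(names(members))
  absent <- setdiff(unique(ann$chrom), unique(meth$sites$chrom))
  if (length(absent) > 0) {
    message("build_cpg_clusters: annotation chromosome(s) without CpG sites: ",
            paste(absent, collapse = ", "))
  }
  tibble::tibble(
    gene_id = ann$gene_id[gidx],
    chrom = ann$chrom[gidx],
    window_start = win_start[gidx],
    window_end = win_end[gidx],
    member_sites = unname(lapply(members, as.integer))
  )
}

#' Average CpG clusters into a gene-level methylation matrix
#'
#' Per cell, a cluster's value is the mean beta over its *observed* member
#' sites. Cells with no observed member site are imputed with the cluster's
#' mean over cells where it is observed; clusters observed in no cell are
#' dropped. The output has no missing entries and stays in `[0, 1]`.
#'
#' @param meth a methylation [site_matrix()].
#' @param clusters cluster table from [build_cpg_clusters()].
#' @return A methylation [omics_matrix()], one feature per retained cluster
#'   (`feature_id = "<gene>_meCl"`, anchored to the gene).
#' @export
cluster_methylation <- function(meth, clusters) {
  stopifnot(inherits(meth, "site_matrix"), nrow(clusters) > 0)
  n_cells <- nrow(meth$values)
  vals <- matrix(NA_real_, n_cells, nrow(clusters))
  obs_vals <- meth$values
  obs_vals[!meth$mask] <- NA
  for (ci in seq_len(nrow(clusters))) {
    mem <- clusters$member_sites[[ci]]
    sub <- obs_vals[, mem, drop = FALSE]
    n_obs <- rowSums(!is.na(sub))
    s <- rowSums(sub, na.rm = TRUE)
    vals[, ci] <- ifelse(n_obs > 0, s / n_obs, NA_real_)
  }
  observed_any <- colSums(!is.na(vals)) > 0
  if (!any(observed_any)) {
    stop("cluster_methylation: every CpG cluster is unobserved in all cells")
  }
  vals <- vals[, observed_any, drop = FALSE]
  clusters <- clusters[observed_any, , drop = FALSE]
  # mean imputation across cells
  for (ci in seq_len(ncol(vals))) {
    miss <- is.na(vals[, ci])
    if (any(miss)) vals[miss, ci] <- mean(vals[!miss, ci])
  }
  rownames(vals) <- meth$cells
  omics_matrix(vals,
               tibble::tibble(feature_id = paste0(clusters$gene_id, "_meCl"),
                              anchor_gene_id = clusters$gene_id),
               "methylation")
}

#' Sum accessibility peaks over gene bodies
#'
#' Gene activity is the per-cell sum of accessibility signal over all peaks
#' overlapping the gene body `[body_start, body_end)` by at least 1 bp.
#' Genes with no overlapping peak are dropped.
#'
#' @param acc an accessibility [site_matrix()] of peak signal.
#' @param ann a [gene_annotation()].
#' @return An accessibility [omics_matrix()] (`feature_id = "<gene>_act"`).
#' @export
aggregate_accessibility <- function(acc, ann) {
  stopifnot(inherits(acc, "site_matrix"), acc$omics_kind == "accessibility")
  if (nrow(ann) == 0) stop("aggregate_accessibility: empty annotation")
  bodies <- GenomicRanges::GRanges(
    ann$chrom, IRanges::IRanges(start = ann$body_start + 1L, end = ann$body_end))
  peaks <- GenomicRanges::GRanges(
    acc$sites$chrom,
    IRanges::IRanges(start = acc$sites$start + 1L, end = acc$sites$end))
  hits <- GenomicRanges::findOverlaps(bodies, peaks, ignore.strand = TRUE)
  members <- split(S4Vectors::subjectHits(hits), S4Vectors::queryHits(hits))
  if (length(members) == 0) {
    stop("aggregate_accessibility: no peak overlaps any gene body")
  }
  gidx <- as.integer(names(members))
  vals <- vapply(members, function(mem) {
    rowSums(acc$values[, mem, drop = FALSE])
  }, numeric(nrow(acc$values)))
  vals <- matrix(vals, nrow = nrow(acc$values),
                 dimnames = list(acc$cells, NULL))
  omics_matrix(vals,
               tibble::tibble(feature_id = paste0(ann$gene_id[gidx], "_act"),
                              anchor_gene_id = ann$gene_id[gidx]),
               "accessibility")
}

#' Fit or apply per-feature min-max scaling
#'
#' Rescales each feature to `[0, 1]` so expression and accessibility ranges
#' align with methylation betas. With `fit_stats` supplied (e.g. fitted on
#' training cells), the stored ranges are applied and outputs are clipped to
#' `[0, 1]`; otherwise ranges are computed from `matrix` itself. A constant
#' feature maps to 0.
#'
#' @param matrix an [omics_matrix()] without missing entries.
#' @param fit_stats optional tibble (`feature_id`, `min`, `max`) from a
#'   previous fit.
#' @return A list with elements `matrix` (the scaled [omics_matrix()]) and
#'   `fit_stats`.
#' @export
minmax_normalize <- function(matrix, fit_stats = NULL) {
  stopifnot(inherits(matrix, "omics_matrix"))
  vals <- matrix$values
  external <- !is.null(fit_stats)
  if (external) {
    stopifnot(identical(fit_stats$feature_id, matrix$features$feature_id))
    mins <- fit_stats$min
    maxs <- fit_stats$max
  } else {
    mins <- unname(apply(vals, 2, min))
    maxs <- unname(apply(vals, 2, max))
    fit_stats <- tibble::tibble(feature_id = matrix$features$feature_id,
                                min = mins, max = maxs)
  }
  rng <- maxs - mins
  scaled <- sweep(vals, 2, mins, "-")
  scaled <- sweep(scaled, 2, ifelse(rng > 0, rng, 1), "/")
  scaled[, rng == 0] <- 0
  if (external) scaled <- pmin(pmax(scaled, 0), 1)
  list(matrix = omics_matrix(scaled, matrix$features, matrix$omics_kind),
       fit_stats = fit_stats)
}

#' Run the full per-omics preprocessing chain
#'
#' Expression: zero-gene filter, library-size normalisation, log transform.
#' Methylation: promoter CpG clustering, per-cell averaging, mean
#' imputation. Accessibility: gene-body peak summation. Min-max alignment
#' is deliberately left to the classifier (fitted on training cells only
#' during cross-validation); see [train_attention()].
#'
#' @param expr raw-count expression [omics_matrix()] (or `NULL` to skip).
#' @param meth methylation [site_matrix()] (or `NULL`).
#' @param acc accessibility [site_matrix()] (or `NULL`).
#' @param ann a [gene_annotation()].
#' @param config a [preprocess_config()].
#' @return A named list of gene-anchored [omics_matrix()] objects.
#' @export
preprocess_multiomics <- function(expr = NULL, meth = NULL, acc = NULL, ann,
                                  config = preprocess_config()) {
  out <- list()
  if (!is.null(expr)) {
    out$expression <- normalize_expression(filter_zero_genes(expr), config)
  }
  if (!is.null(meth)) {
    clusters <- build_cpg_clusters(meth, ann, config)
    if (nrow(clusters) == 0) stop("preprocess_multiomics: no CpG clusters formed")
    out$methylation <- cluster_methylation(meth, clusters)
  }
  if (!is.null(acc)) {
    out$accessibility <- aggregate_accessibility(acc, ann)
  }
  out
}
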