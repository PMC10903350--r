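#' Site-level omics matrix
#'
#' Holds raw per-site measurements before gene anchoring: methylation beta
#' values at CpG sites (with an observation mask, since single-cell
#' bisulfite coverage is sparse) or accessibility signal on peaks. Genomic
#' coordinates are 0-based half-open; a CpG site has `end = start + 1`.
#'
#' @param values numeric matrix, cells x sites; rownames are cell IDs.
#' @param sites data frame with columns `chrom`, `start`, `end` (one row per
#'   column of `values`).
#' @param omics_kind `"methylation"` or `"accessibility"`.
#' @param mask logical matrix of the same shape marking observed entries;
#'   defaults to `!is.na(values)`.
#' @return A `site_matrix` object.
#' @export
site_matrix <- function(values, sites, omics_kind = c("methylation", "accessibility"),
                        mask = NULL) {
  omics_kind <- match.arg(omics_kind)
  values <- as.matrix(values)
  sites <- tibble::as_tibble(sites)
  stopifnot(all(c("chrom", "start", "end") %in% names(sites)))
  if (ncol(values) != nrow(sites)) {
    stop("site_matrix: ", ncol(values), " value columns but ", nrow(sites), " sites")
  }
  if (is.null(mask)) mask <- !is.na(values)
  mask <- as.matrix(mask)
  stopifnot(identical(dim(mask), dim(values)))
  if (is.null(rownames(values))) {
    rownames(values) <- paste0("cell", seq_len(nrow(values)))
  }
  obs <- values[mask]
  if (any(!is.finite(obs))) stop("site_matrix: non-finite observed values")
  if (omics_kind == "accessibility" && any(obs < 0)) {
    stop("site_matrix: accessibility values must be >= 0")
  }
  if (omics_kind == "methylation" && (any(obs < 0) || any(obs > 1))) {
    stop("site_matrix: methylation beta values must lie in [0, 1]")
  }
  structure(
    list(cells = rownames(values), sites = sites, values = values,
         mask = mask, omics_kind = omics_kind),
    class = "site_matrix"
  )
}

#' Gene-anchored omics matrix
#'
#' A dense cells x features matrix in which every feature is anchored to a
#' gene: an expression gene, a promoter CpG cluster, or a gene-activity
#' (accessibility) feature. Post-imputation matrices contain no missing
#' entries.
#'
#' @param values numeric matrix, cells x features; rownames are cell IDs.
#' @param features data frame with columns `feature_id` (unique) and
#'   `anchor_gene_id`.
#' @param omics_kind one of `"expression"`, `"methylation"`, `"accessibility"`.
#' @return An `omics_matrix` object.
#' @export
omics_matrix <- function(values,
                         features,
                         omics_kind = c("expression", "methylation", "accessibility")) {
  omics_kind <- match.arg(omics_kind)
  values <- as.matrix(values)
  features <- tibble::as_tibble(features)
  stopifnot(all(c("feature_id", "anchor_gene_id") %in% names(features)))
  if (ncol(values) != nrow(features)) {
    stop("omics_matrix: ", ncol(values), " value columns but ",
         nrow(features), " feature records")
  }
  if (anyDuplicated(features$feature_id)) {
    stop("omics_matrix: duplicated feature_id: ",
         paste(unique(features$feature_id[duplicated(features$feature_id)]),
               collapse = ", "))
  }
  if (any(!is.finite(values))) {
    stop("omics_matrix: values must be finite (impute before constructing)")
  }
  if (is.null(rownames(values))) {
    rownames(values) <- paste0("cell", seq_len(nrow(values)))
  }
  colnames(values) <- features$feature_id
  structure(
    list(cells = rownames(values), features = features, values = values,
         omics_kind = omics_kind),
    class = "omics_matrix"
  )
}

#' Multi-omics dataset over a shared cell set
#'
#' Bundles one [omics_matrix()] per omics layer, co-indexed over an identical
#' ordered cell list, with optional subtype labels.
#'
#' @param omics named list of [omics_matrix()] objects (names are the omics
#'   kinds); all must share an identical, identically ordered cell list.
#' @param labels optional named character vector or two-column data frame
#'   (`cell_id`, `subtype`) labelling cells.
#' @return A `multi_omics_dataset` object with a sorted `class_inventory`
#'   when labels are present.
#' @export
multi_omics_dataset <- function(omics, labels = NULL) {
  stopifnot(length(omics) >= 1, all(vapply(omics, inherits, TRUE, "omics_matrix")))
  kinds <- vapply(omics, function(o) o$omics_kind, "")
  names(omics) <- kinds
  cells <- omics[[1]]$cells
  for (o in omics) {
    if (!identical(o$cells, cells)) {
      stop("multi_omics_dataset: member matrices must share an identical ",
           "ordered cell list")
    }
  }
  lab <- NULL
  if (!is.null(labels)) {
    if (is.data.frame(labels)) {
      lab <- stats::setNames(as.character(labels[[2]]), as.character(labels[[1]]))
    } else {
      lab <- labels
    }
    unknown <- setdiff(names(lab), cells)
    if (length(unknown) > 0) {
      warning("multi_omics_dataset: dropping labels for unknown cells: ",
              paste(utils::head(unknown, 5), collapse = ", "))
      lab <- lab[setdiff(names(lab), unknown)]
    }
    lab <- lab[intersect(cells, names(lab))]
  }
  structure(
    list(omics = omics, cells = cells, labels = lab,
         class_inventory = if (is.null(lab)) NULL else sort(unique(unname(lab)))),
    class = "multi_omics_dataset"
  )
}

#' @export
print.site_matrix <- function(x, ...) {
  cat(sprintf("<site_matrix: %s> %d cells x %d sites (%.1f%% observed)\n",
              x$omics_kind, nrow(x$values), ncol(x$values), 100 * mean(x$mask)))
  invisible(x)
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("<omics_matrix: %s> %d cells x %d features (%d anchor genes)\n",
              x$omics_kind, nrow(x$values), ncol(x$values),
              length(unique(x$features$anchor_gene_id))))
  invisible(x)
}

#' @export
print.multi_omics_dataset <- function(x, ...) {
  cat(sprintf("<multi_omics_dataset> %d cells, %d omics\n",
              length(x$cells), length(x$omics)))
  for (o in x$omics) {
    cat(sprintf("  %-13s %d features\n", o$omics_kind, ncol(o$values)))
  }
  if (!is.null(x$labels)) {
    cat(sprintf("  labels: %d cells, %d subtypes\n",
                length(x$labels), length(x$class_inventory)))
  }
  invisible(x)
}

# internal: subset a dataset to a cell index vector, preserving order
subset_cells <- function(dataset, idx) {
  omics <- lapply(dataset$omics, function(o) {
    omics_matrix(o$values[idx, , drop = FALSE], o$features, o$omics_kind)
  })
  lab <- dataset$labels
  if (!is.null(lab)) lab <- lab[intersect(dataset$cells[idx], names(lab))]
  multi_omics_dataset(omics, lab)
}

# internal: subset a dataset to a subset of omics kinds (order preserved)
subset_omics <- function(dataset, kinds) {
  keep <- intersect(names(dataset$omics), kinds)
  if (length(keep) == 0) stop("no requested omics present in dataset")
  multi_omics_dataset(dataset$omics[keep],
                      if (is.null(dataset$labels)) NULL else
                        tibble::tibble(cell_id = names(dataset$labels),
                                       subtype = unname(dataset$labels)))
}
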