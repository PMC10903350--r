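#' Keep only features whose anchor gene appears in every omics
#'
#' Multi-omics integration is grounded in shared genes: a feature survives
#' iff its anchor gene has at least one feature in every input matrix. All
#' matrices are reordered to the cell ordering of the first.
#'
#' @param matrices list of gene-anchored [omics_matrix()] objects over the
#'   same cell set.
#' @return A [multi_omics_dataset()] (unlabelled).
#' @export
intersect_by_gene <- function(matrices) {
  stopifnot(length(matrices) >= 1)
  cells <- sort(matrices[[1]]$cells)
  common <- Reduce(intersect, lapply(matrices, function(m) {
    unique(m$features$anchor_gene_id)
  }))
  if (length(common) == 0) stop("intersect_by_gene: no common genes across omics")
  out <- lapply(matrices, function(m) {
    if (!setequal(m$cells, cells)) {
      stop("intersect_by_gene: matrices do not share the same cell set")
    }
    keep <- m$features$anchor_gene_id %in% common
    ord <- match(cells, m$cells)
    dup_genes <- sum(duplicated(m$features$anchor_gene_id[keep]))
    message(sprintf("intersect_by_gene: %s keeps %d/%d features (%d shared genes%s)",
                    m$omics_kind, sum(keep), ncol(m$values), length(common),
                    if (dup_genes > 0) sprintf(", %d multi-feature genes", dup_genes)
                    else ""))
    omics_matrix(m$values[ord, keep, drop = FALSE],
                 m$features[keep, , drop = FALSE], m$omics_kind)
  })
  multi_omics_dataset(out)
}

#' Attach subtype labels to a dataset
#'
#' @param dataset a [multi_omics_dataset()].
#' @param labels a tibble (`cell_id`, `subtype`) as from [read_labels()].
#' @param strict if `TRUE` (training mode) every cell must be labelled;
#'   if `FALSE` (predict mode) unlabelled cells are allowed.
#' @return The dataset with labels and a sorted class inventory attached.
#' @export
align_labels <- function(dataset, labels, strict = TRUE) {
  stopifnot(inherits(dataset, "multi_omics_dataset"))
  if (strict) {
    missing <- setdiff(dataset$cells, labels$cell_id)
    if (length(missing) > 0) {
      stop("align_labels: unlabelled cell(s) in strict mode: ",
           paste(utils::head(missing, 10), collapse = ", "),
           if (length(missing) > 10) sprintf(" (+%d more)", length(missing) - 10))
    }
  }
  multi_omics_dataset(dataset$omics, labels)
}
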