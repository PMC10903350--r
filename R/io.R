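#' Read an omics matrix from CSV/TSV or MatrixMarket triplet
#'
#' Delimited files carry features as rows (first column `feature_id`,
#' remaining columns one per cell, header = cell IDs); set
#' `cells_as = "rows"` for the transposed orientation. A second column
#' named `anchor_gene_id` (as written by [write_matrix()]) is honoured.
#' MatrixMarket input (`format = "mtx_triplet"`) expects `<path>` plus
#' sidecar files: the prefix with `.features.tsv` and `.barcodes.tsv`
#' replacing `.mtx`, features as rows.
#'
#' Site-level kinds (`methylation`, `accessibility`) parse feature IDs as
#' genomic coordinates — `chrom:pos` for CpG sites (half-open
#' `[pos, pos+1)`), `chrom:start-end` for peaks — and return a
#' [site_matrix()]. Missing methylation entries (empty/NA cells) become
#' unobserved entries in the mask; missing expression or accessibility
#' entries are zeros.
#'
#' @param path file path (for `mtx_triplet`, the `.mtx` file).
#' @param format `"csv"`, `"tsv"` or `"mtx_triplet"`; `"auto"` guesses from
#'   the extension.
#' @param omics_kind `"expression"`, `"methylation"` or `"accessibility"`.
#' @param cells_as `"columns"` (default) or `"rows"`.
#' @return A [site_matrix()] for site-level kinds without an anchor column,
#'   otherwise an [omics_matrix()].
#' @export
read_matrix <- function(path,
                        format = c("auto", "csv", "tsv", "mtx_triplet"),
                        omics_kind = c("expression", "methylation", "accessibility"),
                        cells_as = c("columns", "rows")) {
  format <- match.arg(format)
  omics_kind <- match.arg(omics_kind)
  cells_as <- match.arg(cells_as)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     csv = "csv", mtx = "mtx_triplet", "tsv")
  }
  if (!file.exists(path)) stop("read_matrix: file not found: ", path)

  anchors <- NULL
  if (format == "mtx_triplet") {
    prefix <- sub("\\.mtx$", "", path)
    fpath <- paste0(prefix, ".features.tsv")
    bpath <- paste0(prefix, ".barcodes.tsv")
    if (!file.exists(fpath) || !file.exists(bpath)) {
      stop("read_matrix: sidecar files missing for ", path,
           " (expected ", fpath, " and ", bpath, ")")
    }
    m <- as.matrix(Matrix::readMM(path))
    feats <- utils::read.table(fpath, sep = "\t", header = FALSE,
                               stringsAsFactors = FALSE)
    cells <- utils::read.table(bpath, sep = "\t", header = FALSE,
                               stringsAsFactors = FALSE)[[1]]
    if (nrow(m) != nrow(feats) || ncol(m) != length(cells)) {
      stop("read_matrix: dimension mismatch: matrix is ", nrow(m), " x ",
           ncol(m), " but sidecars list ", nrow(feats), " features and ",
           length(cells), " barcodes")
    }
    feature_id <- feats[[1]]
    if (ncol(feats) >= 2) anchors <- feats[[2]]
    vals <- t(m)                        # features x cells -> cells x features
    rownames(vals) <- cells
    mask <- matrix(TRUE, nrow(vals), ncol(vals))
  } else {
    sep <- if (format == "csv") "," else "\t"
    df <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                            stringsAsFactors = FALSE, na.strings = c("NA", ""))
    feature_id <- as.character(df[[1]])
    df[[1]] <- NULL
    if (ncol(df) > 0 && names(df)[1] == "anchor_gene_id") {
      anchors <- as.character(df[[1]])
      df[[1]] <- NULL
    }
    for (j in seq_along(df)) {
      if (!is.numeric(df[[j]])) {
        bad <- which(!is.na(df[[j]]) & is.na(suppressWarnings(as.numeric(df[[j]]))))
        stop("read_matrix: non-numeric value in column '", names(df)[j],
             "', row ", if (length(bad)) bad[1] else 1, " of ", path)
      }
    }
    vals <- t(as.matrix(df))            # now cells x features
    colnames(vals) <- feature_id
    if (cells_as == "rows") {
      # file already had cells as rows: first column was cell IDs
      cells <- feature_id
      vals <- as.matrix(df)
      feature_id <- colnames(df)
      rownames(vals) <- cells
    }
    mask <- !is.na(vals)
    if (omics_kind != "methylation") vals[!mask] <- 0
  }

  if (!is.null(anchors) || omics_kind == "expression") {
    if (omics_kind == "methylation") vals[!mask] <- NA  # keep explicit
    if (anyNA(vals)) stop("read_matrix: gene-level matrix contains missing values")
    return(omics_matrix(vals,
                        tibble::tibble(feature_id = feature_id,
                                       anchor_gene_id = anchors %||% feature_id),
                        omics_kind))
  }
  sites <- parse_site_ids(feature_id, omics_kind)
  if (omics_kind == "methylation") vals[!mask] <- NA
  site_matrix(vals, sites, omics_kind, mask = mask)
}

# "chr1:100" (CpG) or "chr1:100-200" (peak) -> interval table
parse_site_ids <- function(ids, omics_kind) {
  parts <- strsplit(ids, ":", fixed = TRUE)
  if (any(lengths(parts) != 2)) {
    stop("read_matrix: cannot parse site ID(s) as chrom:pos or chrom:start-end: ",
         paste(utils::head(ids[lengths(parts) != 2], 3), collapse = ", "))
  }
  chrom <- vapply(parts, `[`, "", 1)
  coord <- vapply(parts, `[`, "", 2)
  if (omics_kind == "accessibility" || any(grepl("-", coord, fixed = TRUE))) {
    se <- strsplit(coord, "-", fixed = TRUE)
    start <- as.integer(vapply(se, `[`, "", 1))
    end <- as.integer(vapply(se, `[`, "", 2))
  } else {
    start <- as.integer(coord)
    end <- start + 1L
  }
  if (anyNA(start) || anyNA(end)) stop("read_matrix: non-integer site coordinate")
  tibble::tibble(chrom = chrom, start = start, end = end)
}

site_ids <- function(sites, omics_kind) {
  if (omics_kind == "methylation") {
    paste0(sites$chrom, ":", sites$start)
  } else {
    paste0(sites$chrom, ":", sites$start, "-", sites$end)
  }
}

#' Write a matrix container to TSV
#'
#' Features as rows: `feature_id`, `anchor_gene_id` (omics matrices only),
#' then one column per cell. Values are written with full precision so that
#' `read_matrix(write_matrix(x))` round-trips. Unobserved methylation
#' entries are written as `NA`.
#'
#' @param x an [omics_matrix()] or [site_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path) {
  vals <- t(x$values)                   # features x cells
  vals[is.na(vals)] <- NA
  if (inherits(x, "omics_matrix")) {
    df <- data.frame(feature_id = x$features$feature_id,
                     anchor_gene_id = x$features$anchor_gene_id,
                     check.names = FALSE)
  } else {
    m <- t(x$values)
    m[t(!x$mask)] <- NA
    vals <- m
    df <- data.frame(feature_id = site_ids(x$sites, x$omics_kind),
                     check.names = FALSE)
  }
  num <- as.data.frame(format(vals, digits = 15, trim = TRUE, scientific = FALSE),
                       stringsAsFactors = FALSE)
  num[is.na(vals)] <- NA
  names(num) <- x$cells
  out <- cbind(df, num)
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "NA")
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("write_matrix: cannot write to ", path)
  invisible(path)
}

#' Write a metrics record as JSON
#'
#' @param metrics a one-row data frame or named list with at least
#'   `accuracy`, `f1_weighted`, `mcc`, `auc`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(metrics, path) {
  metrics <- as.list(metrics)
  need <- c("accuracy", "f1_weighted", "mcc", "auc")
  missing <- setdiff(need, names(metrics))
  if (length(missing) > 0) stop("write_metrics: missing keys: ",
                                paste(missing, collapse = ", "))
  jsonlite::write_json(metrics, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a marker table as TSV
#'
#' Rows are sorted by omics then descending mean attention (the ranking
#' order of [rank_markers()]).
#'
#' @param markers a marker tibble as returned by [rank_markers()] (columns
#'   `omics`, `feature_id`, `anchor_gene_id`, `mean_attention`, `rank`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_marker_table <- function(markers, path) {
  markers <- dplyr::arrange(markers, .data$omics, dplyr::desc(.data$mean_attention),
                            .data$feature_id)
  utils::write.table(markers, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a cell label table
#'
#' @param path two-column TSV (`cell_id`, `subtype`), with or without header.
#' @return A tibble with columns `cell_id` and `subtype`.
#' @export
read_labels <- function(path) {
  first <- readLines(path, n = 1)
  header <- grepl("cell_id", first, fixed = TRUE)
  df <- utils::read.table(path, sep = "\t", header = header,
                          stringsAsFactors = FALSE)
  tibble::tibble(cell_id = as.character(df[[1]]), subtype = as.character(df[[2]]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
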