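#' Build a gene annotation table
#'
#' The gene annotation anchors all three omics layers to genes: the
#' transcription start site (TSS) anchors promoter CpG windows and the gene
#' body interval collects accessibility peaks. Coordinates are stored
#' 0-based half-open; the TSS is strand-aware (`body_start` on `+`,
#' `body_end` on `-`).
#'
#' @param gene_id character vector of unique gene identifiers.
#' @param chrom,strand,body_start,body_end per-gene chromosome, strand
#'   (`"+"`/`"-"`), and 0-based half-open gene-body interval.
#' @return A tibble of class `gene_annotation` with columns `gene_id`,
#'   `chrom`, `strand`, `body_start`, `body_end`, `tss`.
#' @export
gene_annotation <- function(gene_id, chrom, strand, body_start, body_end) {
  strand <- as.character(strand)
  bad <- !strand %in% c("+", "-")
  if (any(bad)) {
    warning("gene_annotation: rejecting ", sum(bad),
            " record(s) with unknown strand symbol: ",
            paste(utils::head(unique(strand[bad]), 3), collapse = ", "))
    keep <- !bad
    gene_id <- gene_id[keep]; chrom <- chrom[keep]; strand <- strand[keep]
    body_start <- body_start[keep]; body_end <- body_end[keep]
  }
  if (any(body_start >= body_end)) {
    stop("gene_annotation: body_start must be < body_end")
  }
  if (anyDuplicated(gene_id)) {
    warning("gene_annotation: duplicated gene_id, keeping first occurrence: ",
            paste(utils::head(unique(gene_id[duplicated(gene_id)]), 5),
                  collapse = ", "))
    keep <- !duplicated(gene_id)
    gene_id <- gene_id[keep]; chrom <- chrom[keep]; strand <- strand[keep]
    body_start <- body_start[keep]; body_end <- body_end[keep]
  }
  ann <- tibble::tibble(
    gene_id = as.character(gene_id),
    chrom = as.character(chrom),
    strand = strand,
    body_start = as.integer(body_start),
    body_end = as.integer(body_end),
    tss = as.integer(ifelse(strand == "+", body_start, body_end))
  )
  class(ann) <- c("gene_annotation", class(ann))
  ann
}

#' Read a gene annotation from GTF or BED
#'
#' GTF records (1-based inclusive, Ensembl dialect with a `gene_id`
#' attribute) and BED6 records (already 0-based half-open) are both
#' converted to the internal 0-based half-open convention at this boundary.
#' For GTF only rows with feature type `"gene"` are used.
#'
#' @param path file path.
#' @param format `"gtf"` or `"bed"`; default guessed from the file extension.
#' @return A [gene_annotation()] tibble.
#' @export
read_annotation <- function(path, format = c("auto", "gtf", "bed")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("read_annotation: file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "gtf"
  }
  lines <- readLines(path, warn = FALSE)
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(body) == 0) {
    warning("read_annotation: empty annotation file: ", path)
    return(gene_annotation(character(), character(), character(),
                           integer(), integer()))
  }
  gr <- tryCatch(
    rtracklayer::import(path, format = format),
    error = function(e) stop("read_annotation: parse error in ", path, ": ",
                             conditionMessage(e))
  )
  if (format == "gtf") {
    type <- as.character(gr$type)
    gr <- gr[type == "gene"]
    ids <- as.character(gr$gene_id)
  } else {
    ids <- as.character(gr$name)
    if (length(ids) == 0 || all(is.na(ids))) {
      stop("read_annotation: BED file lacks a name column for gene IDs")
    }
  }
  # GRanges are 1-based inclusive internally regardless of source dialect
  gene_annotation(
    gene_id = ids,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    body_start = GenomicRanges::start(gr) - 1L,
    body_end = GenomicRanges::end(gr)
  )
}

#' Write a gene annotation as BED6
#'
#' @param ann a [gene_annotation()] tibble.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_annotation_bed <- function(ann, path) {
  df <- data.frame(ann$chrom, ann$body_start, ann$body_end, ann$gene_id,
                   0L, ann$strand)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
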