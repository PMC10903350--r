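#' Simulation configuration for synthetic multi-omics data
#'
#' The generator emulates the statistical shape of single-cell multi-omics
#' inputs: negative-binomial expression counts, beta-distributed CpG
#' methylation with missingness, and sparse non-negative peak counts in
#' gene bodies, with subtype-discriminative features planted per omics.
#'
#' @param n_cells,n_genes,n_subtypes dataset dimensions.
#' @param markers_per_omics number of planted marker genes per omics.
#' @param effect_size planted mean shift in units of the within-class SD of
#'   the feature's raw distribution.
#' @param meth_missing_rate per-entry probability that a CpG measurement is
#'   unobserved.
#' @param cpgs_per_promoter CpG sites placed inside each promoter window.
#' @param peaks_per_gene accessibility peaks placed inside each gene body.
#' @param expr_dispersion negative-binomial dispersion (variance =
#'   `mu + dispersion * mu^2`).
#' @param class_proportions subtype sampling probabilities (default equal).
#' @param disjoint_markers if `TRUE` (default), the three omics receive
#'   disjoint marker gene sets.
#' @param seed integer seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_cells = 600, n_genes = 120, n_subtypes = 4,
                       markers_per_omics = 10, effect_size = 3,
                       meth_missing_rate = 0.3, cpgs_per_promoter = 5,
                       peaks_per_gene = 3, expr_dispersion = 0.5,
                       class_proportions = NULL, disjoint_markers = TRUE,
                       seed = 1L) {
  if (is.null(class_proportions)) {
    class_proportions <- rep(1 / n_subtypes, n_subtypes)
  }
  stopifnot(abs(sum(class_proportions) - 1) < 1e-8,
            length(class_proportions) == n_subtypes,
            markers_per_omics <= n_genes,
            meth_missing_rate >= 0, meth_missing_rate < 1)
  n_marked <- if (disjoint_markers) 3 * markers_per_omics else markers_per_omics
  if (n_marked > n_genes) {
    stop("sim_config: disjoint markers require 3 * markers_per_omics <= n_genes")
  }
  structure(list(n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
                 n_subtypes = as.integer(n_subtypes),
                 markers_per_omics = as.integer(markers_per_omics),
                 effect_size = effect_size,
                 meth_missing_rate = meth_missing_rate,
                 cpgs_per_promoter = as.integer(cpgs_per_promoter),
                 peaks_per_gene = as.integer(peaks_per_gene),
                 expr_dispersion = expr_dispersion,
                 class_proportions = class_proportions,
                 disjoint_markers = isTRUE(disjoint_markers),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Synthetic gene annotation
#'
#' Lays out non-overlapping 4 kb gene bodies every 10 kb on one synthetic
#' chromosome with alternating strands, so promoter windows (TSS +/- 2 kb)
#' of neighbouring genes never collide. The layout is a deterministic
#' function of the configuration.
#'
#' @param sim a [sim_config()].
#' @return A [gene_annotation()] tibble.
#' @export
generate_annotation <- function(sim) {
  i <- seq_len(sim$n_genes)
  body_start <- 10000L * i
  body_end <- body_start + 4000L
  strand <- ifelse(i %% 2 == 1, "+", "-")
  gene_annotation(gene_id = sprintf("gene%03d", i), chrom = "chrS",
                  strand = strand, body_start = body_start,
                  body_end = body_end)
}

#' Generate a synthetic single-cell multi-omics dataset
#'
#' Subtype labels are multinomial over `class_proportions`. Expression
#' counts are negative binomial with gene-specific baseline means;
#' methylation betas are beta-distributed around gene-specific baseline
#' levels at `cpgs_per_promoter` CpGs inside each promoter window, with
#' Bernoulli missingness; accessibility is sparse negative-binomial peak
#' signal inside gene bodies. For each planted marker gene one subtype's
#' mean is shifted upward by `effect_size` within-class SDs of the raw
#' feature; marker genes are disjoint across omics when requested.
#'
#' @param sim a [sim_config()].
#' @return A list: `annotation`, `expression` (raw-count [omics_matrix()]),
#'   `methylation` and `accessibility` ([site_matrix()] objects), `labels`
#'   (tibble `cell_id`, `subtype`) and `truth` (tibble of planted markers:
#'   `omics`, `gene_id`, `up_subtype`, `direction`).
#' @export
generate_multiomics <- function(sim) {
  set.seed(sim$seed)
  ann <- generate_annotation(sim)
  n <- sim$n_cells
  G <- sim$n_genes
  cells <- sprintf("cell%04d", seq_len(n))
  subtypes <- sprintf("subtype%d", seq_len(sim$n_subtypes))
  labels <- sample(subtypes, n, replace = TRUE, prob = sim$class_proportions)

  M <- sim$markers_per_omics
  if (sim$disjoint_markers) {
    marker_idx <- list(expression = seq_len(M),
                       methylation = M + seq_len(M),
                       accessibility = 2L * M + seq_len(M))
  } else {
    marker_idx <- lapply(
      c(expression = 1, methylation = 2, accessibility = 3),
      function(...) sort(sample.int(G, M)))
  }
  # Discriminative signal is split across omics: subtypes are dealt to the
  # omics round-robin and an omics' markers are up only in its own
  # subtypes, so no single omics separates all classes and integration is
  # required (the construction behind the multi-omics-beats-single-omics
  # property). With 4 subtypes and 3 omics the first omics resolves
  # subtypes 1 and 4, the second subtype 2, the third subtype 3.
  n_omics <- length(marker_idx)
  omics_classes <- lapply(seq_len(n_omics), function(o) {
    cls <- subtypes[(seq_len(sim$n_subtypes) - 1L) %% n_omics == (o - 1L)]
    # fewer subtypes than omics: wrap so every omics marks some subtype
    if (length(cls) == 0) cls <- subtypes[((o - 1L) %% sim$n_subtypes) + 1L]
    cls
  })
  up_class <- function(o, j) {
    cls <- omics_classes[[o]]
    cls[((j - 1L) %% length(cls)) + 1L]
  }
  # markers alternate direction: in its subtype a marker is either
  # elevated ("up") or depleted ("down"), as real markers are
  mk_dir <- function(j) if (j %% 2 == 1) "up" else "down"
  truth <- purrr::map_dfr(seq_along(marker_idx), function(o) {
    idx <- marker_idx[[o]]
    tibble::tibble(omics = names(marker_idx)[o], gene_id = ann$gene_id[idx],
                   up_subtype = vapply(seq_along(idx), function(j) up_class(o, j), ""),
                   direction = vapply(seq_along(idx), function(j) mk_dir(j), ""))
  })
  dir_sign <- function(j) if (j %% 2 == 1) 1 else -1

  # --- expression: NB counts, subtype-shifted means on planted genes ---
  # baseline means are low (median ~1 count) so the count matrix is sparse,
  # as in real droplet/plate scRNA-seq
  phi <- sim$expr_dispersion
  base_mu <- stats::rgamma(G, shape = 1.5, scale = 1) + 0.2
  mu <- matrix(base_mu, n, G, byrow = TRUE)
  # the planted shift is calibrated on the scale the classifier sees
  # (log1p of normalised counts, delta method for the log-scale SD), like
  # the cluster-level and gene-sum calibrations of the other omics
  for (j in seq_along(marker_idx$expression)) {
    g <- marker_idx$expression[j]
    sd_log <- sqrt(base_mu[g] + phi * base_mu[g]^2) / (1 + base_mu[g])
    shifted <- expm1(log1p(base_mu[g]) +
                       dir_sign(j) * sim$effect_size * sd_log)
    up <- labels == up_class(1L, j)
    mu[up, g] <- max(shifted, 0.02)
  }
  counts <- matrix(stats::rnbinom(n * G, mu = mu, size = 1 / phi), n, G)
  rownames(counts) <- cells
  expr <- omics_matrix(counts,
                       tibble::tibble(feature_id = ann$gene_id,
                                      anchor_gene_id = ann$gene_id),
                       "expression")

  # --- methylation: beta values at promoter CpGs, with missingness ---
  ncpg <- sim$cpgs_per_promoter
  nu <- 30   # beta precision; within-class SD ~ sqrt(m(1-m)/(1+nu))
  cpg_pos <- unlist(lapply(seq_len(G), function(g) {
    w0 <- ann$tss[g] - 2000L
    sort(sample.int(4000L, ncpg) - 1L + w0)
  }))
  site_gene <- rep(seq_len(G), each = ncpg)
  # promoter methylation is bimodal in real data: most promoters are either
  # hypo- or hypermethylated
  hyper <- stats::runif(G) < 0.5
  base_m <- ifelse(hyper, stats::runif(G, 0.7, 0.9), stats::runif(G, 0.1, 0.3))
  mlev <- matrix(base_m[site_gene], n, G * ncpg, byrow = TRUE)
  # the subtype shift moves every member site's mean by effect_size
  # site-level SDs, the scale on which differentially methylated promoters
  # differ in real data (hypo vs hyper swings of 0.2-0.4 in beta)
  for (j in seq_along(marker_idx$methylation)) {
    g <- marker_idx$methylation[j]
    sd_site <- sqrt(base_m[g] * (1 - base_m[g]) / (1 + nu))
    shifted <- min(max(base_m[g] + dir_sign(j) * sim$effect_size * sd_site, 0.05),
                   0.95)
    up <- labels == up_class(2L, j)
    mlev[up, site_gene == g] <- shifted
  }
  betas <- matrix(stats::rbeta(n * G * ncpg, mlev * nu, (1 - mlev) * nu),
                  n, G * ncpg)
  observed <- matrix(stats::runif(n * G * ncpg) >= sim$meth_missing_rate,
                     n, G * ncpg)
  betas[!observed] <- NA
  rownames(betas) <- cells
  meth <- site_matrix(betas,
                      tibble::tibble(chrom = "chrS", start = cpg_pos,
                                     end = cpg_pos + 1L),
                      "methylation", mask = observed)

  # --- accessibility: sparse NB counts on peaks inside gene bodies ---
  npk <- sim$peaks_per_gene
  pk_width <- 200L
  pk_start <- unlist(lapply(seq_len(G), function(g) {
    slots <- floor(4000 / npk)
    ann$body_start[g] + (seq_len(npk) - 1L) * slots +
      sample.int(slots - pk_width, npk, replace = TRUE)
  }))
  peak_gene <- rep(seq_len(G), each = npk)
  base_lam <- stats::rgamma(G * npk, shape = 2, scale = 1) + 0.2
  lam <- matrix(base_lam, n, G * npk, byrow = TRUE)
  size_acc <- 2
  # every member peak's mean moves by effect_size peak-level SDs, the
  # scale on which differentially accessible regions open or close
  for (j in seq_along(marker_idx$accessibility)) {
    g <- marker_idx$accessibility[j]
    cols <- which(peak_gene == g)
    up <- labels == up_class(3L, j)
    sd_p <- sqrt(base_lam[cols] + base_lam[cols]^2 / size_acc)
    lam[up, cols] <- rep(pmax(base_lam[cols] + dir_sign(j) * sim$effect_size * sd_p,
                              0.05 * base_lam[cols]),
                         each = sum(up))
  }
  pk_counts <- matrix(stats::rnbinom(n * G * npk, mu = lam, size = size_acc),
                      n, G * npk)
  rownames(pk_counts) <- cells
  acc <- site_matrix(pk_counts,
                     tibble::tibble(chrom = "chrS", start = pk_start,
                                    end = pk_start + pk_width),
                     "accessibility")

  list(annotation = ann, expression = expr, methylation = meth,
       accessibility = acc,
       labels = tibble::tibble(cell_id = cells, subtype = labels),
       truth = truth)
}

#' Canonical easy synthetic fixture
#'
#' 600 cells, 120 genes, 4 subtypes, 10 disjoint planted markers per omics
#' at effect size 3 within-class SDs, run through the full preprocessing
#' and gene-intersection chain. This is the reference dataset for the
#' package's end-to-end checks: a linearly separable problem on which the
#' classifier should be near-perfect.
#'
#' @param seed integer seed.
#' @return A labelled [multi_omics_dataset()] (gene-level, pre min-max)
#'   with the planted-marker `truth` tibble attached as attribute
#'   `"truth"`.
#' @export
easy_fixture <- function(seed = 1L) {
  sim <- sim_config(seed = seed)
  raw <- generate_multiomics(sim)
  mats <- preprocess_multiomics(expr = raw$expression, meth = raw$methylation,
                                acc = raw$accessibility, ann = raw$annotation)
  dataset <- intersect_by_gene(mats)
  dataset <- align_labels(dataset, raw$labels)
  attr(dataset, "truth") <- raw$truth
  dataset
}
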