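#' Rank marker candidates by mean attention
#'
#' Per omics, the `top_k` features with the highest per-feature mean
#' attention are returned, ranked 1..`top_k`; ties in mean attention break
#' lexicographically on `feature_id`.
#'
#' @param report an `attention_report` from [extract_attention()].
#' @param top_k number of features to keep per omics (default 30).
#' @return A `marker_table` tibble (`omics`, `feature_id`,
#'   `anchor_gene_id`, `mean_attention`, `rank`).
#' @export
rank_markers <- function(report, top_k = 30) {
  stopifnot(inherits(report, "attention_report"))
  out <- report$mean |>
    dplyr::group_by(.data$omics) |>
    dplyr::arrange(dplyr::desc(.data$mean_attention), .data$feature_id,
                   .by_group = TRUE) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::ungroup()
  n_feat <- table(out$omics)
  if (any(n_feat < top_k)) {
    warning("rank_markers: top_k = ", top_k, " exceeds the feature count of ",
            "some omics; returning the full ranking there")
  }
  out <- dplyr::filter(out, .data$rank <= top_k)
  class(out) <- c("marker_table", class(out))
  out
}

#' Cross-omics overlap of marker anchor genes
#'
#' Intersections are computed on anchor genes (one gene can surface as an
#' expression feature, a CpG cluster and an activity feature), for every
#' pair of omics and for the full set.
#'
#' @param markers a `marker_table` from [rank_markers()].
#' @return A tibble with columns `omics_set`, `n_genes`, `genes`
#'   (list-column), covering each single omics and every 2-way and higher
#'   intersection.
#' @export
overlap_markers <- function(markers) {
  sets <- split(markers$anchor_gene_id, markers$omics)
  sets <- lapply(sets, unique)
  kinds <- names(sets)
  combos <- unlist(lapply(seq_along(kinds), function(sz) {
    utils::combn(kinds, sz, simplify = FALSE)
  }), recursive = FALSE)
  purrr::map_dfr(combos, function(kset) {
    genes <- Reduce(intersect, sets[kset])
    tibble::tibble(omics_set = paste(kset, collapse = "&"),
                   n_omics = length(kset),
                   n_genes = length(genes),
                   genes = list(sort(genes)))
  })
}

#' One-way analysis of variance for a single feature
#'
#' Classic equal-variance one-way ANOVA (between/within mean squares, F
#' distributed on `g - 1` and `n - g` degrees of freedom), as used to test
#' whether a candidate marker differs among cell subtypes.
#'
#' @param values numeric vector of per-cell feature values.
#' @param groups vector of subtype labels, same length.
#' @return A one-row tibble with `f_statistic`, `p_value`, `df_between`,
#'   `df_within`. Degenerate inputs (a single group, or zero variance
#'   everywhere with equal means) return `NaN` with a `reason`.
#' @export
one_way_anova <- function(values, groups) {
  groups <- factor(groups)
  g <- nlevels(groups)
  n <- length(values)
  out <- tibble::tibble(f_statistic = NaN, p_value = NaN,
                        df_between = g - 1L, df_within = n - g,
                        reason = NA_character_)
  if (g < 2) {
    out$reason <- "fewer than 2 groups"
    return(out)
  }
  if (n - g < 1) {
    out$reason <- "no within-group degrees of freedom"
    return(out)
  }
  gm <- tapply(values, groups, mean)
  ssw <- sum((values - gm[groups])^2)
  if (ssw == 0 && length(unique(gm)) == 1) {
    out$reason <- "zero within-group variance with equal means"
    return(out)
  }
  ht <- stats::oneway.test(values ~ groups, var.equal = TRUE)
  out$f_statistic <- unname(ht$statistic)
  out$p_value <- unname(ht$p.value)
  out
}

#' Marker candidates with ANOVA validation
#'
#' Composes attention extraction, top-k ranking, cross-omics overlap and a
#' per-marker one-way ANOVA of the normalised abundances across subtypes.
#' Markers with `p < alpha_threshold` are flagged as significant. No
#' multiple-testing correction is applied by default (flagging uses the raw
#' per-feature threshold); set `adjust = "BH"` for Benjamini-Hochberg
#' within each omics.
#'
#' @param dataset a labelled [multi_omics_dataset()].
#' @param model a fitted `attention_model` (with attention).
#' @param top_k markers per omics (default 30).
#' @param alpha_threshold significance threshold (default 0.01).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return A list with `markers` (the ranked table plus `f_statistic`,
#'   `p_value`, `significant`), `overlap` (from [overlap_markers()]) and
#'   `report` (the raw [extract_attention()] output).
#' @export
marker_report <- function(dataset, model, top_k = 30, alpha_threshold = 0.01,
                          adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  stopifnot(!is.null(dataset$labels))
  report <- extract_attention(model, dataset)
  markers <- rank_markers(report, top_k = top_k)
  scaled <- apply_scaling(dataset, model$scaling)
  labels <- unname(dataset$labels[dataset$cells])
  anova_tbl <- purrr::map_dfr(seq_len(nrow(markers)), function(i) {
    vals <- scaled[[markers$omics[i]]]$values[, markers$feature_id[i]]
    one_way_anova(vals, labels)[, c("f_statistic", "p_value")]
  })
  markers <- dplyr::bind_cols(markers, anova_tbl)
  if (adjust == "BH") {
    markers <- markers |>
      dplyr::group_by(.data$omics) |>
      dplyr::mutate(p_value = stats::p.adjust(.data$p_value, "BH")) |>
      dplyr::ungroup()
  }
  markers$significant <- !is.na(markers$p_value) &
    markers$p_value < alpha_threshold
  list(markers = markers, overlap = overlap_markers(markers), report = report)
}
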