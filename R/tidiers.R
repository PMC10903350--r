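#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the training trace of a fitted model
#'
#' @param x an `attention_model`.
#' @param ... unused.
#' @return A tibble with `epoch` and mean mini-batch `loss`.
#' @export
tidy.attention_model <- function(x, ...) {
  tibble::tibble(epoch = seq_along(x$loss_trace), loss = x$loss_trace)
}

#' One-row summary of a fitted model
#'
#' @param x an `attention_model`.
#' @param ... unused.
#' @return A one-row tibble with architecture and final-loss columns.
#' @export
glance.attention_model <- function(x, ...) {
  tibble::tibble(
    n_omics = length(x$omics_kinds),
    n_features = sum(x$ks),
    n_classes = length(x$classes),
    use_attention = x$config$use_attention,
    epochs = x$config$epochs,
    final_loss = if (length(x$loss_trace)) x$loss_trace[length(x$loss_trace)]
                 else NA_real_)
}

#' Per-fold metrics of a cross-validation result
#'
#' @param x a `cv_result`.
#' @param ... unused.
#' @return A long tibble with `fold`, `metric`, `value`.
#' @export
tidy.cv_result <- function(x, ...) {
  tidyr::pivot_longer(x$per_fold, -"fold", names_to = "metric",
                      values_to = "value")
}

#' One-row summary of a cross-validation result
#'
#' @param x a `cv_result`.
#' @param ... unused.
#' @return A one-row tibble with the mean of each metric and fold count.
#' @export
glance.cv_result <- function(x, ...) {
  wide <- stats::setNames(as.list(x$summary$mean), x$summary$metric)
  dplyr::bind_cols(tibble::as_tibble(wide), tibble::tibble(k = x$k))
}

#' Plot the training loss curve
#'
#' @param object an `attention_model`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.attention_model <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "epoch", y = "mean mini-batch cross-entropy",
                  title = "Training loss") +
    ggplot2::theme_minimal()
}

#' Plot per-fold cross-validation metrics
#'
#' @param object a `cv_result`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.cv_result <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot(fill = "grey90") +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.6) +
    ggplot2::labs(x = NULL, y = "per-fold value",
                  title = sprintf("%d-fold cross-validation", object$k)) +
    ggplot2::theme_minimal()
}

#' Plot the top mean-attention features per omics
#'
#' @param object an `attention_report`.
#' @param top_k features per omics to display.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.attention_report <- function(object, top_k = 15, ...) {
  df <- object$mean |>
    dplyr::group_by(.data$omics) |>
    dplyr::slice_max(.data$mean_attention, n = top_k, with_ties = FALSE) |>
    dplyr::ungroup()
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$mean_attention,
    y = stats::reorder(.data$feature_id, .data$mean_attention))) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~omics, scales = "free") +
    ggplot2::labs(x = "mean attention", y = NULL,
                  title = "Top features by mean attention") +
    ggplot2::theme_minimal()
}
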