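#' Stratified k-fold assignment
#'
#' Cells are split into `k` folds stratified by subtype: within each class,
#' shuffled cells are dealt to folds in rotation, so per-class fold sizes
#' differ by at most one. Classes with fewer than `k` members are pooled
#' into folds best-effort with a warning.
#'
#' @param cells character vector of cell IDs.
#' @param labels named character vector (or tibble `cell_id`, `subtype`)
#'   labelling the cells.
#' @param k number of folds.
#' @param seed integer seed for the shuffles.
#' @return A tibble with columns `cell_id`, `subtype`, `fold`.
#' @export
kfold_split <- function(cells, labels, k = 5, seed = 1L) {
  if (is.data.frame(labels)) {
    labels <- stats::setNames(as.character(labels[[2]]), as.character(labels[[1]]))
  }
  lab <- labels[cells]
  if (anyNA(lab)) stop("kfold_split: unlabelled cell(s)")
  set.seed(seed)
  fold <- integer(length(cells))
  offset <- 0L
  for (cl in sort(unique(lab))) {
    idx <- which(lab == cl)
    if (length(idx) < k) {
      warning("kfold_split: class '", cl, "' has fewer than ", k,
              " members; pooled into folds best-effort")
    }
    idx <- idx[sample.int(length(idx))]
    # rotate the starting fold across classes so small classes do not all
    # land in fold 1
    fold[idx] <- ((seq_along(idx) - 1L + offset) %% k) + 1L
    offset <- (offset + length(idx)) %% k
  }
  tibble::tibble(cell_id = cells, subtype = unname(lab), fold = fold)
}

#' Cross-validated evaluation of the attention classifier
#'
#' Runs stratified k-fold cross-validation. With
#' `minmax_fit = "train_only"` (default) the min-max statistics are fitted
#' inside each fold on the training cells only and applied (with clipping)
#' to the held-out cells; `"all"` scales once on the full dataset before
#' splitting.
#'
#' @param dataset a labelled [multi_omics_dataset()] (unscaled gene-level
#'   values).
#' @param config an [attention_config()]; fold f trains with seed
#'   `config$seed + f` so folds are independent but reproducible.
#' @param k number of folds.
#' @param seed seed for the fold assignment.
#' @param minmax_fit `"train_only"` or `"all"`.
#' @param details keep per-fold fitted models and scaling statistics.
#' @return A `cv_result`: list with `folds` (assignment tibble),
#'   `per_fold` (metrics tibble with a `fold` column), `summary`
#'   (mean/sd per metric), `per_class` (pooled per-subtype table) and
#'   `predictions`.
#' @export
run_cv <- function(dataset, config = attention_config(), k = 5, seed = 1L,
                   minmax_fit = c("train_only", "all"), details = FALSE) {
  minmax_fit <- match.arg(minmax_fit)
  stopifnot(!is.null(dataset$labels))
  folds <- kfold_split(dataset$cells, dataset$labels, k = k, seed = seed)
  prescaled <- minmax_fit == "all"
  if (prescaled) {
    scaling <- fit_scaling(dataset)
    omics <- apply_scaling(dataset, scaling)
    dataset <- multi_omics_dataset(omics, tibble::tibble(
      cell_id = names(dataset$labels), subtype = unname(dataset$labels)))
  }
  per_fold <- vector("list", k)
  preds <- vector("list", k)
  fold_details <- if (details) vector("list", k) else NULL
  for (f in seq_len(k)) {
    tr_idx <- which(folds$fold != f)
    te_idx <- which(folds$fold == f)
    cfg <- config
    cfg$seed <- config$seed + f
    train_set <- subset_cells(dataset, tr_idx)
    test_set <- subset_cells(dataset, te_idx)
    model <- tryCatch(
      train_attention(train_set, cfg, prescaled = prescaled),
      error = function(e) stop("run_cv: fold ", f, ": ", conditionMessage(e))
    )
    out <- forward_internal(model, test_set)
    y_true <- unname(dataset$labels[test_set$cells])
    y_pred <- model$classes[max.col(out$prob, ties.method = "first")]
    per_fold[[f]] <- dplyr::bind_cols(
      tibble::tibble(fold = f),
      compute_metrics(y_true, y_pred, out$prob, model$classes))
    preds[[f]] <- tibble::tibble(cell_id = test_set$cells, fold = f,
                                 subtype = y_true, .pred = y_pred)
    preds[[f]] <- dplyr::bind_cols(preds[[f]], tibble::as_tibble(out$prob))
    if (details) {
      fold_details[[f]] <- list(model = model, scaling = model$scaling)
    }
  }
  per_fold <- dplyr::bind_rows(per_fold)
  predictions <- dplyr::bind_rows(preds)
  classes <- sort(unique(unname(dataset$labels)))
  summary <- tidyr::pivot_longer(per_fold, -"fold", names_to = "metric") |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(mean = mean(.data$value), sd = stats::sd(.data$value),
                     .groups = "drop")
  per_class <- per_class_metrics(predictions$subtype, predictions$.pred,
                                 as.matrix(predictions[, classes]), classes)
  structure(list(folds = folds, per_fold = per_fold, summary = summary,
                 per_class = per_class, predictions = predictions,
                 details = fold_details,
                 config = config, k = k, seed = seed, minmax_fit = minmax_fit),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d-fold CV, %d cells\n", x$k, nrow(x$folds)))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-12s %.4f +/- %.4f\n", s$metric[i], s$mean[i], s$sd[i]))
  }
  invisible(x)
}

#' Cross-validate every requested omics combination
#'
#' Runs one cross-validation per omics subset; subsets are tagged in the
#' conventional scheme `gene` (expression), `methyl` (methylation), `acc`
#' (accessibility), joined with `+`.
#'
#' @param dataset a labelled [multi_omics_dataset()].
#' @param config an [attention_config()].
#' @param combos list of character vectors of omics kinds; `"all"` (default)
#'   evaluates every nonempty subset of the dataset's omics.
#' @param k,seed,minmax_fit passed to [run_cv()].
#' @return A tibble with one row per combination and metric means, plus a
#'   `cv` list-column of the full `cv_result` objects.
#' @export
run_omics_ablation <- function(dataset, config = attention_config(),
                               combos = "all", k = 5, seed = 1L,
                               minmax_fit = "train_only") {
  kinds <- names(dataset$omics)
  if (identical(combos, "all")) {
    combos <- unlist(lapply(seq_along(kinds), function(sz) {
      utils::combn(kinds, sz, simplify = FALSE)
    }), recursive = FALSE)
  }
  tags <- c(expression = "gene", methylation = "methyl",
            accessibility = "acc")
  purrr::map_dfr(combos, function(kset) {
    sub <- subset_omics(dataset, kset)
    cv <- run_cv(sub, config, k = k, seed = seed, minmax_fit = minmax_fit)
    means <- stats::setNames(cv$summary$mean, cv$summary$metric)
    tibble::tibble(
      combination = paste(tags[names(sub$omics)], collapse = "+"),
      n_omics = length(kset),
      accuracy = means[["accuracy"]], f1_weighted = means[["f1_weighted"]],
      mcc = means[["mcc"]], auc = means[["auc"]],
      cv = list(cv))
  })
}

#' Grid search over configurations on a stratified 80/20 split
#'
#' Each candidate configuration is trained once on the training split and
#' scored by accuracy on the held-out split; the best test accuracy wins,
#' ties resolving to the earlier grid entry.
#'
#' @param dataset a labelled [multi_omics_dataset()].
#' @param grid list of [attention_config()] objects, or a data frame whose
#'   columns override [attention_config()] defaults row by row.
#' @param split_ratio training fraction (default 0.8).
#' @param seed seed for the split.
#' @return A list with `best_config`, `best_index` and `table` (one row per
#'   grid point with its test accuracy).
#' @export
grid_search <- function(dataset, grid, split_ratio = 0.8, seed = 1L) {
  if (is.data.frame(grid)) {
    grid <- lapply(seq_len(nrow(grid)), function(i) {
      do.call(attention_config, as.list(grid[i, , drop = FALSE]))
    })
  }
  stopifnot(length(grid) >= 1)
  # stratified split via a k-fold assignment with k = 1/(1 - ratio)
  k <- max(2L, as.integer(round(1 / (1 - split_ratio))))
  folds <- kfold_split(dataset$cells, dataset$labels, k = k, seed = seed)
  te_idx <- which(folds$fold == 1)
  tr_idx <- which(folds$fold != 1)
  train_set <- subset_cells(dataset, tr_idx)
  test_set <- subset_cells(dataset, te_idx)
  acc <- numeric(length(grid))
  for (i in seq_along(grid)) {
    model <- train_attention(train_set, grid[[i]])
    out <- forward_internal(model, test_set)
    y_pred <- model$classes[max.col(out$prob, ties.method = "first")]
    acc[i] <- mean(y_pred == unname(dataset$labels[test_set$cells]))
  }
  best <- which.max(acc)   # ties -> first in grid order
  tbl <- purrr::map_dfr(seq_along(grid), function(i) {
    cfg <- grid[[i]]
    tibble::tibble(grid_index = i, embed_dim = cfg$embed_dim,
                   encoded_dim = cfg$encoded_dim,
                   hidden_nodes = cfg$hidden_nodes,
                   dropout_rate = cfg$dropout_rate,
                   learning_rate = cfg$learning_rate, epochs = cfg$epochs,
                   batch_size = cfg$batch_size,
                   use_attention = cfg$use_attention,
                   test_accuracy = acc[i])
  })
  list(best_config = grid[[best]], best_index = best, table = tbl)
}
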