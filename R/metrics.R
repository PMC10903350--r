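#' Multiclass classification metrics
#'
#' Computes the four evaluation metrics: accuracy, support-weighted F1,
#' the Gorodkin multiclass Matthews correlation coefficient, and
#' macro-averaged one-vs-rest ROC AUC on the predicted probabilities.
#' Classes absent from `y_true` have undefined OvR AUC and are excluded
#' from the macro mean.
#'
#' @param y_true,y_pred character vectors of true and predicted subtypes.
#' @param y_prob numeric matrix of class probabilities with one column per
#'   class in `class_inventory` (required for AUC; `NULL` gives `NA` AUC).
#' @param class_inventory ordered vector of all classes; defaults to the
#'   sorted union of `y_true` and `y_pred`.
#' @return A one-row tibble with columns `accuracy`, `f1_weighted`, `mcc`,
#'   `auc`.
#' @export
compute_metrics <- function(y_true, y_pred, y_prob = NULL,
                            class_inventory = NULL) {
  classes <- class_inventory %||% sort(unique(c(y_true, y_pred)))
  stopifnot(length(y_true) == length(y_pred))
  yt <- factor(y_true, levels = classes)
  yp <- factor(y_pred, levels = classes)
  cm <- table(yt, yp)

  accuracy <- mean(y_true == y_pred)

  support <- rowSums(cm)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  prec <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  rec <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  f1_weighted <- sum(f1 * support) / sum(support)

  mcc <- mcc_multiclass(cm)

  auc <- NA_real_
  if (!is.null(y_prob)) {
    stopifnot(ncol(y_prob) == length(classes))
    present <- classes[classes %in% y_true & !vapply(classes, function(cl) {
      all(y_true == cl)
    }, TRUE)]
    if (length(present) < length(classes)) {
      message("compute_metrics: OvR AUC undefined for class(es) without both ",
              "positives and negatives; excluded from macro mean")
    }
    aucs <- vapply(present, function(cl) {
      ovr_auc(y_true == cl, y_prob[, which(classes == cl)])
    }, 0)
    auc <- mean(aucs)
  }

  tibble::tibble(accuracy = accuracy, f1_weighted = f1_weighted,
                 mcc = mcc, auc = auc)
}

# Gorodkin's generalization of the Matthews correlation to C classes
mcc_multiclass <- function(cm) {
  cm <- as.matrix(cm)
  n <- sum(cm)
  t_k <- rowSums(cm)   # true occurrences
  p_k <- colSums(cm)   # predicted occurrences
  num <- sum(diag(cm)) * n - sum(t_k * p_k)
  den <- sqrt(n^2 - sum(p_k^2)) * sqrt(n^2 - sum(t_k^2))
  if (den == 0) return(0)
  num / den
}

# one-vs-rest AUC via pROC; direction fixed so higher prob -> positive
ovr_auc <- function(is_pos, prob) {
  r <- pROC::roc(response = factor(is_pos, levels = c(FALSE, TRUE)),
                 predictor = prob, quiet = TRUE, direction = "<")
  as.numeric(pROC::auc(r))
}

#' Per-class precision/recall/F1 (and OvR AUC) table
#'
#' @inheritParams compute_metrics
#' @return A tibble with one row per class.
#' @export
per_class_metrics <- function(y_true, y_pred, y_prob = NULL,
                              class_inventory = NULL) {
  classes <- class_inventory %||% sort(unique(c(y_true, y_pred)))
  yt <- factor(y_true, levels = classes)
  yp <- factor(y_pred, levels = classes)
  cm <- table(yt, yp)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  prec <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  rec <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  auc <- rep(NA_real_, length(classes))
  if (!is.null(y_prob)) {
    for (i in seq_along(classes)) {
      pos <- y_true == classes[i]
      if (any(pos) && !all(pos)) auc[i] <- ovr_auc(pos, y_prob[, i])
    }
  }
  tibble::tibble(subtype = classes, support = as.integer(rowSums(cm)),
                 precision = unname(prec), recall = unname(rec),
                 f1 = unname(f1), auc = auc)
}
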