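#' Configuration of the omics-level attention classifier
#'
#' Defaults: 128-dimensional feature embeddings, 64-dimensional encoded
#' vectors, a 100-node hidden layer with dropout 0.2, Adam with learning
#' rate 1e-3, 300 epochs, batch size 128.
#'
#' @param embed_dim embedding dimension m of each feature's random vector.
#' @param encoded_dim dimension of the encoded feature vectors (and hence of
#'   each omics' context vector).
#' @param attn_dim width d_a of the scoring layer; defaults to `encoded_dim`.
#' @param hidden_nodes nodes in the first fully connected layer.
#' @param dropout_rate dropout probability applied (inverted dropout) to
#'   the FC-head input and to the fc1 activations, in `[0, 1)`.
#' @param learning_rate Adam learning rate.
#' @param epochs training epochs.
#' @param batch_size mini-batch size.
#' @param seed integer seed driving initialisation, batch shuffling and
#'   dropout.
#' @param use_attention `FALSE` builds the no-attention ablation: raw
#'   normalised features are concatenated and fed directly to the FC head.
#' @param freeze_embeddings if `TRUE`, embeddings stay at their random
#'   initialisation instead of being trained.
#' @param hidden_activation activation of the FC hidden layer.
#' @param weight_decay decoupled (AdamW-style) weight decay applied to
#'   weight matrices; 0 disables it.
#' @param branch_lr_scale learning-rate multiplier for the per-omics
#'   attention branches relative to the FC head. The default 0.1 slows the
#'   branch drift that otherwise destabilises the head's fit; 1 recovers a
#'   single global learning rate.
#' @return An `attention_config` list.
#' @export
attention_config <- function(embed_dim = 128, encoded_dim = 64, attn_dim = NULL,
                             hidden_nodes = 100, dropout_rate = 0.2,
                             learning_rate = 1e-3, epochs = 300,
                             batch_size = 128, seed = 1L,
                             use_attention = TRUE, freeze_embeddings = FALSE,
                             hidden_activation = c("relu", "tanh"),
                             weight_decay = 0, branch_lr_scale = 0.1) {
  hidden_activation <- match.arg(hidden_activation)
  attn_dim <- attn_dim %||% encoded_dim
  stopifnot(embed_dim > 0, encoded_dim > 0, attn_dim > 0, hidden_nodes > 0,
            dropout_rate >= 0, dropout_rate < 1, learning_rate > 0,
            epochs >= 0, batch_size > 0)
  structure(list(embed_dim = as.integer(embed_dim),
                 encoded_dim = as.integer(encoded_dim),
                 attn_dim = as.integer(attn_dim),
                 hidden_nodes = as.integer(hidden_nodes),
                 dropout_rate = dropout_rate,
                 learning_rate = learning_rate,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed),
                 use_attention = isTRUE(use_attention),
                 freeze_embeddings = isTRUE(freeze_embeddings),
                 hidden_activation = hidden_activation,
                 weight_decay = weight_decay,
                 branch_lr_scale = branch_lr_scale),
            class = "attention_config")
}

#' No-attention ablation of a configuration
#'
#' @param config an [attention_config()].
#' @return The same configuration with the attention transform removed.
#' @export
build_no_attention_variant <- function(config = attention_config()) {
  config$use_attention <- FALSE
  config
}

# ---- elementary operations (exported for transparency and testing) ----

#' Embed a scalar feature value
#'
#' The embedding of feature j for one sample is its random vector scaled by
#' the observed value: `e_j * x`.
#'
#' @param x_value scalar feature value.
#' @param e_j the feature's m-dimensional embedding vector.
#' @return The m-dimensional embedded feature.
#' @export
embed_feature <- function(x_value, e_j) e_j * x_value

#' Encode an embedded feature
#'
#' @param x_hat embedded feature (m-vector).
#' @param W1 encoding weights (encoded_dim x m).
#' @param b1 encoding bias (encoded_dim).
#' @return `tanh(W1 x_hat + b1)`.
#' @export
encode_feature <- function(x_hat, W1, b1) {
  tanh(drop(W1 %*% x_hat) + b1)
}

#' Raw attention score of an embedded feature
#'
#' @param x_hat embedded feature (m-vector).
#' @param W2 scoring weights (attn_dim x m).
#' @param b2 scoring bias (attn_dim).
#' @param W3 scoring projection (attn_dim vector).
#' @return Scalar score `W3' tanh(W2 x_hat + b2)`.
#' @export
score_feature <- function(x_hat, W2, b2, W3) {
  sum(W3 * tanh(drop(W2 %*% x_hat) + b2))
}

#' Softmax-normalise attention scores
#'
#' Computed with max-subtraction for numerical stability; the result sums
#' to 1.
#'
#' @param s vector of raw scores over a sample's features.
#' @return Attention weights of the same length.
#' @export
normalize_attention <- function(s) {
  if (length(s) == 0) stop("normalize_attention: empty score vector")
  z <- exp(s - max(s))
  z / sum(z)
}

#' Attention-pooled context vector
#'
#' @param alpha attention weights (k-vector summing to 1).
#' @param x_bar encoded feature matrix (k x encoded_dim).
#' @return The weighted sum over features, an encoded_dim-vector.
#' @export
context_vector <- function(alpha, x_bar) {
  drop(crossprod(x_bar, alpha))
}

#' Cross-entropy loss
#'
#' @param y_true one-hot (or probability) vector over classes.
#' @param y_hat predicted probability vector; floored at 1e-12 before the
#'   log.
#' @return Scalar loss `-sum(y * log(y_hat))`.
#' @export
cross_entropy <- function(y_true, y_hat) {
  -sum(y_true * log(pmax(y_hat, 1e-12)))
}

# ---- parameter handling ----

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

# Parameters live in a nested list: $omics (one 6-array set per omics,
# absent for the no-attention variant) plus the shared head F1/g1/F2/g2.
# The C++ trainer mutates these arrays in place, so they must never be
# aliased at the R level.
init_params <- function(ks, config, n_classes, n_omics) {
  m <- config$embed_dim; h <- config$encoded_dim; da <- config$attn_dim
  H <- config$hidden_nodes
  par <- list(omics = list())
  if (config$use_attention) {
    for (o in seq_along(ks)) {
      k <- ks[o]
      par$omics[[o]] <- list(
        # standard-normal random embedding vectors, one per feature
        E = matrix(stats::rnorm(k * m), k, m),
        W1 = glorot(h, m),
        b1 = numeric(h),
        W2 = glorot(da, m),
        b2 = numeric(da),
        # the score projection starts at zero: attention begins exactly
        # uniform and concentrates only as informative scores are learned,
        # instead of locking onto features favoured by random init
        W3 = numeric(da),
        # running statistics of the context standardisation (not
        # Adam-trained); negative variance marks them uninitialised
        bn_mu = numeric(h),
        bn_var = rep(-1, h))
    }
    width <- h * n_omics
  } else {
    width <- sum(ks)
  }
  par$F1 <- glorot(H, width)
  par$g1 <- numeric(H)
  par$F2 <- glorot(n_classes, H)
  par$g2 <- numeric(n_classes)
  par
}

zero_like <- function(par) {
  rapply(par, function(x) x * 0, how = "replace")
}

# R-side Adam (decoupled weight decay on weight matrices, not biases) for
# the no-attention head; the attention path updates in C++
adam_update <- function(par, grads, state, lr, wd = 0) {
  state$t <- state$t + 1
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  corr1 <- 1 - b1^state$t
  corr2 <- 1 - b2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g * g
    decay <- if (nm %in% c("F1", "F2")) wd * par[[nm]] else 0
    par[[nm]] <- par[[nm]] -
      lr * ((state$m[[nm]] / corr1) / (sqrt(state$v[[nm]] / corr2) + eps) + decay)
  }
  list(par = par, state = state)
}

# ---- scaling ----

fit_scaling <- function(dataset) {
  lapply(dataset$omics, function(o) {
    if (o$omics_kind == "methylation") NULL else minmax_normalize(o)$fit_stats
  })
}

apply_scaling <- function(dataset, scaling) {
  omics <- lapply(names(dataset$omics), function(kind) {
    o <- dataset$omics[[kind]]
    st <- scaling[[kind]]
    if (is.null(st)) o else minmax_normalize(o, fit_stats = st)$matrix
  })
  names(omics) <- names(dataset$omics)
  omics
}

# ---- training ----

#' Train the omics-level attention classifier
#'
#' Each omics is min-max scaled (statistics fitted on the cells passed in
#' here; methylation betas are already in `[0, 1]` and pass through), then
#' all parameters — embeddings included — are optimised with Adam on
#' mini-batch cross-entropy. With `config$use_attention = FALSE` the same
#' FC head is trained on the concatenated scaled features instead (the
#' no-attention ablation).
#'
#' @param dataset a labelled [multi_omics_dataset()].
#' @param config an [attention_config()].
#' @param prescaled set `TRUE` when the dataset has already been min-max
#'   scaled elsewhere (e.g. whole-dataset scaling before cross-validation).
#' @return An `attention_model` with parameters, scaling statistics, class
#'   inventory, omics layout and the per-epoch loss trace.
#' @export
train_attention <- function(dataset, config = attention_config(),
                            prescaled = FALSE) {
  stopifnot(inherits(dataset, "multi_omics_dataset"))
  if (is.null(dataset$labels)) stop("train_attention: dataset has no labels")
  set.seed(config$seed)

  classes <- dataset$class_inventory
  C <- length(classes)
  n <- length(dataset$cells)
  scaling <- if (prescaled) {
    stats::setNames(vector("list", length(dataset$omics)), names(dataset$omics))
  } else {
    fit_scaling(dataset)
  }
  scaled <- apply_scaling(dataset, scaling)
  Xs <- lapply(scaled, function(o) o$values)
  ks <- vapply(Xs, ncol, 0L)
  n_omics <- length(Xs)

  y_idx <- match(dataset$labels[dataset$cells], classes)
  Y <- matrix(0, n, C)
  Y[cbind(seq_len(n), y_idx)] <- 1

  par <- init_params(ks, config, C, n_omics)
  tanh_hidden <- config$hidden_activation == "tanh"
  p_drop <- config$dropout_rate
  H <- config$hidden_nodes
  loss_trace <- numeric(config$epochs)
  starts <- seq(1, n, by = config$batch_size)
  n_batches <- length(starts)

  if (config$use_attention) {
    m_state <- zero_like(par)
    v_state <- zero_like(par)
    t_adam <- 0
    width <- config$encoded_dim * n_omics
    for (epoch in seq_len(config$epochs)) {
      perm <- sample.int(n)
      masks <- lapply(seq_len(n_batches), function(bi) {
        B <- min(starts[bi] + config$batch_size - 1, n) - starts[bi] + 1
        if (p_drop > 0) {
          matrix((stats::runif(B * H) >= p_drop) / (1 - p_drop), B, H)
        } else NULL
      })
      masks_z <- lapply(seq_len(n_batches), function(bi) {
        B <- min(starts[bi] + config$batch_size - 1, n) - starts[bi] + 1
        if (p_drop > 0) {
          matrix((stats::runif(B * width) >= p_drop) / (1 - p_drop), B, width)
        } else NULL
      })
      # parameters and Adam state are updated in place inside C++
      res <- cpp_train_epoch(Xs, Y, perm, config$batch_size, par,
                             m_state, v_state, t_adam, config$learning_rate,
                             masks, masks_z, tanh_hidden,
                             config$freeze_embeddings, config$weight_decay,
                             config$branch_lr_scale)
      if (!is.finite(res$loss)) {
        stop("train_attention: divergence (non-finite loss) at epoch ", epoch)
      }
      t_adam <- res$t
      loss_trace[epoch] <- res$loss
    }
  } else {
    head <- par[c("F1", "g1", "F2", "g2")]
    state <- list(t = 0, m = lapply(head, function(x) x * 0),
                  v = lapply(head, function(x) x * 0))
    Xall <- do.call(cbind, Xs)
    for (epoch in seq_len(config$epochs)) {
      idx <- sample.int(n)
      batch_losses <- numeric(n_batches)
      for (bi in seq_len(n_batches)) {
        rows <- idx[starts[bi]:min(starts[bi] + config$batch_size - 1, n)]
        B <- length(rows)
        mask <- if (p_drop > 0) {
          matrix((stats::runif(B * H) >= p_drop) / (1 - p_drop), B, H)
        } else NULL
        mask_x <- if (p_drop > 0) {
          matrix((stats::runif(B * ncol(Xall)) >= p_drop) / (1 - p_drop),
                 B, ncol(Xall))
        } else NULL
        step <- mlp_step(Xall[rows, , drop = FALSE], head,
                         Y[rows, , drop = FALSE], mask, tanh_hidden, mask_x)
        if (!is.finite(step$loss)) {
          stop("train_attention: divergence (non-finite loss) at epoch ", epoch)
        }
        upd <- adam_update(head, step$grads, state, config$learning_rate,
                           config$weight_decay)
        head <- upd$par
        state <- upd$state
        batch_losses[bi] <- step$loss
      }
      loss_trace[epoch] <- mean(batch_losses)
    }
    par[c("F1", "g1", "F2", "g2")] <- head
  }

  structure(
    list(config = config,
         classes = classes,
         omics_kinds = names(dataset$omics),
         features = lapply(dataset$omics, function(o) o$features),
         ks = ks,
         par = par,
         scaling = scaling,
         loss_trace = loss_trace),
    class = "attention_model"
  )
}

# plain two-layer head on concatenated features (no-attention ablation);
# mask_x drops input features (fc1 input), mask the fc1 activations
mlp_step <- function(X, par, Y, mask, tanh_hidden, mask_x = NULL) {
  B <- nrow(X)
  if (!is.null(mask_x)) X <- X * mask_x
  H1 <- X %*% t(par$F1)
  H1 <- sweep(H1, 2, par$g1, "+")
  R <- if (tanh_hidden) tanh(H1) else pmax(H1, 0)
  A <- if (is.null(mask)) R else R * mask
  logits <- sweep(A %*% t(par$F2), 2, par$g2, "+")
  prob <- softmax_rows(logits)
  loss <- -sum(Y * log(pmax(prob, 1e-12))) / B
  Glog <- (prob - Y) / B
  dA <- Glog %*% par$F2
  if (!is.null(mask)) dA <- dA * mask
  dH1 <- if (tanh_hidden) dA * (1 - R^2) else dA * (H1 > 0)
  list(loss = loss,
       grads = list(F1 = t(dH1) %*% X, g1 = colSums(dH1),
                    F2 = t(Glog) %*% A, g2 = colSums(Glog)))
}

softmax_rows <- function(m) {
  z <- exp(m - apply(m, 1, max))
  z / rowSums(z)
}

# ---- inference ----

check_feature_layout <- function(model, dataset) {
  if (!identical(names(dataset$omics), model$omics_kinds)) {
    stop("model/dataset omics mismatch: model expects [",
         paste(model$omics_kinds, collapse = ", "), "], dataset has [",
         paste(names(dataset$omics), collapse = ", "), "]")
  }
  for (kind in model$omics_kinds) {
    ka <- ncol(dataset$omics[[kind]]$values)
    ke <- model$ks[[kind]]
    if (ka != ke) {
      stop("feature-count mismatch for ", kind, ": expected ", ke,
           ", got ", ka)
    }
  }
}

forward_internal <- function(model, dataset, chunk = 256L, want_alpha = FALSE) {
  check_feature_layout(model, dataset)
  scaled <- apply_scaling(dataset, model$scaling)
  Xs <- lapply(scaled, function(o) o$values)
  n <- nrow(Xs[[1]])
  n_omics <- length(Xs)
  tanh_hidden <- model$config$hidden_activation == "tanh"
  prob <- matrix(NA_real_, n, length(model$classes))
  alphas <- if (want_alpha) {
    lapply(model$ks, function(k) matrix(NA_real_, n, k))
  } else NULL
  for (s in seq(1, n, by = chunk)) {
    rows <- s:min(s + chunk - 1, n)
    if (model$config$use_attention) {
      out <- cpp_attn_forward(lapply(Xs, function(X) X[rows, , drop = FALSE]),
                              model$par$omics,
                              model$par$F1, model$par$g1,
                              model$par$F2, model$par$g2, NULL, tanh_hidden)
      prob[rows, ] <- out$prob
      if (want_alpha) {
        for (o in seq_len(n_omics)) alphas[[o]][rows, ] <- out$alpha[[o]]
      }
    } else {
      Xb <- do.call(cbind, lapply(Xs, function(X) X[rows, , drop = FALSE]))
      H1 <- sweep(Xb %*% t(model$par$F1), 2, model$par$g1, "+")
      R <- if (tanh_hidden) tanh(H1) else pmax(H1, 0)
      prob[rows, ] <- softmax_rows(sweep(R %*% t(model$par$F2), 2,
                                         model$par$g2, "+"))
    }
  }
  colnames(prob) <- model$classes
  rownames(prob) <- dataset$cells
  list(prob = prob, alpha = alphas)
}

#' Forward pass of a fitted model
#'
#' Runs the deterministic (dropout-off) forward pass, returning class
#' probabilities and, for attention models, the per-sample attention
#' weights of every omics.
#'
#' @param model an `attention_model` from [train_attention()].
#' @param dataset a [multi_omics_dataset()] with the model's feature layout.
#' @return A list with `prob` (cells x classes matrix) and `alpha` (named
#'   list of cells x features attention matrices; `NULL` for no-attention
#'   models).
#' @export
forward_attention <- function(model, dataset) {
  out <- forward_internal(model, dataset,
                          want_alpha = model$config$use_attention)
  if (!is.null(out$alpha)) names(out$alpha) <- model$omics_kinds
  out
}

#' Predict cell subtypes
#'
#' @param object an `attention_model`.
#' @param dataset a [multi_omics_dataset()].
#' @param type `"class"` for a tibble of predicted subtypes, `"prob"` to
#'   also include one probability column per subtype.
#' @param ... unused.
#' @return A tibble with `cell_id`, `.pred` and (for `type = "prob"`) the
#'   class probability columns. Ties in the argmax resolve to the first
#'   class in the sorted inventory.
#' @export
predict.attention_model <- function(object, dataset,
                                    type = c("class", "prob"), ...) {
  type <- match.arg(type)
  prob <- forward_internal(object, dataset)$prob
  pred <- object$classes[max.col(prob, ties.method = "first")]
  out <- tibble::tibble(cell_id = dataset$cells, .pred = pred)
  if (type == "prob") {
    out <- dplyr::bind_cols(out, tibble::as_tibble(prob))
  }
  out
}

#' Extract per-feature attention scores
#'
#' Computes every sample's attention weights (dropout off) and averages
#' them per feature — the substrate for marker ranking.
#'
#' @param model an `attention_model` trained with attention.
#' @param dataset a [multi_omics_dataset()].
#' @return An `attention_report`: list with `alpha` (named list of
#'   cells x features matrices) and `mean` (tibble `omics`, `feature_id`,
#'   `anchor_gene_id`, `mean_attention`).
#' @export
extract_attention <- function(model, dataset) {
  if (!model$config$use_attention) {
    stop("extract_attention: model was trained without attention")
  }
  out <- forward_internal(model, dataset, want_alpha = TRUE)
  names(out$alpha) <- model$omics_kinds
  mean_tbl <- purrr::map_dfr(model$omics_kinds, function(kind) {
    feats <- model$features[[kind]]
    tibble::tibble(omics = kind,
                   feature_id = feats$feature_id,
                   anchor_gene_id = feats$anchor_gene_id,
                   mean_attention = colMeans(out$alpha[[kind]]))
  })
  structure(list(alpha = out$alpha, mean = mean_tbl),
            class = "attention_report")
}

#' @export
print.attention_model <- function(x, ...) {
  cat(sprintf("<attention_model%s> %d omics [%s], %d classes, final loss %.4f\n",
              if (x$config$use_attention) "" else " (no-attn)",
              length(x$omics_kinds), paste(x$omics_kinds, collapse = ", "),
              length(x$classes),
              if (length(x$loss_trace)) x$loss_trace[length(x$loss_trace)] else NA))
  invisible(x)
}

#' @export
print.attention_report <- function(x, ...) {
  cat(sprintf("<attention_report> %d omics, %d features\n",
              length(x$alpha), nrow(x$mean)))
  invisible(x)
}

# ---- model serialization (config JSON + parameter arrays in one file) ----

#' Save a fitted model to a JSON archive
#'
#' The archive stores the configuration, class inventory, omics order,
#' feature tables, min-max statistics and every parameter array at full
#' precision, so a reloaded model reproduces predictions exactly.
#'
#' @param model an `attention_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  ser <- list(
    config = unclass(model$config),
    classes = model$classes,
    omics_kinds = model$omics_kinds,
    features = lapply(model$features, as.list),
    ks = as.list(model$ks),
    par = rapply(model$par, function(p) {
      list(dim = dim(p) %||% length(p), data = as.numeric(p))
    }, how = "list"),
    scaling = lapply(model$scaling, function(s) if (is.null(s)) NULL else as.list(s)),
    loss_trace = model$loss_trace
  )
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Load a model saved by [save_model()]
#'
#' @param path archive path.
#' @return The restored `attention_model`.
#' @export
load_model <- function(path) {
  ser <- jsonlite::read_json(path)   # no simplification: keep nesting exact
  unser <- function(p) {
    if (is.list(p) && !is.null(p$dim) && !is.null(p$data)) {
      d <- unlist(p$dim)
      dat <- as.numeric(unlist(p$data))
      if (length(d) == 2) matrix(dat, d[1], d[2]) else dat
    } else {
      lapply(p, unser)
    }
  }
  cfgl <- lapply(ser$config, unlist)
  cfg <- do.call(attention_config, cfgl[names(cfgl) != "attn_dim"])
  cfg$attn_dim <- as.integer(cfgl$attn_dim)
  structure(
    list(config = cfg,
         classes = unlist(ser$classes),
         omics_kinds = unlist(ser$omics_kinds),
         features = lapply(ser$features, function(f) {
           tibble::tibble(feature_id = unlist(f$feature_id),
                          anchor_gene_id = unlist(f$anchor_gene_id))
         }),
         ks = stats::setNames(as.integer(unlist(ser$ks)), names(ser$ks)),
         par = unser(ser$par),
         scaling = lapply(ser$scaling, function(s) {
           if (is.null(s) || length(s) == 0) return(NULL)
           tibble::tibble(feature_id = unlist(s$feature_id),
                          min = as.numeric(unlist(s$min)),
                          max = as.numeric(unlist(s$max)))
         }),
         loss_trace = as.numeric(unlist(ser$loss_trace))),
    class = "attention_model"
  )
}
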