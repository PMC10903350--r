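# Independent brute-force oracles. These deliberately re-derive every
# quantity from first principles (plain loops, no shared code with the
# package internals) so that agreement is evidence of correctness.

# full forward pass: embedding -> encoding -> scoring -> softmax attention
# -> pooled context -> per-dimension standardisation -> fc1/ReLU -> fc2 ->
# softmax, one sample at a time
oracle_forward <- function(Xs, par, tanh_hidden = FALSE) {
  B <- nrow(Xs[[1]])
  n_omics <- length(Xs)
  ctx_all <- NULL
  alphas <- vector("list", n_omics)
  for (o in seq_len(n_omics)) {
    p <- par$omics[[o]]
    X <- Xs[[o]]
    k <- ncol(X)
    h <- nrow(p$W1)
    Cn <- matrix(0, B, h)
    A <- matrix(0, B, k)
    sig <- sqrt(p$bn_var + 1e-6)
    for (i in seq_len(B)) {
      xbar <- matrix(0, k, h)
      s <- numeric(k)
      for (j in seq_len(k)) {
        xhat <- p$E[j, ] * X[i, j]
        xbar[j, ] <- tanh(drop(p$W1 %*% xhat) + p$b1)
        s[j] <- sum(p$W3 * tanh(drop(p$W2 %*% xhat) + p$b2))
      }
      a <- exp(s - max(s))
      a <- a / sum(a)
      A[i, ] <- a
      cvec <- colSums(a * xbar)
      Cn[i, ] <- (cvec - p$bn_mu) / sig
    }
    alphas[[o]] <- A
    ctx_all <- cbind(ctx_all, Cn)
  }
  H1 <- sweep(ctx_all %*% t(par$F1), 2, par$g1, "+")
  R <- if (tanh_hidden) tanh(H1) else pmax(H1, 0)
  logits <- sweep(R %*% t(par$F2), 2, par$g2, "+")
  prob <- t(apply(logits, 1, function(z) {
    e <- exp(z - max(z))
    e / sum(e)
  }))
  list(prob = prob, alpha = alphas)
}

# random parameter set with initialised standardisation stats, so the
# inference path is fully determined
oracle_random_par <- function(ks, m, h, da, C, H) {
  omics <- lapply(ks, function(k) {
    list(E = matrix(rnorm(k * m), k, m),
         W1 = matrix(rnorm(h * m, sd = 0.3), h, m),
         b1 = rnorm(h, sd = 0.2),
         W2 = matrix(rnorm(da * m, sd = 0.3), da, m),
         b2 = rnorm(da, sd = 0.2),
         W3 = rnorm(da, sd = 0.5),
         bn_mu = rnorm(h, sd = 0.05),
         bn_var = runif(h, 0.01, 0.5))
  })
  list(omics = omics,
       F1 = matrix(rnorm(H * h * length(ks), sd = 0.3), H, h * length(ks)),
       g1 = rnorm(H, sd = 0.1),
       F2 = matrix(rnorm(C * H, sd = 0.3), C, H),
       g2 = rnorm(C, sd = 0.1))
}

# O(genes x sites) membership scan for promoter windows [tss-w, tss+w)
oracle_cpg_members <- function(ann, sites, window_half) {
  out <- list()
  for (g in seq_len(nrow(ann))) {
    lo <- ann$tss[g] - window_half
    hi <- ann$tss[g] + window_half
    mem <- integer(0)
    for (s in seq_len(nrow(sites))) {
      if (sites$chrom[s] == ann$chrom[g] &&
          sites$start[s] >= lo && sites$start[s] < hi) {
        mem <- c(mem, s)
      }
    }
    out[[ann$gene_id[g]]] <- mem
  }
  out
}

# O(genes x peaks) any-overlap sum over gene bodies [body_start, body_end)
oracle_gene_activity <- function(ann, sites, values) {
  res <- matrix(0, nrow(values), nrow(ann),
                dimnames = list(rownames(values), ann$gene_id))
  used <- logical(nrow(ann))
  for (g in seq_len(nrow(ann))) {
    for (s in seq_len(nrow(sites))) {
      if (sites$chrom[s] == ann$chrom[g] &&
          sites$start[s] < ann$body_end[g] &&
          sites$end[s] > ann$body_start[g]) {
        res[, g] <- res[, g] + values[, s]
        used[g] <- TRUE
      }
    }
  }
  res[, used, drop = FALSE]
}

# metrics re-derived from definitions: confusion counts, Pearson-style
# multiclass correlation of one-hot encodings, pairwise-comparison AUC
oracle_metrics <- function(y_true, y_pred, y_prob, classes) {
  n <- length(y_true)
  acc <- sum(y_true == y_pred) / n
  f1s <- supports <- numeric(length(classes))
  for (ci in seq_along(classes)) {
    cl <- classes[ci]
    tp <- sum(y_true == cl & y_pred == cl)
    fp <- sum(y_true != cl & y_pred == cl)
    fn <- sum(y_true == cl & y_pred != cl)
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1s[ci] <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    supports[ci] <- sum(y_true == cl)
  }
  f1w <- sum(f1s * supports) / n
  # multiclass correlation via covariances of one-hot indicator matrices
  Xoh <- sapply(classes, function(cl) as.numeric(y_true == cl))
  Yoh <- sapply(classes, function(cl) as.numeric(y_pred == cl))
  covsum <- function(A, B) {
    s <- 0
    for (kk in seq_along(classes)) s <- s + stats::cov(A[, kk], B[, kk])
    s
  }
  den <- sqrt(covsum(Xoh, Xoh) * covsum(Yoh, Yoh))
  mcc <- if (is.na(den) || den == 0) 0 else covsum(Xoh, Yoh) / den
  # macro OvR AUC by exhaustive pair comparison
  aucs <- c()
  for (ci in seq_along(classes)) {
    pos <- which(y_true == classes[ci])
    neg <- which(y_true != classes[ci])
    if (length(pos) == 0 || length(neg) == 0) next
    wins <- 0
    for (i in pos) for (j in neg) {
      d <- y_prob[i, ci] - y_prob[j, ci]
      wins <- wins + (d > 0) + 0.5 * (d == 0)
    }
    aucs <- c(aucs, wins / (length(pos) * length(neg)))
  }
  list(accuracy = acc, f1_weighted = f1w, mcc = mcc, auc = mean(aucs))
}

# classic one-way ANOVA from explicit sums of squares
oracle_anova <- function(values, groups) {
  groups <- factor(groups)
  g <- nlevels(groups)
  n <- length(values)
  gm <- tapply(values, groups, mean)
  ng <- tapply(values, groups, length)
  grand <- mean(values)
  ssb <- sum(ng * (gm - grand)^2)
  ssw <- sum((values - gm[groups])^2)
  f <- (ssb / (g - 1)) / (ssw / (n - g))
  list(f = f, p = stats::pf(f, g - 1, n - g, lower.tail = FALSE))
}
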