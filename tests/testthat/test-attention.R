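test_that("elementary attention operations obey their closed forms", {
  e <- c(1, 1)
  expect_equal(embed_feature(0, e), c(0, 0))
  expect_equal(embed_feature(3, e), c(3, 3))
  a <- runif(1); b <- runif(1); ej <- rnorm(4)
  expect_equal(embed_feature(a + b, ej),
               embed_feature(a, ej) + embed_feature(b, ej))

  W1 <- matrix(0, 3, 4); b1 <- numeric(3)
  expect_equal(encode_feature(rnorm(4), W1, b1), c(0, 0, 0))
  big <- encode_feature(rep(100, 4), matrix(1, 3, 4), numeric(3))
  expect_true(all(big > 1 - 1e-10 & big <= 1))

  W2 <- matrix(rnorm(8), 2, 4); b2 <- rnorm(2)
  expect_equal(score_feature(rnorm(4), W2, b2, c(0, 0)), 0)
  W3 <- rnorm(2)
  expect_lte(abs(score_feature(rnorm(4) * 100, W2, b2, W3)), sum(abs(W3)))

  expect_equal(normalize_attention(c(0, 0, 0)), rep(1 / 3, 3))
  expect_equal(normalize_attention(c(log(2), 0)), c(2 / 3, 1 / 3))
  s <- rnorm(6)
  expect_equal(normalize_attention(s), normalize_attention(s + 5))
  expect_error(normalize_attention(numeric(0)), "empty")

  xb <- matrix(rnorm(8), 2, 4)
  expect_equal(context_vector(c(1), xb[1, , drop = FALSE]), xb[1, ])
  expect_equal(context_vector(c(0.5, 0.5), rbind(xb[1, ], -xb[1, ])),
               rep(0, 4))
  # convex combination stays within the per-coordinate hull
  alpha <- normalize_attention(rnorm(2))
  cv <- context_vector(alpha, xb)
  expect_true(all(cv >= apply(xb, 2, min) - 1e-12 &
                  cv <= apply(xb, 2, max) + 1e-12))
})

test_that("cross-entropy matches its closed forms", {
  expect_equal(cross_entropy(c(0, 1, 0), c(0, 1, 0)), 0)
  expect_equal(cross_entropy(rep(0.25, 4) * 0 + c(1, 0, 0, 0), rep(0.25, 4)),
               log(4), tolerance = 1e-10)
  expect_equal(cross_entropy(c(1, 0, 0), c(0.7, 0.2, 0.1)), -log(0.7),
               tolerance = 1e-10)
})

test_that("the compiled forward pass matches the brute-force oracle", {
  set.seed(11)
  for (rep in 1:8) {
    ks <- sample(1:5, sample(1:3, 1), replace = TRUE)
    m <- sample(2:4, 1); h <- sample(2:4, 1); da <- sample(2:4, 1)
    C <- sample(2:3, 1); H <- sample(3:6, 1)
    par <- oracle_random_par(ks, m, h, da, C, H)
    B <- sample(1:6, 1)
    Xs <- lapply(ks, function(k) matrix(runif(B * k), B, k))
    got <- scmoa:::cpp_attn_forward(Xs, par$omics, par$F1, par$g1,
                                    par$F2, par$g2, NULL, FALSE)
    want <- oracle_forward(Xs, par)
    expect_equal(got$prob, want$prob, tolerance = 1e-5, ignore_attr = TRUE)
    for (o in seq_along(ks)) {
      expect_equal(got$alpha[[o]], want$alpha[[o]], tolerance = 1e-5,
                   ignore_attr = TRUE)
    }
  }
})

test_that("attention rows and class probabilities lie on the simplex", {
  set.seed(12)
  par <- oracle_random_par(c(4, 3), 4, 3, 3, 3, 5)
  X <- lapply(c(4, 3), function(k) matrix(runif(200 * k, -2, 2), 200, k))
  out <- scmoa:::cpp_attn_forward(X, par$omics, par$F1, par$g1,
                                  par$F2, par$g2, NULL, FALSE)
  expect_equal(rowSums(out$prob), rep(1, 200), tolerance = 1e-6)
  for (a in out$alpha) {
    expect_equal(rowSums(a), rep(1, 200), tolerance = 1e-6)
    expect_true(all(a >= 0))
  }
})

test_that("training is deterministic under a fixed seed and reports its config", {
  cfg <- attention_config()
  expect_equal(cfg$embed_dim, 128L)
  expect_equal(cfg$encoded_dim, 64L)
  expect_equal(cfg$hidden_nodes, 100L)
  expect_equal(cfg$dropout_rate, 0.2)
  expect_equal(cfg$learning_rate, 1e-3)
  expect_equal(cfg$epochs, 300L)
  expect_equal(cfg$batch_size, 128L)

  ds <- small_dataset()
  m1 <- train_attention(ds, quick_config(seed = 3))
  m2 <- train_attention(ds, quick_config(seed = 3))
  expect_identical(m1$par, m2$par)
  expect_identical(m1$loss_trace, m2$loss_trace)
  m3 <- train_attention(ds, quick_config(seed = 4))
  expect_false(identical(m1$par, m3$par))
})

test_that("a full-batch step decreases the training loss", {
  ds <- small_dataset()
  cfg <- quick_config(seed = 2, epochs = 3, batch_size = 500,
                      learning_rate = 1e-4, dropout_rate = 0)
  m <- train_attention(ds, cfg)
  expect_lt(m$loss_trace[2], m$loss_trace[1])
  expect_lt(m$loss_trace[3], m$loss_trace[2])
})

test_that("prediction is deterministic, argmax-consistent and tie-stable", {
  ds <- small_dataset()
  m <- train_attention(ds, quick_config(seed = 9, epochs = 10))
  p1 <- predict(m, ds, type = "prob")
  p2 <- predict(m, ds, type = "prob")
  expect_identical(p1, p2)
  probs <- as.matrix(p1[, m$classes])
  expect_equal(p1$.pred, m$classes[max.col(probs, ties.method = "first")])
  # feature-count mismatch is fatal and names the omics
  ds_bad <- scmoa:::subset_omics(ds, c("expression", "methylation"))
  expect_error(predict(m, ds_bad), "omics mismatch")
})

test_that("the no-attention variant drops all attention parameters", {
  ds <- small_dataset()
  cfg <- build_no_attention_variant(quick_config(seed = 5, epochs = 80))
  expect_false(cfg$use_attention)
  m <- train_attention(ds, cfg)
  expect_length(m$par$omics, 0)
  k_total <- sum(vapply(ds$omics, function(o) ncol(o$values), 0L))
  expect_equal(ncol(m$par$F1), k_total)
  lab <- unname(ds$labels[ds$cells])
  expect_gt(mean(predict(m, ds)$.pred == lab), 0.7)
})

test_that("attention extraction averages per-sample simplex rows", {
  ds <- small_dataset()
  m <- train_attention(ds, quick_config(seed = 6, epochs = 10))
  rep <- extract_attention(m, ds)
  for (a in rep$alpha) {
    expect_equal(rowSums(a), rep(1, nrow(a)), tolerance = 1e-6)
  }
  expect_true(all(rep$mean$mean_attention >= 0))
  agg <- rep$mean |> dplyr::count(omics)
  expect_equal(sort(agg$n), sort(unname(vapply(ds$omics, function(o)
    ncol(o$values), 0L))))
  # no-attention models cannot report attention
  mna <- train_attention(ds, build_no_attention_variant(quick_config(epochs = 2)))
  expect_error(extract_attention(mna, ds), "without attention")
})

test_that("models serialise to JSON and reload with identical predictions", {
  ds <- small_dataset()
  m <- train_attention(ds, quick_config(seed = 8, epochs = 10))
  path <- tempfile(fileext = ".json")
  save_model(m, path)
  m2 <- load_model(path)
  expect_equal(predict(m2, ds, type = "prob"), predict(m, ds, type = "prob"),
               tolerance = 1e-12)
  expect_equal(m2$classes, m$classes)
  expect_equal(m2$scaling$expression, m$scaling$expression, tolerance = 1e-12)
})
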