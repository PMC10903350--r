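test_that("metrics match hand-computed values on a small binary case", {
  y_true <- c("a", "a", "b", "b")
  y_pred <- c("a", "b", "b", "b")
  m <- compute_metrics(y_true, y_pred)
  expect_equal(m$accuracy, 0.75)
  expect_equal(m$f1_weighted, (2 / 3 + 0.8) / 2, tolerance = 1e-10)
  expect_equal(m$mcc, 2 / sqrt(12), tolerance = 1e-10)
})

test_that("perfect and no-information predictors hit the metric boundaries", {
  y <- rep(c("a", "b", "c"), each = 4)
  prob <- matrix(0, 12, 3, dimnames = list(NULL, c("a", "b", "c")))
  prob[cbind(seq_len(12), as.integer(factor(y)))] <- 1
  m <- compute_metrics(y, y, prob, c("a", "b", "c"))
  expect_equal(m$accuracy, 1)
  expect_equal(m$f1_weighted, 1)
  expect_equal(m$mcc, 1)
  expect_equal(m$auc, 1)

  # constant predictor on balanced binary labels
  yb <- rep(c("a", "b"), each = 5)
  m0 <- compute_metrics(yb, rep("a", 10))
  expect_equal(m0$mcc, 0)
})

test_that("metrics agree with an independent reference on random predictions", {
  set.seed(99)
  for (rep in 1:100) {
    C <- sample(2:5, 1)
    n <- sample(20:60, 1)
    classes <- paste0("k", seq_len(C))
    y_true <- sample(classes, n, replace = TRUE)
    # ensure every class appears so OvR AUC is defined everywhere
    y_true[seq_len(C)] <- classes
    prob <- matrix(rexp(n * C), n, C)
    prob <- prob / rowSums(prob)
    colnames(prob) <- classes
    y_pred <- classes[max.col(prob, ties.method = "first")]
    got <- compute_metrics(y_true, y_pred, prob, classes)
    want <- oracle_metrics(y_true, y_pred, prob, classes)
    expect_equal(got$accuracy, want$accuracy, tolerance = 1e-10)
    expect_equal(got$f1_weighted, want$f1_weighted, tolerance = 1e-10)
    expect_equal(got$mcc, want$mcc, tolerance = 1e-10)
    expect_equal(got$auc, want$auc, tolerance = 1e-10)
  }
})

test_that("classes absent from the truth are excluded from the AUC macro mean", {
  classes <- c("a", "b", "c")
  y_true <- c("a", "a", "b", "b")
  prob <- matrix(runif(12), 4, 3, dimnames = list(NULL, classes))
  prob <- prob / rowSums(prob)
  expect_message(
    m <- compute_metrics(y_true, c("a", "a", "b", "b"), prob, classes),
    "excluded")
  want <- oracle_metrics(y_true, c("a", "a", "b", "b"), prob, classes)
  expect_equal(m$auc, want$auc, tolerance = 1e-10)
})

test_that("the per-class table reports support-consistent rows", {
  y_true <- c("a", "a", "a", "b")
  y_pred <- c("a", "b", "a", "b")
  tab <- per_class_metrics(y_true, y_pred)
  expect_equal(tab$support, c(3L, 1L))
  expect_equal(tab$recall[1], 2 / 3)
  expect_equal(tab$precision[2], 0.5)
})
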