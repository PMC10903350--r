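test_that("stratified folds partition cells with balanced class counts", {
  cells <- paste0("c", 1:10)
  labels <- stats::setNames(rep("x", 10), cells)
  f <- kfold_split(cells, labels, k = 5, seed = 1)
  expect_equal(sort(table(f$fold)), sort(table(c(1:5, 1:5))))
  expect_setequal(f$cell_id, cells)

  # two classes 6 + 4 with k = 2: each fold gets 3 + 2
  cells2 <- paste0("c", 1:10)
  lab2 <- stats::setNames(rep(c("a", "b"), c(6, 4)), cells2)
  f2 <- kfold_split(cells2, lab2, k = 2, seed = 3)
  tab <- table(f2$subtype, f2$fold)
  expect_true(all(tab["a", ] == 3))
  expect_true(all(tab["b", ] == 2))

  expect_identical(kfold_split(cells2, lab2, k = 2, seed = 7),
                   kfold_split(cells2, lab2, k = 2, seed = 7))
  expect_warning(kfold_split(cells2[1:3], lab2[1:3], k = 5, seed = 1),
                 "fewer than")
})

test_that("cross-validation aggregates per-fold metrics coherently", {
  ds <- small_dataset()
  cv <- suppressMessages(run_cv(ds, quick_config(seed = 1, epochs = 25),
                                k = 3, seed = 2))
  expect_equal(nrow(cv$per_fold), 3)
  expect_true(all(cv$per_fold$accuracy >= 0 & cv$per_fold$accuracy <= 1))
  expect_true(all(cv$per_fold$mcc >= -1 & cv$per_fold$mcc <= 1))
  means <- cv$summary$mean[match(c("accuracy", "f1_weighted", "mcc", "auc"),
                                 cv$summary$metric)]
  expect_equal(means[1], mean(cv$per_fold$accuracy), tolerance = 1e-12)
  # every cell predicted exactly once
  expect_setequal(cv$predictions$cell_id, ds$cells)
  # folds partition the labelled cells
  expect_equal(sort(unique(cv$folds$fold)), 1:3)
})

test_that("train-only min-max fitting never uses held-out cells", {
  ds <- small_dataset()
  folds <- kfold_split(ds$cells, ds$labels, k = 3, seed = 2)
  cv <- suppressMessages(run_cv(ds, quick_config(seed = 1, epochs = 2),
                                k = 3, seed = 2, details = TRUE))
  for (f in 1:3) {
    tr_cells <- folds$cell_id[folds$fold != f]
    got <- cv$details[[f]]$scaling$expression
    vals <- ds$omics$expression$values[tr_cells, , drop = FALSE]
    expect_equal(unname(got$min), unname(apply(vals, 2, min)),
                 tolerance = 1e-12)
    expect_equal(unname(got$max), unname(apply(vals, 2, max)),
                 tolerance = 1e-12)
  }
})

test_that("omics ablation evaluates every subset with conventional tags", {
  ds <- small_dataset()
  tbl <- suppressMessages(run_omics_ablation(
    ds, quick_config(seed = 1, epochs = 8), k = 2, seed = 3))
  expect_equal(nrow(tbl), 7)   # 2^3 - 1 subsets
  expect_setequal(
    tbl$combination,
    c("gene", "methyl", "acc", "gene+methyl", "gene+acc", "methyl+acc",
      "gene+methyl+acc"))
  expect_true(all(is.finite(tbl$accuracy)))
  expect_true(all(c("accuracy", "f1_weighted", "mcc", "auc") %in% names(tbl)))
})

test_that("grid search selects by held-out accuracy with first-wins ties", {
  ds <- small_dataset()
  grid <- list(quick_config(seed = 1, epochs = 0),
               quick_config(seed = 1, epochs = 30))
  gs <- suppressMessages(grid_search(ds, grid, seed = 4))
  expect_equal(nrow(gs$table), 2)
  # an untrained model should not beat a trained one on separable data
  expect_equal(gs$best_index, 2)
  expect_equal(gs$best_config$epochs, 30L)

  one <- suppressMessages(grid_search(ds, grid[2], seed = 4))
  expect_equal(one$best_index, 1)
})
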