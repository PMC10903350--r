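test_that("synthetic annotations are disjoint, strand-aware and deterministic", {
  sim <- sim_config(n_genes = 20, markers_per_omics = 5)
  ann <- generate_annotation(sim)
  expect_equal(nrow(ann), 20)
  ord <- order(ann$body_start)
  expect_true(all(ann$body_end[ord][-20] <= ann$body_start[ord][-1]))
  minus <- ann[ann$strand == "-", ]
  expect_equal(minus$tss, minus$body_end)
  plus <- ann[ann$strand == "+", ]
  expect_equal(plus$tss, plus$body_start)
  expect_identical(generate_annotation(sim), generate_annotation(sim))
})

test_that("generated data respect type invariants and reproducibility", {
  sim <- small_sim(11)
  raw <- generate_multiomics(sim)
  expect_true(all(raw$expression$values >= 0))
  obs <- raw$methylation$values[raw$methylation$mask]
  expect_true(all(obs >= 0 & obs <= 1))
  expect_true(all(raw$accessibility$values >= 0))
  expect_equal(mean(!raw$methylation$mask), sim$meth_missing_rate,
               tolerance = 0.05)
  # class counts exactly reproducible under the seed
  raw2 <- generate_multiomics(sim)
  expect_identical(raw$labels, raw2$labels)
  expect_identical(raw$expression$values, raw2$expression$values)
  # disjoint marker genes across omics
  sets <- split(raw$truth$gene_id, raw$truth$omics)
  expect_equal(length(Reduce(intersect, sets)), 0)
  expect_error(sim_config(n_genes = 10, markers_per_omics = 5),
               "disjoint markers")
})

test_that("every planted methylation gene yields at least one CpG cluster", {
  raw <- generate_multiomics(small_sim(2))
  clusters <- build_cpg_clusters(raw$methylation, raw$annotation)
  planted <- raw$truth$gene_id[raw$truth$omics == "methylation"]
  expect_true(all(planted %in% clusters$gene_id))
})

test_that("planted effects are recoverable by per-feature ANOVA at effect 2", {
  # power check: fraction of planted (preprocessed) features with p < 0.01
  hits <- 0; total <- 0
  for (seed in 1:5) {
    sim <- sim_config(n_cells = 200, n_genes = 40, n_subtypes = 3,
                      markers_per_omics = 5, effect_size = 2, seed = seed)
    raw <- generate_multiomics(sim)
    mats <- suppressMessages(preprocess_multiomics(
      raw$expression, raw$methylation, raw$accessibility, raw$annotation))
    labs <- stats::setNames(raw$labels$subtype, raw$labels$cell_id)
    for (kind in names(mats)) {
      m <- mats[[kind]]
      planted <- raw$truth$gene_id[raw$truth$omics == kind]
      idx <- which(m$features$anchor_gene_id %in% planted)
      for (j in idx) {
        p <- one_way_anova(m$values[, j], labs[m$cells])$p_value
        total <- total + 1
        hits <- hits + (is.finite(p) && p < 0.01)
      }
    }
  }
  expect_gte(hits / total, 0.9)
})

test_that("with zero effect size planted features are null-calibrated", {
  sim <- sim_config(n_cells = 150, n_genes = 70, n_subtypes = 3,
                    markers_per_omics = 10, effect_size = 0, seed = 31)
  raw <- generate_multiomics(sim)
  mats <- suppressMessages(preprocess_multiomics(
    raw$expression, raw$methylation, raw$accessibility, raw$annotation))
  labs <- stats::setNames(raw$labels$subtype, raw$labels$cell_id)
  pvals <- unlist(lapply(mats, function(m) {
    apply(m$values[, seq_len(min(70, ncol(m$values))), drop = FALSE], 2,
          function(v) one_way_anova(v, labs[m$cells])$p_value)
  }))
  pvals <- pvals[is.finite(pvals)]
  expect_gte(length(pvals), 200)
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("the easy fixture is separable and aligned across omics", {
  ds <- acceptance_fixture()
  expect_length(ds$omics, 3)
  for (o in ds$omics) expect_identical(o$cells, ds$cells)
  expect_identical(suppressMessages(easy_fixture(1))$omics$expression$values,
                   ds$omics$expression$values)
  # a multinomial (lasso) oracle fit on half the cells generalises
  sc <- scmoa:::apply_scaling(ds, scmoa:::fit_scaling(ds))
  X <- do.call(cbind, lapply(sc, function(o) o$values))
  lab <- unname(ds$labels[ds$cells])
  set.seed(1)
  tr <- sample(nrow(X), 300)
  fit <- glmnet::glmnet(X[tr, ], factor(lab[tr]), family = "multinomial",
                        lambda = 0.01)
  acc <- mean(predict(fit, X[-tr, ], type = "class") == lab[-tr])
  expect_gte(acc, 0.95)
})
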