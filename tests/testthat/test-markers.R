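fake_report <- function(means_by_omics) {
  mean_tbl <- purrr::map_dfr(names(means_by_omics), function(kind) {
    m <- means_by_omics[[kind]]
    tibble::tibble(omics = kind, feature_id = names(m),
                   anchor_gene_id = sub("_.*$", "", names(m)),
                   mean_attention = unname(m))
  })
  structure(list(alpha = list(), mean = mean_tbl), class = "attention_report")
}

test_that("marker ranking honours top-k, ties and permutation invariance", {
  rep1 <- fake_report(list(expression = c(gA_x = 0.9, gB_x = 0.1)))
  mk <- rank_markers(rep1, top_k = 1)
  expect_equal(mk$feature_id, "gA_x")
  expect_equal(mk$rank, 1L)

  tied <- fake_report(list(expression = c(gB_x = 0.5, gA_x = 0.5, gC_x = 0.1)))
  mk2 <- rank_markers(tied, top_k = 2)
  expect_equal(mk2$feature_id, c("gA_x", "gB_x"))  # lexicographic tie-break

  shuffled <- fake_report(list(expression = c(gC_x = 0.1, gA_x = 0.5, gB_x = 0.5)))
  expect_equal(rank_markers(shuffled, top_k = 2)$feature_id,
               mk2$feature_id)

  expect_warning(big <- rank_markers(rep1, top_k = 10), "exceeds")
  expect_equal(nrow(big), 2)
  expect_equal(big$rank, 1:2)
})

test_that("marker overlaps follow set algebra on anchor genes", {
  mk <- rank_markers(fake_report(list(
    expression = c(gA_x = 0.9, gB_x = 0.8),
    methylation = c(gB_m = 0.9, gC_m = 0.8),
    accessibility = c(gB_a = 0.9, gD_a = 0.8))), top_k = 2)
  ov <- overlap_markers(mk)
  three <- ov$genes[[which(ov$n_omics == 3)]]
  expect_equal(three, "gB")
  pairwise <- ov[ov$n_omics == 2, ]
  expect_true(all(lengths(ov$genes[ov$n_omics == 3]) <= pairwise$n_genes))

  disjoint <- rank_markers(fake_report(list(
    expression = c(gA_x = 1), methylation = c(gB_m = 1))), top_k = 1)
  ov2 <- overlap_markers(disjoint)
  expect_equal(ov2$n_genes[ov2$n_omics == 2], 0)

  identical_lists <- rank_markers(fake_report(list(
    expression = c(gA_x = 1, gB_x = 0.5),
    methylation = c(gA_m = 1, gB_m = 0.5))), top_k = 2)
  ov3 <- overlap_markers(identical_lists)
  expect_setequal(ov3$genes[[which(ov3$n_omics == 2)]], c("gA", "gB"))
})

test_that("one-way ANOVA reproduces hand-computed F and degenerate cases", {
  out <- one_way_anova(c(1, 2, 3, 4), rep(c("A", "B"), each = 2))
  expect_equal(out$f_statistic, 8, tolerance = 1e-10)
  expect_equal(out$p_value, stats::pf(8, 1, 2, lower.tail = FALSE),
               tolerance = 1e-10)
  expect_equal(out$p_value, 0.1056, tolerance = 1e-3)

  same <- one_way_anova(c(1, 2, 3, 1, 2, 3), rep(c("A", "B"), each = 3))
  expect_equal(same$f_statistic, 0)
  expect_equal(same$p_value, 1)

  degenerate <- one_way_anova(c(1, 1, 1, 1), rep(c("A", "B"), each = 2))
  expect_true(is.nan(degenerate$f_statistic))
  expect_match(degenerate$reason, "zero within-group")
  onegrp <- one_way_anova(1:4, rep("A", 4))
  expect_true(is.nan(onegrp$f_statistic))
})

test_that("one-way ANOVA matches the sums-of-squares oracle on random data", {
  set.seed(23)
  for (rep in 1:50) {
    g <- sample(2:5, 1)
    n_per <- sample(3:10, g, replace = TRUE)
    groups <- rep(paste0("grp", seq_len(g)), n_per)
    values <- rnorm(length(groups)) + rep(rnorm(g), n_per)
    got <- one_way_anova(values, groups)
    want <- oracle_anova(values, groups)
    expect_equal(got$f_statistic, want$f, tolerance = 1e-8)
    expect_equal(got$p_value, want$p, tolerance = 1e-8)
  }
})

test_that("the marker report composes ranking, overlap and significance", {
  ds <- small_dataset()
  m <- train_attention(ds, quick_config(seed = 2, epochs = 20))
  rep <- marker_report(ds, m, top_k = 5)
  expect_equal(nrow(rep$markers), 15)  # 3 omics x top 5
  expect_true(all(c("f_statistic", "p_value", "significant") %in%
                  names(rep$markers)))
  flagged <- rep$markers[rep$markers$significant, ]
  expect_true(all(flagged$p_value < 0.01))
  expect_s3_class(rep$overlap, "tbl_df")
})
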