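make_expr <- function(vals, cells = NULL) {
  vals <- as.matrix(vals)
  if (is.null(cells)) cells <- paste0("c", seq_len(nrow(vals)))
  rownames(vals) <- cells
  omics_matrix(vals, tibble::tibble(feature_id = paste0("g", seq_len(ncol(vals))),
                                    anchor_gene_id = paste0("g", seq_len(ncol(vals)))),
               "expression")
}

test_that("all-zero genes are removed and empty matrices are fatal", {
  expr <- make_expr(cbind(c(0, 0), c(1, 0)))
  out <- filter_zero_genes(expr)
  expect_equal(out$features$feature_id, "g2")
  expect_equal(out$cells, expr$cells)

  dense <- make_expr(cbind(c(1, 2), c(3, 4)))
  expect_equal(filter_zero_genes(dense)$values, dense$values)

  one <- make_expr(matrix(0, 1, 1))
  expect_error(filter_zero_genes(one), "empty expression matrix")
})

test_that("library-size normalisation matches hand arithmetic", {
  # two cells with libraries 100 and 200; target = median = 150
  vals <- rbind(c(10, 90), c(40, 160))
  expr <- make_expr(vals)
  out <- normalize_expression(expr)
  expect_equal(unname(out$values[1, 1]), log1p(10 * 150 / 100), tolerance = 1e-12)
  expect_equal(unname(out$values[1, 1]), 2.7726, tolerance = 1e-4)

  # equal libraries: scale factor 1
  eq <- make_expr(rbind(c(5, 5), c(3, 7)))
  expect_equal(unname(normalize_expression(eq)$values[2, 1]), log1p(3))
  # zeros stay zero
  z <- make_expr(rbind(c(0, 10), c(5, 5)))
  expect_equal(unname(normalize_expression(z)$values[1, 1]), 0)
  # zero library is fatal
  bad <- make_expr(rbind(c(0, 0), c(1, 1)))
  expect_error(normalize_expression(filter_zero_genes(make_expr(rbind(c(0, 1), c(0, 1))))),
               NA)  # zero gene columns fine as long as libraries > 0
  expect_error(normalize_expression(bad), "library size 0")
})

test_that("CpG clusters use half-open TSS windows and match a brute-force scan", {
  ann <- gene_annotation("gA", "chr1", "+", 10000, 14000)
  sites <- tibble::tibble(chrom = "chr1",
                          start = c(8500L, 11500L, 13000L, 8000L, 12000L),
                          end = c(8501L, 11501L, 13001L, 8001L, 12001L))
  sm <- site_matrix(matrix(0.5, 2, 5), sites, "methylation")
  cl <- build_cpg_clusters(sm, ann)
  expect_equal(nrow(cl), 1)
  expect_setequal(cl$member_sites[[1]], c(1L, 2L, 4L))  # 8500,11500,8000 in [8000,12000)

  # boundary: tss - 2000 included, tss + 2000 excluded
  expect_true(4L %in% cl$member_sites[[1]])   # at exactly tss - 2000
  expect_false(5L %in% cl$member_sites[[1]])  # at exactly tss + 2000

  set.seed(42)
  for (rep in 1:10) {
    ngene <- sample(2:8, 1); nsite <- sample(5:60, 1)
    bs <- sort(sample.int(50000, ngene)) * 3
    ann_r <- gene_annotation(paste0("g", seq_len(ngene)), "chr1",
                             sample(c("+", "-"), ngene, TRUE),
                             body_start = bs, body_end = bs + 2000)
    pos <- sample.int(200000, nsite)
    sm_r <- site_matrix(matrix(runif(2 * nsite), 2, nsite),
                        tibble::tibble(chrom = "chr1", start = pos, end = pos + 1L),
                        "methylation")
    got <- build_cpg_clusters(sm_r, ann_r)
    want <- oracle_cpg_members(ann_r, sm_r$sites, 2000)
    want <- want[vapply(want, length, 0L) > 0]
    expect_equal(nrow(got), length(want))
    for (i in seq_len(nrow(got))) {
      expect_setequal(got$member_sites[[i]], want[[got$gene_id[i]]])
    }
  }
})

test_that("cluster averaging imputes missing cells and keeps betas in range", {
  ann <- gene_annotation("gA", "chr1", "+", 10000, 14000)
  sites <- tibble::tibble(chrom = "chr1", start = c(9000L, 11000L),
                          end = c(9001L, 11001L))
  vals <- rbind(c(0.2, 0.8), c(NA, NA))
  rownames(vals) <- c("c1", "c2")
  sm <- site_matrix(vals, sites, "methylation")
  cl <- build_cpg_clusters(sm, ann)
  out <- cluster_methylation(sm, cl)
  expect_equal(unname(out$values["c1", 1]), 0.5)   # mean of member betas
  expect_equal(unname(out$values["c2", 1]), 0.5)   # imputed with observed mean
  expect_false(anyNA(out$values))
  expect_true(all(out$values >= 0 & out$values <= 1))

  # cluster unobserved everywhere is fatal when it is the only one
  all_na <- site_matrix(matrix(NA_real_, 2, 2,
                               dimnames = list(c("c1", "c2"), NULL)),
                        sites, "methylation")
  expect_error(cluster_methylation(all_na, build_cpg_clusters(all_na, ann)),
               "unobserved")
})

test_that("gene activity sums any-overlap peaks and matches brute force", {
  ann <- gene_annotation("gA", "chr1", "+", 1000, 2000)
  sites <- tibble::tibble(chrom = "chr1",
                          start = c(1500L, 1800L, 2500L),
                          end = c(1600L, 1900L, 2600L))
  vals <- matrix(c(3, 2, 7), 1, 3, dimnames = list("c1", NULL))
  acc <- site_matrix(vals, sites, "accessibility")
  out <- aggregate_accessibility(acc, ann)
  expect_equal(unname(out$values["c1", 1]), 5)   # 3 + 2; peak at 2500 outside

  set.seed(7)
  for (rep in 1:10) {
    ngene <- sample(2:6, 1); npeak <- sample(5:40, 1)
    starts <- sort(sample.int(30000, ngene)) * 2
    ann_r <- gene_annotation(paste0("g", seq_len(ngene)), "chr1",
                             rep("+", ngene), starts, starts + 1500)
    ps <- sample.int(70000, npeak)
    acc_r <- site_matrix(matrix(rpois(3 * npeak, 2), 3, npeak),
                         tibble::tibble(chrom = "chr1", start = ps,
                                        end = ps + sample(50:400, npeak, TRUE)),
                         "accessibility")
    want <- oracle_gene_activity(ann_r, acc_r$sites, acc_r$values)
    if (ncol(want) == 0) {
      expect_error(aggregate_accessibility(acc_r, ann_r), "no peak overlaps")
    } else {
      got <- aggregate_accessibility(acc_r, ann_r)
      expect_equal(unname(got$values),
                   unname(want[, got$features$anchor_gene_id, drop = FALSE]))
    }
  }
})

test_that("min-max scaling covers closed form, constants, and clipping", {
  om <- make_expr(matrix(c(2, 4, 6, 5, 5, 5), 3, 2))
  out <- minmax_normalize(om)
  expect_equal(unname(out$matrix$values[, 1]), c(0, 0.5, 1))
  expect_equal(unname(out$matrix$values[, 2]), c(0, 0, 0))  # constant -> 0

  test_m <- make_expr(matrix(c(8, 1, 5, 5), 2, 2))
  scaled <- minmax_normalize(test_m, fit_stats = out$fit_stats)
  expect_equal(unname(scaled$matrix$values[, 1]), c(1, 0))  # 8 clipped to 1
  expect_true(all(scaled$matrix$values >= 0 & scaled$matrix$values <= 1))
})

test_that("the preprocessing chain is deterministic", {
  raw <- generate_multiomics(small_sim(3))
  run <- function() {
    mats <- suppressMessages(preprocess_multiomics(
      raw$expression, raw$methylation, raw$accessibility, raw$annotation))
    lapply(mats, function(m) m$values)
  }
  expect_identical(run(), run())
})
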