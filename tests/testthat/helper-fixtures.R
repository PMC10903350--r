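# Shared fixtures. Small instances keep unit tests fast; the expensive
# fitted objects used by the end-to-end checks are computed once per test
# run and cached in this environment.

.scmoa_cache <- new.env(parent = emptyenv())

cache_get <- function(key, compute) {
  if (!exists(key, envir = .scmoa_cache)) {
    assign(key, compute(), envir = .scmoa_cache)
  }
  get(key, envir = .scmoa_cache)
}

# a small but non-trivial simulated multi-omics dataset (fast to train on)
small_sim <- function(seed = 5) {
  sim_config(n_cells = 150, n_genes = 30, n_subtypes = 3,
             markers_per_omics = 4, effect_size = 3, cpgs_per_promoter = 3,
             peaks_per_gene = 2, seed = seed)
}

small_dataset <- function(seed = 5) {
  raw <- generate_multiomics(small_sim(seed))
  mats <- suppressMessages(preprocess_multiomics(
    expr = raw$expression, meth = raw$methylation, acc = raw$accessibility,
    ann = raw$annotation))
  ds <- suppressMessages(intersect_by_gene(mats))
  ds <- align_labels(ds, raw$labels)
  attr(ds, "truth") <- raw$truth
  ds
}

# quick training configuration for machinery tests (not a study condition)
quick_config <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(embed_dim = 16, encoded_dim = 8, attn_dim = 8, hidden_nodes = 16,
         epochs = 40, batch_size = 64, seed = seed),
    list(...))
  do.call(attention_config, args)
}

# the canonical fixture and the expensive fitted objects, shared across
# acceptance checks
acceptance_fixture <- function() {
  cache_get("fixture", function() suppressMessages(easy_fixture(1)))
}

acceptance_models <- function(seeds = 1:5) {
  lapply(seeds, function(s) {
    cache_get(paste0("model_seed", s), function() {
      train_attention(acceptance_fixture(), attention_config(seed = s))
    })
  })
}

acceptance_cv <- function(kind = "all") {
  key <- paste0("cv_", kind)
  cache_get(key, function() {
    ds <- acceptance_fixture()
    if (kind != "all") ds <- scmoa:::subset_omics(ds, kind)
    suppressMessages(run_cv(ds, attention_config(seed = 100), k = 5, seed = 100))
  })
}
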