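#' Run the end-to-end pipeline
#'
#' Chains the workflow stages `simulate` -> `preprocess` -> `select` ->
#' `train` / `predict` / `cv` / `ablate` / `gridsearch` / `markers` over
#' files in an output directory, writing a manifest (config echo, seed,
#' package version, input hashes) after each stage so a run can be
#' reproduced bit for bit.
#'
#' @param config a named list (or path to a YAML file) with optional
#'   sections `seed`, `out_dir`, `sim`, `preprocess`, `model`, `cv`
#'   (`k`, `minmax_fit`), `markers` (`top_k`, `alpha_threshold`),
#'   `grid` (list of model overrides), `ablation` (`combos`). Unknown
#'   sections are rejected.
#' @param stages ordered subset of
#'   `c("simulate", "preprocess", "select", "train", "predict", "cv",
#'   "ablate", "gridsearch", "markers")`.
#' @return Invisibly, a named list of artifact paths per stage.
#' @export
run_pipeline <- function(config = list(), stages = c("simulate", "preprocess",
                                                     "select", "train", "cv",
                                                     "markers")) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  allowed <- c("seed", "out_dir", "sim", "preprocess", "model", "cv",
               "markers", "grid", "ablation", "verbosity")
  unknown <- setdiff(names(config), allowed)
  if (length(unknown) > 0) {
    stop("run_pipeline: unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  known_stages <- c("simulate", "preprocess", "select", "train", "predict",
                    "cv", "ablate", "gridsearch", "markers")
  stages <- match.arg(stages, known_stages, several.ok = TRUE)
  out_dir <- config$out_dir %||% "."
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed %||% 1L)
  pp_cfg <- do.call(preprocess_config, config$preprocess %||% list())
  model_cfg <- do.call(attention_config,
                       utils::modifyList(list(seed = seed),
                                         config$model %||% list()))
  pth <- function(...) file.path(out_dir, ...)
  artifacts <- list()

  need <- function(stage, files) {
    missing <- files[!file.exists(files)]
    if (length(missing) > 0) {
      stop("run_pipeline: stage '", stage, "' is missing input(s): ",
           paste(missing, collapse = ", "))
    }
    files
  }
  manifest_path <- pth("manifest.json")
  log_stage <- function(stage, inputs, outputs) {
    man <- if (file.exists(manifest_path)) {
      jsonlite::read_json(manifest_path)
    } else list()
    man[[stage]] <- list(
      stage = stage, seed = seed,
      package_version = as.character(utils::packageVersion("scmoa")),
      config = config,
      input_md5 = as.list(tools::md5sum(inputs)),
      outputs = outputs,
      time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
    jsonlite::write_json(man, manifest_path, auto_unbox = TRUE, null = "null")
  }

  raw_files <- c(annotation = pth("annotation.bed"),
                 expression = pth("expression_counts.tsv"),
                 methylation = pth("methylation_sites.tsv"),
                 accessibility = pth("accessibility_peaks.tsv"),
                 labels = pth("labels.tsv"))
  gene_files <- c(expression = pth("expression.tsv"),
                  methylation = pth("methylation.tsv"),
                  accessibility = pth("accessibility.tsv"))
  sel_files <- c(expression = pth("selected_expression.tsv"),
                 methylation = pth("selected_methylation.tsv"),
                 accessibility = pth("selected_accessibility.tsv"))

  load_selected <- function(stage) {
    need(stage, c(sel_files, raw_files[["labels"]]))
    mats <- lapply(names(sel_files), function(kind) {
      read_matrix(sel_files[[kind]], omics_kind = kind)
    })
    align_labels(multi_omics_dataset(mats), read_labels(raw_files[["labels"]]))
  }

  for (stage in stages) {
    if (stage == "simulate") {
      sim <- do.call(sim_config,
                     utils::modifyList(list(seed = seed), config$sim %||% list()))
      raw <- generate_multiomics(sim)
      write_annotation_bed(raw$annotation, raw_files[["annotation"]])
      write_matrix(raw$expression, raw_files[["expression"]])
      write_matrix(raw$methylation, raw_files[["methylation"]])
      write_matrix(raw$accessibility, raw_files[["accessibility"]])
      utils::write.table(raw$labels, raw_files[["labels"]], sep = "\t",
                         quote = FALSE, row.names = FALSE)
      utils::write.table(raw$truth, pth("truth.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      artifacts$simulate <- unname(c(raw_files, pth("truth.tsv")))
      log_stage("simulate", character(), artifacts$simulate)
    } else if (stage == "preprocess") {
      need(stage, raw_files)
      ann <- read_annotation(raw_files[["annotation"]], format = "bed")
      expr <- read_matrix(raw_files[["expression"]], omics_kind = "expression")
      meth <- read_matrix(raw_files[["methylation"]], omics_kind = "methylation")
      acc <- read_matrix(raw_files[["accessibility"]],
                         omics_kind = "accessibility")
      mats <- preprocess_multiomics(expr, meth, acc, ann, pp_cfg)
      for (kind in names(mats)) write_matrix(mats[[kind]], gene_files[[kind]])
      artifacts$preprocess <- unname(gene_files)
      log_stage("preprocess", unname(raw_files), artifacts$preprocess)
    } else if (stage == "select") {
      need(stage, gene_files)
      mats <- lapply(names(gene_files), function(kind) {
        read_matrix(gene_files[[kind]], omics_kind = kind)
      })
      dataset <- intersect_by_gene(mats)
      for (kind in names(dataset$omics)) {
        write_matrix(dataset$omics[[kind]], sel_files[[kind]])
      }
      artifacts$select <- unname(sel_files)
      log_stage("select", unname(gene_files), artifacts$select)
    } else if (stage == "train") {
      dataset <- load_selected(stage)
      model <- train_attention(dataset, model_cfg)
      save_model(model, pth("model.json"))
      artifacts$train <- pth("model.json")
      log_stage("train", unname(sel_files), artifacts$train)
    } else if (stage == "predict") {
      need(stage, c(pth("model.json"), sel_files))
      model <- load_model(pth("model.json"))
      dataset <- load_selected(stage)
      preds <- predict(model, dataset, type = "prob")
      utils::write.table(preds, pth("predictions.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      artifacts$predict <- pth("predictions.tsv")
      log_stage("predict", pth("model.json"), artifacts$predict)
    } else if (stage == "cv") {
      dataset <- load_selected(stage)
      cv_args <- config$cv %||% list()
      cv <- run_cv(dataset, model_cfg, k = cv_args$k %||% 5, seed = seed,
                   minmax_fit = cv_args$minmax_fit %||% pp_cfg$minmax_fit)
      means <- stats::setNames(as.list(cv$summary$mean), cv$summary$metric)
      write_metrics(means, pth("metrics.json"))
      utils::write.table(cv$per_fold, pth("per_fold.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      artifacts$cv <- c(pth("metrics.json"), pth("per_fold.tsv"))
      log_stage("cv", unname(sel_files), artifacts$cv)
    } else if (stage == "ablate") {
      dataset <- load_selected(stage)
      abl_args <- config$ablation %||% list()
      tbl <- run_omics_ablation(dataset, model_cfg,
                                combos = abl_args$combos %||% "all",
                                k = (config$cv %||% list())$k %||% 5,
                                seed = seed)
      utils::write.table(tbl[, setdiff(names(tbl), "cv")], pth("ablation.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      artifacts$ablate <- pth("ablation.tsv")
      log_stage("ablate", unname(sel_files), artifacts$ablate)
    } else if (stage == "gridsearch") {
      dataset <- load_selected(stage)
      grid <- lapply(config$grid %||% list(list()), function(over) {
        do.call(attention_config,
                utils::modifyList(list(seed = seed), over))
      })
      gs <- grid_search(dataset, grid, seed = seed)
      utils::write.table(gs$table, pth("gridsearch.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      artifacts$gridsearch <- pth("gridsearch.tsv")
      log_stage("gridsearch", unname(sel_files), artifacts$gridsearch)
    } else if (stage == "markers") {
      need(stage, pth("model.json"))
      model <- load_model(pth("model.json"))
      dataset <- load_selected(stage)
      mk_args <- config$markers %||% list()
      rep <- marker_report(dataset, model,
                           top_k = mk_args$top_k %||% 30,
                           alpha_threshold = mk_args$alpha_threshold %||% 0.01)
      write_marker_table(rep$markers, pth("markers.tsv"))
      ov <- rep$overlap
      jsonlite::write_json(
        stats::setNames(ov$genes, ov$omics_set), pth("overlap.json"),
        null = "list")
      artifacts$markers <- c(pth("markers.tsv"), pth("overlap.json"))
      log_stage("markers", pth("model.json"), artifacts$markers)
    }
  }
  invisible(artifacts)
}
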