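#' Default pipeline configuration
#'
#' @param ... overrides of the defaults (see Details).
#' @details Fields: `task` ("attention"/"incident"), `modalities`,
#'   `methods` (named list per modality), `classifier` ("elm"/"lstm"),
#'   `n_components` (30 for feature classification, 60 per step for the
#'   LSTM), `n_hidden` (ELM width, 170), `fit_scope` ("train_only" or the
#'   across-subject "global"), `embedder` ("stub"), `embedder_seed`,
#'   `windows_per_second` (LSTM path), `bin_count`, `generator` (overrides
#'   for [generator_config()]), `seed`, `out_dir`.
#' @return named list of configuration values.
#' @export
pipeline_config <- function(...) {
  cfg <- list(task = "attention", modalities = "eeg", methods = list(),
              classifier = "elm", n_components = 30, n_hidden = 170,
              fit_scope = "train_only", embedder = "stub", embedder_seed = 1,
              windows_per_second = 30, bin_count = 16,
              generator = list(), seed = 1, out_dir = NULL)
  over <- list(...)
  if (length(over) == 1 && is.null(names(over)) && is.list(over[[1]])) over <- over[[1]]
  utils::modifyList(cfg, over)
}

#' Run the full awareness-classification pipeline
#'
#' Chains the stages end-to-end: synthesize (or reuse) a dataset, extract
#' the configured feature blocks, classify under leave-one-subject-out
#' cross-validation, and summarize accuracy and AUC per subject. Requesting
#' PPG or GSR features for the 2-s incident task is refused: those
#' modalities lack the temporal resolution. Identical configuration and seed
#' give byte-identical feature tables and metrics.
#'
#' @param config a list from [pipeline_config()] (or overrides for it).
#' @param dataset optionally, a pre-built `aware_dataset` to reuse.
#' @return list with `config`, `dataset`, `features` (ELM path) or
#'   `sequences` (LSTM path), `cv` (a `cv_result`) and `summary`.
#' @export
run_pipeline <- function(config = pipeline_config(), dataset = NULL) {
  cfg <- pipeline_config(config)
  check_task_modalities(cfg$task, cfg$modalities)
  gen_over <- utils::modifyList(list(seed = cfg$seed), cfg$generator)
  if (is.null(dataset)) dataset <- gen_dataset(do.call(generator_config, gen_over))
  emb <- image_embedder(cfg$embedder, seed = cfg$embedder_seed)
  out <- list(config = cfg, dataset = dataset)
  if (cfg$classifier == "elm") {
    feats <- extract_features(dataset, task = cfg$task,
                              modalities = cfg$modalities, methods = cfg$methods,
                              embedder = emb, bin_count = cfg$bin_count)
    X <- as.matrix(feats[, -(1:3), drop = FALSE])
    cv <- loso_cv(X, feats$label, feats$subject,
                  n_components = cfg$n_components, n_hidden = cfg$n_hidden,
                  seed = cfg$seed, fit_scope = cfg$fit_scope)
    out$features <- feats
  } else if (cfg$classifier == "lstm") {
    sq <- extract_sequences(dataset, task = cfg$task,
                            windows_per_second = cfg$windows_per_second,
                            embedder = emb)
    spec <- lstm_spec(input_dim = cfg$n_components, seed = cfg$seed)
    cv <- loso_cv_sequences(sq$sequences, sq$labels, sq$subjects,
                            n_components = cfg$n_components, spec = spec,
                            fit_scope = cfg$fit_scope)
    out$sequences <- sq
  } else stopf("unknown classifier '%s'", cfg$classifier)
  out$cv <- cv
  out$summary <- list(task = cfg$task,
                      modalities = paste(cfg$modalities, collapse = "+"),
                      classifier = cfg$classifier,
                      n_folds = nrow(cv$per_subject),
                      mean_accuracy = cv$mean_accuracy,
                      sd_accuracy = cv$sd_accuracy,
                      mean_auc = cv$mean_auc, sd_auc = cv$sd_auc,
                      seed = cfg$seed)
  if (!is.null(cfg$out_dir)) write_pipeline_outputs(out, cfg$out_dir)
  out
}

write_pipeline_outputs <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(result$features)) {
    utils::write.csv(result$features, file.path(dir, "features.csv"),
                     row.names = FALSE)
  }
  metrics <- list(summary = result$summary,
                  per_subject = result$cv$per_subject,
                  fold_sizes = result$cv$fold_sizes)
  jsonlite::write_json(metrics, file.path(dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  cfg <- result$config
  cfg$out_dir <- NULL
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
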