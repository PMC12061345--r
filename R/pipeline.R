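#' @title End-to-end pipeline runner
#'
#' @description
#' One call wires the stages together: generate a synthetic corpus, split it
#' at the visit level, extract the 270-feature matrices, train all three
#' model kinds, and evaluate each on the held-out test set. Every artifact
#' is written to a run directory together with a manifest recording seeds,
#' catalog version and file digests, so a rerun with the same configuration
#' is digest-identical.
#'
#' @name cli-pipeline
NULL

#' Pipeline run configuration
#'
#' @param synthetic a [synthetic_config()]
#' @param train_fraction training share of the corpus (default 0.8)
#' @param catalog_path feature catalog TSV (default: shipped catalog)
#' @param model_configs named list of [model_config()]s, one per kind
#' @param seed master seed; stage seeds derive from it
#' @return a `run_config`
#' @export
run_config <- function(synthetic = synthetic_config(n_visits = 500),
                       train_fraction = 0.8,
                       catalog_path = default_catalog_path(),
                       model_configs = NULL, seed = 1L) {
  seed <- as.integer(seed)
  if (is.null(model_configs)) {
    model_configs <- list(
      lr = model_config("lr", seed = seed),
      knn = model_config("knn", seed = seed),
      cnn = model_config("cnn", seed = seed, epochs = 40L))
  }
  structure(list(synthetic = synthetic, train_fraction = train_fraction,
                 catalog_path = catalog_path, model_configs = model_configs,
                 seed = seed),
            class = "run_config")
}

#' Run the full pipeline into a directory
#'
#' @param config a [run_config()]
#' @param out_dir run directory (created if absent)
#' @return named list of `evaluation_report`s (one per model kind),
#'   invisibly; artifacts and `manifest.json` under `out_dir`
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  step <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  gen <- step("generate", generate_corpus(config$synthetic))
  write_corpus(gen$visits, file.path(out_dir, "corpus.jsonl"))
  utils::write.csv(gen$truth, file.path(out_dir, "truth.csv"),
                   row.names = FALSE)

  split <- step("split", split_corpus(gen$visits, config$train_fraction,
                                      seed = config$seed, stratified = TRUE))
  catalog <- step("catalog", load_catalog(config$catalog_path))
  feats <- step("extract", list(
    train = extract_feature_matrix(split$train, catalog),
    test = extract_feature_matrix(split$test, catalog)))
  y <- list(train = corpus_labels(split$train),
            test = corpus_labels(split$test))
  write_feature_csv(feats$train, file.path(out_dir, "features_train.csv"),
                    y$train)
  write_feature_csv(feats$test, file.path(out_dir, "features_test.csv"),
                    y$test)

  reports <- list()
  for (kind in names(config$model_configs)) {
    model <- step(paste0("train_", kind),
                  train_model(feats$train, y$train,
                              config$model_configs[[kind]],
                              catalog_version = catalog_version(catalog)))
    save_model(model, file.path(out_dir, sprintf("model_%s.json", kind)))
    reports[[kind]] <- step(paste0("evaluate_", kind),
                            evaluate_model(model, split$test, catalog,
                                           features = feats$test))
    write_report(reports[[kind]],
                 file.path(out_dir, sprintf("report_%s.json", kind)),
                 file.path(out_dir, sprintf("roc_%s.csv", kind)))
  }

  files <- sort(setdiff(list.files(out_dir), "manifest.json"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("hemobleed")),
    seed = config$seed,
    catalog_version = catalog_version(catalog),
    n_visits = config$synthetic$n_visits,
    digests = as.list(tools::md5sum(file.path(out_dir, files))))
  names(manifest$digests) <- files
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(reports)
}
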