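#' Configuration of the end-to-end analysis pipeline
#'
#' One nested list drives the whole analysis: generate (or load) a dataset,
#' preprocess (canonicalize, case-wise delete, encode, split), fit both
#' surrogates, compare them by k-fold cross-validation, rank feature
#' importance, run the parametric sweeps and benchmark, and produce the
#' release-kinetics table. Exactly one of `generator` / `dataset_path` is
#' active. Defaults reproduce the reference synthetic experiment (99
#' records, seed 42).
#'
#' @param generator A [generator_config()], or `NULL` when loading from file.
#' @param dataset_path CSV path in the record schema, or `NULL`.
#' @param required_fields Fields required complete for modelling.
#' @param encoding `"onehot"` or `"compact"`.
#' @param test_fraction Held-out fraction for the stratified split.
#' @param split_seed Seed of the stratified split.
#' @param network An [ann_config()].
#' @param cv_k,cv_seed Cross-validation folds and fold-assignment seed.
#' @param release A [release_params()].
#' @param release_configs Data frame of `(pore_diameter_nm, K_pct)` rows for
#'   the release table.
#' @param output_dir Directory for the CSV report bundle, or `NULL` to skip
#'   writing.
#' @return List of class `"pipeline_config"`.
#' @export
pipeline_config <- function(generator = generator_config(),
                            dataset_path = NULL,
                            required_fields = c("voltage_V", "temperature_C",
                                                "time_min", "electrolyte"),
                            encoding = c("onehot", "compact"),
                            test_fraction = 0.22, split_seed = 42,
                            network = ann_config(),
                            cv_k = 5, cv_seed = 123,
                            release = release_params(),
                            release_configs = RELEASE_REFERENCE,
                            output_dir = NULL) {
  encoding <- match.arg(encoding)
  if (is.null(generator) == is.null(dataset_path))
    stop("exactly one of generator / dataset_path must be given")
  structure(list(generator = generator, dataset_path = dataset_path,
                 required_fields = required_fields, encoding = encoding,
                 test_fraction = test_fraction, split_seed = split_seed,
                 network = network, cv_k = cv_k, cv_seed = cv_seed,
                 release = release, release_configs = release_configs,
                 output_dir = output_dir),
            class = "pipeline_config")
}

#' Run the full anodization-to-release analysis
#'
#' Executes, in order: data acquisition (synthetic generation with
#' missingness, or CSV load), electrolyte canonicalization, summary
#' statistics, case-wise deletion, stratified train/test split, OLS and
#' network fits with train/test metrics, k-fold cross-validation of both
#' surrogates, feature importance for both, voltage and temperature sweeps,
#' the empirical-rule benchmark on oxalic records, pore-interpore
#' regression, electrolyte-wise diameter statistics, and the
#' release-kinetics table. All randomness is governed by the seeds in the
#' config, so a rerun reproduces identical numbers. If `output_dir` is set,
#' each table is also written as CSV.
#'
#' @param config A [pipeline_config()].
#' @return List of class `"report_bundle"` with the tables named above plus
#'   a `log` recording seeds, counts and package version.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  records <- if (!is.null(config$generator)) {
    ds <- inject_missingness(generate_dataset(config$generator))
    ds$records
  } else {
    read_dataset(config$dataset_path)
  }
  records$electrolyte <- canonicalize_electrolyte(records$electrolyte)
  summary_tab <- summarize_dataset(records)

  complete <- suppressMessages(complete_cases(records, config$required_fields))
  complete <- complete[complete$electrolyte %in% ELECTROLYTES, , drop = FALSE]
  split <- stratified_split(complete, config$test_fraction, config$split_seed)

  fm_train <- encode_features(split$train, mode = config$encoding)
  fm_test <- encode_features(split$train, split$test, mode = config$encoding)
  mlr <- fit_mlr(fm_train)
  ann <- fit_ann(fm_train, config$network)

  metric_row <- function(label, model) {
    tr <- evaluate_predictions(fm_train$y, predict(model, fm_train))
    te <- evaluate_predictions(fm_test$y, predict(model, fm_test))
    data.frame(model = label, train_r2 = tr$r2, train_rmse = tr$rmse,
               train_mae = tr$mae, test_r2 = te$r2, test_rmse = te$rmse,
               test_mae = te$mae, n_train = tr$n, n_test = te$n)
  }
  metrics_tab <- rbind(metric_row("mlr", mlr), metric_row("ann", ann))

  cv_mlr <- kfold_cv(split$train, "mlr", k = config$cv_k,
                     seed = config$cv_seed, mode = config$encoding)
  cv_ann <- kfold_cv(split$train, "ann", k = config$cv_k,
                     seed = config$cv_seed, mode = config$encoding,
                     config = config$network)
  cv_tab <- data.frame(fold = c(seq_len(config$cv_k), "mean", "sd"),
                       mlr_r2 = c(cv_mlr$fold_r2, cv_mlr$mean, cv_mlr$sd),
                       ann_r2 = c(cv_ann$fold_r2, cv_ann$mean, cv_ann$sd))

  imp_mlr <- mlr_importance(mlr)$table
  imp_ann <- ann_importance(ann)$table
  importance_tab <- merge(imp_ann, imp_mlr, by = "feature",
                          suffixes = c("_ann", "_mlr"))

  electrolyte_tab <- do.call(rbind, lapply(ELECTROLYTES, function(e) {
    x <- complete$pore_diameter_nm[complete$electrolyte == e]
    if (!length(x)) return(NULL)
    data.frame(electrolyte = e, count = length(x), mean_nm = mean(x),
               sd_nm = pop_sd(x), min_nm = min(x), max_nm = max(x))
  }))

  sweeps <- list(
    voltage = voltage_response(mlr, "H2C2O4"),
    temperature = temperature_sensitivity(mlr, "H2C2O4")
  )
  benchmark <- tryCatch(rule_benchmark(mlr, split$train),
                        error = function(e) NULL)
  pore_interpore <- tryCatch(pore_interpore_regression(records),
                             error = function(e) NULL)
  release_tab <- release_table(config$release_configs)

  bundle <- structure(list(
    summary = summary_tab, metrics = metrics_tab, cv = cv_tab,
    importance = importance_tab, electrolyte = electrolyte_tab,
    release = release_tab, sweeps = sweeps, benchmark = benchmark,
    pore_interpore = pore_interpore,
    models = list(mlr = mlr, ann = ann),
    log = list(
      n_records = nrow(records), n_complete = nrow(complete),
      n_train = nrow(split$train), n_test = nrow(split$test),
      encoding = config$encoding,
      seeds = list(generator = if (!is.null(config$generator))
        config$generator$seed else NA,
        split = config$split_seed, cv = config$cv_seed,
        network = config$network$seed),
      package_version = as.character(utils::packageVersion("anodpore")),
      r_version = R.version.string)
  ), class = "report_bundle")

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    tabs <- c("summary", "metrics", "cv", "importance", "electrolyte",
              "release")
    for (tb in tabs)
      utils::write.csv(bundle[[tb]],
                       file.path(config$output_dir, paste0(tb, ".csv")),
                       row.names = FALSE)
  }
  bundle
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("Anodization-to-release report bundle\n")
  cat(sprintf("  records: %d total, %d complete (%d train / %d test)\n",
              x$log$n_records, x$log$n_complete, x$log$n_train,
              x$log$n_test))
  cat(sprintf("  train R2: MLR %.3f, ANN %.3f; CV mean R2: MLR %.3f, ANN %.3f\n",
              x$metrics$train_r2[1], x$metrics$train_r2[2],
              x$cv$mlr_r2[x$cv$fold == "mean"],
              x$cv$ann_r2[x$cv$fold == "mean"]))
  cat("  tables: summary, metrics, cv, importance, electrolyte, release\n")
  invisible(x)
}
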