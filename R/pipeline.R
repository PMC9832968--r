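# Pipeline orchestration: simulate -> split -> train/ensemble -> predict ->
# evaluate -> attribute, with config validation, seed fan-out and
# self-describing artifact directories.

#' Assemble and validate a pipeline run configuration
#'
#' A single global seed fans out to per-stage seeds by fixed offsets
#' (simulate +0, split +1, train +2, bootstrap +3) so stages are
#' independently reproducible.
#'
#' @param out_dir artifact directory.
#' @param seed global seed.
#' @param synthetic a [synthetic_config()] (or NULL when reading files).
#' @param train a [train_config()].
#' @param label a [label_spec()].
#' @param fractions train/validation/test fractions for labeled patients.
#' @param n_bootstrap bootstrap replicates for metric CIs.
#' @param ensemble number of ensemble members (1 = single model).
#' @param paths optional named list (expression, clinical, survival) of
#'   input files to use instead of simulation.
#' @return a validated `run_config`.
#' @export
run_config <- function(out_dir = "prognet_run", seed = 1,
                       synthetic = synthetic_config(),
                       train = train_config(),
                       label = label_spec(),
                       fractions = c(train = 0.6, validation = 0.2, test = 0.2),
                       n_bootstrap = 1000, ensemble = 1,
                       paths = NULL) {
  if (any(fractions < 0 | fractions > 1) || abs(sum(fractions) - 1) > 1e-8) {
    stop("invalid split fractions")
  }
  if (n_bootstrap < 1) stop("`n_bootstrap` must be >= 1")
  if (ensemble < 1) stop("`ensemble` must be >= 1")
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 synthetic = synthetic, train = train, label = label,
                 fractions = fractions, n_bootstrap = n_bootstrap,
                 ensemble = ensemble, paths = paths),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [run_config()]; the `synthetic`,
#' `train` and `label` sections accept the corresponding constructor
#' arguments.
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  for (nm in c("out_dir", "seed", "n_bootstrap", "ensemble", "paths")) {
    if (!is.null(y[[nm]])) args[[nm]] <- y[[nm]]
  }
  if (!is.null(y$fractions)) args$fractions <- unlist(y$fractions)
  if (!is.null(y$synthetic)) args$synthetic <- do.call(synthetic_config, y$synthetic)
  if (!is.null(y$train)) args$train <- do.call(train_config, y$train)
  if (!is.null(y$label)) args$label <- do.call(label_spec, y$label)
  do.call(run_config, args)
}

#' Run the full pipeline
#'
#' Simulates (or reads) a cohort, splits it, trains a model or seed
#' ensemble, predicts the test split, evaluates (bootstrap metrics, mean
#' ROC/PRC curves, KM/log-rank stratification) and writes attribution
#' reports. Every artifact directory contains the exact configuration and
#' seed used (`run_config.json`) and the package version.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with the cohort, fit, predictions and metric
#'   report; artifacts are written under `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(config = lapply(unclass(config), function(x) if (is.list(x)) unclass(x) else x),
         package_version = as.character(utils::packageVersion("prognet"))),
    file.path(config$out_dir, "run_config.json"),
    auto_unbox = TRUE, digits = NA, null = "null", force = TRUE)

  if (!is.null(config$paths)) {
    cohort <- read_cohort(config$paths$expression, config$paths$clinical,
                          config$paths$survival, config$label)
    truth <- NULL
  } else {
    scfg <- config$synthetic
    scfg$seed <- config$seed
    gen <- generate_cohort(scfg)
    cohort <- gen$cohort
    truth <- gen$truth
    write_cohort(cohort, file.path(config$out_dir, "cohort"))
    jsonlite::write_json(truth, file.path(config$out_dir, "cohort", "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, null = "null", force = TRUE)
  }
  cohort <- split_cohort(cohort, config$fractions, seed = config$seed + 1L)
  utils::write.csv(split_manifest(cohort),
                   file.path(config$out_dir, "split_manifest.csv"), row.names = FALSE)
  summ <- summarize_cohort(cohort)
  jsonlite::write_json(unclass(summ), file.path(config$out_dir, "cohort_summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")

  tcfg <- config$train
  tcfg$seed <- config$seed + 2L
  if (config$ensemble > 1L) {
    fit <- train_ensemble(cohort, tcfg, n_members = config$ensemble,
                          base_seed = tcfg$seed)
    predictor <- fit
    for (i in seq_along(fit$members)) {
      save_checkpoint(fit$members[[i]],
                      file.path(config$out_dir, sprintf("model_%03d.json", i)))
    }
  } else {
    fit <- train_prognet(cohort, tcfg)
    predictor <- fit$model
    save_checkpoint(fit$model, file.path(config$out_dir, "model.json"))
    utils::write.csv(fit$history, file.path(config$out_dir, "history.csv"),
                     row.names = FALSE)
  }

  test_rows <- which(cohort$split %in% "test")
  pred <- predict(predictor, cohort, rows = test_rows)
  utils::write.csv(pred, file.path(config$out_dir, "predictions.csv"),
                   row.names = FALSE)

  y <- as.integer(cohort$label[test_rows] == "poor")
  times <- cohort$survival$time_months[test_rows]
  events <- cohort$survival$event[test_rows]
  report <- bootstrap_report(pred$y_tilde, y, times, events,
                             n = config$n_bootstrap, seed = config$seed + 3L)
  jsonlite::write_json(list(metrics = report,
                            n_bootstrap = attr(report, "n_bootstrap"),
                            n_skipped = attr(report, "n_skipped")),
                       file.path(config$out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  for (kind in c("roc", "prc")) {
    cb <- mean_curve(pred$y_tilde, y, kind, n_boot = config$n_bootstrap,
                     seed = config$seed + 3L)
    utils::write.csv(data.frame(grid = cb$grid, mean = cb$mean, sd = cb$sd),
                     file.path(config$out_dir, paste0("curve_", kind, ".csv")),
                     row.names = FALSE)
  }
  strat <- NULL
  if (length(unique(pred$predicted_class)) == 2L) {
    strat <- km_logrank(times, events, pred$predicted_class)
    utils::write.csv(strat$km, file.path(config$out_dir, "km_curves.csv"),
                     row.names = FALSE)
    jsonlite::write_json(list(chisq = strat$chisq, p_value = strat$p_value,
                              medians = as.list(strat$medians)),
                         file.path(config$out_dir, "logrank.json"),
                         auto_unbox = TRUE, digits = NA)
  } else {
    warning("all test patients predicted in one class; KM stratification skipped")
    jsonlite::write_json(list(chisq = NA, p_value = NA,
                              note = "single predicted class"),
                         file.path(config$out_dir, "logrank.json"),
                         auto_unbox = TRUE, null = "null")
  }
  utils::write.csv(attribution_report(predictor),
                   file.path(config$out_dir, "attribution.csv"), row.names = FALSE)

  invisible(list(cohort = cohort, truth = truth, fit = fit,
                 predictions = pred, report = report, stratification = strat))
}
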