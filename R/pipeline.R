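#' Configure a full analysis run
#'
#' Bundles every knob of the pipeline into one validated object. Either
#' `input` (path to a tidy TBARS CSV) or `truth` (a [synthetic_truth()] to
#' simulate from) must be supplied.
#'
#' @param input Optional path to a CSV readable by [read_tbars_table()].
#' @param truth Optional [synthetic_truth()]; used when `input` is `NULL`.
#' @param design [storage_design()] used with `truth`.
#' @param kelvin_offset Celsius-to-kelvin offset (default 273.15).
#' @param fix_intercept Force the primary-fit intercept to ln(100)?
#' @param holdout_temperature_c Temperature held out for external
#'   validation (default 12).
#' @param models Character subset of
#'   `c("arrhenius", "log_logistic", "ann", "mlr")` to run.
#' @param seed Integer seed for the ANN stage.
#' @param output_dir Directory for the report bundle.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, truth = NULL,
                            design = storage_design(),
                            kelvin_offset = 273.15,
                            fix_intercept = FALSE,
                            holdout_temperature_c = 12,
                            models = c("arrhenius", "log_logistic", "ann",
                                       "mlr"),
                            seed = 1L,
                            output_dir = tempfile("lipidox_run_")) {
  if (is.null(input) && is.null(truth)) {
    stop("configuration error: supply 'input' or 'truth'", call. = FALSE)
  }
  models <- match.arg(models, several.ok = TRUE)
  structure(list(input = input, truth = truth, design = design,
                 kelvin_offset = kelvin_offset,
                 fix_intercept = fix_intercept,
                 holdout_temperature_c = holdout_temperature_c,
                 models = models, seed = as.integer(seed),
                 output_dir = output_dir),
            class = "pipeline_config")
}

#' Run the full TBARS modelling pipeline
#'
#' Loads or simulates the dataset, then runs the requested stages and
#' writes a report bundle to the configured output directory:
#' `rate_table.csv` (first-order rate constants), `secondary_models.csv`
#' (Arrhenius + log-logistic parameters per treatment),
#' `validation_<model>.json` and `validation_<model>_pairs.csv` (external
#' validation at the holdout temperature), `mlr_table.csv` (ranked
#' dummy-regression coefficients) and `ann_table.csv` (retained networks).
#' Numbers are serialized with full precision; each stage is logged via
#' `message()`.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress stage logging? Default `FALSE`.
#' @return Invisibly, a list with the dataset, stage results and the
#'   vector of written file paths.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  log_ <- function(...) if (!quiet) message(sprintf(...))

  dataset <- if (!is.null(config$input)) {
    log_("reading %s", config$input)
    ds <- read_tbars_table(config$input)
    if (ds$scale[1] == "raw") ds <- to_percent(ds)
    ds
  } else {
    log_("simulating dataset (seed %d, sigma %.3f, %d replicates)",
         config$truth$seed, config$truth$noise_sigma,
         config$truth$replicates)
    simulate_dataset(config$truth, config$design)
  }

  validate_requested <- any(c("arrhenius", "log_logistic") %in%
                              config$models)
  if (validate_requested &&
      !config$holdout_temperature_c %in% dataset$temperature_c) {
    stop("configuration error: holdout temperature ",
         config$holdout_temperature_c, " not present in dataset",
         call. = FALSE)
  }

  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  results <- list(dataset = dataset)

  log_("fitting first-order rate constants (fix_intercept = %s)",
       config$fix_intercept)
  rates <- rate_table(dataset, fix_intercept = config$fix_intercept)
  results$rates <- rates
  p <- file.path(config$output_dir, "rate_table.csv")
  write_rate_table(rates, p)
  paths <- c(paths, p)

  log_("fitting secondary models (kelvin offset %.2f)",
       config$kelvin_offset)
  sec <- secondary_table(rates, kelvin_offset = config$kelvin_offset)
  results$secondary <- sec
  p <- file.path(config$output_dir, "secondary_models.csv")
  write.csv(format(sec$table, digits = 10), p, row.names = FALSE,
            quote = FALSE)
  paths <- c(paths, p)

  for (m in intersect(config$models, c("arrhenius", "log_logistic"))) {
    log_("external validation of the %s model at %.1f C", m,
         config$holdout_temperature_c)
    rep <- holdout_pipeline(dataset, config$holdout_temperature_c,
                            model = m,
                            fix_intercept = config$fix_intercept,
                            kelvin_offset = config$kelvin_offset)
    results[[paste0("validation_", m)]] <- rep
    p <- file.path(config$output_dir, paste0("validation_", m, ".json"))
    jsonlite::write_json(
      list(model = rep$model, n = rep$n, r2_adj = rep$r2_adj,
           rmse = rep$rmse, slope = rep$slope, intercept = rep$intercept),
      p, auto_unbox = TRUE, digits = NA)
    pp <- file.path(config$output_dir,
                    paste0("validation_", m, "_pairs.csv"))
    write.csv(format(rep$pairs, digits = 10), pp, row.names = FALSE,
              quote = FALSE)
    paths <- c(paths, p, pp)
  }

  if ("mlr" %in% config$models) {
    log_("dummy-coded multiple linear regression")
    mlr <- fit_mlr_dummy(dataset)
    results$mlr <- mlr
    p <- file.path(config$output_dir, "mlr_table.csv")
    write.csv(format(rank_treatment_effects(mlr), digits = 10), p,
              row.names = FALSE, quote = FALSE)
    paths <- c(paths, p)
  }

  if ("ann" %in% config$models) {
    log_("training the perceptron grid (seed %d)", config$seed)
    ft <- encode_features(dataset)
    sel <- select_best_networks(default_ann_grid(seed = config$seed), ft,
                                n_keep = 5L, split_seed = config$seed)
    results$ann <- sel
    p <- file.path(config$output_dir, "ann_table.csv")
    write.csv(format(ann_table(sel), digits = 10), p, row.names = FALSE,
              quote = FALSE)
    paths <- c(paths, p)
  }

  results$paths <- paths
  log_("wrote %d artifact(s) to %s", length(paths), config$output_dir)
  invisible(results)
}
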