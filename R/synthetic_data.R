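#' Define a multi-temperature storage design
#'
#' Describes which storage temperatures are run, for how long, and on which
#' days samples are drawn. The default mirrors the study design the package
#' models: storage at 4/8/12/16/20 degrees C, 13 days at <= 12 degrees and
#' 5 days at 16/20 degrees, sampled daily from day 0.
#'
#' @param temperatures_c Storage temperatures (degrees Celsius).
#' @param duration_days Named numeric vector (names = temperatures) of
#'   maximum storage day per temperature. Default: 13 at <= 12 degrees, 5
#'   above.
#' @param sampling_days Named list (names = temperatures) of sampling-day
#'   grids; each must include day 0 and stay within the duration. Default:
#'   daily.
#' @return An object of class `storage_design`.
#' @export
storage_design <- function(temperatures_c = c(4, 8, 12, 16, 20),
                           duration_days = NULL, sampling_days = NULL) {
  key <- as.character(temperatures_c)
  if (is.null(duration_days)) {
    duration_days <- setNames(ifelse(temperatures_c <= 12, 13, 5), key)
  }
  if (is.null(sampling_days)) {
    sampling_days <- setNames(
      lapply(key, function(tt) 0:duration_days[[tt]]), key)
  }
  stopifnot(setequal(names(duration_days), key),
            setequal(names(sampling_days), key))
  for (tt in key) {
    d <- sampling_days[[tt]]
    if (!0 %in% d) stop("sampling grid for ", tt, " C must include day 0",
                        call. = FALSE)
    if (max(d) > duration_days[[tt]]) {
      stop("sampling grid for ", tt, " C exceeds its storage duration",
           call. = FALSE)
    }
  }
  structure(list(temperatures_c = temperatures_c,
                 duration_days = duration_days,
                 sampling_days = sampling_days),
            class = "storage_design")
}

#' Define ground-truth kinetics for the synthetic generator
#'
#' Per-treatment true secondary model and parameters, plus the measurement
#' noise model: TBARS observations are the exact first-order curve times a
#' multiplicative lognormal error (i.e. additive Gaussian on the log
#' scale), which makes the log-linear primary fit the correctly specified
#' estimator.
#'
#' @param params Data frame with columns `treatment`, `model`
#'   (`"arrhenius"` or `"log_logistic"`), and either (`ea` in J/mol and
#'   `k0` in day^-1) or (`c` per degree C and `tc` in degrees C); unused
#'   columns may be `NA`.
#' @param noise_sigma SD of the lognormal measurement noise on the log
#'   scale; default 0.05.
#' @param replicates Number of replicate series per treatment x
#'   temperature; default 3.
#' @param seed Integer seed making the generator reproducible.
#' @param kelvin_offset Celsius-to-kelvin offset used when evaluating
#'   Arrhenius truths.
#' @return An object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(params, noise_sigma = 0.05, replicates = 3L,
                            seed = 1L, kelvin_offset = 273.15) {
  stopifnot(is.data.frame(params),
            all(c("treatment", "model") %in% names(params)),
            noise_sigma >= 0, replicates >= 1L)
  for (i in seq_len(nrow(params))) {
    if (params$model[i] == "arrhenius") {
      stopifnot(params$ea[i] > 0, params$k0[i] > 0)
    } else if (params$model[i] == "log_logistic") {
      stopifnot(params$c[i] > 0)
    } else {
      stop("unknown truth model: ", params$model[i], call. = FALSE)
    }
  }
  structure(list(params = params, noise_sigma = noise_sigma,
                 replicates = as.integer(replicates), seed = as.integer(seed),
                 kelvin_offset = kelvin_offset),
            class = "synthetic_truth")
}

#' True rate constant of a synthetic truth at given temperatures
#'
#' @param truth A `synthetic_truth`.
#' @param treatment Treatment label.
#' @param temperature_c Temperatures in degrees Celsius.
#' @return True k (day^-1).
#' @export
true_rate <- function(truth, treatment, temperature_c) {
  stopifnot(inherits(truth, "synthetic_truth"))
  p <- truth$params[truth$params$treatment == treatment, ]
  if (nrow(p) != 1L) stop("unknown treatment: ", treatment, call. = FALSE)
  if (p$model == "arrhenius") {
    tk <- celsius_to_kelvin(temperature_c, truth$kelvin_offset)
    p$k0 * exp(-p$ea / (R_GAS * tk))
  } else {
    log1p(exp(p$c * (temperature_c - p$tc)))
  }
}

#' Simulate a TBARS storage experiment
#'
#' Generates a percent-scale [kinetic_dataset()]:
#' `tbars = 100 * exp(k_true(T) * day) * exp(eps)` with
#' `eps ~ N(0, noise_sigma^2)` independent across records; day-0 records
#' are fixed at exactly 100 (the normalization anchor). Reproducible given
#' the truth's seed.
#'
#' @param truth A [synthetic_truth()].
#' @param design A [storage_design()]; default [storage_design()].
#' @return A [kinetic_dataset()] on the percent scale.
#' @export
simulate_dataset <- function(truth, design = storage_design()) {
  stopifnot(inherits(truth, "synthetic_truth"),
            inherits(design, "storage_design"))
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(truth$seed)

  rows <- list()
  i <- 0L
  for (tr in truth$params$treatment) {
    for (tt in design$temperatures_c) {
      k <- true_rate(truth, tr, tt)
      days <- design$sampling_days[[as.character(tt)]]
      for (rep_id in seq_len(truth$replicates)) {
        eps <- rnorm(length(days), 0, truth$noise_sigma)
        tbars <- 100 * exp(k * days) * exp(eps)
        tbars[days == 0] <- 100
        i <- i + 1L
        rows[[i]] <- data.frame(
          treatment = tr, temperature_c = tt, replicate = rep_id,
          day = days, tbars = tbars, scale = "percent",
          stringsAsFactors = FALSE)
      }
    }
  }
  kinetic_dataset(do.call(rbind, c(rows, make.row.names = FALSE)),
                  treatments = truth$params$treatment,
                  temperatures_c = design$temperatures_c)
}

#' Ground truth emulating the published beef study
#'
#' Builds a 14-treatment Arrhenius truth from the packaged rate-constant
#' table: per treatment, the activation energy is recomputed by
#' [fit_arrhenius()] from the published mean rate constants (two published
#' parameter rows are internally inconsistent, so the recomputed values are
#' the usable ground truth), and the pre-exponential factor is re-anchored
#' so that the true k at 4 degrees C equals the published k at 277 K
#' exactly. The kelvin offset is therefore 273.0, matching the
#' integer-rounded kelvins of the source table.
#'
#' @inheritParams synthetic_truth
#' @return A [synthetic_truth()] with 14 treatments.
#' @export
paper_like_truth <- function(noise_sigma = 0.05, replicates = 3L, seed = 1L) {
  pub <- published_rate_constants()
  rows <- lapply(unique(pub$extract), function(tr) {
    d <- pub[pub$extract == tr, ]
    arr <- fit_arrhenius(d$temperature_k, d$k_mean, treatment = tr)
    k277 <- d$k_mean[d$temperature_k == 277]
    data.frame(treatment = tr, model = "arrhenius", ea = arr$ea,
               k0 = k277 * exp(arr$ea / (R_GAS * 277)),
               c = NA_real_, tc = NA_real_, stringsAsFactors = FALSE)
  })
  synthetic_truth(do.call(rbind, c(rows, make.row.names = FALSE)),
                  noise_sigma = noise_sigma, replicates = replicates,
                  seed = seed, kelvin_offset = 273.0)
}
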