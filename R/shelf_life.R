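#' Predict TBARS at arbitrary time and temperature
#'
#' Evaluates the integrated shelf-life model
#' \eqn{TBARS(t, T) = 100 \exp(k(T) t)} where \eqn{k(T)} comes from a
#' fitted secondary model: Arrhenius
#' (\eqn{k = k_0 e^{-E_a / RT}}, T in kelvin) or log-logistic
#' (\eqn{k = m' \ln(1 + e^{c (T - T_c)})}, T in degrees Celsius). TBARS0 is
#' 100 % by definition of the percent scale, so `day = 0` always returns
#' 100. Predictions are not clipped: overestimation at high temperature is
#' reported as-is.
#'
#' @param fit An `arrhenius_fit` or `log_logistic_fit`.
#' @param temperature_c Storage temperature in degrees Celsius.
#' @param day Storage times in days, all >= 0.
#' @param kelvin_offset Celsius-to-kelvin offset for Arrhenius fits.
#' @return Predicted TBARS values (percent of day 0), same length as `day`.
#' @export
predict_tbars <- function(fit, temperature_c, day, kelvin_offset = 273.15) {
  day <- as.numeric(day)
  if (any(!is.finite(day)) || any(day < 0)) {
    stop("domain error: 'day' must be finite and >= 0", call. = FALSE)
  }
  k <- if (inherits(fit, "arrhenius_fit")) {
    arrhenius_rate(fit, temperature_c, kelvin_offset)
  } else if (inherits(fit, "log_logistic_fit")) {
    log_logistic_rate(fit, temperature_c)
  } else {
    stop("'fit' must be an arrhenius_fit or log_logistic_fit", call. = FALSE)
  }
  100 * exp(k * day)
}

#' Invert the Arrhenius shelf-life model for time-to-threshold
#'
#' Convenience inversion of the integrated model: the storage time at which
#' predicted TBARS reaches `threshold_pct` at a constant temperature.
#' Provided as a helper for shelf-life estimation; it is a pure algebraic
#' inversion and carries the model's extrapolation error.
#'
#' @inheritParams predict_tbars
#' @param threshold_pct TBARS threshold in percent of day 0 (> 100).
#' @return Days until the threshold is reached.
#' @export
shelf_life_days <- function(fit, temperature_c, threshold_pct,
                            kelvin_offset = 273.15) {
  stopifnot(is.numeric(threshold_pct), all(threshold_pct > 100))
  k <- if (inherits(fit, "arrhenius_fit")) {
    arrhenius_rate(fit, temperature_c, kelvin_offset)
  } else {
    log_logistic_rate(fit, temperature_c)
  }
  log(threshold_pct / 100) / k
}

#' Score predictions against held-out observations
#'
#' External-validation metrics for paired predicted/observed TBARS values:
#' the observed-vs-predicted regression line (slope, intercept), its
#' adjusted coefficient of determination
#' \eqn{R^2_{adj} = 1 - (1 - R^2)(n - 1)/(n - 2)}, and the RMSE of the raw
#' paired errors \eqn{\sqrt{\mathrm{mean}((obs - pred)^2)}} on the percent
#' scale (not the regression residuals).
#'
#' @param predicted,observed Equal-length numeric vectors, n >= 3.
#' @return An object of class `validation_report`: list with `model`
#'   (label, `NA` here), `n`, `r2_adj`, `rmse`, `slope`, `intercept`.
#' @examples
#' validate_external(c(100, 150, 200, 300), c(102, 149, 205, 290))
#' @export
validate_external <- function(predicted, observed) {
  predicted <- as.numeric(predicted)
  observed <- as.numeric(observed)
  if (length(predicted) != length(observed)) {
    stop("contract error: 'predicted' and 'observed' lengths differ",
         call. = FALSE)
  }
  n <- length(predicted)
  if (n < 3L) stop("need at least 3 pairs", call. = FALSE)
  if (var(predicted) == 0) {
    stop("degenerate validation: zero variance in predictions",
         call. = FALSE)
  }
  fit <- lm(observed ~ predicted)
  # R^2 of the simple regression; 0 when the observations are constant
  r2 <- if (sd(observed) > 0) cor(observed, predicted)^2 else 0
  structure(list(
    model = NA_character_,
    n = n,
    r2_adj = 1 - (1 - r2) * (n - 1) / (n - 2),
    rmse = sqrt(mean((observed - predicted)^2)),
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    per_treatment = NULL
  ), class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> %s: n = %d, adj R2 = %.4f, RMSE = %.2f %%\n",
              if (is.na(x$model)) "model" else x$model, x$n, x$r2_adj, x$rmse))
  invisible(x)
}

#' External validation of the integrated model at a held-out temperature
#'
#' Fits the full two-stage pipeline — first-order rate constants per
#' series, replicate aggregation, secondary model per treatment — on all
#' storage temperatures except the holdout, then predicts every observation
#' at the holdout temperature and scores predicted vs observed with
#' [validate_external()], pooled and per treatment.
#'
#' @param dataset A [kinetic_dataset()] on the percent scale containing the
#'   holdout temperature plus at least 3 other temperatures.
#' @param holdout_temperature_c The held-out storage temperature (degrees
#'   Celsius); default 12.
#' @param model `"arrhenius"` or `"log_logistic"`.
#' @param fix_intercept Passed to [rate_table()].
#' @param kelvin_offset Celsius-to-kelvin offset for Arrhenius fits.
#' @return A `validation_report` with `per_treatment` filled in and an
#'   extra element `pairs` (data frame of treatment, day, predicted,
#'   observed).
#' @export
holdout_pipeline <- function(dataset, holdout_temperature_c = 12,
                             model = c("arrhenius", "log_logistic"),
                             fix_intercept = FALSE,
                             kelvin_offset = 273.15) {
  model <- match.arg(model)
  stopifnot(inherits(dataset, "kinetic_dataset"))
  temps <- temperatures_c(dataset)
  if (!holdout_temperature_c %in% dataset$temperature_c) {
    stop("configuration error: holdout temperature ", holdout_temperature_c,
         " not present in dataset", call. = FALSE)
  }
  if (length(setdiff(temps, holdout_temperature_c)) < 3L) {
    stop("configuration error: need at least 3 non-holdout temperatures",
         call. = FALSE)
  }
  train <- dataset[dataset$temperature_c != holdout_temperature_c, ]
  train <- kinetic_dataset(train, treatments = treatments(dataset))
  test <- dataset[dataset$temperature_c == holdout_temperature_c &
                    dataset$day > 0, ]

  rates <- rate_table(train, fix_intercept = fix_intercept)
  sec <- secondary_table(rates, kelvin_offset = kelvin_offset)
  fits <- if (model == "arrhenius") sec$arrhenius else sec$log_logistic

  pred <- numeric(nrow(test))
  for (i in seq_len(nrow(test))) {
    f <- fits[[test$treatment[i]]]
    if (is.null(f)) stop("no secondary fit for treatment ",
                         test$treatment[i], call. = FALSE)
    pred[i] <- predict_tbars(f, holdout_temperature_c, test$day[i],
                             kelvin_offset = kelvin_offset)
  }
  report <- validate_external(pred, test$tbars)
  report$model <- model
  report$per_treatment <- lapply(split(seq_len(nrow(test)), test$treatment),
                                 function(idx) {
    if (length(idx) < 3L || var(pred[idx]) == 0) return(NULL)
    r <- validate_external(pred[idx], test$tbars[idx])
    r$model <- model
    r
  })
  report$pairs <- data.frame(treatment = test$treatment, day = test$day,
                             predicted = pred, observed = test$tbars,
                             stringsAsFactors = FALSE)
  report
}
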