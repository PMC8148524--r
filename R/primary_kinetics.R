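#' Fit the first-order TBARS formation model to one storage series
#'
#' Estimates the rate constant `k` (day^-1) of
#' \eqn{TBARS(t) = TBARS_0 \exp(k t)} by ordinary least squares of
#' `ln(tbars_pct)` on `day`. With `fix_intercept = TRUE` the intercept is
#' forced to `ln(100)` (TBARS0 identically 100 %) and only the slope is
#' estimated through that point; otherwise both slope and intercept are
#' free.
#'
#' @param day Numeric vector of storage times (days), all distinct, >= 3
#'   values.
#' @param tbars_pct TBARS values on the percent-of-day-0 scale, all
#'   positive.
#' @param fix_intercept Force the intercept to `ln(100)`? Default `FALSE`.
#' @param treatment,temperature_c,replicate Optional labels carried into the
#'   result for bookkeeping.
#' @return An object of class `rate_fit`: a list with elements `k`,
#'   `intercept_log`, `r2` (coefficient of determination on the log scale),
#'   `rmse_log`, `n_points`, plus the labels.
#' @examples
#' f <- fit_first_order(0:5, 100 * exp(0.1 * (0:5)))
#' f$k  # 0.1
#' @export
fit_first_order <- function(day, tbars_pct, fix_intercept = FALSE,
                            treatment = NA_character_,
                            temperature_c = NA_real_,
                            replicate = NA) {
  day <- as.numeric(day)
  tbars_pct <- as.numeric(tbars_pct)
  if (length(day) != length(tbars_pct)) {
    stop("'day' and 'tbars_pct' lengths differ", call. = FALSE)
  }
  if (length(day) < 3L) {
    stop("insufficient data: need at least 3 points, got ", length(day),
         call. = FALSE)
  }
  if (any(!is.finite(tbars_pct)) || any(tbars_pct <= 0)) {
    stop("domain error: all tbars_pct must be positive and finite",
         call. = FALSE)
  }
  if (length(unique(day)) < 2L) {
    stop("degenerate design: all days equal", call. = FALSE)
  }
  if (anyDuplicated(day)) {
    stop("degenerate design: duplicated days", call. = FALSE)
  }

  y <- log(tbars_pct)
  if (fix_intercept) {
    intercept_log <- log(100)
    yc <- y - intercept_log
    k <- sum(day * yc) / sum(day^2)
  } else {
    fit <- lm(y ~ day)
    k <- unname(coef(fit)[2])
    intercept_log <- unname(coef(fit)[1])
  }
  resid <- y - (intercept_log + k * day)
  sse <- sum(resid^2)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) max(0, min(1, 1 - sse / sst)) else as.numeric(sse < 1e-24)
  structure(list(
    treatment = treatment,
    temperature_c = temperature_c,
    replicate = replicate,
    k = k,
    intercept_log = intercept_log,
    r2 = r2,
    rmse_log = sqrt(sse / length(day)),
    n_points = length(day),
    fix_intercept = fix_intercept
  ), class = "rate_fit")
}

#' @export
print.rate_fit <- function(x, ...) {
  cat(sprintf("<rate_fit> k = %.5f /day, ln(TBARS0) = %.4f, R2 = %.4f (n = %d)\n",
              x$k, x$intercept_log, x$r2, x$n_points))
  invisible(x)
}

#' Fit first-order rate constants for every series in a dataset
#'
#' Runs [fit_first_order()] on every (treatment, temperature, replicate)
#' series of a percent-scale dataset and aggregates the rate constants per
#' (treatment, temperature) as mean and sample SD over replicates (SD = 0
#' when only one replicate exists). Series failing the fit preconditions
#' are skipped and collected in an error report rather than aborting the
#' whole table.
#'
#' @param dataset A [kinetic_dataset()] on the percent scale.
#' @inheritParams fit_first_order
#' @return An object of class `rate_table`: list with `fits` (data frame of
#'   per-series fits), `aggregated` (data frame with `k_mean`, `k_sd`,
#'   `r2_mean` per treatment x temperature) and `errors` (data frame of
#'   skipped groups with messages).
#' @export
rate_table <- function(dataset, fix_intercept = FALSE) {
  stopifnot(inherits(dataset, "kinetic_dataset"))
  if (nrow(dataset) == 0L) stop("empty dataset", call. = FALSE)
  if (dataset$scale[1] != "percent") {
    stop("dataset must be on the percent scale; call to_percent() first",
         call. = FALSE)
  }
  key <- group_key(dataset)
  fits <- list()
  errs <- list()
  for (g in levels(key)) {
    idx <- which(key == g)
    rows <- dataset[idx, ]
    f <- tryCatch(
      fit_first_order(rows$day, rows$tbars, fix_intercept = fix_intercept,
                      treatment = rows$treatment[1],
                      temperature_c = rows$temperature_c[1],
                      replicate = rows$replicate[1]),
      error = function(e) e)
    if (inherits(f, "error")) {
      errs[[g]] <- data.frame(group = g, message = conditionMessage(f),
                              stringsAsFactors = FALSE)
    } else {
      fits[[g]] <- data.frame(
        treatment = f$treatment, temperature_c = f$temperature_c,
        replicate = f$replicate, k = f$k, intercept_log = f$intercept_log,
        r2 = f$r2, rmse_log = f$rmse_log, n_points = f$n_points,
        stringsAsFactors = FALSE)
    }
  }
  fits <- if (length(fits)) do.call(rbind, c(fits, make.row.names = FALSE))
          else data.frame()
  errors <- if (length(errs)) do.call(rbind, c(errs, make.row.names = FALSE))
            else data.frame(group = character(), message = character())

  aggregated <- data.frame()
  if (nrow(fits)) {
    sp <- split(fits, list(fits$treatment, fits$temperature_c), drop = TRUE)
    aggregated <- do.call(rbind, c(lapply(sp, function(d) {
      data.frame(treatment = d$treatment[1],
                 temperature_c = d$temperature_c[1],
                 k_mean = mean(d$k),
                 k_sd = if (nrow(d) > 1L) sd(d$k) else 0,
                 r2_mean = mean(d$r2),
                 n_replicates = nrow(d),
                 stringsAsFactors = FALSE)
    }), make.row.names = FALSE))
    # stable ordering: treatment order of the dataset, then temperature
    aggregated <- aggregated[order(match(aggregated$treatment,
                                         treatments(dataset)),
                                   aggregated$temperature_c), ]
    rownames(aggregated) <- NULL
  }
  structure(list(fits = fits, aggregated = aggregated, errors = errors,
                 fix_intercept = fix_intercept),
            class = "rate_table")
}

#' @export
print.rate_table <- function(x, ...) {
  cat(sprintf("<rate_table> %d series fit(s), %d aggregate(s), %d error(s)\n",
              nrow(x$fits), nrow(x$aggregated), nrow(x$errors)))
  invisible(x)
}

#' Serialize a rate table to CSV
#'
#' Writes the per-(treatment, temperature) aggregates — `k_mean`, `k_sd`
#' and mean log-scale R2 — in the layout of a published rate-constant
#' table.
#'
#' @param x A `rate_table` from [rate_table()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_rate_table <- function(x, path) {
  stopifnot(inherits(x, "rate_table"))
  write.csv(x$aggregated, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
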