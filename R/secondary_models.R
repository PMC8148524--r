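#' Fit the Arrhenius temperature model to rate constants
#'
#' Linear regression of \eqn{\ln k} on \eqn{1/T} (T in kelvin):
#' \eqn{\ln k = \ln k_0 - E_a / (R T)}, so the activation energy is
#' `-slope * R` and the pre-exponential factor `exp(intercept)`.
#' The gas constant is [R_GAS] (8.314 J mol^-1 K^-1).
#'
#' @param temperature_k Absolute temperatures in kelvin, at least 2
#'   distinct values.
#' @param k Positive rate constants (day^-1), same length.
#' @param treatment Optional label carried into the result.
#' @return An object of class `arrhenius_fit`: list with `ea` (J/mol), `k0`
#'   (day^-1), `r2` of the ln k vs 1/T regression, `n_temps`, and the input
#'   data.
#' @examples
#' fit_arrhenius(c(277, 281, 289, 293), c(0.147, 0.201, 0.410, 0.613))
#' @export
fit_arrhenius <- function(temperature_k, k, treatment = NA_character_) {
  temperature_k <- as.numeric(temperature_k)
  k <- as.numeric(k)
  if (length(temperature_k) != length(k)) {
    stop("'temperature_k' and 'k' lengths differ", call. = FALSE)
  }
  if (any(!is.finite(k)) || any(k <= 0)) {
    stop("domain error: all k must be positive", call. = FALSE)
  }
  if (length(unique(temperature_k)) < 2L) {
    stop("degenerate design: need at least 2 distinct temperatures",
         call. = FALSE)
  }
  inv_t <- 1 / temperature_k
  fit <- lm(log(k) ~ inv_t)
  slope <- unname(coef(fit)[2])
  intercept <- unname(coef(fit)[1])
  resid <- log(k) - (intercept + slope * inv_t)
  sst <- sum((log(k) - mean(log(k)))^2)
  r2 <- if (sst > 0) 1 - sum(resid^2) / sst else 1
  structure(list(
    treatment = treatment,
    ea = -slope * R_GAS,
    k0 = exp(intercept),
    r2 = r2,
    n_temps = length(unique(temperature_k)),
    temperature_k = temperature_k,
    k = k
  ), class = "arrhenius_fit")
}

#' @export
print.arrhenius_fit <- function(x, ...) {
  cat(sprintf("<arrhenius_fit> Ea = %.0f J/mol, k0 = %.4g /day, R2 = %.4f (%d temps)\n",
              x$ea, x$k0, x$r2, x$n_temps))
  invisible(x)
}

#' Evaluate an Arrhenius fit at given temperatures
#'
#' @param fit An `arrhenius_fit`.
#' @param temperature_c Temperatures in degrees Celsius.
#' @param kelvin_offset See [celsius_to_kelvin()].
#' @return Predicted rate constants (day^-1).
#' @export
arrhenius_rate <- function(fit, temperature_c, kelvin_offset = 273.15) {
  stopifnot(inherits(fit, "arrhenius_fit"))
  tk <- celsius_to_kelvin(temperature_c, kelvin_offset)
  fit$k0 * exp(-fit$ea / (R_GAS * tk))
}

#' Fit the log-logistic temperature model to rate constants
#'
#' Nonlinear least squares (on the k scale, unweighted) of
#' \eqn{k = m' \ln(1 + e^{c (T - T_c)})} with temperatures in degrees
#' Celsius and `m'` fixed at 1 by default. The fit is initialized by a
#' deterministic coarse grid search over `c` in \[0.01, 0.6\] per degree C
#' and `Tc` in \[-10, 90\] degrees C, then refined by Levenberg-Marquardt
#' (`minpack.lm::nlsLM`); if the refinement fails to improve, the best grid
#' point (polished by Nelder-Mead) is returned.
#'
#' @param temperature_c Storage temperatures in degrees Celsius.
#' @param k Positive rate constants (day^-1), same length; at least 3 pairs
#'   when `m_prime_fixed` (2 free parameters), at least 4 otherwise.
#' @param m_prime_fixed Keep `m'` fixed at 1? Default `TRUE`.
#' @param treatment Optional label carried into the result.
#' @param grid_n Number of grid points per parameter in the initialization
#'   search (default 40).
#' @return An object of class `log_logistic_fit`: list with `c` (per degree
#'   C), `tc` (degrees C), `m_prime`, `r2` (on the k scale), `sse`,
#'   `n_temps`, and the input data.
#' @examples
#' fit_log_logistic(c(4, 8, 16, 20), c(0.147, 0.201, 0.410, 0.613))
#' @export
fit_log_logistic <- function(temperature_c, k, m_prime_fixed = TRUE,
                             treatment = NA_character_, grid_n = 40L) {
  temperature_c <- as.numeric(temperature_c)
  k <- as.numeric(k)
  n_free <- if (m_prime_fixed) 2L else 3L
  if (length(temperature_c) != length(k)) {
    stop("'temperature_c' and 'k' lengths differ", call. = FALSE)
  }
  if (length(k) <= n_free) {
    stop("degenerate design: need more pairs than free parameters (",
         n_free, ")", call. = FALSE)
  }
  if (any(!is.finite(k)) || any(k <= 0)) {
    stop("domain error: all k must be positive", call. = FALSE)
  }

  pred <- function(cc, tc, mp) mp * log1p(exp(cc * (temperature_c - tc)))
  sse_of <- function(p) {
    mp <- if (m_prime_fixed) 1 else p[3]
    if (p[1] <= 0 || mp <= 0) return(Inf)
    sum((k - pred(p[1], p[2], mp))^2)
  }

  # deterministic coarse grid
  c_grid <- seq(0.01, 0.6, length.out = grid_n)
  tc_grid <- seq(-10, 90, length.out = grid_n)
  grid <- expand.grid(c = c_grid, tc = tc_grid)
  grid_sse <- vapply(seq_len(nrow(grid)), function(i)
    sse_of(c(grid$c[i], grid$tc[i], 1)), numeric(1))
  best <- which.min(grid_sse)
  start <- c(grid$c[best], grid$tc[best], 1)

  # local refinement: Levenberg-Marquardt on the k scale
  refine <- tryCatch({
    df <- data.frame(tt = temperature_c, k = k)
    if (m_prime_fixed) {
      nlfit <- minpack.lm::nlsLM(
        k ~ log1p(exp(cc * (tt - tc))), data = df,
        start = list(cc = start[1], tc = start[2]),
        control = minpack.lm::nls.lm.control(maxiter = 500))
      p <- coef(nlfit); c(p[["cc"]], p[["tc"]], 1)
    } else {
      nlfit <- minpack.lm::nlsLM(
        k ~ mp * log1p(exp(cc * (tt - tc))), data = df,
        start = list(cc = start[1], tc = start[2], mp = 1),
        control = minpack.lm::nls.lm.control(maxiter = 500))
      p <- coef(nlfit); c(p[["cc"]], p[["tc"]], p[["mp"]])
    }
  }, error = function(e) NULL)

  # Nelder-Mead polish as fallback / tie-break toward the lower SSE
  nm_par <- if (m_prime_fixed) start[1:2] else start
  nm <- optim(nm_par, function(p) sse_of(c(p, 1)[1:3]),
              method = "Nelder-Mead",
              control = list(maxit = 2000, reltol = 1e-14))
  cand <- list(c(nm$par, 1)[1:3])
  if (!is.null(refine)) cand <- c(cand, list(refine))
  sses <- vapply(cand, sse_of, numeric(1))
  if (all(!is.finite(sses))) {
    stop("fit failure: no finite optimum; best grid point c = ",
         signif(start[1], 4), ", tc = ", signif(start[2], 4), call. = FALSE)
  }
  p <- cand[[which.min(sses)]]
  sse <- min(sses)
  sst <- sum((k - mean(k))^2)
  structure(list(
    treatment = treatment,
    c = p[1],
    tc = p[2],
    m_prime = p[3],
    r2 = if (sst > 0) 1 - sse / sst else 1,
    sse = sse,
    n_temps = length(unique(temperature_c)),
    temperature_c = temperature_c,
    k = k
  ), class = "log_logistic_fit")
}

#' @export
print.log_logistic_fit <- function(x, ...) {
  cat(sprintf("<log_logistic_fit> c = %.4f /C, Tc = %.2f C, m' = %.3f, R2 = %.4f\n",
              x$c, x$tc, x$m_prime, x$r2))
  invisible(x)
}

#' Evaluate a log-logistic fit at given temperatures
#'
#' @param fit A `log_logistic_fit`.
#' @param temperature_c Temperatures in degrees Celsius.
#' @return Predicted rate constants (day^-1).
#' @export
log_logistic_rate <- function(fit, temperature_c) {
  stopifnot(inherits(fit, "log_logistic_fit"))
  fit$m_prime * log1p(exp(fit$c * (temperature_c - fit$tc)))
}

#' Fit both secondary models to every treatment of a rate table
#'
#' Consumes the aggregated mean rate constants of a [rate_table()] and fits
#' [fit_arrhenius()] and [fit_log_logistic()] per treatment.
#'
#' @param rates A `rate_table`.
#' @param kelvin_offset Celsius-to-kelvin offset used for the Arrhenius
#'   regression (see [celsius_to_kelvin()]).
#' @return A list with `arrhenius` and `log_logistic` (named lists of fits,
#'   one per treatment) and `table` (a data frame mirroring a published
#'   secondary-parameter table: treatment, ea, k0, r2_arr, c, tc, r2_ll).
#' @export
secondary_table <- function(rates, kelvin_offset = 273.15) {
  stopifnot(inherits(rates, "rate_table"))
  agg <- rates$aggregated
  if (nrow(agg) == 0L) stop("rate table has no aggregates", call. = FALSE)
  out_arr <- list()
  out_ll <- list()
  rows <- list()
  for (tr in unique(agg$treatment)) {
    d <- agg[agg$treatment == tr, ]
    arr <- fit_arrhenius(celsius_to_kelvin(d$temperature_c, kelvin_offset),
                         d$k_mean, treatment = tr)
    ll <- fit_log_logistic(d$temperature_c, d$k_mean, treatment = tr)
    out_arr[[tr]] <- arr
    out_ll[[tr]] <- ll
    rows[[tr]] <- data.frame(
      treatment = tr, ea = arr$ea, k0 = arr$k0, r2_arr = arr$r2,
      c = ll$c, tc = ll$tc, r2_ll = ll$r2, stringsAsFactors = FALSE)
  }
  list(arrhenius = out_arr, log_logistic = out_ll,
       table = do.call(rbind, c(rows, make.row.names = FALSE)))
}
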