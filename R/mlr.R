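#' Dummy-coded multiple linear regression of log TBARS
#'
#' Because TBARS grows exponentially during storage, its natural log is
#' linear in time, so treatments are compared by OLS of `ln(tbars_pct)` on
#' storage day, temperature (degrees Celsius) and one 0/1 dummy per
#' non-control treatment, the control being the uncoded reference level.
#' A more negative treatment coefficient means stronger inhibition of
#' lipid oxidation relative to the control. Coefficient significance is
#' the usual two-sided t-test; a Holm-adjusted p-value column is provided
#' alongside the raw one (which mirrors the conventional presentation) for
#' users who want family-wise control over the treatment contrasts.
#'
#' @param dataset A [kinetic_dataset()] on the percent scale with all
#'   `tbars > 0`, containing `"control"` and at least one other treatment.
#' @return An object of class `mlr_fit`: list with `coefficients` (data
#'   frame of term, estimate, std_error, t_value, p_value, p_holm), scalar
#'   `intercept`, `coef_time`, `coef_temperature`, `r2`, `n`, and the
#'   underlying `lm` object as `fit`.
#' @export
fit_mlr_dummy <- function(dataset) {
  stopifnot(inherits(dataset, "kinetic_dataset"))
  if (dataset$scale[1] != "percent") {
    stop("dataset must be on the percent scale", call. = FALSE)
  }
  if (!"control" %in% dataset$treatment) {
    stop("reference-level error: 'control' treatment absent", call. = FALSE)
  }
  if (any(dataset$tbars <= 0)) {
    stop("domain error: nonpositive tbars", call. = FALSE)
  }
  trts <- treatments(dataset)
  if (length(trts) < 2L) stop("need at least 2 treatments", call. = FALSE)

  df <- data.frame(
    log_tbars = log(dataset$tbars),
    day = dataset$day,
    temperature_c = dataset$temperature_c,
    treatment = factor(dataset$treatment,
                       levels = c("control", setdiff(trts, "control"))))
  fit <- lm(log_tbars ~ day + temperature_c + treatment, data = df)
  if (any(is.na(coef(fit)))) {
    stop("collinearity error: rank-deficient design; aliased column(s): ",
         paste(names(coef(fit))[is.na(coef(fit))], collapse = ", "),
         call. = FALSE)
  }
  sm <- summary(fit)
  co <- sm$coefficients
  terms_ <- rownames(co)
  is_trt <- grepl("^treatment", terms_)
  p_holm <- rep(NA_real_, length(terms_))
  p_holm[is_trt] <- p.adjust(co[is_trt, 4], method = "holm")
  coefs <- data.frame(
    term = sub("^treatment", "", terms_),
    estimate = co[, 1], std_error = co[, 2],
    t_value = co[, 3], p_value = co[, 4], p_holm = p_holm,
    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(
    coefficients = coefs,
    intercept = co["(Intercept)", 1],
    coef_time = co["day", 1],
    coef_temperature = co["temperature_c", 1],
    r2 = sm$r.squared,
    n = nrow(df),
    fit = fit
  ), class = "mlr_fit")
}

#' @importFrom stats p.adjust
#' @export
print.mlr_fit <- function(x, ...) {
  cat(sprintf(paste0("<mlr_fit> n = %d, R2 = %.4f; intercept = %.4f, ",
                     "time = %.4f /day, temperature = %.4f /C, ",
                     "%d treatment dummies\n"),
              x$n, x$r2, x$intercept, x$coef_time, x$coef_temperature,
              sum(!x$coefficients$term %in%
                    c("(Intercept)", "day", "temperature_c"))))
  invisible(x)
}

#' Rank treatment effects from a dummy-coded regression
#'
#' Orders the treatment coefficients ascending (most negative first, i.e.
#' strongest inhibition of oxidation first) and flags coefficients not
#' significant at the given level. Ties are broken alphabetically so the
#' order is deterministic.
#'
#' @param fit An `mlr_fit` from [fit_mlr_dummy()].
#' @param alpha Significance level for the flag (default 0.05).
#' @return Data frame with columns `treatment`, `coefficient`, `p_value`,
#'   `significant`.
#' @export
rank_treatment_effects <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "mlr_fit"))
  co <- fit$coefficients
  trt <- co[!co$term %in% c("(Intercept)", "day", "temperature_c"), ]
  trt <- trt[order(trt$estimate, trt$term), ]
  data.frame(treatment = trt$term,
             coefficient = trt$estimate,
             p_value = trt$p_value,
             significant = trt$p_value <= alpha,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Correlation between DPPH activity and total phenolic content
#'
#' Pearson correlation (with the two-sided t-distribution p-value) between
#' the DPPH radical-scavenging capacity and the total phenolic content of
#' the extract panel.
#'
#' @param table Data frame with numeric columns `dpph_umol_te_g` and
#'   `tpc_mg_gae_g`, at least 3 rows; default is the packaged
#'   [extract_assay_table()].
#' @return List with `r`, `p_value`, `n`.
#' @export
dpph_tpc_correlation <- function(table = extract_assay_table()) {
  stopifnot(is.data.frame(table),
            all(c("dpph_umol_te_g", "tpc_mg_gae_g") %in% names(table)))
  if (nrow(table) < 3L) stop("need at least 3 rows", call. = FALSE)
  if (sd(table$dpph_umol_te_g) == 0 || sd(table$tpc_mg_gae_g) == 0) {
    stop("degeneracy error: zero variance in an assay column",
         call. = FALSE)
  }
  ct <- cor.test(table$dpph_umol_te_g, table$tpc_mg_gae_g,
                 method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = nrow(table))
}
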