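#' Packaged reference tables
#'
#' Small reference tables shipped with the package:
#'
#' * `extract_assay_table()` — antioxidant characterization of the 13 plant
#'   extracts: DPPH radical-scavenging activity (umol Trolox equivalent per
#'   g dry extract) and total phenolic content (mg gallic acid equivalent
#'   per g).
#' * `published_rate_constants()` — published first-order TBARS formation
#'   rate constants (mean and replicate SD, day^-1) for the control and 13
#'   extract-treated beef samples at the four fitting temperatures, indexed
#'   by integer-rounded kelvin (277/281/289/293 K, i.e. 4/8/16/20 degrees C).
#' * `published_secondary_params()` — the secondary-model parameters
#'   published alongside those rate constants (Arrhenius Ea, k0, R2;
#'   log-logistic c, Tc, R2). Note two rows are internally inconsistent
#'   with their own rate constants (the clove Ea sign and the control k0);
#'   see the package vignette. They are shipped verbatim for comparison,
#'   not as ground truth.
#'
#' @return A data frame.
#' @name fixtures
NULL

fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "lipidox")
  if (p == "") stop("packaged fixture not found: ", file, call. = FALSE)
  p
}

#' @rdname fixtures
#' @export
extract_assay_table <- function() {
  tab <- read.csv(fixture_path("extract_assays.csv"),
                  stringsAsFactors = FALSE)
  stopifnot(nrow(tab) == 13L)
  tab
}

#' @rdname fixtures
#' @export
published_rate_constants <- function() {
  read.csv(fixture_path("rate_constants.csv"), stringsAsFactors = FALSE)
}

#' @rdname fixtures
#' @export
published_secondary_params <- function() {
  read.csv(fixture_path("secondary_params_published.csv"),
           stringsAsFactors = FALSE)
}
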