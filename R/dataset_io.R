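#' Construct a kinetic TBARS dataset
#'
#' A `kinetic_dataset` is a data frame of TBARS measurements, one row per
#' record, with columns `treatment`, `temperature_c`, `replicate`, `day`,
#' `tbars` and `scale` (`"raw"` = mg MDA/kg, `"percent"` = percent of the
#' day-0 value). Treatment and temperature level orderings are kept as
#' attributes so that downstream design matrices are reproducible.
#'
#' @param records Data frame with columns `treatment` (character),
#'   `temperature_c` (numeric), `replicate` (positive integer), `day`
#'   (numeric, >= 0), `tbars` (numeric) and optionally `scale`
#'   (all `"raw"` or all `"percent"`; default `"raw"`).
#' @param treatments Optional character vector fixing the treatment order.
#'   Defaults to first appearance, with `"control"` moved to the front when
#'   present.
#' @param temperatures_c Optional numeric vector fixing the temperature
#'   order. Defaults to sorted unique temperatures.
#' @return An object of class `kinetic_dataset`.
#' @examples
#' d <- kinetic_dataset(data.frame(
#'   treatment = "control", temperature_c = 4, replicate = 1L,
#'   day = 0:3, tbars = c(0.5, 0.6, 0.75, 0.9)))
#' treatments(d)
#' @export
kinetic_dataset <- function(records, treatments = NULL, temperatures_c = NULL) {
  required <- c("treatment", "temperature_c", "replicate", "day", "tbars")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0L) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  records <- as.data.frame(records)
  if (is.null(records$scale)) records$scale <- "raw"
  records$treatment <- as.character(records$treatment)
  records$replicate <- as.integer(records$replicate)
  records$scale <- as.character(records$scale)

  if (!all(records$scale %in% c("raw", "percent"))) {
    stop("'scale' must be 'raw' or 'percent'", call. = FALSE)
  }
  if (length(unique(records$scale)) > 1L) {
    stop("mixed 'scale' values in one dataset", call. = FALSE)
  }
  if (any(!is.finite(records$day)) || any(records$day < 0)) {
    stop("'day' must be finite and >= 0", call. = FALSE)
  }
  if (any(!is.finite(records$tbars))) {
    stop("'tbars' must be finite", call. = FALSE)
  }
  dup <- duplicated(records[c("treatment", "temperature_c", "replicate", "day")])
  if (any(dup)) {
    stop("duplicate day within a (treatment, temperature, replicate) group ",
         "at row(s): ", paste(which(dup), collapse = ", "), call. = FALSE)
  }

  if (is.null(treatments)) {
    treatments <- unique(records$treatment)
    if ("control" %in% treatments) {
      treatments <- c("control", setdiff(treatments, "control"))
    }
  }
  if (is.null(temperatures_c)) {
    temperatures_c <- sort(unique(records$temperature_c))
  }
  if (!all(records$treatment %in% treatments)) {
    stop("record treatment not in treatment set", call. = FALSE)
  }
  if (!all(records$temperature_c %in% temperatures_c)) {
    stop("record temperature not in temperature set", call. = FALSE)
  }

  rownames(records) <- NULL
  structure(records,
            treatments = treatments,
            temperatures_c = temperatures_c,
            class = c("kinetic_dataset", "data.frame"))
}

#' @rdname kinetic_dataset
#' @param x A `kinetic_dataset`.
#' @export
treatments <- function(x) attr(x, "treatments")

#' @rdname kinetic_dataset
#' @export
temperatures_c <- function(x) attr(x, "temperatures_c")

#' @export
`[.kinetic_dataset` <- function(x, ...) {
  out <- NextMethod()
  # row subsets keep the dataset class and its level orderings; column
  # selections fall back to plain data frames / vectors
  if (is.data.frame(out) &&
      all(c("treatment", "temperature_c", "replicate", "day",
            "tbars") %in% names(out))) {
    attr(out, "treatments") <- attr(x, "treatments")
    attr(out, "temperatures_c") <- attr(x, "temperatures_c")
    class(out) <- class(x)
  } else if (is.data.frame(out)) {
    class(out) <- "data.frame"
  }
  out
}

#' @export
print.kinetic_dataset <- function(x, ...) {
  cat(sprintf(
    "<kinetic_dataset> %d records, %d treatment(s), %d temperature(s), scale = %s\n",
    nrow(x), length(treatments(x)), length(temperatures_c(x)),
    if (nrow(x)) x$scale[1] else "empty"))
  NextMethod()
}

# group key used everywhere a per-series operation is needed
group_key <- function(records) {
  interaction(records$treatment, records$temperature_c, records$replicate,
              drop = TRUE, lex.order = TRUE)
}

#' Read a tidy TBARS table from CSV
#'
#' The expected dialect is fixed: comma separator, `.` decimal, UTF-8,
#' header row naming at least `treatment,temperature_c,replicate,day,tbars`
#' (a `scale` column is optional and defaults to `"raw"`). Rows with
#' non-numeric `day`, `tbars`, `temperature_c` or `replicate` are rejected
#' with their line numbers.
#'
#' @param path Path to a CSV file.
#' @return A [kinetic_dataset()].
#' @seealso [write_tbars_table()]
#' @export
read_tbars_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                  fileEncoding = "UTF-8")
  if (nrow(raw) == 0L) stop("empty dataset in ", path, call. = FALSE)
  required <- c("treatment", "temperature_c", "replicate", "day", "tbars")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0L) {
    stop("schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "), " in ", path, call. = FALSE)
  }
  numeric_cols <- c("temperature_c", "replicate", "day", "tbars")
  parsed <- lapply(numeric_cols, function(col) {
    suppressWarnings(as.numeric(raw[[col]]))
  })
  names(parsed) <- numeric_cols
  bad <- Reduce(`|`, lapply(parsed, is.na))
  if (any(bad)) {
    # +1 for the header line
    stop("parse error: non-numeric value(s) at line(s) ",
         paste(which(bad) + 1L, collapse = ", "), " of ", path,
         call. = FALSE)
  }
  records <- data.frame(
    treatment = raw$treatment,
    temperature_c = parsed$temperature_c,
    replicate = as.integer(parsed$replicate),
    day = parsed$day,
    tbars = parsed$tbars,
    stringsAsFactors = FALSE)
  if (!is.null(raw$scale)) records$scale <- raw$scale
  kinetic_dataset(records)
}

#' Write a kinetic dataset to tidy CSV
#'
#' Rows are sorted by (treatment, temperature, replicate, day) so the output
#' is byte-deterministic regardless of insertion order.
#'
#' @param dataset A [kinetic_dataset()]; must be non-empty.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tbars_table <- function(dataset, path) {
  stopifnot(inherits(dataset, "kinetic_dataset"))
  if (nrow(dataset) == 0L) stop("refusing to write an empty dataset",
                                call. = FALSE)
  ord <- order(dataset$treatment, dataset$temperature_c,
               dataset$replicate, dataset$day)
  out <- as.data.frame(dataset)[ord, c("treatment", "temperature_c",
                                       "replicate", "day", "tbars", "scale")]
  ok <- tryCatch({
    write.csv(out, path, row.names = FALSE, quote = FALSE,
              fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("I/O error writing ", path, ": ",
                        conditionMessage(ok), call. = FALSE)
  invisible(path)
}

#' Normalize TBARS to percent of the day-0 value
#'
#' Each record's TBARS is divided by its (treatment, temperature, replicate)
#' group's day-0 value and multiplied by 100, so every group starts at
#' exactly 100 %. Idempotent on already-normalized data.
#'
#' @param dataset A [kinetic_dataset()] on the raw (mg MDA/kg) scale; every
#'   group must contain a day-0 record with a positive value.
#' @return The dataset with `tbars` on the percent scale and
#'   `scale = "percent"`.
#' @export
to_percent <- function(dataset) {
  stopifnot(inherits(dataset, "kinetic_dataset"))
  if (nrow(dataset) == 0L) return(dataset)
  if (dataset$scale[1] == "percent") return(dataset)
  key <- group_key(dataset)
  baseline <- rep(NA_real_, nrow(dataset))
  for (g in levels(key)) {
    idx <- which(key == g)
    day0 <- idx[dataset$day[idx] == 0]
    if (length(day0) == 0L) {
      stop("normalization error: group ", g, " lacks a day-0 record",
           call. = FALSE)
    }
    b <- dataset$tbars[day0[1]]
    if (!is.finite(b) || b <= 0) {
      stop("domain error: nonpositive day-0 value in group ", g,
           call. = FALSE)
    }
    baseline[idx] <- b
  }
  dataset$tbars <- 100 * dataset$tbars / baseline
  dataset$scale <- "percent"
  dataset
}
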