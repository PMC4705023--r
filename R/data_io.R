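# Diary ingestion and validation.
#
# An ema_dataset is a tibble carrying three attributes: `variables` (the
# endogenous diary variables, in model order), `date_column` (optional), and
# `exogenous` (optional extra predictor columns). Rows are consecutive daily
# assessments; missing cells are a hard error (never imputed), and calendar
# dates, when present, must advance by exactly one day per row.

new_ema_dataset <- function(data, variables, date_column = NULL,
                            exogenous = character()) {
  out <- tibble::as_tibble(data)
  attr(out, "variables") <- variables
  attr(out, "date_column") <- date_column
  attr(out, "exogenous") <- exogenous
  class(out) <- c("ema_dataset", class(tibble::tibble()))
  out
}

#' Validate a data frame as an EMA diary dataset
#'
#' Checks the invariants every downstream step relies on: all endogenous and
#' exogenous columns are numeric with no missing entries, and calendar dates
#' (if any) are consecutive daily assessments. Day indices throughout the
#' package are 1-based: "day 4" is the fourth assessment row.
#'
#' @param data A data frame or tibble, one row per daily assessment.
#' @param variables Character vector of endogenous variable names. Defaults to
#'   every column that is neither the date column nor listed in `exogenous`.
#' @param date_column Optional name of a calendar-date column (coerced with
#'   [as.Date()]).
#' @param exogenous Optional character vector of exogenous predictor columns
#'   kept alongside the diary (0/1 or numeric).
#' @return An `ema_dataset`: a tibble with attributes `variables`,
#'   `date_column`, `exogenous`.
#' @examples
#' as_ema_dataset(data.frame(Activity = c(30, 60, 45), Depression = c(9, 7, 8)))
#' @export
as_ema_dataset <- function(data, variables = NULL, date_column = NULL,
                           exogenous = NULL) {
  data <- tibble::as_tibble(data)
  exogenous <- exogenous %||% character()
  missing_cols <- setdiff(c(variables, date_column, exogenous), names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("column(s) not found: ", paste(missing_cols, collapse = ", ")))
  }
  if (is.null(variables)) {
    variables <- setdiff(names(data), c(date_column, exogenous))
  }
  if (length(variables) < 1) abort("at least one endogenous variable required")

  if (!is.null(date_column)) {
    dates <- tryCatch(as.Date(data[[date_column]]),
                      error = function(e) abort(paste0(
                        "column ", date_column, " is not parseable as dates")))
    if (anyNA(dates)) {
      abort(paste0("missing or unparseable date at row ",
                   which(is.na(dates))[1]))
    }
    gaps <- diff(as.integer(dates))
    if (any(gaps != 1L)) {
      i <- which(gaps != 1L)[1]
      abort(paste0("assessments must be daily and consecutive: gap between ",
                   "row ", i, " (", dates[i], ") and row ", i + 1,
                   " (", dates[i + 1], ")"))
    }
    data[[date_column]] <- dates
  }

  for (col in c(variables, exogenous)) {
    x <- data[[col]]
    if (is.character(x) || is.factor(x)) {
      x_chr <- trimws(as.character(x))
      num <- suppressWarnings(as.numeric(x_chr))
      bad <- which(!is.na(x_chr) & x_chr != "" & is.na(num))
      if (length(bad) > 0) {
        abort(paste0("non-numeric value at row ", bad[1], ", column ", col,
                     " (", x_chr[bad[1]], ")"))
      }
      num[x_chr == ""] <- NA_real_
      data[[col]] <- num
    } else if (!is.numeric(x)) {
      abort(paste0("column ", col, " must be numeric"))
    }
    if (anyNA(data[[col]])) {
      abort(paste0("missing value at row ", which(is.na(data[[col]]))[1],
                   ", column ", col,
                   " (missing data are not supported; complete or drop the row)"))
    }
  }

  new_ema_dataset(data, variables, date_column, exogenous)
}

#' Read a daily diary from delimited text
#'
#' Reads a CSV or TSV file with a header row (delimiter auto-detected unless
#' given) and validates it with [as_ema_dataset()]. Any missing cell,
#' non-numeric score or non-daily date gap is a hard error naming the
#' offending row and column.
#'
#' @param path Path to a delimited text file with a header row.
#' @param delim Field delimiter; `NULL` auto-detects `","` vs tab from the
#'   header line.
#' @inheritParams as_ema_dataset
#' @return An `ema_dataset`.
#' @seealso [write_diary()] for the inverse.
#' @examples
#' # a small synthetic bivariate diary shipped with the package
#' path <- system.file("extdata", "synthetic_diary.csv", package = "emavar")
#' diary <- read_diary(path, date_column = "date")
#' describe_diary(diary)
#' @export
read_diary <- function(path, variables = NULL, date_column = NULL,
                       exogenous = NULL, delim = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (is.null(delim)) {
    header <- readLines(path, n = 1L)
    delim <- if (grepl("\t", header)) "\t" else ","
  }
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE,
                           col_types = readr::cols(.default = readr::col_character()))
  as_ema_dataset(raw, variables = variables, date_column = date_column,
                 exogenous = exogenous)
}

#' Write a diary dataset back to CSV
#'
#' Values are written at full double precision so that finite decimals
#' round-trip bit-exactly through [read_diary()].
#'
#' @param dataset An `ema_dataset`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_diary <- function(dataset, path) {
  readr::write_csv(tibble::as_tibble(dataset), path, progress = FALSE)
  invisible(path)
}

#' @export
print.ema_dataset <- function(x, ...) {
  cat("<ema_dataset> ", nrow(x), " daily assessments, ",
      length(ema_variables(x)), " endogenous variable(s)\n", sep = "")
  cat("  variables: ", paste(ema_variables(x), collapse = ", "), "\n", sep = "")
  if (!is.null(attr(x, "date_column"))) {
    d <- ema_dates(x)
    cat("  dates: ", format(d[1]), " .. ", format(d[length(d)]), "\n", sep = "")
  }
  if (length(attr(x, "exogenous")) > 0) {
    cat("  exogenous: ", paste(attr(x, "exogenous"), collapse = ", "), "\n",
        sep = "")
  }
  NextMethod()
}

#' Accessors for EMA diary datasets
#'
#' @param dataset An `ema_dataset`.
#' @return `ema_variables()` the endogenous variable names; `ema_values()` the
#'   T x V numeric matrix of diary scores; `ema_dates()` the calendar dates or
#'   `NULL`; `ema_exogenous()` the T x E matrix of exogenous columns (0-column
#'   matrix when none).
#' @export
ema_variables <- function(dataset) attr(dataset, "variables")

#' @rdname ema_variables
#' @export
ema_values <- function(dataset) {
  vars <- ema_variables(dataset)
  m <- as.matrix(tibble::as_tibble(dataset)[vars])
  storage.mode(m) <- "double"
  m
}

#' @rdname ema_variables
#' @export
ema_dates <- function(dataset) {
  dc <- attr(dataset, "date_column")
  if (is.null(dc)) NULL else dataset[[dc]]
}

#' @rdname ema_variables
#' @export
ema_exogenous <- function(dataset) {
  ex <- attr(dataset, "exogenous")
  if (length(ex) == 0) {
    matrix(numeric(0), nrow = nrow(dataset), ncol = 0)
  } else {
    m <- as.matrix(tibble::as_tibble(dataset)[ex])
    storage.mode(m) <- "double"
    m
  }
}

#' Per-variable diary summary
#'
#' One row per endogenous variable with n, mean, sample SD (denominator
#' n - 1), min, max, and the count of exact zeros. The zero count informs the
#' shifted log transform (see [apply_log()]); a zero SD flags a degenerate
#' (constant) series that no VAR can use.
#'
#' @param dataset An `ema_dataset`.
#' @return A tibble with columns `variable`, `n`, `mean`, `sd`, `min`, `max`,
#'   `n_zero`, `degenerate`.
#' @export
describe_diary <- function(dataset) {
  vals <- ema_values(dataset)
  purrr::map_dfr(ema_variables(dataset), function(v) {
    x <- vals[, v]
    tibble::tibble(variable = v, n = length(x), mean = mean(x),
                   sd = stats::sd(x), min = min(x), max = max(x),
                   n_zero = sum(x == 0), degenerate = stats::sd(x) == 0)
  })
}

#' Run configuration for an automated VAR search
#'
#' Bundles every knob of the pipeline. All diagnostic and pruning tests share
#' the single significance level `alpha`.
#'
#' @param max_lag Maximum VAR lag order to enumerate (default 2, the usual
#'   choice for daily diaries where dynamics beyond two days are implausible).
#' @param criterion Information criterion used for pruning and ranking:
#'   `"AIC"` (default) or `"BIC"`.
#' @param timestamps If `TRUE` (default) and the dataset carries dates, the
#'   search branches on weekday dummies (every model is evaluated with and
#'   without them).
#' @param allow_25_sd Extend the outlier-severity ladder from
#'   none < 3.5 < 3.0 SD with a final 2.5 SD rung (off by default). The
#'   ladder order itself never changes.
#' @param alpha Significance level shared by all diagnostic tests, coefficient
#'   pruning, and Granger significance (default 0.05).
#' @param variables Optional subset of endogenous variables to analyse.
#' @param exogenous Optional subset of user exogenous columns to include in
#'   every model.
#' @param seed Optional integer seed recorded with the run (the search itself
#'   is deterministic).
#' @return A `run_config` list.
#' @export
run_config <- function(max_lag = 2, criterion = c("AIC", "BIC"),
                       timestamps = TRUE, allow_25_sd = FALSE, alpha = 0.05,
                       variables = NULL, exogenous = NULL, seed = NULL) {
  criterion <- match.arg(criterion)
  if (max_lag < 1 || max_lag != round(max_lag)) {
    abort("max_lag must be a positive integer")
  }
  if (!(alpha > 0 && alpha < 1)) abort("alpha must lie strictly in (0, 1)")
  structure(list(max_lag = as.integer(max_lag), criterion = criterion,
                 timestamps = isTRUE(timestamps),
                 allow_25_sd = isTRUE(allow_25_sd), alpha = alpha,
                 variables = variables, exogenous = exogenous, seed = seed),
            class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config> max_lag=", x$max_lag, ", criterion=", x$criterion,
      ", timestamps=", x$timestamps, ", allow_25_sd=", x$allow_25_sd,
      ", alpha=", x$alpha, "\n", sep = "")
  invisible(x)
}
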