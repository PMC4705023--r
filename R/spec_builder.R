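# Candidate model structure: the "spec" axis of the search space and the
# machinery that turns a spec into concrete design columns.

.outlier_ladder <- c(3.5, 3.0, 2.5)

# severity rank: none = 0 < 3.5 = 1 < 3.0 = 2 < 2.5 = 3
severity_rank <- function(level) {
  ifelse(is.na(level), 0L, match(level, .outlier_ladder))
}

#' Describe one candidate VAR specification
#'
#' A model spec is one point of the combinatorial search space: lag order,
#' weekday-dummy flag, log-transform flag, a per-variable outlier severity
#' level with the resolved outlier days, the (data-determined) trend flag,
#' user exogenous columns, and the set of coefficients constrained to zero by
#' pruning.
#'
#' @param lag VAR order p (>= 1).
#' @param weekday Include Monday..Saturday one-hot dummies (Sunday reference).
#' @param log_transform Model `log(x + 1)` of every endogenous variable.
#' @param outlier_levels Named numeric vector, one entry per endogenous
#'   variable: `NA` (none), `3.5`, `3.0` or `2.5` residual SDs.
#' @param outlier_days Named list of 1-based diary day indices flagged per
#'   variable (resolved from base-model residuals; see [detect_outliers()]).
#' @param trend Include a linear day-index (1..T) exogenous column.
#' @param user_exogenous Labels of user exogenous columns to include.
#' @param constraints Tibble with columns `equation`, `term`: coefficients
#'   fixed to zero.
#' @param presample Optional number of leading rows to condition on (>= lag).
#'   Direct fits condition on exactly `lag` rows (`T_eff = T - lag`); the
#'   model search sets `presample = max_lag` for every candidate so that
#'   models of different lag order are estimated on a common sample and
#'   their information criteria are comparable.
#' @return A `model_spec`.
#' @export
model_spec <- function(lag, weekday = FALSE, log_transform = FALSE,
                       outlier_levels = NULL, outlier_days = NULL,
                       trend = FALSE, user_exogenous = character(),
                       constraints = NULL, presample = NULL) {
  if (lag < 1 || lag != round(lag)) abort("lag must be a positive integer")
  if (!is.null(outlier_levels)) {
    bad <- !is.na(outlier_levels) & !outlier_levels %in% .outlier_ladder
    if (any(bad)) abort("outlier levels must be NA, 3.5, 3.0 or 2.5")
  }
  constraints <- constraints %||%
    tibble::tibble(equation = character(), term = character())
  if (!is.null(presample) && presample < lag) {
    abort("presample must be at least the lag order")
  }
  structure(list(lag = as.integer(lag), weekday = isTRUE(weekday),
                 log_transform = isTRUE(log_transform),
                 outlier_levels = outlier_levels,
                 outlier_days = outlier_days, trend = isTRUE(trend),
                 user_exogenous = user_exogenous, constraints = constraints,
                 presample = if (is.null(presample)) NULL
                             else as.integer(presample)),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec> ", format_spec(x), "\n", sep = "")
  if (nrow(x$constraints) > 0) {
    cat("  constraints: ",
        paste(x$constraints$equation, x$constraints$term, sep = "~",
              collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

# one-line description used in the model table and text report
format_spec <- function(spec) {
  out <- if (is.null(spec$outlier_levels) || all(is.na(spec$outlier_levels))) {
    "none"
  } else {
    lv <- spec$outlier_levels[!is.na(spec$outlier_levels)]
    paste(purrr::imap_chr(lv, function(l, v) {
      days <- spec$outlier_days[[v]]
      d <- if (is.null(days) || length(days) == 0) "-" else
        paste(days, collapse = "+")
      sprintf("%s:%.1fsd@%s", v, l, d)
    }), collapse = ",")
  }
  sprintf("lag=%d weekday=%s log=%s trend=%s outliers=%s",
          spec$lag, if (spec$weekday) "yes" else "no",
          if (spec$log_transform) "yes" else "no",
          if (spec$trend) "yes" else "no", out)
}

#' Shifted log transform of the diary
#'
#' Replaces every endogenous variable by `log(x + 1)`. The +1 shift keeps
#' legitimate zeros (e.g. zero activity minutes) in the domain; exogenous
#' columns are untouched.
#'
#' @param dataset An `ema_dataset` with all endogenous values >= 0.
#' @param variables Variables to transform (default: all endogenous).
#' @return The transformed `ema_dataset`.
#' @export
apply_log <- function(dataset, variables = NULL) {
  vars <- variables %||% ema_variables(dataset)
  for (v in vars) {
    x <- dataset[[v]]
    if (any(x < 0)) {
      abort(paste0("log transform requires nonnegative values: row ",
                   which(x < 0)[1], ", variable ", v))
    }
    dataset[[v]] <- log1p(x)
  }
  attr(dataset, "log_applied") <- TRUE
  dataset
}

#' Weekday dummy matrix
#'
#' One-hot columns for Monday..Saturday; Sunday is the dropped reference
#' category, so a Sunday row is all zeros.
#'
#' @param dates Consecutive daily calendar dates.
#' @return A `length(dates)` x 6 0/1 matrix with columns `wd_Mon`..`wd_Sat`.
#' @export
weekday_dummies <- function(dates) {
  dates <- as.Date(dates)
  # 1970-01-01 is a Thursday; map to 1 = Monday .. 7 = Sunday, locale-free
  dow <- ((as.integer(dates) + 3L) %% 7L) + 1L
  labs <- paste0("wd_", c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat"))
  m <- matrix(0, nrow = length(dates), ncol = 6L, dimnames = list(NULL, labs))
  for (j in 1:6) m[dow == j, j] <- 1
  m
}

#' Flag residual outlier days
#'
#' A day is an outlier at severity `level` when its residual deviates from the
#' residual mean by more than `level` sample standard deviations. Indices
#' refer to positions in the residual series; callers shift them by the lag
#' offset so they name original diary days.
#'
#' @param residuals Numeric residual series.
#' @param level Severity threshold in SD units: 3.5, 3.0 or 2.5.
#' @return Integer vector of flagged 1-based positions (possibly empty).
#' @export
detect_outliers <- function(residuals, level) {
  s <- stats::sd(residuals)
  if (!is.finite(s) || s == 0) {
    warn("constant residual series: no outliers detectable")
    return(integer(0))
  }
  which(abs(residuals - mean(residuals)) > level * s)
}

#' Materialize a model spec against a dataset
#'
#' Applies the log transform if flagged, then appends the spec's exogenous
#' design columns to the dataset in a fixed order: trend (day index 1..T),
#' weekday dummies, outlier dummies (by endogenous variable, then day), user
#' exogenous columns. Each outlier dummy is a one-hot column named
#' `out_<variable>_d<day>`.
#'
#' @param dataset An `ema_dataset`.
#' @param spec A `model_spec` consistent with the dataset (dates present when
#'   `weekday` is on; exogenous labels exist).
#' @return An `ema_dataset` whose `exogenous` attribute lists exactly the
#'   spec's model exogenous columns, ready for [build_design()].
#' @export
materialize <- function(dataset, spec) {
  n <- nrow(dataset)
  if (spec$log_transform) dataset <- apply_log(dataset)

  cols <- list()
  if (spec$trend) cols$trend <- seq_len(n)
  if (spec$weekday) {
    dates <- ema_dates(dataset)
    if (is.null(dates)) abort("weekday dummies require a date column")
    wd <- weekday_dummies(dates)
    for (j in colnames(wd)) cols[[j]] <- wd[, j]
  }
  for (v in ema_variables(dataset)) {
    days <- spec$outlier_days[[v]]
    for (d in sort(unique(days))) {
      if (d < 1 || d > n) abort(paste0("outlier day ", d, " outside 1..", n))
      one <- numeric(n)
      one[d] <- 1
      cols[[sprintf("out_%s_d%d", v, d)]] <- one
    }
  }
  for (u in spec$user_exogenous) {
    if (!u %in% names(dataset)) abort(paste0("exogenous column not found: ", u))
    cols[[u]] <- dataset[[u]]
  }

  data <- tibble::as_tibble(dataset)[c(attr(dataset, "date_column"),
                                       ema_variables(dataset))]
  for (nm in names(cols)) data[[nm]] <- cols[[nm]]
  new_ema_dataset(data, ema_variables(dataset),
                  date_column = attr(dataset, "date_column"),
                  exogenous = names(cols) %||% character())
}
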