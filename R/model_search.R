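# The combinatorial search: enumerate specs simple-first, resolve outlier
# days lazily from base-model residuals, skip specs dominated by already
# valid simpler ones, run fit -> prune -> validity for the rest, and rank the
# valid models by information criterion.

#' Enumerate the combinatorial model space
#'
#' The space is the Cartesian product of lag order 1..max_lag, weekday
#' dummies off/on (the on branch only when `config$timestamps` and the
#' dataset has dates), log transform off/on, and a per-variable outlier
#' severity level from the ladder none < 3.5 < 3.0 (< 2.5 when
#' `allow_25_sd`). The trend flag is decided from the data by the
#' Phillips-Perron rule before enumeration and is not a search factor.
#' Ordering is simple-first: ascending lag, weekday off before on, log off
#' before on, then outlier severity vectors in lexicographic order, so every
#' specification is preceded by all specifications that could dominate it.
#'
#' @param dataset An `ema_dataset`.
#' @param config A [run_config()].
#' @param trend Optional logical overriding the data-determined trend flag.
#' @return List of `model_spec` (outlier days unresolved), with attributes
#'   `enumerated` (the closed-form count) and `trend`.
#' @export
enumerate_space <- function(dataset, config = run_config(), trend = NULL) {
  vars <- config$variables %||% ema_variables(dataset)
  vals <- ema_values(dataset)[, vars, drop = FALSE]

  if (is.null(trend)) {
    trend <- if (nrow(vals) >= 20) {
      any(purrr::map_lgl(vars,
                         ~ trend_needed(vals[, .x], config$alpha)$include_trend))
    } else FALSE
  }

  weekday_opts <- if (config$timestamps && !is.null(ema_dates(dataset))) {
    c(FALSE, TRUE)
  } else FALSE
  ladder <- c(NA, 3.5, 3.0, if (config$allow_25_sd) 2.5)

  specs <- list()
  sev_grid <- expand.grid(rep(list(seq_along(ladder)), length(vars)))[,
    rev(seq_along(vars)), drop = FALSE]  # first variable varies slowest
  sev_grid <- sev_grid[do.call(order, as.list(sev_grid)), , drop = FALSE]
  for (lag in seq_len(config$max_lag)) {
    for (wd in weekday_opts) {
      for (lg in c(FALSE, TRUE)) {
        for (r in seq_len(nrow(sev_grid))) {
          levels <- ladder[as.integer(sev_grid[r, ])]
          names(levels) <- vars
          specs[[length(specs) + 1L]] <- model_spec(
            lag = lag, weekday = wd, log_transform = lg,
            outlier_levels = levels, trend = trend,
            user_exogenous = config$exogenous %||% character(),
            presample = config$max_lag)
        }
      }
    }
  }
  structure(specs, enumerated = length(specs), trend = trend)
}

# complexity partial order: a dominates b (a "precedes" b) iff they share
# lag/weekday/log/trend and a's outlier severity is weaker-or-equal
# everywhere, strictly weaker somewhere
dominates <- function(a, b) {
  if (a$lag != b$lag || a$weekday != b$weekday ||
      a$log_transform != b$log_transform || a$trend != b$trend) return(FALSE)
  ra <- severity_rank(a$outlier_levels)
  rb <- severity_rank(b$outlier_levels)
  all(ra <= rb) && any(ra < rb)
}

#' Is a candidate specification redundant?
#'
#' A candidate is redundant when some already-valid tested specification
#' shares its lag, weekday, log and trend factors and has weaker-or-equal
#' outlier severity on every variable (strictly weaker on at least one): a
#' valid model without modeled outliers makes the same model with modeled
#' outliers redundant.
#'
#' @param spec Candidate `model_spec`.
#' @param valid_specs List of valid, already-tested specs.
#' @return List with `redundant` flag and `dominated_by` (index into
#'   `valid_specs`, or `NA`).
#' @export
is_redundant <- function(spec, valid_specs) {
  for (i in seq_along(valid_specs)) {
    if (dominates(valid_specs[[i]], spec)) {
      return(list(redundant = TRUE, dominated_by = i))
    }
  }
  list(redundant = FALSE, dominated_by = NA_integer_)
}

#' Run the automated VAR model search
#'
#' Iterates the enumerated specifications in simple-first order. For each
#' non-redundant candidate: outlier days are resolved from the residuals of
#' the unconstrained no-outlier fit sharing the same lag/weekday/log/trend
#' factors (single-pass detection), the model is estimated, nonsignificant
#' coefficients are pruned under the criterion-decrease rule, and the final
#' model is gated on the four validity tests. Candidates dominated by an
#' already-valid simpler model are skipped and their dominating model
#' recorded; candidates with more regressors than effective observations are
#' recorded as infeasible (counted under tested). The search is deterministic
#' given the dataset and configuration.
#'
#' @param dataset An `ema_dataset` with at least two endogenous variables.
#' @param config A [run_config()].
#' @param verbose Log each model tested or skipped with its reason.
#' @return A `var_search` object: `models` (one row per specification, with
#'   list-columns `spec`, `fit`, `report`), the bookkeeping counts
#'   (`enumerated = tested + skipped_redundant`), and the criterion used.
#'   Valid models carry ascending `rank` by the chosen criterion (ties broken
#'   by smaller k, then enumeration order).
#' @export
run_search <- function(dataset, config = run_config(), verbose = FALSE) {
  vars <- config$variables %||% ema_variables(dataset)
  if (length(vars) < 2) {
    abort("a Granger analysis run requires at least 2 endogenous variables")
  }
  if (!identical(vars, ema_variables(dataset)) || !is.null(config$variables)) {
    keep <- c(attr(dataset, "date_column"), vars,
              config$exogenous %||% character())
    dataset <- new_ema_dataset(tibble::as_tibble(dataset)[keep], vars,
                               attr(dataset, "date_column"),
                               config$exogenous %||% character())
  }
  if (nrow(dataset) < 50) {
    warn(paste0("only ", nrow(dataset), " assessments; intensive time-series ",
                "designs are usually based on at least 50"))
  }

  specs <- enumerate_space(dataset, config)
  say <- function(...) if (verbose) message(sprintf(...))

  base_cache <- new.env(parent = emptyenv())
  base_residuals <- function(spec) {
    key <- paste(spec$lag, spec$weekday, spec$log_transform, sep = "|")
    if (!is.null(base_cache[[key]])) return(base_cache[[key]])
    base_spec <- model_spec(lag = spec$lag, weekday = spec$weekday,
                            log_transform = spec$log_transform,
                            trend = spec$trend,
                            user_exogenous = spec$user_exogenous,
                            presample = spec$presample)
    res <- fit_var(dataset, base_spec, inference = FALSE)$residuals
    base_cache[[key]] <- res
    res
  }

  rows <- list()
  valid_specs <- list()
  valid_ids <- integer(0)

  for (i in seq_along(specs)) {
    spec <- specs[[i]]
    row <- tibble::tibble(
      id = i, lag = spec$lag, weekday = spec$weekday,
      log_transform = spec$log_transform, trend = spec$trend,
      outliers = NA_character_, status = NA_character_,
      dominated_by = NA_integer_, k = NA_integer_, logL = NA_real_,
      AIC = NA_real_, BIC = NA_real_, valid = FALSE, reason = NA_character_)

    red <- is_redundant(spec, valid_specs)
    if (red$redundant) {
      row$status <- "skipped_redundant"
      row$dominated_by <- valid_ids[red$dominated_by]
      row$outliers <- format_spec(spec)
      say("spec %d skipped (redundant, dominated by %d): %s", i,
          row$dominated_by, format_spec(spec))
      rows[[i]] <- c(as.list(row), list(spec = list(spec), fit = list(NULL),
                                        fit_unpruned = list(NULL),
                                        report = list(NULL)))
      next
    }

    result <- tryCatch({
      if (!is.null(spec$outlier_levels) && any(!is.na(spec$outlier_levels))) {
        res <- base_residuals(spec)
        off <- max(spec$lag, spec$presample %||% spec$lag)
        spec$outlier_days <- purrr::imap(spec$outlier_levels, function(l, v) {
          if (is.na(l)) return(integer(0))
          detect_outliers(res[, v], l) + off
        })
      }
      fit0 <- fit_var(dataset, spec)
      fit <- prune_parameters(dataset, fit0, criterion = config$criterion,
                              alpha = config$alpha)
      report <- assess_validity(fit, alpha = config$alpha)
      list(spec = fit$spec, fit = fit, fit_unpruned = fit0, report = report,
           status = "tested", reason = NA_character_)
    }, error = function(e) {
      msg <- conditionMessage(e)
      status <- if (grepl("insufficient observations", msg)) "infeasible"
                else "error"
      list(spec = spec, fit = NULL, fit_unpruned = NULL, report = NULL,
           status = status, reason = msg)
    })

    spec <- result$spec
    row$status <- result$status
    row$reason <- result$reason
    row$outliers <- format_spec(spec)
    if (!is.null(result$fit)) {
      row$k <- result$fit$k
      row$logL <- result$fit$logL
      row$AIC <- result$fit$AIC
      row$BIC <- result$fit$BIC
      row$valid <- result$report$overall_valid
    }
    say("spec %d %s%s: %s", i, row$status,
        if (row$valid) " VALID" else "", format_spec(spec))
    if (row$valid) {
      valid_specs[[length(valid_specs) + 1L]] <- spec
      valid_ids <- c(valid_ids, i)
    }
    rows[[i]] <- c(as.list(row), list(spec = list(spec),
                                      fit = list(result$fit),
                                      fit_unpruned = list(result$fit_unpruned),
                                      report = list(result$report)))
  }

  models <- dplyr::bind_rows(purrr::map(rows, tibble::as_tibble))
  crit_col <- models[[config$criterion]]
  vidx <- which(models$valid)
  models$rank <- NA_integer_
  if (length(vidx) > 0) {
    ord <- vidx[order(crit_col[vidx], models$k[vidx], models$id[vidx])]
    models$rank[ord] <- seq_along(ord)
  }

  structure(list(models = models,
                 enumerated = attr(specs, "enumerated"),
                 tested = sum(models$status != "skipped_redundant"),
                 skipped_redundant = sum(models$status == "skipped_redundant"),
                 n_valid = sum(models$valid),
                 criterion = config$criterion, alpha = config$alpha,
                 trend = attr(specs, "trend"), variables = vars,
                 config = config, dataset = dataset),
            class = "var_search")
}

#' Valid models of a search, in rank order
#'
#' @param search A `var_search`.
#' @return The `models` rows with `valid == TRUE`, ordered by `rank` (fits
#'   and validity reports in the list-columns).
#' @export
valid_models <- function(search) {
  m <- search$models[search$models$valid, , drop = FALSE]
  if (nrow(m) == 0 || is.null(m$rank)) return(m)
  m[order(m$rank), , drop = FALSE]
}

#' @export
print.var_search <- function(x, ...) {
  cat("<var_search> ", x$tested, " of ", x$enumerated,
      " specifications tested (",
      sprintf("%.1f%%", 100 * x$tested / x$enumerated), "), ",
      x$skipped_redundant, " skipped as redundant, ", x$n_valid,
      " valid\n", sep = "")
  vm <- valid_models(x)
  if (nrow(vm) > 0) {
    best <- vm[1, ]
    cat(sprintf("  best (%s): %s | AIC %.2f, BIC %.2f\n", x$criterion,
                best$outliers, best$AIC, best$BIC))
  }
  invisible(x)
}

#' Tidy the model table of a search
#'
#' @param x A `var_search`.
#' @param ... Unused.
#' @return One row per enumerated specification, without list-columns.
#' @export
tidy.var_search <- function(x, ...) {
  dplyr::select(x$models,
                -dplyr::any_of(c("spec", "fit", "fit_unpruned", "report")))
}

#' One-row bookkeeping summary of a search
#'
#' @param x A `var_search`.
#' @param ... Unused.
#' @return Tibble with `enumerated`, `tested`, `skipped_redundant`,
#'   `n_valid`, `criterion`, `trend`.
#' @export
glance.var_search <- function(x, ...) {
  tibble::tibble(enumerated = x$enumerated, tested = x$tested,
                 skipped_redundant = x$skipped_redundant,
                 n_valid = x$n_valid, criterion = x$criterion,
                 trend = x$trend)
}
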