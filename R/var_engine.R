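# VAR estimation core: design construction, equation-wise OLS with zero
# constraints, Gaussian system likelihood, information criteria, and the
# criterion-decrease coefficient pruning loop.
#
# Every equation shares one regressor matrix [const | lags 1..p | exogenous];
# constraints remove columns from an individual equation's regressor set, so
# equations remain separable ordinary least squares problems.

lag_labels <- function(vars, p) {
  unlist(lapply(seq_len(p), function(l) paste0(vars, ".l", l)))
}

#' Build the common VAR design matrices
#'
#' Stacks the response rows `o+1..T` (with `o = max(lag, presample)`, the
#' conditioning offset) and the regressor matrix in the fixed column order:
#' intercept, lagged endogenous variables at lags 1..p, then the
#' materialized exogenous columns (trend, weekday dummies, outlier dummies,
#' user exogenous). Every equation uses this same matrix.
#'
#' @param dataset A materialized `ema_dataset` (see [materialize()]).
#' @param spec A `model_spec` (only the lag order and presample are used
#'   here).
#' @return A list with `Y` (T_eff x V response), `X` (T_eff x K regressors),
#'   and `labels` (the K column labels).
#' @export
build_design <- function(dataset, spec) {
  y0 <- ema_values(dataset)
  vars <- colnames(y0)
  n <- nrow(y0)
  p <- spec$lag
  o <- max(p, spec$presample %||% p)
  if (n <= o) abort("series shorter than the conditioning presample")
  t_eff <- n - o

  y <- y0[(o + 1):n, , drop = FALSE]
  lagged <- do.call(cbind, lapply(seq_len(p), function(l) {
    m <- y0[(o + 1 - l):(n - l), , drop = FALSE]
    colnames(m) <- paste0(vars, ".l", l)
    m
  }))
  exog <- ema_exogenous(dataset)
  exog <- exog[(o + 1):n, , drop = FALSE]
  x <- cbind(const = 1, lagged, exog)
  labels <- colnames(x)

  if (t_eff < ncol(x)) {
    abort(sprintf(
      "insufficient observations: %d effective rows for %d regressors",
      t_eff, ncol(x)))
  }
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    drop <- labels[qx$pivot[(qx$rank + 1):ncol(x)]]
    abort(paste0("rank-deficient design: collinear column(s) ",
                 paste(drop, collapse = ", ")))
  }
  list(Y = y, X = x, labels = labels)
}

free_terms <- function(labels, constraints, eq) {
  setdiff(labels, constraints$term[constraints$equation == eq])
}

#' Estimate a VAR specification by equation-wise least squares
#'
#' Each endogenous variable is regressed on the shared design; coefficients
#' listed in `spec$constraints` are removed from that equation's regressor set
#' and reported as exact zeros with no degrees-of-freedom contribution. The
#' residual covariance uses divisor T_eff, the system log-likelihood is the
#' Gaussian one including additive constants, and
#' `AIC = -2 logL + 2k`, `BIC = -2 logL + k log(T)` with nominal series
#' length T and k the count of freely estimated regression coefficients
#' (intercepts included; covariance entries not counted), so
#' `BIC - AIC = k (log T - 2)` exactly. Coefficient p-values come from the t
#' distribution with per-equation residual degrees of freedom.
#'
#' @param dataset An `ema_dataset` (materialized internally).
#' @param spec A `model_spec`.
#' @param inference Compute standard errors, p-values and the likelihood
#'   (default). With `inference = FALSE` only coefficients and residuals are
#'   returned, which permits fitting a degenerate (zero residual variance)
#'   system whose inference would be undefined.
#' @return A `var_fit` object; see [tidy.var_fit()] and [glance.var_fit()].
#' @export
fit_var <- function(dataset, spec, inference = TRUE) {
  mat <- materialize(dataset, spec)
  d <- build_design(mat, spec)
  if (spec$log_transform) {
    # change-of-variables term: report the likelihood of log-transformed
    # models in raw-data units so AIC/BIC are comparable across the
    # transform branch (y* = log(y+1) has log-Jacobian -sum log(y+1))
    raw <- ema_values(dataset)
    n <- nrow(raw)
    o <- max(spec$lag, spec$presample %||% spec$lag)
    d$logL_adjust <- -sum(log1p(raw[(o + 1):n, , drop = FALSE]))
  }
  fit_from_design(d, spec, n_nominal = nrow(dataset), inference = inference)
}

# OLS core over a prebuilt design; lets the pruning loop refit without
# re-materializing the dataset
fit_from_design <- function(d, spec, n_nominal, inference = TRUE) {
  vars <- colnames(d$Y)
  v <- length(vars)
  t_eff <- nrow(d$Y)

  coefs <- matrix(0, nrow = length(d$labels), ncol = v,
                  dimnames = list(d$labels, vars))
  se <- p_val <- matrix(NA_real_, nrow = length(d$labels), ncol = v,
                        dimnames = list(d$labels, vars))
  resid <- matrix(NA_real_, nrow = t_eff, ncol = v,
                  dimnames = list(NULL, vars))
  cov_list <- vector("list", v)
  names(cov_list) <- vars
  k_eq <- integer(v)

  for (i in seq_len(v)) {
    free <- free_terms(d$labels, spec$constraints, vars[i])
    if (length(free) == 0) {
      resid[, i] <- d$Y[, i]
      next
    }
    xf <- d$X[, free, drop = FALSE]
    fit <- stats::lm.fit(xf, d$Y[, i])
    coefs[free, i] <- fit$coefficients
    resid[, i] <- fit$residuals
    k_eq[i] <- length(free)
  }
  k <- sum(k_eq)
  sigma <- crossprod(resid) / t_eff

  scale_ref <- colMeans(d$Y^2) + 1
  degenerate <- any(diag(sigma) < 1e-12 * scale_ref)

  log_l <- aic <- bic <- NA_real_
  if (!degenerate) {
    ldet <- determinant(sigma, logarithm = TRUE)
    log_l <- -(t_eff / 2) * (v * log(2 * pi) + as.numeric(ldet$modulus) + v) +
      (d$logL_adjust %||% 0)
    aic <- -2 * log_l + 2 * k
    bic <- -2 * log_l + k * log(n_nominal)
  }

  if (inference) {
    if (degenerate) {
      abort("degenerate fit: zero residual variance, inference undefined")
    }
    for (i in seq_len(v)) {
      free <- free_terms(d$labels, spec$constraints, vars[i])
      if (length(free) == 0) next
      df <- t_eff - k_eq[i]
      if (df <= 0) abort("no residual degrees of freedom for inference")
      xf <- d$X[, free, drop = FALSE]
      xtx_inv <- chol2inv(chol(crossprod(xf)))
      s2 <- sum(resid[, i]^2) / df
      covb <- s2 * xtx_inv
      dimnames(covb) <- list(free, free)
      cov_list[[i]] <- covb
      se_i <- sqrt(diag(covb))
      tval <- coefs[free, i] / se_i
      se[free, i] <- se_i
      p_val[free, i] <- 2 * stats::pt(-abs(tval), df)
    }
  }

  structure(list(spec = spec, variables = vars, labels = d$labels,
                 coefficients = coefs, se = se, p_values = p_val,
                 residuals = resid, sigma = sigma, k = k, k_eq = k_eq,
                 logL = log_l, AIC = aic, BIC = bic, T = n_nominal,
                 T_eff = t_eff, cov = cov_list,
                 constraints = spec$constraints, design = d,
                 degenerate = degenerate),
            class = "var_fit")
}

#' Lag coefficient matrices of a fitted VAR
#'
#' @param fit A `var_fit`.
#' @return List of p V x V matrices; entry `[i, j]` of matrix l is the
#'   coefficient of variable j at lag l in equation i.
#' @export
lag_matrices <- function(fit) {
  vars <- fit$variables
  lapply(seq_len(fit$spec$lag), function(l) {
    m <- t(fit$coefficients[paste0(vars, ".l", l), , drop = FALSE])
    dimnames(m) <- list(vars, vars)
    m
  })
}

#' Information criteria of a fitted VAR
#'
#' @param fit A `var_fit`.
#' @return A one-row tibble with `AIC`, `BIC`, `k`, `logL`, `T`.
#' @export
information_criteria <- function(fit) {
  tibble::tibble(AIC = fit$AIC, BIC = fit$BIC, k = fit$k, logL = fit$logL,
                 T = fit$T)
}

#' @export
print.var_fit <- function(x, ...) {
  cat("<var_fit> ", format_spec(x$spec), "\n", sep = "")
  cat(sprintf("  T=%d (T_eff=%d), k=%d, logL=%.3f, AIC=%.2f, BIC=%.2f\n",
              x$T, x$T_eff, x$k, x$logL, x$AIC, x$BIC))
  invisible(x)
}

#' Tidy a fitted VAR into a coefficient table
#'
#' @param x A `var_fit`.
#' @param ... Unused.
#' @return A tibble with one row per (equation, term): `estimate`,
#'   `std.error`, `p.value`, and `constrained` (coefficient fixed to zero by
#'   pruning).
#' @export
tidy.var_fit <- function(x, ...) {
  purrr::map_dfr(x$variables, function(eq) {
    con <- x$constraints$term[x$constraints$equation == eq]
    tibble::tibble(equation = eq, term = x$labels,
                   estimate = x$coefficients[, eq],
                   std.error = x$se[, eq], p.value = x$p_values[, eq],
                   constrained = x$labels %in% con)
  })
}

#' One-row model summary of a fitted VAR
#'
#' @param x A `var_fit`.
#' @param ... Unused.
#' @return Tibble with `k`, `logL`, `AIC`, `BIC`, `T`, `T_eff`,
#'   `n_constraints`.
#' @export
glance.var_fit <- function(x, ...) {
  tibble::tibble(k = x$k, logL = x$logL, AIC = x$AIC, BIC = x$BIC, T = x$T,
                 T_eff = x$T_eff, n_constraints = nrow(x$constraints))
}

#' Prune nonsignificant coefficients under the criterion-decrease rule
#'
#' Iteratively constrains to zero the single lag or exogenous coefficient with
#' the highest p-value above `alpha` (intercepts are never pruned), refits,
#' and keeps the constraint only if the chosen information criterion strictly
#' decreased; otherwise the step is reverted and pruning stops. After every
#' accepted constraint the four validity assumptions are re-checked and the
#' reports attached. Ties in the highest p-value are broken by the fixed
#' regressor order (first equation, then first term label, wins).
#'
#' @param dataset The `ema_dataset` the fit was estimated on.
#' @param fit A `var_fit`.
#' @param criterion `"AIC"` or `"BIC"`.
#' @param alpha Significance level below which a coefficient is kept.
#' @return A `var_fit` with updated constraints and attributes
#'   `pruning` (step log tibble) and `pruning_validity` (list of
#'   `validity_report`s after each accepted step).
#' @export
prune_parameters <- function(dataset, fit, criterion = c("AIC", "BIC"),
                             alpha = 0.05) {
  criterion <- match.arg(criterion)
  crit <- function(f) f[[criterion]]
  log_rows <- list()
  reports <- list()
  step <- 0L

  repeat {
    # candidate pool straight off the p-value matrix: lag/exogenous terms
    # only (row 1 is the intercept), unconstrained, p above alpha; the matrix
    # walks terms within equations, so which.max's first-hit rule realizes
    # the fixed-order tie-break
    pmat <- fit$p_values[-1, , drop = FALSE]
    pmat[is.na(pmat)] <- -Inf
    if (all(pmat <= alpha)) break
    idx <- which.max(t(pmat))  # scans terms outer, equations inner
    n_eq <- ncol(pmat)
    eq_i <- (idx - 1) %% n_eq + 1
    term_i <- (idx - 1) %/% n_eq + 2
    pick <- list(equation = fit$variables[eq_i],
                 term = fit$labels[term_i],
                 p.value = fit$p_values[term_i, eq_i])

    spec2 <- fit$spec
    spec2$constraints <- tibble::new_tibble(list(
      equation = c(fit$constraints$equation, pick$equation),
      term = c(fit$constraints$term, pick$term)),
      nrow = nrow(fit$constraints) + 1L)
    fit2 <- fit_from_design(fit$design, spec2, n_nominal = fit$T)

    step <- step + 1L
    accepted <- crit(fit2) < crit(fit)
    log_rows[[step]] <- tibble::new_tibble(list(
      step = step, equation = pick$equation, term = pick$term,
      p_removed = pick$p.value, criterion_before = crit(fit),
      criterion_after = crit(fit2), accepted = accepted), nrow = 1L)
    if (!accepted) break
    fit <- fit2
    reports[[length(reports) + 1L]] <- assess_validity(fit, alpha = alpha)
  }

  attr(fit, "pruning") <- if (length(log_rows) == 0) {
    tibble::tibble(step = integer(), equation = character(),
                   term = character(), p_removed = numeric(),
                   criterion_before = numeric(), criterion_after = numeric(),
                   accepted = logical())
  } else {
    dplyr::bind_rows(log_rows)
  }
  attr(fit, "pruning_validity") <- reports
  attr(fit, "pruning_criterion") <- criterion
  fit
}

#' Export a fitted model as JSON
#'
#' Structured-text export: spec descriptor, the full coefficient table
#' (estimate, standard error, p-value, constrained flag), and the fit summary.
#'
#' @param fit A `var_fit`.
#' @param path Optional file to write to.
#' @return The JSON string, invisibly when `path` is given.
#' @export
model_to_json <- function(fit, path = NULL) {
  payload <- list(spec = format_spec(fit$spec),
                  lag = fit$spec$lag,
                  coefficients = tidy(fit),
                  summary = glance(fit))
  js <- jsonlite::toJSON(payload, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, na = "null", pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
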