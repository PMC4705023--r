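# The validity gate: eigenvalue stability, Ljung-Box white noise,
# Ljung-Box on squared residuals (homoscedasticity), Jarque-Bera normality,
# plus the Phillips-Perron trend decision. A model is valid only when the
# stability condition holds and every residual test is nonsignificant for
# every variable.

#' Portmanteau (Ljung-Box) test for residual autocorrelation
#'
#' `Q = n (n + 2) * sum_{j=1..h} r_j^2 / (n - j)` with sample autocorrelations
#' `r_j`, referred to a chi-square with `df = h` (no reduction for fitted lag
#' order). The homoscedasticity variant applies the same statistic to the
#' squared residuals.
#'
#' @param x Residual series (length n > h), nonconstant.
#' @param h Maximum autocorrelation lag tested (>= 1).
#' @return List with `statistic`, `df`, `p_value`.
#' @export
ljung_box <- function(x, h) {
  n <- length(x)
  if (h < 1) abort("h must be >= 1")
  if (n <= h) abort("series must be longer than h")
  if (stats::sd(x) == 0) abort("zero variance: constant series")
  r <- as.numeric(stats::acf(x, lag.max = h, plot = FALSE,
                             demean = TRUE)$acf)[-1]
  q <- n * (n + 2) * sum(r^2 / (n - seq_len(h)))
  list(statistic = q, df = h,
       p_value = stats::pchisq(q, df = h, lower.tail = FALSE))
}

#' Skewness-kurtosis (Jarque-Bera) normality test
#'
#' `JB = n/6 * (S^2 + (K - 3)^2 / 4)` with moment-based sample skewness S and
#' kurtosis K (population-moment divisors), referred to a chi-square with 2
#' degrees of freedom.
#'
#' @param x Residual series, nonconstant; a warning is issued below n = 8
#'   where the chi-square reference is unreliable.
#' @return List with `statistic`, `skewness`, `kurtosis`, `p_value`.
#' @export
jarque_bera <- function(x) {
  n <- length(x)
  if (stats::sd(x) == 0) abort("zero variance: constant series")
  if (n < 8) warn("Jarque-Bera on fewer than 8 observations is unreliable")
  m <- mean(x)
  s2 <- mean((x - m)^2)
  s <- mean((x - m)^3) / s2^1.5
  k <- mean((x - m)^4) / s2^2
  jb <- n / 6 * (s^2 + (k - 3)^2 / 4)
  list(statistic = jb, skewness = s, kurtosis = k,
       p_value = stats::pchisq(jb, df = 2, lower.tail = FALSE))
}

#' Eigenvalue stability condition
#'
#' Builds the pV x pV companion matrix of the lag coefficient matrices; the
#' VAR is stable (stationary) when every eigenvalue modulus is strictly below
#' one.
#'
#' @param fit A `var_fit`, or a list of p V x V lag matrices.
#' @return List with `max_modulus`, `pass`, `eigenvalues`.
#' @export
stability_check <- function(fit) {
  mats <- if (inherits(fit, "var_fit")) lag_matrices(fit) else fit
  comp <- companion_matrix(mats)
  ev <- eigen(comp, only.values = TRUE)$values
  mm <- max(Mod(ev))
  list(max_modulus = mm, pass = mm < 1, eigenvalues = ev)
}

companion_matrix <- function(mats) {
  p <- length(mats)
  v <- nrow(mats[[1]])
  top <- do.call(cbind, mats)
  if (p == 1) return(top)
  rbind(top, cbind(diag(1, v * (p - 1)), matrix(0, v * (p - 1), v)))
}

#' Decide whether a linear trend term is needed
#'
#' Runs the Phillips-Perron unit-root test with an intercept-plus-trend
#' regression (Newey-West truncation lag `floor(4 * (T/100)^(1/4))`). A
#' significant test means the series is stationary around a deterministic
#' trend, and a linear day-index regressor is then added to every model as an
#' exogenous variable. Note the literal rule also fires for trendless
#' stationary series; see the package vignette.
#'
#' @param x Endogenous series of length >= 20.
#' @param alpha Significance level.
#' @return List with `statistic`, `p_value`, `include_trend`.
#' @export
trend_needed <- function(x, alpha = 0.05) {
  if (length(x) < 20) abort("trend decision requires at least 20 observations")
  if (stats::sd(x) == 0) {
    warn("constant series: trend test skipped")
    return(list(statistic = NA_real_, p_value = NA_real_,
                include_trend = FALSE))
  }
  pp <- stats::PP.test(x, lshort = TRUE)
  list(statistic = unname(pp$statistic), p_value = pp$p.value,
       include_trend = pp$p.value < alpha)
}

#' Run the four-test validity gate on a fitted VAR
#'
#' Stability is checked once; the Ljung-Box test on residuals, the Ljung-Box
#' test on squared residuals, and the Jarque-Bera test run per variable with
#' Portmanteau lag `h = min(12, floor(T_eff / 4))`. The model is valid only
#' when stability passes and every per-variable test is nonsignificant at
#' `alpha`.
#'
#' @param fit A `var_fit` with residuals for every variable.
#' @param alpha Shared significance level.
#' @param h Portmanteau maximum lag; default `min(12, floor(T_eff / 4))`.
#' @return A `validity_report`; see [tidy.validity_report()].
#' @export
assess_validity <- function(fit, alpha = 0.05, h = NULL) {
  h <- h %||% min(12L, floor(fit$T_eff / 4))
  h <- max(1L, h)
  st <- stability_check(fit)

  per_var <- function(f) {
    rs <- lapply(fit$variables, function(v) f(fit$residuals[, v]))
    pv <- vapply(rs, `[[`, 0, "p_value")
    tibble::new_tibble(list(
      variable = fit$variables,
      statistic = vapply(rs, `[[`, 0, "statistic"),
      df = vapply(rs, function(r) as.integer(r$df %||% NA_integer_), 0L),
      p_value = pv, pass = pv >= alpha), nrow = length(rs))
  }
  wn <- per_var(function(e) ljung_box(e, h))
  hs <- per_var(function(e) ljung_box(e^2, h))
  nm <- per_var(jarque_bera)

  structure(list(stability = st[c("max_modulus", "pass")],
                 white_noise = wn, homoscedasticity = hs, normality = nm,
                 overall_valid = st$pass && all(wn$pass) && all(hs$pass) &&
                   all(nm$pass),
                 alpha = alpha, h = h),
            class = "validity_report")
}

#' @export
print.validity_report <- function(x, ...) {
  cat("<validity_report> overall ",
      if (x$overall_valid) "VALID" else "invalid",
      sprintf(" (alpha=%.3g, h=%d)\n", x$alpha, x$h), sep = "")
  cat(sprintf("  stability: max |eigenvalue| = %.4f (%s)\n",
              x$stability$max_modulus,
              if (x$stability$pass) "pass" else "FAIL"))
  print(tidy(x), n = Inf)
  invisible(x)
}

#' Tidy a validity report into one row per test
#'
#' @param x A `validity_report`.
#' @param ... Unused.
#' @return Tibble with `test`, `variable`, `statistic`, `df`, `p_value`,
#'   `pass`.
#' @export
tidy.validity_report <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(test = "stability", variable = NA_character_,
                   statistic = x$stability$max_modulus, df = NA_integer_,
                   p_value = NA_real_, pass = x$stability$pass),
    dplyr::mutate(x$white_noise, test = "white_noise", .before = 1),
    dplyr::mutate(x$homoscedasticity, test = "homoscedasticity", .before = 1),
    dplyr::mutate(x$normality, test = "normality", .before = 1))
}
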