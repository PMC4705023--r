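# Independent oracles used across the suite. Each one deliberately avoids
# the code path it checks: OLS through explicit normal equations, stability
# through roots of the reverse characteristic polynomial, Granger through a
# restricted-vs-unrestricted residual-sum-of-squares F test, and a minimal
# regex DOT reader for graph round-trips.

# normal-equation least squares: solve (X'X) b = X'y directly
ols_oracle <- function(x, y) {
  as.numeric(solve(crossprod(x), crossprod(x, y)))
}

# polynomial product, coefficient vectors in ascending powers
poly_mult <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1)
  for (i in seq_along(a)) {
    out[i:(i + length(b) - 1)] <- out[i:(i + length(b) - 1)] + a[i] * b
  }
  out
}

# stability via det(I - A1 z - ... - Ap z^p): stable iff all roots |z| > 1.
# Handles V = 1 and V = 2 (2x2 determinant expanded by polynomial algebra).
stability_oracle <- function(lag_mats) {
  p <- length(lag_mats)
  v <- nrow(lag_mats[[1]])
  entry_poly <- function(i, j) {
    c(as.numeric(i == j), -vapply(lag_mats, function(a) a[i, j], 0))
  }
  det_poly <- if (v == 1) {
    entry_poly(1, 1)
  } else if (v == 2) {
    poly_mult(entry_poly(1, 1), entry_poly(2, 2)) -
      poly_mult(entry_poly(1, 2), entry_poly(2, 1))
  } else {
    stop("oracle implemented for V <= 2")
  }
  roots <- polyroot(det_poly)
  all(Mod(roots) > 1)
}

# restricted-vs-unrestricted F test for Granger causality in one equation,
# computed from scratch with lm() on hand-built lag columns
granger_f_oracle <- function(values, cause, effect, p) {
  n <- nrow(values)
  y <- values[(p + 1):n, effect]
  lags <- do.call(cbind, lapply(seq_len(p), function(l) {
    m <- values[(p + 1 - l):(n - l), , drop = FALSE]
    colnames(m) <- paste0(colnames(values), ".l", l)
    m
  }))
  unres <- lm(y ~ lags)
  keep <- !grepl(paste0("^", cause, "\\.l"), colnames(lags))
  res <- lm(y ~ lags[, keep, drop = FALSE])
  rss_u <- sum(resid(unres)^2)
  rss_r <- sum(resid(res)^2)
  q <- p
  df2 <- length(y) - ncol(lags) - 1
  f <- ((rss_r - rss_u) / q) / (rss_u / df2)
  list(f = f, q = q, df2 = df2, p_value = pf(f, q, df2, lower.tail = FALSE),
       wald_equiv = (rss_r - rss_u) / (rss_u / df2))
}

# minimal DOT reader: node and edge statements of the dialect render_graph()
# emits
parse_dot <- function(text) {
  lines <- trimws(strsplit(text, "\n")[[1]])
  edge_lines <- grep("->", lines, value = TRUE)
  node_lines <- grep('^"[^"]+";$', lines, value = TRUE)
  edges <- do.call(rbind, lapply(edge_lines, function(l) {
    m <- regmatches(l, regexec('^"([^"]+)" -> "([^"]+)" \\[(.*)\\];$', l))[[1]]
    data.frame(from = m[2], to = m[3], attrs = m[4])
  }))
  list(nodes = gsub('[";]', "", node_lines),
       edges = if (is.null(edges)) data.frame(from = character(),
                                              to = character(),
                                              attrs = character()) else edges)
}

# quick bivariate dataset with known VAR(1) dynamics, positive mean
sim_var1 <- function(a, seed, n_days = 100, means = c(10, 10), noise = diag(2),
                     vars = c("x", "y")) {
  simulate_ema(synthetic_spec(vars, list(a), noise = noise, means = means,
                              n_days = n_days),
               seed = seed)
}

# stub objects for formatter tests: a var_search shell with given counts
stub_search <- function(tested, enumerated, skipped = enumerated - tested,
                        n_valid = 0, variables = c("Activity", "Depression")) {
  structure(list(models = tibble::tibble(valid = logical(0)),
                 enumerated = enumerated, tested = tested,
                 skipped_redundant = skipped, n_valid = n_valid,
                 criterion = "AIC", alpha = 0.05, trend = FALSE,
                 variables = variables),
            class = "var_search")
}

stub_summary <- function(edges, variables = c("Activity", "Depression"),
                         n_valid = 2) {
  structure(list(edges = edges, detail = NULL, n_valid = n_valid,
                 alpha = 0.05, variables = variables,
                 none = nrow(edges) == 0),
            class = "granger_summary")
}

# stub var_fit exposing just what sign_classify/granger_wald need
stub_fit <- function(coefs, variables, lag, constraints = NULL) {
  structure(list(spec = model_spec(lag, constraints = constraints),
                 variables = variables, labels = rownames(coefs),
                 coefficients = coefs,
                 constraints = constraints %||%
                   tibble::tibble(equation = character(), term = character())),
            class = "var_fit")
}
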