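# Design construction, equation-wise OLS, information criteria, pruning.

test_that("build_design lags the series and orders regressors", {
  d <- as_ema_dataset(tibble::tibble(x = c(1, 2, 1, 2, 1, 2)))
  des <- build_design(materialize(d, model_spec(1)), model_spec(1))
  expect_equal(as.numeric(des$Y), c(2, 1, 2, 1, 2))
  expect_equal(des$labels, c("const", "x.l1"))
  expect_equal(unname(des$X[, "x.l1"]), c(1, 2, 1, 2, 1))

  # T_eff = T - p
  d83 <- as_ema_dataset(tibble::tibble(a = rnorm(83, 10), b = rnorm(83, 10)))
  des2 <- build_design(materialize(d83, model_spec(2)), model_spec(2))
  expect_equal(nrow(des2$Y), 81)

  # bivariate p = 2 with two outlier dummies: K = 1 + 4 + 2 = 7
  sp <- model_spec(2, outlier_levels = c(a = 3.5, b = 3.5),
                   outlier_days = list(a = 4L, b = 13L))
  des3 <- build_design(materialize(d83, sp), sp)
  expect_equal(ncol(des3$X), 7)
  expect_equal(des3$labels,
               c("const", "a.l1", "b.l1", "a.l2", "b.l2",
                 "out_a_d4", "out_b_d13"))
})

test_that("a collinear design errors naming the offending column", {
  d <- as_ema_dataset(tibble::tibble(x = rnorm(30, 10), y = rnorm(30, 10),
                                     dup = 0),
                      variables = c("x", "y"), exogenous = "dup")
  sp <- model_spec(1, user_exogenous = "dup")
  expect_error(build_design(materialize(d, sp), sp), "collinear.*dup")
})

test_that("a perfectly alternating series fits exactly and inference errors", {
  d <- as_ema_dataset(tibble::tibble(x = c(1, 2, 1, 2, 1, 2)))
  fit <- fit_var(d, model_spec(1), inference = FALSE)
  expect_equal(unname(fit$coefficients["const", "x"]), 3)
  expect_equal(unname(fit$coefficients["x.l1", "x"]), -1)
  expect_equal(max(abs(fit$residuals)), 0)
  expect_error(fit_var(d, model_spec(1)), "degenerate fit")
})

test_that("coefficients equal independent normal-equation solutions", {
  set.seed(11)
  for (rep in 1:15) {
    nv <- sample(1:3, 1)
    p <- sample(1:2, 1)
    n <- sample(25:50, 1)
    vars <- paste0("v", seq_len(nv))
    d <- as_ema_dataset(tibble::as_tibble(matrix(rnorm(n * nv, 10), n, nv,
                                                 dimnames = list(NULL, vars))))
    fit <- fit_var(d, model_spec(p))
    des <- build_design(materialize(d, model_spec(p)), model_spec(p))
    for (v in vars) {
      expect_equal(unname(fit$coefficients[, v]),
                   ols_oracle(des$X, des$Y[, v]), tolerance = 1e-8)
    }
  }
})

test_that("simulated VAR(1) coefficients are recovered within 3 SEs", {
  a <- matrix(c(0.5, -0.3, 0.0, 0.4), 2, 2)
  d <- sim_var1(a, seed = 901, n_days = 500)
  fit <- fit_var(d, model_spec(1))
  truth <- t(a)  # coefficients matrix stores [term, equation]
  for (i in 1:2) for (j in 1:2) {
    term <- paste0(c("x", "y")[i], ".l1")
    eq <- c("x", "y")[j]
    expect_lt(abs(fit$coefficients[term, eq] - truth[i, j]),
              3 * fit$se[term, eq])
  }
})

test_that("information criteria follow the penalized-likelihood convention", {
  d <- sim_var1(matrix(c(0.5, 0, 0, 0.4), 2, 2), seed = 33, n_days = 83)
  fit <- fit_var(d, model_spec(2))
  expect_equal(fit$AIC, -2 * fit$logL + 2 * fit$k)
  expect_equal(fit$BIC, -2 * fit$logL + fit$k * log(83))
  expect_equal(fit$BIC - fit$AIC, fit$k * (log(83) - 2))
  # printed-table structure: k = 10 free coefficients at T = 83 gives a
  # BIC - AIC gap of 24.19 at two decimals
  expect_equal(round(10 * (log(83) - 2), 2), 24.19)
})

test_that("constraints zero coefficients and shrink k", {
  d <- sim_var1(matrix(c(0.5, 0.3, 0, 0.4), 2, 2), seed = 5, n_days = 120)
  free <- fit_var(d, model_spec(1))
  con <- fit_var(d, model_spec(1, constraints = tibble::tibble(
    equation = "x", term = "y.l1")))
  expect_equal(unname(con$coefficients["y.l1", "x"]), 0)
  expect_true(is.na(con$p_values["y.l1", "x"]))
  expect_equal(con$k, free$k - 1)
  # constraining a term in one equation leaves the other equation untouched
  expect_equal(con$residuals[, "y"], free$residuals[, "y"])
  expect_equal(con$coefficients[, "y"], free$coefficients[, "y"])
})

test_that("pruning removes a true-zero coefficient and stops on increase", {
  # true zero cross-coefficient y -> x; strong everything else
  a <- matrix(c(0.5, 0.3, 0, 0.4), 2, 2)
  d <- sim_var1(a, seed = 1205, n_days = 200)
  fit <- fit_var(d, model_spec(1))
  pruned <- prune_parameters(d, fit, criterion = "BIC")
  log <- attr(pruned, "pruning")
  expect_gt(nrow(log), 0)
  acc <- log[log$accepted, ]
  expect_equal(acc$term[1], "y.l1")
  expect_equal(acc$equation[1], "x")
  # accepted steps strictly decrease the criterion
  expect_true(all(acc$criterion_after < acc$criterion_before))
  # validity re-checked after every accepted constraint
  expect_length(attr(pruned, "pruning_validity"), nrow(acc))
})

test_that("pruning returns the fit unchanged when all terms are significant", {
  a <- matrix(c(0.6, 0.4, -0.3, 0.5), 2, 2)
  d <- sim_var1(a, seed = 42, n_days = 400)
  fit <- fit_var(d, model_spec(1))
  expect_true(all(fit$p_values[-1, ] < 0.05))
  pruned <- prune_parameters(d, fit)
  expect_equal(nrow(pruned$constraints), 0)
  expect_equal(pruned$coefficients, fit$coefficients)
})

test_that("a pruning step that raises the criterion is reverted", {
  # hunt for an instance whose only nonsignificant coefficient would raise
  # AIC when dropped (|t| between sqrt(2) and 1.96), then check the revert
  found <- FALSE
  for (seed in 1:200) {
    a <- matrix(c(0.5, 0.3, 0.12, 0.4), 2, 2)
    d <- sim_var1(a, seed = seed, n_days = 150)
    fit <- fit_var(d, model_spec(1))
    pv <- fit$p_values[-1, ]
    cand <- pv[pv > 0.05]
    if (length(cand) != 1) next
    tval <- qt(cand / 2, df = fit$T_eff - fit$k_eq[1])^2
    if (tval > 2.4 && tval < 3.6) {
      found <- TRUE
      pruned <- prune_parameters(d, fit, criterion = "AIC")
      log <- attr(pruned, "pruning")
      expect_equal(nrow(log), 1)
      expect_false(log$accepted[1])
      expect_gte(log$criterion_after[1], log$criterion_before[1])
      expect_equal(pruned$coefficients, fit$coefficients)
      break
    }
  }
  expect_true(found)
})

test_that("model export serializes the coefficient table as JSON", {
  d <- sim_var1(matrix(c(0.5, 0.2, 0, 0.4), 2, 2), seed = 2, n_days = 80)
  fit <- fit_var(d, model_spec(1))
  js <- jsonlite::fromJSON(model_to_json(fit))
  expect_equal(js$lag, 1)
  expect_equal(nrow(js$coefficients), 2 * 3)
  expect_equal(js$summary$k, fit$k)
})

test_that("tidy and glance expose the fitted model", {
  d <- sim_var1(matrix(c(0.5, 0.2, 0, 0.4), 2, 2), seed = 3, n_days = 80)
  fit <- fit_var(d, model_spec(1))
  td <- tidy(fit)
  expect_setequal(names(td), c("equation", "term", "estimate", "std.error",
                               "p.value", "constrained"))
  expect_equal(nrow(td), 6)
  gl <- glance(fit)
  expect_equal(gl$T, 80)
  expect_equal(gl$T_eff, 79)
})
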