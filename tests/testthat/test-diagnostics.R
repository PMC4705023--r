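# The validity gate: Ljung-Box, Jarque-Bera, eigenvalue stability,
# Phillips-Perron trend rule, and the conjunction verdict.

test_that("Ljung-Box reproduces hand-computed statistics", {
  # alternating +/-1 over n = 8: r1 = -0.875, Q = 8*10*0.765625/7 = 8.75
  e <- rep(c(1, -1), 4)
  lb <- ljung_box(e, h = 1)
  expect_equal(lb$statistic, 8.75)
  expect_equal(lb$df, 1)
  expect_equal(lb$p_value, pchisq(8.75, 1, lower.tail = FALSE))
  expect_lt(lb$p_value, 0.0032)
  expect_gt(lb$p_value, 0.0030)

  # orthogonal lag products: [1, 0, -1, 0] repeated has r1 = 0
  lb0 <- ljung_box(rep(c(1, 0, -1, 0), 3), h = 1)
  expect_equal(lb0$statistic, 0)
  expect_equal(lb0$p_value, 1)

  expect_error(ljung_box(rep(1, 10), h = 2), "zero variance")
  expect_error(ljung_box(rnorm(5), h = 5), "longer than h")
})

test_that("Ljung-Box agrees with the reference implementation", {
  set.seed(400)
  for (rep in 1:10) {
    x <- rnorm(50 + rep)
    h <- sample(1:10, 1)
    ours <- ljung_box(x, h)
    ref <- Box.test(x, lag = h, type = "Ljung-Box")
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("Jarque-Bera reproduces moment arithmetic and flags skew", {
  expect_warning(jb <- jarque_bera(c(-1, 0, 1)), "fewer than 8")
  expect_equal(jb$statistic, 0.28125)
  expect_equal(jb$skewness, 0)
  expect_equal(jb$kurtosis, 1.5)
  expect_gt(jb$p_value, 0.05)

  set.seed(7)
  expect_gte(jarque_bera(rnorm(100))$statistic, 0)
  # log-normal residuals are right-skewed: decisive rejection
  skewed <- exp(rnorm(200))
  expect_lt(jarque_bera(skewed)$p_value, 1e-6)
  expect_gt(jarque_bera(skewed)$skewness, 1)
  expect_error(jarque_bera(rep(3, 20)), "zero variance")
})

test_that("eigenvalue stability condition handles canonical cases", {
  expect_equal(stability_check(list(matrix(0, 2, 2)))$max_modulus, 0)
  expect_true(stability_check(list(matrix(0, 2, 2)))$pass)

  unit <- stability_check(list(matrix(1, 1, 1)))
  expect_equal(unit$max_modulus, 1)
  expect_false(unit$pass)

  di <- stability_check(list(diag(c(0.5, 0.9))))
  expect_equal(sort(Mod(di$eigenvalues)), c(0.5, 0.9))
  expect_true(di$pass)
})

test_that("stability verdicts agree with the characteristic-root oracle", {
  set.seed(52)
  for (rep in 1:40) {
    v <- sample(1:2, 1)
    p <- sample(1:2, 1)
    mats <- replicate(p, matrix(runif(v * v, -0.9, 0.9), v, v),
                      simplify = FALSE)
    expect_equal(stability_check(mats)$pass, stability_oracle(mats),
                 info = sprintf("rep %d", rep))
  }
})

test_that("the trend rule includes a trend for trend-stationary series only", {
  set.seed(99)
  trended <- 0.1 * (1:200) + rnorm(200)
  tr <- trend_needed(trended)
  expect_true(tr$include_trend)
  expect_lt(tr$p_value, 0.05)

  walk <- cumsum(rnorm(200))
  expect_false(trend_needed(walk)$include_trend)

  expect_warning(flat <- trend_needed(rep(2, 50)), "constant")
  expect_false(flat$include_trend)
  expect_error(trend_needed(rnorm(10)), "at least 20")
})

test_that("assess_validity passes clean models and is a pure function", {
  a <- matrix(c(0.5, 0.2, 0, 0.4), 2, 2)
  d <- sim_var1(a, seed = 101, n_days = 150)
  fit <- fit_var(d, model_spec(1))
  rep1 <- assess_validity(fit)
  expect_true(rep1$overall_valid)
  expect_equal(rep1$h, min(12, floor(fit$T_eff / 4)))
  # purity: identical input, identical report
  expect_identical(rep1, assess_validity(fit))
  td <- tidy(rep1)
  expect_setequal(unique(td$test),
                  c("stability", "white_noise", "homoscedasticity",
                    "normality"))
  expect_true(all(td$p_value[!is.na(td$p_value)] >= 0 &
                    td$p_value[!is.na(td$p_value)] <= 1))
})

test_that("an explosive coefficient matrix fails the gate regardless", {
  d <- sim_var1(matrix(c(0.5, 0, 0, 0.4), 2, 2), seed = 13, n_days = 100)
  fit <- fit_var(d, model_spec(1))
  fit$coefficients["x.l1", "x"] <- 1.2  # overwrite to force instability
  rep <- assess_validity(fit)
  expect_false(rep$stability$pass)
  expect_false(rep$overall_valid)
})

test_that("residual autocorrelation in one variable fails that variable only", {
  # variable y is MA(1) with a large coefficient; a VAR(1) cannot whiten it
  set.seed(31)
  eta <- rnorm(301)
  d <- as_ema_dataset(tibble::tibble(
    x = rnorm(300, 10),
    y = 10 + eta[-1] + 0.9 * eta[-301]))
  fit <- fit_var(d, model_spec(1))
  rep <- assess_validity(fit)
  wn <- rep$white_noise
  expect_false(wn$pass[wn$variable == "y"])
  expect_true(wn$pass[wn$variable == "x"])
  expect_false(rep$overall_valid)
})
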