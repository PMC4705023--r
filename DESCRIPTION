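Package: emavar
Title: Automated Vector Autoregressive Modeling of Daily Diary Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated idiographic (n-of-1) time-series analysis for ecological
    momentary assessment (EMA) diaries. Enumerates a combinatorial space of
    vector autoregressive (VAR) model specifications (lag order, weekday
    dummies, log transformation, residual-outlier dummies at an escalating
    severity ladder, a Phillips-Perron-determined linear trend), skips
    specifications made redundant by simpler valid models, estimates each
    candidate by equation-wise least squares, prunes nonsignificant
    coefficients while an information criterion keeps decreasing, gates models
    on four residual diagnostics (eigenvalue stability, Ljung-Box white noise,
    Ljung-Box on squared residuals, Jarque-Bera normality), ranks valid models
    by AIC or BIC, and aggregates per-model Granger-causality Wald tests into a
    weighted, signed directed graph. Includes a synthetic diary generator with
    known VAR ground truth for calibration and recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
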