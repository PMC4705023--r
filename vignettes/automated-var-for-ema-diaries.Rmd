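---
title: "Automated VAR modeling of EMA diaries: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated VAR modeling of EMA diaries: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emavar)
```

## The problem

Ecological momentary assessment (EMA) diaries record a handful of variables —
say, a daily depression score (0–27) and minutes of physical activity — once
per day for one individual over two to three months. The idiographic
(n-of-1) question is directional: does a change in one variable *precede* a
change in the other? Vector autoregression answers it, but a defensible VAR
analysis of a single short diary requires dozens of judgment calls: lag
order, trend, weekday seasonality, outlier handling, transformation,
coefficient restrictions, and residual diagnostics. `emavar` automates the
whole loop so that the analysis is reproducible and does not require a
statistician in it.

## The model

For V endogenous variables the VAR(p) is

$$y_t = c + A_1 y_{t-1} + \cdots + A_p y_{t-p} + B x_t + \varepsilon_t,$$

with intercept vector $c$, lag coefficient matrices $A_1,\dots,A_p$,
exogenous terms $x_t$ (linear trend, weekday dummies, outlier dummies, user
covariates), and errors $\varepsilon_t$ that should be serially uncorrelated
but may be contemporaneously correlated. Every equation shares one regressor
matrix, so the system is estimated by equation-wise ordinary least squares
(`fit_var()`); a normal-equation solve serves as an independent oracle in
the test suite. Variable *x* Granger-causes *y* when the coefficients of
*x*'s lags in *y*'s equation are jointly nonzero, tested by a Wald statistic
against a chi-square with one degree of freedom per unconstrained
coefficient (`granger_wald()`).

## The search space and its ordering

`enumerate_space()` forms the Cartesian product of

* lag order $p \in \{1, \dots, \texttt{max\_lag}\}$ (default 2: dynamics
  beyond two days are rarely plausible for daily diaries);
* weekday dummies off/on — the on branch exists only when the diary carries
  calendar dates and `timestamps` is enabled; Monday–Saturday are one-hot
  with Sunday the reference;
* log transformation off/on, system-wide;
* a per-variable outlier severity level from the ladder
  none $\prec$ 3.5 $\prec$ 3.0 ($\prec$ 2.5 SD only when `allow_25_sd` is
  set — the option extends the ladder, never reorders it).

The trend flag is decided *before* enumeration and is not a search factor:
each endogenous series is run through the Phillips–Perron test
(intercept-plus-trend regression, Newey–West truncation lag
$\lfloor 4 (T/100)^{1/4} \rfloor$), and if any series rejects the unit root
a day-index column is added to every model. The rule is deliberately
literal — "significant test ⇒ include trend" — which also fires for
trendless stationary series; a slope-significance refinement would change
the published procedure, so it is noted here but not adopted. A consequence
worth knowing: on stationary diaries, most runs include a (small,
harmless) trend term.

Specs are ordered simple-first: ascending lag, off-before-on flags, then
outlier severity vectors lexicographically. This ordering makes the
redundancy filter sound: a candidate is skipped exactly when an
already-valid, already-tested spec shares its lag/weekday/log/trend factors
and has weaker-or-equal outlier severity everywhere (strictly weaker
somewhere). That reproduces escalate-only-if-invalid behavior — a valid
model without modeled outliers makes the same model with outliers redundant
— while keeping the enumeration exhaustive in principle and the bookkeeping
exact: `tested + skipped_redundant = enumerated` on every run.

## Outlier dummies

Outliers are days whose residual deviates from the residual mean by more
than the level × sample SD. Residuals come from the unconstrained fit of
the *same* lag/weekday/log/trend base with no outlier dummies, so detection
is a deterministic single pass per spec family; days are not re-detected
after pruning or after earlier dummies are added (the alternative —
iterative re-detection — is defensible but makes the search
path-dependent). Each flagged day becomes its own 0/1 column, named
`out_<variable>_d<day>` with 1-based day indices, so "a dummy for day 4"
means the fourth assessment.

## Estimation, criteria, and pruning

The residual covariance uses divisor $T_{\mathrm{eff}} = T - p$; the system
log-likelihood is Gaussian with all additive constants. The criteria are

$$\mathrm{AIC} = -2\log L + 2k, \qquad
  \mathrm{BIC} = -2\log L + k \log T,$$

with *nominal* $T$ and $k$ the count of freely estimated regression
coefficients, intercepts included, covariance entries excluded. Under this
convention $\mathrm{BIC} - \mathrm{AIC} = k(\log T - 2)$ exactly, which is
asserted for every fit in the test suite.

Two numerical choices deserve emphasis:

* **Cross-transform comparability.** Log-transformed models report their
  likelihood in raw-data units through the change-of-variables term
  $-\sum_t \sum_v \log(y_{tv} + 1)$. Without it, the AIC of a model for
  $\log(y+1)$ sits on a different scale than the AIC of a model for $y$,
  and the transformed branch would mechanically dominate the ranking for
  any large-scale variable (activity minutes); with it, the ranking
  compares all models as densities for the same observed data.
* **Shifted log.** The transform is $\log(x+1)$, not $\log x$, because
  zeros are legitimate diary values (zero activity minutes). `expm1()`
  inverts it exactly.

Pruning (`prune_parameters()`) iterates: among unconstrained lag and
exogenous coefficients with $p > \alpha$, constrain the single highest-p
coefficient to zero (ties broken by fixed regressor order), refit, and keep
the step only if the chosen criterion strictly decreased; otherwise revert
and stop. Intercepts are never pruned — each equation keeps its constant.
After every accepted constraint the four validity tests are re-run and the
reports attached. The stopping rule has a sharp consequence used in the
calibration studies: at $T = 200$, BIC accepts the removal of any
coefficient with $|t| < \sqrt{\log T} \approx 2.30$, so every
$\alpha$-nonsignificant candidate that is offered is also accepted, and the
"true-zero coefficient is pruned first" event coincides with that
coefficient being nonsignificant (≈95% of seeds). Under AIC the acceptance
region is $|t| < \sqrt 2$, so roughly a third of nonsignificant candidates
would be offered and then reverted; the pruning simulations therefore run
under BIC, which isolates the ordering behavior being tested.

## The validity gate

A model is valid only if *all* of the following hold at the shared level
$\alpha$ (default 0.05):

1. **Stability**: all eigenvalues of the $pV \times pV$ companion matrix lie
   strictly inside the unit circle.
2. **White noise**: per-variable Ljung–Box on the residuals,
   $Q = n(n+2)\sum_{j \le h} r_j^2/(n-j)$, chi-square with $\mathrm{df} = h$.
3. **Homoscedasticity**: the same statistic on squared residuals.
4. **Normality**: per-variable Jarque–Bera,
   $JB = \tfrac n6 (S^2 + (K-3)^2/4)$, chi-square with 2 df.

The Portmanteau lag is $h = \min(12, \lfloor T_{\mathrm{eff}}/4 \rfloor)$
with no reduction of df for fitted lags — the choice is conventional, not
derivable from first principles, and is exposed as an argument. The tests
are per-variable (not one multivariate statistic) because the gate requires
every variable to pass individually.

The gate's arithmetic matters for interpreting results: six 5%-level tests
per bivariate model pass jointly about 74% of the time *on perfectly clean
data*. The suite's calibration study confirms each test holds its nominal
size, and the escalation study is therefore designed around this base rate:
the per-seed assertions concern the shocked-data behavior (the no-outlier
model on the generating scale must fail, and a valid model carrying the
day-20 dummy must appear), while the clean-data property — top-ranked valid
model carries no outlier dummies — is asserted as an aggregate rate
consistent with the gate's own false-alarm probability, not per seed. A
per-seed "everything clean stays clean" requirement would contradict the
calibrated sizes it sits next to.

## Granger aggregation

For each ordered variable pair, the edge weight is the proportion of valid
models in which the Wald test is significant at $\alpha$ — the denominator
is *all* valid models, and a model whose cause-lags were all pruned
contributes a non-significant verdict ($W = 0$, $p = 1$). Edges with zero
proportion are not drawn. The per-model sign is the common sign of the
unconstrained cause-lag coefficients (mixed-within when they disagree
across lags); contributing models that disagree with each other make the
edge mixed-across. No multiple-testing correction is applied across the
$V(V-1)$ ordered pairs; the procedure's protections against capitalization
on chance are the redundancy filter, the validity gate, and the
proportion-weighted display itself.

One inference subtlety is handled deliberately: the Wald tests run on the
*unpruned* fit of each valid specification, not on the pruned model that is
reported and gated. Pruning is data-driven selection — when one of two
cause-lag coefficients is dropped, the survivor is the more significant of
the pair, and a chi-square test restricted to survivors roughly doubles its
false-positive rate (measured: 10.3% versus the 5.3% of the unpruned joint
test at lag 2). Testing the full cause-lag block as originally estimated
keeps the per-model test at its nominal level; the pruned model remains the
model whose coefficients, criteria and diagnostics are reported.

In the rendered DOT graph, pen-width is $1 + 4 \cdot \mathrm{proportion}$
(the display contract is monotonicity — thicker means more models — and an
affine map is the simplest monotone choice); line styles are solid /
dashed / dash-dot / dotted for positive / negative / mixed-within /
mixed-across, with colors green/red/orange/gray carried as extra edge
attributes. The `dashdot` style token is an extension: renderers without it
should fall back to the color coding.

## The synthetic generator

`simulate_ema()` draws a stationary Gaussian VAR core (initialized at the
stationary mean, 100 burn-in steps discarded), then adds deterministic
terms to the observed window: a linear trend, an additive weekday profile,
innovation outliers injected in residual-SD units (so detection-threshold
tests are scale-free), and optionally an exponential transform for
right-skewed marginals. Means are set to positive diary-like values
(e.g. activity ≈ 60 min, depression ≈ 10 points) so the log branch of the
search is exercisable. What it does *not* emulate: integer-valued and
bounded scales, missing days (a hard error by design), floor/ceiling
effects, non-equidistant sampling, and time-varying dynamics. Passing tests
on this generator therefore show that the pipeline recovers the structures
it models, not that those structures exhaust real diaries.

The `rosmalen_like` scenario is an entirely synthetic stand-in for the kind
of post-myocardial-infarction diary the method was built for: T = 83 daily
bivariate observations, VAR(2) dynamics with negative Activity→Depression
cross-lags at both lags (standardized ≈ −0.35 and −0.25), no reverse
coupling, and +5 SD shocks on day 4 (Depression) and day 13 (Activity). One
generator subtlety: Activity's own dynamics are AR(1). If Activity had a
real second own-lag, lagged Depression — itself driven by lagged Activity —
would become a genuine proxy for the omitted second lag inside lag-1
models, making reverse "causality" *true* in the VAR(1) information set and
defeating the scenario's purpose of having a one-directional ground truth.

## Problem sizes and determinism

The search itself is deterministic given data and configuration; seeds
enter only through the generator. The calibration and recovery studies run
at: 1000 replicates for diagnostic sizes (n = 200, h = 10); 500 seeds each
for Granger size and power (T = 100, cross-lag 0.4); 200 seeds for
coefficient bias (T = 500) and pruning order (T = 200); 20 paired runs for
escalation; and 100 end-to-end searches for the idiographic recovery rate.
These sizes keep Monte-Carlo standard errors a factor of 3–10 smaller than
the widths of the asserted bands.

## Known limitations

* Missing data are refused, not imputed, and non-daily grids are refused —
  preprocessing (e.g. spline smoothing and resampling) is out of scope.
* The literal trend rule over-includes trend terms on stationary data.
* Model ranking across the log branch relies on the Jacobian-adjusted
  likelihood; other variance-stabilizing transforms are not considered.
* With many valid models, the unioned 5%-level Granger tests can flag a
  spurious edge in an appreciable share of runs; the proportion weight (a
  thin edge) is the reader's cue, not a formal error rate.
* Inference is classical OLS per equation; no small-sample or
  heteroscedasticity-robust corrections (homoscedasticity is enforced by
  the gate instead).
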