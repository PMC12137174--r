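---
title: "Methods: small-area estimation of healthy life expectancy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: small-area estimation of healthy life expectancy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`halesae` implements, end to end, the estimation machinery behind
county-level healthy life expectancy (HALE) by race and ethnicity, sex,
age, and year: hierarchical small-area prevalence models, regression of
cause-specific years-lived-with-disability (YLD) rates on mortality and
health-indicator covariates, raking of county-level rates to state
benchmarks, Sullivan's method on abridged life tables, and draw-based
uncertainty summaries. Because the survey microdata and burden-of-disease
inputs such analyses consume are restricted, the package ships a
first-class synthetic-data generator with known ground truth; every
statistical claim the test suite makes is a claim about recovering that
truth.

## The synthetic world

`make_geography()` lays counties on a near-square grid with rook
adjacency, optionally rewired, partitioned into contiguous states.
`simulate_truth()` draws, for each surface (indicator prevalence on the
logit scale; mortality and YLD rates on the log scale), a linear predictor
composed of fixed effects plus structured random effects:

* a county field from the intrinsic conditional autoregressive (ICAR)
  model, precision = degree matrix minus adjacency, sampled on the
  sum-to-zero subspace of each connected component via the
  eigendecomposition pseudo-inverse;
* first-order random walks (RW1) over calendar year and over age-group
  index, also constrained to sum to zero;
* exchangeable race effects, centred so they are deviations around the
  shared intercept;
* optional independent stratum-level noise.

Default conditions are 48 counties in 4 states, 2 racial and ethnic
populations, 2 sexes, abridged ages $\{[0,1), [1,5), [5,10), \dots,
[85,\infty)\}$, and years 2009–2019 — small enough that a full run takes
minutes on one CPU while leaving hundreds of strata per fitted effect.
Random-effect variances (logit/log scale) default to 0.04 (county), 0.005
(year), 0.02 (age) and 0.04 (race) for prevalence, with analogous but
smaller values for the rate surfaces.

Two generator choices deserve emphasis:

* **The prevalence surfaces carry no stratum-level residual by default.**
  The estimator's latent field is additive in county, year, age, and race
  main effects (the interaction structure of the real data-generating
  process is unknown; additivity is the documented simplification), so a
  stratum nugget in the generator would be noise the model class cannot
  represent. With tens of thousands of informative observations the
  posterior concentrates on the model surface, and interval coverage of a
  truth that includes irreducible nugget noise would measure the nugget,
  not calibration. Setting the default to zero makes the coverage
  properties meaningful; users can switch it on (`prev_var$resid`) to
  study robustness to unmodelled heterogeneity. The YLD and mortality
  surfaces keep nonzero residual noise, since their estimators carry
  explicit residual variance.
* **True mortality is capped at $0.95/(n_x - a_x)$ per closed age
  group**, the level at which the abridged conversion $q_x = n_x m_x / (1
  + (n_x - a_x) m_x)$ reaches its valid range's edge. Without the cap,
  roughly one stratum in $10^5$ draws a schedule with $q_x > 1$ and the
  life-table constructor (correctly) refuses it.

Survey-style observations are binomial: `simulate_indicator_observations()`
attaches each observation to a *set* of fine strata, with success
probability the population-weighted mean of the set's true prevalences.
That is exactly the aggregation-consistent likelihood the fitter assumes,
so coarsely reported data (counties merged within a state, or merged age
groups) test the estimator's stated model rather than an approximation of
it. Benchmarks are population-weighted state aggregates of true YLD rates
with lognormal draw noise (sd 0.02 by default); life tables are built
deterministically from true mortality.

All stochastic stages derive child seeds from one master seed by hashing a
stage label (`child_seed()`), in a fixed documented order, so each surface
is reproducible in isolation.

## The prevalence model

For observation $i$ with trials $n_i$, successes $k_i$, stratum set $S_i$
and population weights $w_j$:

$$k_i \sim \mathrm{Binomial}\!\left(n_i,\; \bar p_i\right),\qquad
\bar p_i = \frac{\sum_{j \in S_i} w_j\, \mathrm{expit}(\eta_j)}{\sum_{j \in S_i} w_j},\qquad
\eta = X\beta + Z_c u_c + Z_t u_t + Z_a u_a + Z_r u_r .$$

The random-effect blocks carry ICAR (county), RW1 (year, age), and
exchangeable (race, optional education) precision structures with one
log-precision parameter each. Inference follows the Laplace strategy of
modern mixed-model software, re-implemented here directly: an inner Newton
solve (Fisher-scoring curvature, step-halving line search that never
accepts an increase in the objective; near the mode, where improvements
fall below the floating-point resolution of the objective, full Newton
steps are taken unguarded) finds the joint mode of $(\beta, u)$ given the
log-precisions $\theta$, and the outer problem maximises the
Laplace-approximate marginal likelihood

$$-\log L(\theta) = f(\hat x; \theta) - \tfrac12 \log\det P(\theta)
  + \tfrac12 \log\det H(\hat x; \theta) + \tfrac{\theta^\top\theta}{2\cdot 2.5^2}$$

by Nelder–Mead. Numerical choices, all defaults of
`fit_indicator_model()`:

* inner gradient sup-norm tolerance $10^{-6}$, at most 50 inner Newton
  iterations and 200 outer iterations;
* sum-to-zero constraints imposed as soft quadratic penalties (precision
  $10^4$ on each constrained sum), keeping every block precision full rank
  — per component for the ICAR block, over the whole index for RW1, and
  over levels for the exchangeable blocks. Constraining the exchangeable
  blocks is deliberate: with a free intercept and a handful of race
  levels, the unconstrained variance component is not identified and its
  maximum-likelihood path diverges;
* a weak $N(0, 2.5^2)$ penalty on each log-precision. The real analysis'
  priors live in an appendix unavailable here; this penalty is the
  package's own assumption, wide enough (±2 sd spans variances from
  $e^{-5}$ to $e^{5}$) to be immaterial for well-replicated blocks while
  bounding the poorly replicated ones;
* a ridge of precision $10^{-4}$ on fixed effects, raised to 1 with a
  warning when the data are separable (all $k=0$ or all $k=n$);
* posterior draws come from the Gaussian at the joint mode with the
  curvature as precision (`draw_posterior()`), mapped through the design
  and inverse logit, so prevalence draws always lie in $[0,1]$.

Indicator models may include an education axis; `marginalize_education()`
collapses it by population-weighted averaging before draws feed the YLD
stage, whose strata carry no education dimension.

## The YLD model and draw splitting

Cause-group YLD benchmarks exist only at state × sex × age × year
resolution. `fit_cause_model()` regresses the log benchmark on the log of
the population-weighted mean of $\exp(X\gamma)$ over the state's
county-race strata — the same aggregation-consistent device, now on the
log-rate scale with Gaussian error. The stratum design contains an
intercept, county covariates, log YLL rate for the cause, and the
indicator prevalences. Gauss–Newton with an analytic Jacobian and a tiny
ridge ($10^{-10}$ relative) solves the nonlinear least-squares problem;
with noise-free inputs it recovers generating coefficients to $10^{-3}$.

Uncertainty propagates by draw splitting (`propagate_draws()`): 50 models
per cause, model $m$ consuming input draw $m$ of the benchmark and of
every indicator cube, each fitted model contributing 20 prediction draws
(coefficients sampled from the Gaussian at the optimum, times lognormal
residual noise — without the residual term the 20 within-model draws would
be degenerate), concatenated in (model, draw) order into 1000 draws whose
lineage metadata records the ancestry of every column. `sum_causes()` adds
aligned cubes cause-wise and clips the all-cause rate into $[0,1]$ (a YLD
rate is bounded by full-time disability), reporting the number of clipped
cells rather than clipping silently.

## Raking, Sullivan, and summaries

`apply_raking()` scales each (state, sex, age, year, draw) cell
multiplicatively so the population-weighted county-race mean reproduces
the benchmark exactly (asserted to $10^{-10}$ relative error); values
pushed above 1 are clipped and the remaining strata re-raked until no new
clipping occurs (≤ 50 passes), preserving the benchmark constraint while
respecting the range. Raking is multiplicative because rates are positive
and the benchmark adjustment is a scaling; it rakes the all-cause cube by
default (cause-specific raking is available by applying the same function
per cause). Draws are processed in blocks of 200 columns to bound memory.

`lifetable_from_mx()` builds abridged life tables with radix 100 000,
$a_0 = 0.2$ for $[0,1)$ (infant deaths cluster early in the year) and
$a_x = n_x/2$ elsewhere; the terminal group takes $q=1$ and $nL = l/m$.
Sullivan's method discounts person-years by the healthy fraction:

$$\mathrm{HALE}_x = \frac{\sum_{y \ge x} {}_nL_y\,(1 - d_y)}{l_x},$$

with $d_y$ the raked all-cause YLD rate. The plain Sullivan weighting is
used; the within-age-group interpolation refinements of burden-of-disease
implementations live in appendices not reproduced here, and the difference
is absorbed by the draw-based uncertainty. HALE is computed per draw and
only then summarised — the wiring tests assert this, since quantiles do
not commute with the (linear) Sullivan map.

Summaries follow the reporting conventions: population-weighted
aggregation of draws across sexes and counties (`aggregate_weighted()`),
point estimates as draw means with 95% uncertainty intervals as the 2.5th
and 97.5th empirical percentiles under the linear-interpolation (type 7)
quantile definition, pinned for reproducibility (`point_and_ui()`).
`compare_draws()` computes draw-wise differences; a difference is
statistically significant when the posterior probability of being greater
than zero is below 2.5% or above 97.5%. Ties count as not-greater
(conservative), and a comparison whose difference draws are all exactly
zero is reported as not significant: the literal rule would flag it, which
cannot be right for A compared with itself. Estimates for county-race
populations with mean annual population below 1000 are masked
(`mask_small()`), strictly below the threshold, and masked cells are
excluded from — but never altered in — the county disparity statistics
(`county_disparity_stats()`: min/max/range, median and IQR, counts and
shares of significant increases and declines, pairwise cross-population
counts). Reported percentages are count ratios rounded half-up at one
decimal (`pct_round()`), since R's default half-to-even rounding does not
match the reporting convention.

## Pipeline, determinism, and problem sizes

`run_pipeline()` orchestrates `simulate`, `fit_indicators`, `fit_ylds`,
`rake`, `hale`, and `summarize`. Every stage writes a JSON manifest with
the configuration hash, stage seed, and MD5 of each input and output;
stages refuse to run when an upstream manifest is missing or an input
hash no longer matches, and reruns with identical inputs are
byte-identical. A thin command-line wrapper ships in `inst/cli/`.

The test and acceptance workloads choose problem sizes as a deliberate
trade-off between statistical resolution and a single-CPU run: parameter
recovery and raking exactness run at the default 48-county scale with
1000 draws; the end-to-end draw-bookkeeping chain (50 models × 20 draws
through summation, raking, Sullivan, and summaries) runs at 8 counties;
the acceptance script's full pipeline uses 16 counties, 4 causes, and two
indicators. Significance-rule calibration uses 1000 independent null
replicates of 500 draws each.

## What passing tests do and do not show

The generator emulates the *structure* of the real inputs — mixed-resolution
binomial survey data, state-only benchmarks, spatially and temporally
autocorrelated surfaces, draw-based uncertainty — with known truth, so the
suite can verify recovery, calibration, aggregation consistency, raking
exactness, and draw bookkeeping. It does not emulate survey design
effects, questionnaire semantics, racial misclassification, multirace
bridging, or real US geography; passing tests therefore demonstrate that
the machinery is implemented correctly, not that any particular
substantive estimate about real populations is right. Known limitations,
beyond those: the additive main-effects random-effect structure (no
county×year or county×age interactions); conditional-on-$\theta$ posterior
draws (hyperparameter uncertainty is not propagated, which is one reason
empirical coverage can sit slightly below nominal); and a single shared
coefficient vector across populations in the YLD stage, mirroring the
constant-association assumption of the original analysis.
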