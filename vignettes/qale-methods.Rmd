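---
title: "Quality-adjusted life expectancy: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quality-adjusted life expectancy: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qale)
```

## The estimand

Life expectancy counts years; it says nothing about the health in which
those years are lived. Health expectancies weight the years of a period
life table by an age-specific health measure. When that measure is the
mean EQ-5D-5L utility (the *population norm* $\pi_x$), the result is
quality-adjusted life expectancy:

$$QALE_x = \frac{1}{l_x} \sum_{y \ge x} \pi_y L_y,$$

where $l_x$ and $L_y$ are life-table survivors and person-years. When the
measure is the prevalence of reporting *no problem* on one EQ-5D
dimension, the same sum is a dimension-specific healthy life expectancy
(a DFLE). A measure identically equal to 1 recovers $e_x$ exactly; this
identity is asserted in the test suite and is a useful smoke test for any
change to the person-year bookkeeping.

This package estimates QALE and the five dimension-specific DFLEs from
(i) age-specific mortality rates by gender/region/year, (ii) EQ-5D-5L
survey microdata with survey weights, and (iii) a value set mapping each
of the $5^5 = 3125$ health states to a utility. It also decomposes the
change in QALE between two periods into mortality and disutility effects.

## EQ-5D-5L scoring and value sets

A health state is a vector of five severity levels (1–5) on mobility,
self-care, usual activities, pain/discomfort and anxiety/depression.
`index_value()` is a pure table lookup: value sets are stored as explicit
3125-row tables, and additive decrement systems are expanded to the full
table at load time (`expand_additive_value_set()`). This makes toy sets,
published sets and future sets interchangeable and exactly reproducible,
at a negligible memory cost.

The packaged `synthetic_belgian_value_set()` is an additive system
anchored to published Belgian index values — utility 1 for state 11111,
0.849 for 11113, 0.678 for 11333 and a floor of −0.532 for 55555 — with
all remaining decrements filled by synthetic, severity-monotone values.
It is a labelled stand-in, not a reproduction of the Belgian tariff:
analyses that need the real tariff should load it with `read_value_set()`
from the separately distributed table. `toy_value_set()` (0.05 per
severity step) is used throughout the unit tests because every utility
can be verified by hand.

## Population norms

`estimate_norms()` computes, per age band × gender × region × year
stratum, the survey-weighted mean utility $\pi$, the weighted no-problem
prevalence per dimension, and their sampling variances. Design choices,
each of which matters for the standard errors downstream:

* **Complete-case scoring.** A respondent missing any dimension cannot be
  scored and is excluded from the stratum before weighting. No imputation
  is attempted.
* **Kish effective sample size.** Variances divide by
  $N_{eff} = (\sum w)^2 / \sum w^2$ rather than the raw $n$; with unit
  weights $N_{eff} = n$. This is the standard conservative correction
  when the true design information behind the weights is unavailable. The
  weighted sample variance carries a Bessel-type correction
  $N_{eff}/(N_{eff}-1)$.
* **Banding.** Norms default to ten-year bands 15–24 … 75–84 and 85–100,
  partitioning the analysis range 15–100; the banding is a parameter, not
  a constant, because published norms differ in their banding and any
  banding must be reproducible. Band intervals are closed on both ends.
* Prevalence variances are binomial, $p(1-p)/N_{eff}$; the utility
  variance is $s^2/N_{eff}$ with $s^2$ the weighted sample variance. The
  binomial form is the standard health-expectancy convention; extending
  the same $v = s^2/N$ shape to the continuous utility is this package's
  stated convention for QALE standard errors.

An empty stratum (or one whose records are all unscoreable) raises a
`qale_missing_stratum` error naming the stratum, rather than silently
dropping rows from the output.

## Life tables

`build_lifetable()` constructs non-abridged (single-year) period tables
from central death rates $m_x$, starting at 15 — the youngest age with
EQ-5D data — with an open last age group at 100:

* closed intervals: $q_x = m_x / (1 + (1-a_x) m_x)$ with
  $a_x = 0.5$ by default (the standard chord assumption for single-year
  adult ages; `a_default` is exposed so other conventions can be
  replicated exactly), $L_x = l_{x+1} + a_x d_x$;
* open group: $q = 1$ and $L_\omega = l_\omega / m_\omega$, the
  constant-hazard closure;
* a closed-interval $q$ exceeding 1 (possible only for extreme rates) is
  clamped to 1 with a warning rather than producing negative survivors.

The telescoping identity $T_x = L_x + T_{x+1}$ holds exactly and is
asserted exactly in the tests. The builder is validated against a
Monte-Carlo cohort simulation under the same piecewise-constant hazard;
agreement on $e_{15}$ is required within Monte-Carlo error plus a small
allowance (0.05 years) for the chord-vs-exponential discretisation, whose
leading error per interval is $O(m_x^3)$.

## Standard errors and comparisons

Mortality is treated as fixed (register-based); only the health measure
contributes sampling variance:

$$se_x^2 = \frac{1}{l_x^2} \sum_b \Big( \sum_{y \in b,\ y \ge x} L_y \Big)^2 v_b.$$

The sum runs over *norm bands*, not single ages: every age in a band
shares one estimate, so treating ages as independent would understate the
variance. The person-years of a band are therefore summed before
squaring (ages below the index age are excluded from the band sum). The
test suite verifies both that this formula matches a direct evaluation
and that it strictly exceeds the naive per-age version whenever a band
spans several ages.

Two health expectancies are compared with a conservative Z-score,
$z = \Delta / \sqrt{se_1^2 + se_2^2}$, with a two-sided normal p-value.
Two-sided is chosen because change tests have no privileged direction.
Life expectancy itself gets no p-value (its sampling variance is zero
under the fixed-mortality convention), and a comparison with two zero
standard errors and a non-zero difference is an error rather than an
infinite Z.

## Decomposition of a QALE change

The change between periods $t$ and $t+n$ is decomposed at single-year
resolution into a mortality effect and a disutility effect:

$$MOR_x = \frac{\pi_x(t) + \pi_x(t+n)}{2}\,\Delta\lambda_x, \qquad
  DIS_x = \frac{\lambda_x(t) + \lambda_x(t+n)}{2}\,\Delta\pi_x,$$

where $\lambda_x = L_x / l_a$ are person-years *conditioned on survival
to the index age* within each period. This normalisation is a deliberate
reading: QALE at age $a$ is conditional on reaching $a$, and without it
the effect totals fail to sum to $\Delta QALE_a$ whenever $l_a$ differs
between periods. With it, additivity
$\sum_x MOR_x + \sum_x DIS_x = \Delta QALE_a$ is an algebraic identity
($\Delta(\pi\lambda) = \bar\pi\,\Delta\lambda + \bar\lambda\,\Delta\pi$),
which the property tests assert to $10^{-10}$ on random period pairs,
along with exact antisymmetry under swapping the periods. The half-sum
averaging allocates the mortality–health interaction symmetrically; no
separate interaction term is reported. `aggregate_decomposition()` bins
the per-age effects into display bands for plotting; binning is
presentation only.

## The synthetic-data generator

Real survey microdata and registry rates cannot ship with the package, so
every pipeline stage is exercised on synthetic data with known ground
truth.

* **Mortality** is Gompertz–Makeham, $m_x = c + k a e^{bx}$, with
  multiplicative modifiers for gender, region and period. This produces
  realistic adult age patterns and has a closed form to test against.
* **Responses** follow an ordered probit: each respondent has a latent
  severity per dimension, $\sqrt{\rho} Z_0 + \sqrt{1-\rho}\,\varepsilon_d
  + s$, cut at dimension-specific thresholds. The shared factor $Z_0$
  induces a single-parameter Gaussian-copula correlation across
  dimensions; the shift $s$ moves with age, gender and period. The
  ordered-probit/copula choice is deliberate: marginal level
  probabilities are exactly $\Phi(\kappa_k - s)$, so the generator is
  analytically checkable, and `true_norms()` can compute the exact
  population value of every norm (by summation over all 3125 states,
  integrating the shared factor on a fine Gauss-weighted grid —
  trapezoid on $[-8, 8]$ with 101 nodes, accurate far beyond the
  tolerances used, and exactly the product form when $\rho = 0$).
* **Weights** are log-normal, rescaled to mean 1 per stratum
  (`sdlog = 0.5`, moderate dispersion); skewed weights can be requested
  to stress the Kish correction.
* **Ages** are drawn from the stationary population implied by the
  stratum's own life table, so the survey age structure is consistent
  with the mortality regime.

The packaged `scenario_belgium_like()` fixes two survey years five years
apart, two genders, three regions with population shares 0.58/0.10/0.32,
mortality improving between the years (by more for men), and
health-related quality of life that worsens with age, is lower for women,
declines between the periods at younger ages and improves at older ages
for women. Offsets are calibrated once so the later-year utility norm at
age 15 is near 0.92 for men and 0.89 for women, and per-year survey sizes
default to 10,829 and 11,611 — both mirroring the published Belgian
figures for realism. These are scenario parameters, not test targets.

What the generator does **not** emulate: multistage cluster sampling and
its design effects beyond unequal weighting, nonresponse and proxy
interviews, item (single-dimension) missingness patterns, within-person
fluctuation of health states, and any selection of severely impaired
respondents out of the survey. Passing recovery tests therefore shows
that the estimators are consistent under clean unequal-weight sampling
with known truth — not that they are robust to those real-data
complications.

## Problem sizes and numerical tolerances

The test suite asserts exact identities (telescoping, additivity,
antisymmetry, $\pi \equiv 1 \Rightarrow QALE = LE$) at $10^{-10}$ or
tighter, runs the Sullivan-vs-brute-force and decomposition property
checks on 1000 random instances each, validates the life-table builder
against a 300,000-individual simulated cohort, and checks parameter
recovery over 20 replicate surveys of 10,000 respondents per
year–gender stratum, requiring the estimated QALE at 15 to fall within 3
standard errors of the exact synthetic truth in at least 95% of
stratum–replicate pairs. These sizes keep the whole suite under a couple
of minutes while leaving Monte-Carlo margins wide relative to the
tolerances tested.

## Interfaces

The pipeline is driven either from R (`run_analysis()` on an
`analysis_config()`) or from the shell via the thin wrapper installed at
`inst/cli/qale.R`. The wrapper exposes three subcommands — `simulate`,
`validate`, `run` — rather than one per pipeline stage: the intermediate
stages (life tables, norms, expectancies, decomposition) are ordinary
exported functions, and a stage-per-subcommand CLI would only duplicate
their signatures. Outputs are CSV only: a headline table with year,
change and p-value rows (plus a presentation copy rounded to one decimal,
matching how such tables are printed; machine-readable files keep full
precision), decomposition totals and per-age effects, health-expectancy
to life-expectancy ratio curves, per-region supplements, and a run log.
Reruns on the same inputs are byte-identical apart from the log's
timestamp.

## Known limitations

* QALE values depend strongly on the value set; the packaged synthetic
  set supports testing and worked examples, not substantive Belgian
  estimates.
* Standard errors ignore mortality sampling variance and survey design
  effects beyond unequal weighting, and band-level norms induce a step
  approximation to the true age profile of health.
* The analysis starts at 15; child health measurement is out of scope.
* Abridged life tables, rate smoothing, and cause-of-death or
  counterfactual-life-table decompositions are not implemented.
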