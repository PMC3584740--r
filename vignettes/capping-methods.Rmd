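---
title: "Capping alcohol exposure distributions and relative-risk curves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Capping alcohol exposure distributions and relative-risk curves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alcaaf)
```

## The exposure model

Average daily ethanol consumption among current drinkers is modelled as
gamma-distributed. The model is fitted by moments: given a mean $\mu$ and
standard deviation $\sigma$ (both in grams/day), the shape and scale are
$\kappa = \mu^2/\sigma^2$ and $\theta = \sigma^2/\mu$. The mean itself
comes from routinely available aggregates: total adult per-capita
consumption (recorded + unrecorded + tourist, litres of pure ethanol per
person aged 15+ per year) is multiplied by a coverage factor, divided by
the prevalence of current drinkers, and converted to grams/day. The
standard deviation is tied to the mean through the empirical regularity
that drinking populations have a near-constant coefficient of variation,
with sex-specific slopes $\sigma = 1.171\,\mu$ (men) and
$\sigma = 1.258\,\mu$ (women). A consequence worth knowing: the shape
parameter is then a sex constant ($\kappa \approx 0.729$ for men,
$0.632$ for women), below 1, so the density is J-shaped with a pole at
zero — integrable, and excluded from the support since zero average
consumption means "not a current drinker".

Parameters that matter, with defaults:

* **coverage** (0.8): fraction of per-capita alcohol assumed actually
  consumed, absorbing spillage/waste and the undercoverage of the cohort
  studies behind the risk curves. Config-overridable everywhere it enters.
* **litres-to-grams conversion**: 789.24 g per litre of pure ethanol
  (ethanol density), 365 days/year. Arguments, not hard-coded constants.
* **cap** (150 g/day): the truncation point for the capped scenario.

Capping is implemented as truncation-with-renormalization: the fitted
density is divided by its own CDF at the cap so it integrates to 1 on
$(0, \text{cap}]$; shape and scale are untouched. This matches the
convention in comparative risk assessment, where the cap encodes the
judgement that >150 g/day cannot be sustained over a disease latency
period. For the EU male model (mean 31.97 g/day) truncation at 150 pulls
the mean down by 2.85 g/day:

```{r}
m <- fit_gamma_exposure(31.97, sex = "male")
mean(normalize_to_cap(m, 150))
```

## Relative-risk curves and their extension

Risk curves are specified per cause and sex on the log-RR scale over the
dose range the source meta-analysis observed: log-linear, log-quadratic
(J-shaped when $\beta_1 < 0 < \beta_2$, as for ischemic heart disease),
natural-spline, or categorical bands (tuberculosis, myocardial
infarction). The published meta-analytic coefficient sets are not
reproduced here; curves are loaded from a YAML configuration and the
shipped set is synthetic and illustrative.

Beyond the validity limit `x_valid_max` (default 150 g/day, configurable
down to 120) two scenarios apply:

* **capped**: $RR(x) = RR(\min(x, x_{valid}))$.
* **uncapped**: the curve continues linearly from `linear_start`
  (150 g/day) with its tangent slope there, and is held constant past
  `hard_cap` (300 g/day). The tangent — the analytic derivative of the
  parametric form, not a finite difference or a chord — is the natural
  reading of "changed to a linear function", and makes the extension
  $C^0$ at both breakpoints by construction.

Whether a curve is linearized or capped immediately is decided by its
log-slope at the linear start: above `slope_threshold` (default 0.02 per
gram — a doubling every 35 g/day, which we take as "increasing rapidly";
no published value exists, so this is a package choice) the curve is
capped right away. The classification is advisory and can be overridden
per cause in the configuration, since published analyses do not list
which causes they capped immediately. Protective segments ($RR < 1$) are
never floored. Categorical bands are half-open $[lo, hi)$: a dose exactly
at a cut belongs to the upper band.

## The attributable fraction and its integration

$$AAF = \frac{D - 1}{D}, \qquad
D = P_{abst} + P_{former} RR_{former} +
\int_{>0}^{U} p_{current} f(x) RR(x)\,dx$$

with $U = \text{cap}$ for the capped distribution and $U = \infty$
otherwise. Numerical choices:

* "Infinity" is the $1 - 10^{-12}$ quantile of the untruncated gamma; the
  neglected tail mass is $10^{-12}$. This is validated against closed
  forms (for a log-linear curve over the uncapped gamma, the integral is
  the moment-generating function $(1 - \beta_1\theta)^{-\kappa}$, which
  quadrature matches to $10^{-8}$ relative as long as the tilted tail is
  itself negligible, i.e. $\beta_1\theta$ not close to 1).
* The integrand is split at every non-smooth point of the extended curve
  (validity limit, linear start, hard cap, categorical cuts); each piece
  is integrated adaptively (absolute tolerance $10^{-10}$, relative
  $10^{-8}$). The kinks at 150 and 300 g/day defeat single-interval
  adaptive quadrature, which is why the split is not optional.
* Densities are evaluated in log space so that large shapes/scales
  neither overflow $\Gamma(\kappa)$ nor underflow $e^{-x/\theta}$.
* Degenerate inputs are rejected loudly: prevalences not summing to 1
  (within $10^{-6}$) are an error, never renormalized; a population with
  no current drinkers has no exposure model; a capped model cannot be
  capped again.

The AAF is negative when the prevalence-weighted mean RR is below 1
(protective causes). It can fall below $-1$ for strongly protective
curves, so attributable deaths can exceed the cause's death count in
magnitude only on the protective side — averted deaths are not bounded by
observed deaths.

## Scenario comparison

Three runs — capped/capped, uncapped/capped-RR, uncapped/uncapped — give
the decomposition

$$\underbrace{(UU - UC)}_{\text{RR capping}} +
\underbrace{(UC - CC)}_{\text{distribution capping}} = UU - CC.$$

`compare_scenarios()` computes the total difference as the sum of the two
components, which makes the additivity identity exact in floating point
(for integer death totals the two definitions coincide exactly). The
relative underestimation is expressed as a proportion of the *capped*
(conservative) estimate — the only denominator under which the published
headline percentages are mutually consistent — and the RR-capping share
as a proportion of the total difference; both are reported as
not-applicable when the difference is zero. Output tables round
percentages to one decimal and deaths to integers, but every returned
object carries unrounded values, so capped/uncapped pairs that look equal
at printed precision remain distinguishable.

## The synthetic-data generator

Real inputs to this kind of analysis — country survey prevalences, GBD
mortality extracts, meta-analytic risk coefficients — are not
redistributable here, so the generator produces the three input files
with known ground truth. Its defaults are fixed once and emulate
European-scale populations: true drinker means drawn from 10–45 g/day
(the span of EU country means; female means scaled by 0.4, reflecting
that women drink substantially less), current-drinker prevalence
0.50–0.85, former drinkers 0.03–0.15, former-drinker RRs 1.0–1.3,
cause-level death counts 50–20,000, and a sixteen-cause list whose curve
families mirror the qualitative shapes of the field (monotone cancers and
cirrhosis, J-shaped cardiometabolic causes, categorical tuberculosis, one
shared injury curve). Per-capita figures are constructed by *inverting*
the litres-to-grams conversion, so the fitted mean recovers the stored
truth to floating precision — the basis of the end-to-end recovery test.
A single integer seed drives each generated artifact through an isolated
RNG scope; the session's random state is never touched.

What the generator does *not* emulate: survey/per-capita triangulation
and its biases, age structure (inputs are all-adult, as in the situation
that motivated the pipeline, where age-specific prevalences were simply
unavailable), junk-coded causes of death, and realistic between-country
correlation of consumption and mortality. Passing tests on synthetic data
therefore demonstrate the correctness of the machinery — integration,
capping, decomposition — not the realism of any particular attributable-
death total.

## Problem sizes and validation scale

The test suite validates quadrature AAFs against Monte-Carlo estimates
from $10^6$ individual draws (3 standard errors; 20 seeded
exposure-curve pairs in the acceptance battery), checks the
moment-generating-function closed form to $10^{-8}$ relative, and runs
the full pipeline on scenarios of 2–10 populations times 16 causes —
sizes at which the whole suite completes in well under a minute while the
Monte-Carlo standard errors are already a factor ~30 below the effects
being tested.

## Known limitations

* Band prevalences of the fitted EU-male gamma reproduce published values
  to within 0.03 percentage points for the tail bands; a published
  "below 150" figure that was derived as the complement of rounded tails
  can disagree by slightly more than its own rounding step.
* No uncertainty intervals: the dominant uncertainty (risk-curve shape
  beyond 150 g/day) is unquantified in the literature; the scenario grid
  *is* the sensitivity analysis.
* The counterfactual is lifetime abstention; adjusted/confounded
  attributable fractions are out of scope.
* One pooled gamma per stratum; a population-weighted mixture of country
  gammas can be emulated by passing one record per country and
  aggregating the attributable deaths, but no mixture distribution object
  is provided.
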