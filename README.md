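# alcaaf

Alcohol-attributable mortality estimation with capped and uncapped exposure
distributions and relative-risk functions.

## The problem

Comparative risk assessments estimate, for each cause of death, the
alcohol-attributable fraction (AAF): the share of deaths that would not have
occurred had everyone been a lifetime abstainer. Average daily consumption
among current drinkers is modelled by a gamma distribution, and the
population-mean relative risk is

    D   = P_abst · 1 + P_former · RR_former + ∫ p_current f(x) RR(x) dx
    AAF = (D − 1) / D

with `f(x)` the drinker consumption density (grams of ethanol per day) and
`RR(x)` the cause- and sex-specific dose-response relative risk relative to
lifetime abstainers. Two conservative conventions are widespread:

* **distribution capping** — truncate and renormalize `f(x)` at 150 g/day,
  so no one is modelled as sustaining more than 150 g of ethanol daily;
* **RR capping** — hold `RR(x)` constant beyond the validity limit of the
  underlying meta-analysis (typically 120–150 g/day), instead of extending
  it (linearly from 150 g/day, held constant past 300 g/day).

Both conventions shrink the estimated attributable-death toll. `alcaaf`
implements the full pipeline — exposure fitting, capping, risk-curve
extension, AAF integration, death attribution — and decomposes the
difference between fully capped and fully uncapped totals into the part due
to each convention. It is aimed at burden-of-disease and alcohol-policy
analysts who want the capping sensitivity made explicit.

The exposure model needs only adult per-capita consumption (litres pure
ethanol/year, 80% coverage-adjusted by default) and drinker prevalences:
the gamma is fitted by moments, `κ = μ²/σ²`, `θ = σ²/μ`, with the standard
deviation tied to the mean (`σ = 1.171 μ` for men, `1.258 μ` for women).

## Worked example

The EU male drinker distribution (mean 31.97 g/day):

```r
library(alcaaf)
m <- fit_gamma_exposure(31.97, sex = "male")
m
#> Gamma consumption model for current drinkers
#>   mean 31.97 g/day, sd 37.44 g/day (shape 0.729266, scale 43.8386 g/day)
#>   untruncated (support (0, Inf))

100 * prevalence_in_band(m, 150, 200)   # 1.23% of drinkers at 150-<200 g/day
100 * prevalence_in_band(m, 200, Inf)   # 0.53% at 200+ g/day
mean(normalize_to_cap(m, 150))          # capping pulls the mean to 29.12 g/day
```

A full three-scenario run on the shipped synthetic inputs (three populations,
sixteen causes; generated data with known ground truth, not real surveys):

```r
records <- read_exposure_csv(system.file("extdata", "synthetic_exposure.csv", package = "alcaaf"))
curves  <- read_risk_config(system.file("extdata", "synthetic_risk_config.yaml", package = "alcaaf"))
mort    <- read_mortality_csv(system.file("extdata", "synthetic_mortality.csv", package = "alcaaf"))
out <- run_scenario_comparison(records, curves, mort)
out$comparison
#>  stratum capped/cappedRR uncapped/cappedRR uncapped/uncappedRR difference rel. underestimation RR-capping share
#>   female          20,647            20,662              20,665         19                 0.1%            19.0%
#>     male          40,954            44,126              46,010      5,056                12.3%            37.3%
#>    total          61,600            64,788              66,675      5,075                 8.2%            37.2%
```

Reading the totals row: capping both the distribution and the risk curves
lowers the attributable-death estimate by 5,075 deaths (8.2% of the capped
estimate), and 37.2% of that gap is due to RR capping alone — the rest to
truncating the exposure distribution. The effect concentrates in men, who
are far more likely to exceed 150 g/day.

`compare_scenarios()` performs the same decomposition directly on totals
from any three scenario runs, and `inst/cli/alcaaf.R` exposes the pipeline
(`simulate`, `fit-exposure`, `compute-aaf`, `attribute`, `compare`) from a
shell.

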