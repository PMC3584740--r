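#' Default cause list for synthetic scenarios
#'
#' Sixteen alcohol-related causes of death spanning the qualitative shapes
#' seen in comparative risk assessments: monotone log-linear curves
#' (cancers, cirrhosis, injuries), J-shaped log-quadratic curves with a
#' protective trough (ischemic heart disease, diabetes, stroke in women),
#' and a categorical curve (tuberculosis). Motor vehicle accidents,
#' suicide and other injuries share one injury curve. Coefficient ranges
#' are illustrative — chosen to give plausible attributable fractions —
#' and are sampled per scenario; they are not estimates from any
#' meta-analysis.
#'
#' @return a data.frame with columns `cause`, `family`, `beta1_lo`,
#'   `beta1_hi`, `beta2_lo`, `beta2_hi`, `shared_with`.
#' @export
default_cause_table <- function() {
  tb <- rbind(
    data.frame(cause = "oral cavity and pharynx cancer",
               family = "log_linear", beta1_lo = 0.004, beta1_hi = 0.008,
               beta2_lo = 0, beta2_hi = 0, shared_with = NA),
    data.frame(cause = "esophageal cancer", family = "log_linear",
               beta1_lo = 0.004, beta1_hi = 0.007,
               beta2_lo = 0, beta2_hi = 0, shared_with = NA),
    data.frame(cause = "colorectal cancer", family = "log_linear",
               beta1_lo = 0.001, beta1_hi = 0.003,
               beta2_lo = 0, beta2_hi = 0, shared_with = NA),
    data.frame(cause = "liver cancer", family = "log_linear",
               beta1_lo = 0.003, beta1_hi = 0.006,
               beta2_lo = 0, beta2_hi = 0, shared_with = NA),
    data.frame(cause = "breast cancer", family = "log_linear",
               beta1_lo = 0.002, beta1_hi = 0.004,
               beta2_lo = 0, beta2_hi = 0, shared_with = NA),
    data.frame(cause = "epilepsy", family = "log_linear",
               beta1_lo = 0.006, beta1_hi = 0.010,
               beta2_lo = 0, beta2_hi = 0, shared_with = NA),
    data.frame(cause = "lower respiratory infections", family = "log_linear",
               beta1_lo = 0.002, beta1_hi = 0.005,
               beta2_lo = 0, beta2_hi = 0, shared_with = NA),
    data.frame(cause = "stroke", family = "log_quadratic",
               beta1_lo = -0.006, beta1_hi = -0.002,
               beta2_lo = 4e-05, beta2_hi = 8e-05, shared_with = NA),
    data.frame(cause = "hypertension", family = "log_linear",
               beta1_lo = 0.004, beta1_hi = 0.008,
               beta2_lo = 0, beta2_hi = 0, shared_with = NA),
    data.frame(cause = "liver cirrhosis", family = "log_linear",
               beta1_lo = 0.010, beta1_hi = 0.016,
               beta2_lo = 0, beta2_hi = 0, shared_with = NA),
    data.frame(cause = "diabetes", family = "log_quadratic",
               beta1_lo = -0.010, beta1_hi = -0.005,
               beta2_lo = 6e-05, beta2_hi = 1e-04, shared_with = NA),
    data.frame(cause = "tuberculosis", family = "categorical",
               beta1_lo = NA, beta1_hi = NA,
               beta2_lo = NA, beta2_hi = NA, shared_with = NA),
    data.frame(cause = "ischemic heart disease", family = "log_quadratic",
               beta1_lo = -0.012, beta1_hi = -0.006,
               beta2_lo = 3e-05, beta2_hi = 6e-05, shared_with = NA),
    data.frame(cause = "motor vehicle accidents", family = "log_linear",
               beta1_lo = 0.004, beta1_hi = 0.008,
               beta2_lo = 0, beta2_hi = 0, shared_with = "injury"),
    data.frame(cause = "suicide", family = "log_linear",
               beta1_lo = 0.004, beta1_hi = 0.008,
               beta2_lo = 0, beta2_hi = 0, shared_with = "injury"),
    data.frame(cause = "other injuries", family = "log_linear",
               beta1_lo = 0.004, beta1_hi = 0.008,
               beta2_lo = 0, beta2_hi = 0, shared_with = "injury")
  )
  tb
}

#' Define a synthetic study scenario
#'
#' Bundles the knobs of the synthetic-data generator: number of
#' populations, the range of true drinker means, prevalence ranges, the
#' cause list with its coefficient ranges, and death-count ranges. A
#' single integer seed drives every generated artifact; generation never
#' touches the global random state.
#'
#' Defaults emulate a set of European-scale populations: drinker means
#' between 10 and 45 g/day (the range spanned by EU countries, whose
#' heaviest-drinking population averaged about 62 g/day per drinker before
#' coverage adjustment), current-drinker prevalence 50-85%, former
#' drinkers 3-15%, and cause-level death counts from 50 to 20,000.
#'
#' @param seed integer seed.
#' @param n_populations number of populations; each gets a male and a
#'   female stratum.
#' @param mean_range range of true mean consumption among current
#'   drinkers, grams/day.
#' @param p_current_range,p_former_range prevalence ranges; the lifetime-
#'   abstainer share is the remainder.
#' @param deaths_range range of death counts per (population, sex, cause).
#' @param population_range range of stratum population sizes (persons 15+).
#' @param rr_former_range range of former-drinker relative risks.
#' @param causes a cause table as from [default_cause_table()].
#' @return an object of class `"synthetic_scenario"`.
#' @export
synthetic_scenario <- function(seed, n_populations = 5,
                               mean_range = c(10, 45),
                               p_current_range = c(0.50, 0.85),
                               p_former_range = c(0.03, 0.15),
                               deaths_range = c(50, 20000),
                               population_range = c(5e5, 5e7),
                               rr_former_range = c(1.0, 1.3),
                               causes = default_cause_table()) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  ranges <- list(mean_range = mean_range, p_current_range = p_current_range,
                 p_former_range = p_former_range,
                 deaths_range = deaths_range,
                 population_range = population_range,
                 rr_former_range = rr_former_range)
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    if (length(r) != 2L || r[1] > r[2] || any(r < 0)) {
      stop(nm, " must be a non-degenerate non-negative range c(lo, hi)",
           call. = FALSE)
    }
  }
  if (p_current_range[2] + p_former_range[2] > 1) {
    stop("prevalence ranges admit p_current + p_former > 1", call. = FALSE)
  }
  if (mean_range[1] <= 0) stop("mean_range must be positive", call. = FALSE)
  structure(c(list(seed = as.integer(seed), n_populations = n_populations,
                   causes = causes), ranges),
            class = "synthetic_scenario")
}

#' Generate synthetic exposure records with known ground truth
#'
#' Draws a true drinker mean for every (population, sex) stratum and
#' constructs per-capita consumption figures by inverting the
#' litres-to-grams conversion ([per_capita_from_mean()]), so that fitting
#' the exposure model to the generated record recovers the stored truth
#' exactly (up to floating rounding). Per-capita mass is split randomly
#' into recorded/unrecorded/tourist components.
#'
#' @param scenario a [synthetic_scenario()] object.
#' @param coverage coverage adjustment assumed when inverting; default 0.8.
#' @return a list with `records` (an `"exposure_records"` data frame) and
#'   `truth` (a data.frame with the true `mu`, `sigma`, `kappa`, `theta`
#'   per stratum).
#' @export
generate_exposure <- function(scenario, coverage = 0.8) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  withr::with_seed(scenario$seed, {
    n <- scenario$n_populations
    strata <- expand.grid(population_id = sprintf("pop%02d", seq_len(n)),
                          sex = c("male", "female"),
                          stringsAsFactors = FALSE)
    strata <- strata[order(strata$population_id, strata$sex), ,
                     drop = FALSE]
    m <- nrow(strata)
    mu <- stats::runif(m, scenario$mean_range[1], scenario$mean_range[2])
    # women drink less on average than men; scale their means down
    mu <- ifelse(strata$sex == "female", 0.4 * mu, mu)
    p_cur <- stats::runif(m, scenario$p_current_range[1],
                          scenario$p_current_range[2])
    p_for <- stats::runif(m, scenario$p_former_range[1],
                          scenario$p_former_range[2])
    p_abs <- 1 - p_cur - p_for
    pcc_total <- per_capita_from_mean(mu, p_cur, coverage = coverage)
    w_rec <- stats::runif(m, 0.6, 0.9)
    w_unr <- (1 - w_rec) * stats::runif(m, 0.5, 1.0)
    w_tour <- 1 - w_rec - w_unr
    pop <- round(stats::runif(m, scenario$population_range[1],
                              scenario$population_range[2]))
    records <- validate_exposure_records(data.frame(
      population_id = strata$population_id, sex = strata$sex,
      population = pop,
      pcc_recorded = pcc_total * w_rec,
      pcc_unrecorded = pcc_total * w_unr,
      pcc_tourist = pcc_total * w_tour,
      p_lifetime_abstainer = p_abs, p_former = p_for, p_current = p_cur,
      stringsAsFactors = FALSE
    ))
    sigma <- sd_from_mean(mu, strata$sex)
    truth <- data.frame(
      population_id = strata$population_id, sex = strata$sex,
      mu = mu, sigma = sigma,
      kappa = mu^2 / sigma^2, theta = sigma^2 / mu,
      stringsAsFactors = FALSE
    )
    list(records = records, truth = truth)
  })
}

#' Generate a synthetic mortality table
#'
#' Non-negative integer death counts per (population, sex, cause), drawn
#' uniformly from the scenario's death-count range. Male breast-cancer
#' deaths are set to zero.
#'
#' @param scenario a [synthetic_scenario()] object.
#' @return a `"mortality_table"` data frame.
#' @export
generate_mortality <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  withr::with_seed(scenario$seed + 1L, {
    grid <- expand.grid(
      population_id = sprintf("pop%02d", seq_len(scenario$n_populations)),
      sex = c("male", "female"),
      cause = scenario$causes$cause,
      stringsAsFactors = FALSE
    )
    grid$deaths <- round(stats::runif(nrow(grid),
                                      scenario$deaths_range[1],
                                      scenario$deaths_range[2]))
    grid$deaths[grid$sex == "male" & grid$cause == "breast cancer"] <- 0
    validate_mortality(grid)
  })
}

#' Generate a synthetic set of relative-risk curves
#'
#' Draws coefficients uniformly from the cause table's ranges, one curve
#' per cause and sex; causes sharing a `shared_with` tag (the injury
#' causes) receive identical coefficients. The categorical tuberculosis
#' curve uses fixed three-band risks. Extension policies are resolved by
#' the slope rule.
#'
#' @param scenario a [synthetic_scenario()] object.
#' @param breakpoints an [extension_breakpoints()] object.
#' @return a `"risk_curve_set"` named `"<cause>|<sex>"`.
#' @export
generate_risk_curves <- function(scenario,
                                 breakpoints = extension_breakpoints()) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  withr::with_seed(scenario$seed + 2L, {
    tb <- scenario$causes
    curves <- list()
    shared_cache <- list()
    for (sex in c("male", "female")) {
      for (i in seq_len(nrow(tb))) {
        row <- tb[i, ]
        rrf <- stats::runif(1, scenario$rr_former_range[1],
                            scenario$rr_former_range[2])
        key <- paste(row$cause, sex, sep = "|")
        share_key <- if (!is.na(row$shared_with)) {
          paste(row$shared_with, sex, sep = "|")
        } else NA
        if (!is.na(share_key) && !is.null(shared_cache[[share_key]])) {
          co <- shared_cache[[share_key]]
        } else if (row$family == "categorical") {
          co <- list()
        } else {
          co <- list(beta1 = stats::runif(1, row$beta1_lo, row$beta1_hi),
                     beta2 = stats::runif(1, row$beta2_lo, row$beta2_hi))
          if (!is.na(share_key)) shared_cache[[share_key]] <- co
        }
        curves[[key]] <- if (row$family == "categorical") {
          risk_curve(row$cause, sex, "categorical",
                     bands = data.frame(lo = c(0, 40, 100),
                                        hi = c(40, 100, Inf),
                                        rr = c(1.2, 2.0, 3.3)),
                     rr_former = rrf, breakpoints = breakpoints)
        } else if (row$family == "log_quadratic") {
          risk_curve(row$cause, sex, "log_quadratic",
                     beta1 = co$beta1, beta2 = co$beta2,
                     rr_former = rrf, breakpoints = breakpoints)
        } else {
          risk_curve(row$cause, sex, "log_linear", beta1 = co$beta1,
                     rr_former = rrf, breakpoints = breakpoints)
        }
      }
    }
    structure(curves, class = "risk_curve_set")
  })
}

#' Write the synthetic input files for an external run
#'
#' Writes `exposure.csv`, `mortality.csv` and `risk_config.yaml` (the
#' three pipeline inputs) plus `ground_truth.json` carrying the true
#' gamma parameters, into `dir`.
#'
#' @param scenario a [synthetic_scenario()] object.
#' @param dir output directory (created if needed).
#' @param coverage passed to [generate_exposure()].
#' @return invisibly, the vector of paths written.
#' @export
write_synthetic_inputs <- function(scenario, dir, coverage = 0.8) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  exp <- generate_exposure(scenario, coverage = coverage)
  mort <- generate_mortality(scenario)
  curves <- generate_risk_curves(scenario)
  paths <- file.path(dir, c("exposure.csv", "mortality.csv",
                            "risk_config.yaml", "ground_truth.json"))
  utils::write.csv(exp$records, paths[1], row.names = FALSE)
  utils::write.csv(mort, paths[2], row.names = FALSE)
  write_risk_config(curves, paths[3])
  jsonlite::write_json(exp$truth, paths[4], digits = NA, dataframe = "rows")
  invisible(paths)
}

#' Write a set of risk curves as a YAML configuration
#'
#' Inverse of [read_risk_config()]: the written file loads back to an
#' equivalent curve set.
#'
#' @param curves a `"risk_curve_set"`.
#' @param path output YAML path.
#' @export
write_risk_config <- function(curves, path) {
  entries <- lapply(unname(curves), function(cu) {
    e <- list(cause = cu$cause, sex = cu$sex, form = cu$form,
              x_valid_max = cu$x_valid_max, rr_former = cu$rr_former,
              extension_policy = cu$extension_policy)
    if (cu$form %in% c("log_linear", "log_quadratic")) e$beta1 <- cu$beta1
    if (cu$form == "log_quadratic") e$beta2 <- cu$beta2
    if (cu$form == "log_spline") {
      e$spline_x <- cu$spline_x
      e$spline_logrr <- cu$spline_logrr
    }
    if (cu$form == "categorical") {
      e$bands <- lapply(seq_len(nrow(cu$bands)), function(i) {
        hi <- cu$bands$hi[i]
        list(cu$bands$lo[i], if (is.infinite(hi)) "Inf" else hi,
             cu$bands$rr[i])
      })
    }
    e
  })
  yaml::write_yaml(list(curves = entries), path)
  invisible(path)
}
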