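#' Read a mortality table from CSV
#'
#' Columns: `population_id, sex, cause, deaths`. Death counts must be
#' non-negative and each (population, sex, cause) combination unique. An
#' optional `age_group` column is carried through when present.
#'
#' @param path path to a CSV file.
#' @return a data.frame classed `"mortality_table"`.
#' @export
read_mortality_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_mortality(df)
}

#' @rdname read_mortality_csv
#' @param df a data.frame with the mortality columns.
#' @export
validate_mortality <- function(df) {
  required <- c("population_id", "sex", "cause", "deaths")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("mortality table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (any(df$deaths < 0)) stop("death counts must be >= 0", call. = FALSE)
  keycols <- intersect(c("population_id", "sex", "cause", "age_group"),
                       names(df))
  key <- do.call(paste, c(df[keycols], sep = "\r"))
  if (anyDuplicated(key)) {
    stop("duplicate (population, sex, cause) rows in mortality table",
         call. = FALSE)
  }
  class(df) <- unique(c("mortality_table", class(df)))
  df
}

#' Deaths attributable to alcohol for one cause
#'
#' Multiplies the attributable fraction by the cause's death count. The
#' result is a signed real: protective causes (negative fractions, e.g.
#' ischemic heart disease) yield negative attributable deaths, i.e.
#' deaths averted.
#'
#' @param aaf an `"aaf_result"` object or a numeric attributable fraction
#'   (vectorized).
#' @param deaths number of deaths, `>= 0`.
#' @return attributable deaths (unrounded).
#' @export
attributable_deaths <- function(aaf, deaths) {
  if (inherits(aaf, "aaf_result")) aaf <- aaf$aaf
  if (any(deaths < 0)) stop("deaths must be >= 0", call. = FALSE)
  aaf * deaths
}

#' Aggregate attributable-death rows
#'
#' Sums attributable deaths over causes, sexes or everything. All rows
#' must come from the same scenario; mixing scenarios in one aggregation
#' is an error because their totals are not comparable.
#'
#' @param rows a data.frame with columns `scenario`, `attributable_deaths`
#'   and whatever grouping columns `by` names (as produced by
#'   [run_attribution()]).
#' @param by `"sex"`, `"cause"`, `"sex_cause"` or `"total"`.
#' @return a data.frame of summed counts (a single number for
#'   `by = "total"`).
#' @export
aggregate_deaths <- function(rows, by = c("total", "sex", "cause",
                                          "sex_cause")) {
  by <- match.arg(by)
  if (nrow(rows) == 0L) {
    return(if (by == "total") 0 else
             data.frame(attributable_deaths = numeric(0)))
  }
  if (length(unique(rows$scenario)) > 1L) {
    stop("rows mix scenarios (",
         paste(unique(rows$scenario), collapse = ", "),
         "); aggregate one scenario at a time", call. = FALSE)
  }
  if (by == "total") return(sum(rows$attributable_deaths))
  keys <- switch(by, sex = "sex", cause = "cause",
                 sex_cause = c("sex", "cause"))
  out <- stats::aggregate(rows["attributable_deaths"], by = rows[keys], sum)
  out[do.call(order, out[keys]), , drop = FALSE]
}

#' Compare attributable-death totals across capping scenarios
#'
#' Takes the totals from three scenario runs — fully capped
#' (`capped_capped`: capped distribution, capped RR), fully uncapped
#' (`uncapped_uncapped`), and the intermediate run with uncapped
#' distribution but capped RR (`uncapped_cappedRR`) — and decomposes the
#' difference:
#'
#' * `total_difference = uncapped_uncapped - capped_capped`, the deaths
#'   missed by the fully conservative analysis;
#' * `rr_capping_component = uncapped_uncapped - uncapped_cappedRR`, the
#'   part due to holding the RR curves at their validity limits;
#' * `distribution_capping_component = uncapped_cappedRR - capped_capped`,
#'   the part due to truncating the exposure distribution.
#'
#' The two components sum to the total difference exactly.
#' `relative_underestimation` expresses the total difference as a
#' proportion of the capped (conservative) estimate, and
#' `rr_capping_share` as the RR component's share of the total
#' difference; both are `NA` when the total difference is zero.
#'
#' @param capped_capped,uncapped_uncapped,uncapped_cappedRR attributable-
#'   death totals, either single numbers or identically-named numeric
#'   vectors (e.g. `c(male = ..., female = ...)`); named vectors also get
#'   a pooled `total` row.
#' @return a data.frame classed `"scenario_comparison"` with one row per
#'   stratum plus `total`.
#' @examples
#' compare_scenarios(
#'   capped_capped = c(male = 90552, female = 14342),
#'   uncapped_uncapped = c(male = 113648, female = 15488),
#'   uncapped_cappedRR = c(male = 103654, female = 15020)
#' )
#' @export
compare_scenarios <- function(capped_capped, uncapped_uncapped,
                              uncapped_cappedRR) {
  lens <- c(length(capped_capped), length(uncapped_uncapped),
            length(uncapped_cappedRR))
  if (length(unique(lens)) != 1L) {
    stop("scenario totals must have equal length", call. = FALSE)
  }
  if (length(capped_capped) > 1L || !is.null(names(capped_capped))) {
    nm <- names(capped_capped)
    if (is.null(nm) ||
        !identical(nm, names(uncapped_uncapped)) ||
        !identical(nm, names(uncapped_cappedRR))) {
      stop("scenario totals must share identical names", call. = FALSE)
    }
    strata <- c(nm, "total")
    cc <- c(capped_capped, total = sum(capped_capped))
    uu <- c(uncapped_uncapped, total = sum(uncapped_uncapped))
    ur <- c(uncapped_cappedRR, total = sum(uncapped_cappedRR))
  } else {
    strata <- "total"
    cc <- capped_capped; uu <- uncapped_uncapped; ur <- uncapped_cappedRR
  }
  rr_comp <- uu - ur
  dist_comp <- ur - cc
  # summing the two components keeps the decomposition exactly additive in
  # floating point; for integer death counts this equals uu - cc exactly
  diff_total <- rr_comp + dist_comp
  out <- data.frame(
    stratum = strata,
    deaths_capped_capped = as.numeric(cc),
    deaths_uncapped_cappedRR = as.numeric(ur),
    deaths_uncapped_uncapped = as.numeric(uu),
    total_difference = as.numeric(diff_total),
    rr_capping_component = as.numeric(rr_comp),
    distribution_capping_component = as.numeric(dist_comp),
    relative_underestimation = ifelse(diff_total == 0, NA_real_,
                                      as.numeric(diff_total / cc)),
    rr_capping_share = ifelse(diff_total == 0, NA_real_,
                              as.numeric(rr_comp / diff_total)),
    row.names = NULL
  )
  class(out) <- c("scenario_comparison", "data.frame")
  out
}

#' @export
print.scenario_comparison <- function(x, ...) {
  cat("Attributable-death totals by capping scenario\n\n")
  fmt_n <- function(v) formatC(round(v), format = "d", big.mark = ",")
  fmt_p <- function(v) ifelse(is.na(v), "n/a", sprintf("%.1f%%", 100 * v))
  tab <- data.frame(
    stratum = x$stratum,
    `capped/cappedRR` = fmt_n(x$deaths_capped_capped),
    `uncapped/cappedRR` = fmt_n(x$deaths_uncapped_cappedRR),
    `uncapped/uncappedRR` = fmt_n(x$deaths_uncapped_uncapped),
    difference = fmt_n(x$total_difference),
    `rel. underestimation` = fmt_p(x$relative_underestimation),
    `RR-capping share` = fmt_p(x$rr_capping_share),
    check.names = FALSE
  )
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Run the attributable-mortality pipeline for one scenario
#'
#' For every (population, sex) stratum in `records`, fits the gamma
#' exposure model from per-capita consumption (capping it if the scenario
#' says so), computes the attributable fraction for every cause that has
#' a matching risk curve, and multiplies by the death counts in
#' `mortality`.
#'
#' @param records an `"exposure_records"` data frame.
#' @param curves a `"risk_curve_set"` (see [read_risk_config()]) or list
#'   of `"risk_curve"` objects named `"<cause>|<sex>"`.
#' @param mortality a `"mortality_table"` data frame.
#' @param scenario a [scenario_spec()] object.
#' @param coverage passed to [mean_consumption_from_per_capita()].
#' @return a data.frame with one row per (population, sex, cause):
#'   columns `population_id, sex, cause, scenario, aaf, deaths,
#'   attributable_deaths`.
#' @export
run_attribution <- function(records, curves, mortality, scenario,
                            coverage = 0.8) {
  stopifnot(inherits(scenario, "scenario_spec"))
  out <- vector("list", nrow(records))
  for (i in seq_len(nrow(records))) {
    rec <- records[i, , drop = FALSE]
    mu <- mean_consumption_from_per_capita(rec, coverage = coverage)
    model <- fit_gamma_exposure(mu, sex = rec$sex)
    if (scenario$distribution_capped) {
      model <- normalize_to_cap(model, scenario$cap)
    }
    deaths_i <- mortality[mortality$population_id == rec$population_id &
                            mortality$sex == rec$sex, , drop = FALSE]
    if (nrow(deaths_i) == 0L) next
    rows <- vector("list", nrow(deaths_i))
    for (j in seq_len(nrow(deaths_i))) {
      key <- paste(deaths_i$cause[j], rec$sex, sep = "|")
      curve <- curves[[key]]
      if (is.null(curve)) {
        stop("no risk curve for cause '", deaths_i$cause[j], "' and sex '",
             rec$sex, "'", call. = FALSE)
      }
      res <- compute_aaf(rec, model, curve, scenario)
      rows[[j]] <- data.frame(
        population_id = rec$population_id, sex = rec$sex,
        cause = deaths_i$cause[j], scenario = scenario_label(scenario),
        aaf = res$aaf, deaths = deaths_i$deaths[j],
        attributable_deaths = attributable_deaths(res, deaths_i$deaths[j]),
        stringsAsFactors = FALSE
      )
    }
    out[[i]] <- do.call(rbind, rows)
  }
  do.call(rbind, out[!vapply(out, is.null, TRUE)])
}

#' Run the three-scenario comparison end to end
#'
#' Convenience wrapper running [run_attribution()] under the fully capped,
#' fully uncapped, and uncapped-distribution/capped-RR scenarios and
#' feeding the per-sex totals to [compare_scenarios()].
#'
#' @inheritParams run_attribution
#' @param cap distribution cap, grams/day.
#' @param breakpoints an [extension_breakpoints()] object.
#' @return a list with elements `runs` (named list of per-row attribution
#'   tables) and `comparison` (a `"scenario_comparison"`).
#' @export
run_scenario_comparison <- function(records, curves, mortality,
                                    cap = 150,
                                    breakpoints = extension_breakpoints(),
                                    coverage = 0.8) {
  specs <- list(
    capped_capped = scenario_spec(TRUE, TRUE, cap, breakpoints),
    uncapped_cappedRR = scenario_spec(FALSE, TRUE, cap, breakpoints),
    uncapped_uncapped = scenario_spec(FALSE, FALSE, cap, breakpoints)
  )
  runs <- lapply(specs, function(sp) {
    run_attribution(records, curves, mortality, sp, coverage = coverage)
  })
  by_sex <- lapply(runs, function(r) {
    agg <- aggregate_deaths(r, by = "sex")
    stats::setNames(agg$attributable_deaths, agg$sex)
  })
  comparison <- compare_scenarios(
    capped_capped = by_sex$capped_capped,
    uncapped_uncapped = by_sex$uncapped_uncapped,
    uncapped_cappedRR = by_sex$uncapped_cappedRR
  )
  list(runs = runs, comparison = comparison)
}

#' Write attribution results
#'
#' `write_attribution_csv()` writes the per-row table from
#' [run_attribution()] with attributable fractions as percentages to one
#' decimal and deaths rounded to integers, mirroring the conventional
#' table style; the unrounded table is what [run_attribution()] returns.
#' `write_comparison_json()` writes a `"scenario_comparison"` as
#' machine-readable JSON.
#'
#' @param rows a data.frame from [run_attribution()].
#' @param path output file path.
#' @param digits decimals for the AAF percentage column.
#' @export
write_attribution_csv <- function(rows, path, digits = 1) {
  out <- rows
  out$aaf_percent <- round(100 * out$aaf, digits)
  out$aaf <- NULL
  out$attributable_deaths <- round(out$attributable_deaths)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_attribution_csv
#' @param comparison a `"scenario_comparison"` object.
#' @export
write_comparison_json <- function(comparison, path) {
  jsonlite::write_json(as.data.frame(comparison), path, auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}
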