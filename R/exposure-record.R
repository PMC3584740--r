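#' Conversion constants
#'
#' Pure ethanol has a density of 0.78924 kg per litre, so one litre of pure
#' ethanol weighs 789.24 grams; a year is taken as 365 days. Both constants
#' are arguments to the functions that use them and can be overridden.
#'
#' @name conversion-constants
#' @keywords internal
NULL

GRAMS_PER_LITRE_ETHANOL <- 789.24
DAYS_PER_YEAR <- 365

#' Construct a table of population exposure records
#'
#' An exposure record describes one population stratum (one population and
#' sex): its adult (15+) per-capita alcohol consumption in litres of pure
#' ethanol per year, split into recorded, unrecorded and tourist components,
#' and the prevalences of lifetime abstainers, former drinkers and current
#' drinkers.
#'
#' Prevalences must sum to 1 within `1e-6`; records failing this (or any
#' other invariant) are rejected with an error rather than silently
#' renormalized, because a prevalence triple that does not sum to one
#' usually indicates an upstream data problem.
#'
#' @param population_id character label for the population (e.g. a country).
#' @param sex `"male"` or `"female"`.
#' @param population number of persons aged 15 and older; must be positive.
#' @param pcc_recorded,pcc_unrecorded,pcc_tourist per-capita consumption
#'   components, litres pure ethanol per adult per year; non-negative.
#' @param p_lifetime_abstainer,p_former,p_current drinker-status prevalences
#'   in `[0, 1]`, summing to 1 within `1e-6`.
#' @return A `data.frame` with class `"exposure_records"`, one row per
#'   stratum.
#' @examples
#' rec <- exposure_record("EU", "male", 2e8, 10, 1.5, 0.1, 0.20, 0.10, 0.70)
#' rec$p_current
#' @export
exposure_record <- function(population_id, sex, population,
                            pcc_recorded, pcc_unrecorded = 0,
                            pcc_tourist = 0,
                            p_lifetime_abstainer, p_former, p_current) {
  df <- data.frame(
    population_id = as.character(population_id),
    sex = as.character(sex),
    population = as.numeric(population),
    pcc_recorded = as.numeric(pcc_recorded),
    pcc_unrecorded = as.numeric(pcc_unrecorded),
    pcc_tourist = as.numeric(pcc_tourist),
    p_lifetime_abstainer = as.numeric(p_lifetime_abstainer),
    p_former = as.numeric(p_former),
    p_current = as.numeric(p_current),
    stringsAsFactors = FALSE
  )
  validate_exposure_records(df)
}

#' Validate a data frame of exposure records
#'
#' Checks the invariants described in [exposure_record()] and returns the
#' input with class `"exposure_records"` prepended.
#'
#' @param df a data.frame with the exposure-record columns.
#' @return the validated data frame, classed `"exposure_records"`.
#' @export
validate_exposure_records <- function(df) {
  required <- c("population_id", "sex", "population", "pcc_recorded",
                "pcc_unrecorded", "pcc_tourist", "p_lifetime_abstainer",
                "p_former", "p_current")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("exposure records are missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!all(df$sex %in% c("male", "female"))) {
    bad <- unique(df$sex[!df$sex %in% c("male", "female")])
    stop("sex must be 'male' or 'female'; found: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  prev <- df[, c("p_lifetime_abstainer", "p_former", "p_current")]
  if (any(prev < 0 | prev > 1)) {
    stop("prevalences must lie in [0, 1]", call. = FALSE)
  }
  psum <- rowSums(prev)
  if (any(abs(psum - 1) > 1e-6)) {
    bad <- which(abs(psum - 1) > 1e-6)
    stop("drinker-status prevalences must sum to 1 within 1e-6; row(s) ",
         paste(bad, collapse = ", "), " sum to ",
         paste(signif(psum[bad], 8), collapse = ", "),
         " (records are rejected, not renormalized)", call. = FALSE)
  }
  pcc <- df[, c("pcc_recorded", "pcc_unrecorded", "pcc_tourist")]
  if (any(pcc < 0)) stop("per-capita consumption components must be >= 0",
                         call. = FALSE)
  if (any(df$population <= 0)) stop("population must be > 0", call. = FALSE)
  class(df) <- unique(c("exposure_records", class(df)))
  df
}

#' Read exposure records from CSV
#'
#' The file must have columns `population_id, sex, population, pcc_recorded,
#' pcc_unrecorded, pcc_tourist, p_lifetime_abstainer, p_former, p_current`,
#' with sex coded `"male"`/`"female"`.
#'
#' @param path path to a CSV file.
#' @return a validated `"exposure_records"` data frame.
#' @export
read_exposure_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_exposure_records(df)
}

#' Mean daily consumption among current drinkers from per-capita consumption
#'
#' Total adult per-capita consumption (recorded + unrecorded + tourist,
#' litres pure ethanol per adult per year) is multiplied by a coverage
#' factor — by default 0.8, accounting for spillage, waste and
#' undercoverage in the epidemiological studies behind the risk curves —
#' and the remaining mass is divided among current drinkers only, then
#' converted to grams of ethanol per day.
#'
#' @param record an `"exposure_records"` data frame (any number of rows).
#' @param coverage fraction of per-capita consumption assumed actually
#'   consumed, in `(0, 1]`; default 0.8.
#' @param grams_per_litre grams of ethanol per litre; default 789.24.
#' @param days_per_year default 365.
#' @return numeric vector, grams of ethanol per day per current drinker.
#' @examples
#' rec <- exposure_record("X", "male", 1e6, 8, 2, 0, 0.25, 0.05, 0.70)
#' mean_consumption_from_per_capita(rec)
#' @export
mean_consumption_from_per_capita <- function(record, coverage = 0.8,
                                             grams_per_litre = GRAMS_PER_LITRE_ETHANOL,
                                             days_per_year = DAYS_PER_YEAR) {
  if (!is.numeric(coverage) || any(coverage <= 0) || any(coverage > 1)) {
    stop("coverage must lie in (0, 1]", call. = FALSE)
  }
  if (any(record$p_current <= 0)) {
    stop("no current drinkers; exposure model undefined", call. = FALSE)
  }
  litres_per_adult <- record$pcc_recorded + record$pcc_unrecorded +
    record$pcc_tourist
  litres_per_drinker <- coverage * litres_per_adult / record$p_current
  litres_per_drinker * grams_per_litre / days_per_year
}

#' Invert the per-capita conversion
#'
#' Given a target mean daily consumption among current drinkers, returns the
#' total per-capita consumption (litres pure ethanol per adult per year)
#' that [mean_consumption_from_per_capita()] would map back to that mean.
#' Used by the synthetic-data generator so that generated records carry an
#' exactly known ground-truth mean.
#'
#' @param mean_g_day target mean grams/day among current drinkers.
#' @param p_current prevalence of current drinkers, in `(0, 1]`.
#' @inheritParams mean_consumption_from_per_capita
#' @return litres pure ethanol per adult per year.
#' @export
per_capita_from_mean <- function(mean_g_day, p_current, coverage = 0.8,
                                 grams_per_litre = GRAMS_PER_LITRE_ETHANOL,
                                 days_per_year = DAYS_PER_YEAR) {
  if (any(p_current <= 0)) stop("p_current must be > 0", call. = FALSE)
  mean_g_day * days_per_year * p_current / (coverage * grams_per_litre)
}
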