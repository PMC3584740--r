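test_that("per-capita consumption converts to grams/day among drinkers", {
  # 35.8 litres pure ethanol per drinker per year at 80% coverage
  rec <- exposure_record("LVA", "male", 1e6, 35.8, 0, 0, 0, 0, 1)
  got <- mean_consumption_from_per_capita(rec, coverage = 0.8)
  expect_equal(got, 35.8 * 789.24 * 0.8 / 365, tolerance = 1e-12)
  expect_equal(got, 61.93, tolerance = 1e-4)

  # per-capita mass is divided among current drinkers only
  rec2 <- exposure_record("X", "male", 1e6, 10, 0, 0, 0.45, 0.05, 0.5)
  expect_equal(mean_consumption_from_per_capita(rec2),
               2 * mean_consumption_from_per_capita(
                 exposure_record("X", "male", 1e6, 10, 0, 0, 0, 0, 1)))

  # zero consumption maps to zero
  rec0 <- exposure_record("Z", "female", 1e6, 0, 0, 0, 0.3, 0.1, 0.6)
  expect_equal(mean_consumption_from_per_capita(rec0), 0)

  # round trip through the inverse conversion
  for (target in c(5, 20, 31.97, 60)) {
    pcc <- per_capita_from_mean(target, p_current = 0.7)
    rec <- exposure_record("RT", "male", 1e6, pcc, 0, 0, 0.25, 0.05, 0.7)
    expect_equal(mean_consumption_from_per_capita(rec), target,
                 tolerance = 1e-9)
  }

  rec_none <- exposure_record("N", "male", 1e6, 10, 0, 0, 1, 0, 0)
  expect_error(mean_consumption_from_per_capita(rec_none),
               "no current drinkers")
  expect_error(mean_consumption_from_per_capita(rec, coverage = 0),
               "coverage")
})

test_that("exposure records are validated, not silently repaired", {
  expect_error(exposure_record("X", "male", 1e6, 10, 0, 0, 0.5, 0.1, 0.35),
               "sum to 1")
  expect_error(exposure_record("X", "other", 1e6, 10, 0, 0, 0.3, 0.1, 0.6),
               "male")
  expect_error(exposure_record("X", "male", 1e6, -1, 0, 0, 0.3, 0.1, 0.6),
               ">= 0")
  expect_error(exposure_record("X", "male", 0, 10, 0, 0, 0.3, 0.1, 0.6),
               "population")
  expect_error(validate_exposure_records(data.frame(population_id = "X")),
               "missing column")
  # prevalences within 1e-9 of 1 pass
  expect_s3_class(
    exposure_record("X", "male", 1e6, 10, 0, 0, 0.3, 0.1, 0.6 + 1e-10),
    "exposure_records")
})

test_that("sex-specific standard deviation is proportional to the mean", {
  expect_equal(sd_from_mean(31.97, "male"), 1.171 * 31.97)
  expect_equal(sd_from_mean(0, "female"), 0)
  expect_equal(sd_from_mean(10, "female"), 12.58)
  expect_error(sd_from_mean(10, "unknown"), "male")
})

test_that("gamma fit reproduces mean and sd, with sex-constant shape", {
  m <- fit_gamma_exposure(31.97, 37.437)
  expect_equal(m$kappa, 31.97^2 / 37.437^2)
  expect_equal(m$kappa, 0.7293, tolerance = 1e-4)
  expect_equal(m$theta, 43.84, tolerance = 1e-3)

  # round trip: (kappa, theta) back to (mu, sigma)
  for (mu in c(2, 10, 31.97, 80)) {
    mm <- fit_gamma_exposure(mu, sex = "male")
    expect_equal(mm$kappa * mm$theta, mu, tolerance = 1e-12)
    expect_equal(sqrt(mm$kappa) * mm$theta, mm$sigma, tolerance = 1e-12)
    # constant coefficient of variation implies mu-invariant shape
    expect_equal(mm$kappa, 1 / 1.171^2, tolerance = 1e-12)
  }
  expect_error(fit_gamma_exposure(-1, 2), "positive")
  expect_error(fit_gamma_exposure(1, 0), "positive")
  expect_error(fit_gamma_exposure(10), "sigma or sex")
})

test_that("density matches an independent log-space evaluation", {
  m <- eu_male_model()
  x <- c(0.01, 0.5, 2, 10, 31.97, 100, 150, 400)
  manual <- exp((m$kappa - 1) * log(x) - x / m$theta -
                  m$kappa * log(m$theta) - lgamma(m$kappa))
  expect_equal(dexposure(m, x), manual, tolerance = 1e-12)

  # truncation rescales the density by a constant 1/F(cap) below the cap
  mc <- normalize_to_cap(m, 150)
  xx <- seq(1, 149, by = 7)
  ratio <- dexposure(mc, xx) / dexposure(m, xx)
  expect_equal(ratio, rep(1 / mc$normalizer, length(xx)), tolerance = 1e-12)

  # both variants integrate to 1 over their support
  expect_equal(integrate(function(v) dexposure(m, v), 0, Inf,
                         rel.tol = 1e-10)$value, 1, tolerance = 1e-8)
  expect_equal(integrate(function(v) dexposure(mc, v), 0, 150,
                         rel.tol = 1e-10)$value, 1, tolerance = 1e-8)

  expect_error(dexposure(m, 0), "not qualify")
  expect_error(dexposure(mc, 151), "cap")
})

test_that("capping at 150 g/day shifts the mean as expected", {
  m <- eu_male_model()
  mc <- normalize_to_cap(m, 150)
  expect_equal(mc$kappa, m$kappa) # truncation, not refitting
  expect_equal(mc$theta, m$theta)
  expect_equal(mean(mc), 29.12, tolerance = 1e-3)
  expect_equal(m$mu - mean(mc), 2.85, tolerance = 1e-2)

  # an enormous cap changes nothing
  expect_equal(mean(normalize_to_cap(m, 1e6)), m$mu, tolerance = 1e-6)

  # normalizer agrees with the Monte-Carlo fraction of draws below the cap
  draws <- sample_drinkers(m, 1e6, seed = 7)
  phat <- mean(draws <= 150)
  se <- sqrt(phat * (1 - phat) / 1e6)
  expect_lt(abs(mc$normalizer - phat), 3 * se)

  expect_error(normalize_to_cap(m, -5), "positive")
  expect_error(normalize_to_cap(mc, 150), "already capped")
})

test_that("truncated mean is below the mean and non-decreasing in the cap", {
  for (mu in c(8, 20, 40)) {
    m <- fit_gamma_exposure(mu, sex = "female")
    caps <- c(30, 60, 120, 150, 300)
    means <- vapply(caps, function(cp) mean(normalize_to_cap(m, cp)), 0)
    expect_true(all(means < mu))
    expect_true(all(diff(means) > 0))
  }
})

test_that("band prevalences match the published male distribution", {
  m <- eu_male_model()
  expect_equal(100 * prevalence_in_band(m, 150, 200), 1.20,
               tolerance = 0.05 / 1.20)
  expect_equal(100 * prevalence_in_band(m, 200, Inf), 0.50,
               tolerance = 0.05 / 0.50)
  expect_equal(prevalence_in_band(m, 0, Inf), 1)

  # bands partitioning the support sum to one
  parts <- c(prevalence_in_band(m, 0, 150),
             prevalence_in_band(m, 150, 200),
             prevalence_in_band(m, 200, Inf))
  expect_equal(sum(parts), 1, tolerance = 1e-10)

  # virtually all female drinkers fall below 150 g/day
  f <- fit_gamma_exposure(15, sex = "female")
  expect_gt(prevalence_in_band(f, 0, 150), 0.999)

  expect_error(prevalence_in_band(m, 200, 150), "lo < hi")
})

test_that("CDF by quadrature of the density matches pgamma", {
  m <- eu_male_model()
  for (x in c(5, 31.97, 80, 150, 250)) {
    quad <- integrate(function(v) dexposure(m, v), 0, x,
                      rel.tol = 1e-10, abs.tol = 1e-12)$value
    expect_equal(quad, pexposure(m, x), tolerance = 1e-8)
  }
  # quadrature mean matches the analytic kappa * theta
  quad_mean <- integrate(function(v) v * dexposure(m, v), 0, Inf,
                         rel.tol = 1e-10)$value
  expect_equal(quad_mean, m$kappa * m$theta, tolerance = 1e-8)
})

test_that("quantile and CDF are mutually inverse for both variants", {
  m <- eu_male_model()
  mc <- normalize_to_cap(m, 150)
  p <- c(0.01, 0.25, 0.5, 0.9, 0.999)
  expect_equal(pexposure(m, qexposure(m, p)), p, tolerance = 1e-10)
  expect_equal(pexposure(mc, qexposure(mc, p)), p, tolerance = 1e-10)
  expect_lte(qexposure(mc, 1), 150)
})

test_that("exposure CSV round-trips through read and validation", {
  rec <- exposure_record(c("A", "A"), c("male", "female"), c(1e6, 1.1e6),
                         c(9, 6), c(1, 0.5), c(0.1, 0), c(0.2, 0.4),
                         c(0.1, 0.1), c(0.7, 0.5))
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(rec, path, row.names = FALSE)
  back <- read_exposure_csv(path)
  expect_equal(back$pcc_recorded, rec$pcc_recorded)
  expect_s3_class(back, "exposure_records")
})

test_that("the capping overlay plot renders to a file", {
  m <- eu_male_model()
  path <- withr::local_tempfile(fileext = ".png")
  plot(m, cap = 150, file = path)
  expect_true(file.exists(path) && file.size(path) > 0)
})
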