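test_that("capped risks are constant beyond the validity limit", {
  for (cu in curve_battery()) {
    expect_equal(rr_at(cu, 200, "capped"), rr_at(cu, 1e4, "capped"))
    expect_equal(rr_at(cu, cu$x_valid_max, "capped"),
                 rr_at(cu, 200, "capped"))
  }
  # a lower validity limit moves the plateau down with it
  cu120 <- risk_curve("c", "male", "log_linear", beta1 = 0.01,
                      x_valid_max = 120)
  expect_equal(rr_at(cu120, 500, "capped"), exp(0.01 * 120))
})

test_that("uncapped risks linearize at 150 and hold constant past 300", {
  bp <- extension_breakpoints()
  lin <- risk_curve("lin", "male", "log_linear", beta1 = 0.012,
                    extension_policy = "linearize_then_cap")

  # tangent extension: slope checked against a central finite difference
  f <- function(x) exp(0.012 * x)
  slope_fd <- (f(150 + 1e-4) - f(150 - 1e-4)) / 2e-4
  expect_equal(rr_at(lin, 225, "uncapped"), f(150) + slope_fd * 75,
               tolerance = 1e-9)

  # constant past the hard cap
  expect_equal(rr_at(lin, 300, "uncapped"), rr_at(lin, 400, "uncapped"))
  expect_equal(rr_at(lin, 300, "uncapped"), f(150) + slope_fd * 150,
               tolerance = 1e-9)

  # cap_immediately holds the 150 value in both scenarios
  imm <- risk_curve("imm", "male", "log_quadratic", beta1 = 0.002,
                    beta2 = 1e-4, extension_policy = "cap_immediately")
  expect_equal(rr_at(imm, 200, "uncapped"), rr_at(imm, 150, "uncapped"))
  expect_equal(rr_at(imm, 500, "uncapped"), rr_at(imm, 1e4, "uncapped"))

  expect_error(rr_at(lin, -1), ">= 0")
})

test_that("extended curves are continuous at both breakpoints", {
  bp <- extension_breakpoints()
  eps <- 1e-9
  for (cu in curve_battery()) {
    if (cu$form == "categorical") next
    cu$extension_policy <- "linearize_then_cap"
    for (pt in c(bp$linear_start, bp$hard_cap)) {
      left <- rr_at(cu, pt - eps, "uncapped", bp)
      right <- rr_at(cu, pt + eps, "uncapped", bp)
      expect_lt(abs(left - right), 1e-6 * max(1, left))
      # the breakpoint value itself matches both one-sided limits
      expect_equal(rr_at(cu, pt, "uncapped", bp), left,
                   tolerance = 1e-6)
    }
  }
})

test_that("monotone base forms stay monotone and dominate capped risks", {
  grid <- seq(0.5, 500, by = 0.5)
  for (beta in c(0.003, 0.008, 0.013)) {
    cu <- risk_curve("mono", "male", "log_linear", beta1 = beta,
                     extension_policy = "linearize_then_cap")
    unc <- rr_at(cu, grid, "uncapped")
    expect_true(all(diff(unc) >= -1e-12))
    expect_true(all(rr_at(cu, grid, "capped") <= unc + 1e-12))
  }
})

test_that("categorical curves are right-continuous step functions", {
  bands <- data.frame(lo = c(0, 40, 100), hi = c(40, 100, Inf),
                      rr = c(1.2, 2.0, 3.3))
  cu <- risk_curve("tb", "male", "categorical", bands = bands)
  expect_equal(cu$extension_policy, "cap_at_valid_max")
  expect_equal(rr_at(cu, c(10, 39.999), "capped"), c(1.2, 1.2))
  # a dose exactly at a cut belongs to the upper band
  expect_equal(rr_at(cu, 40, "capped"), 2.0)
  expect_equal(rr_at(cu, 100, "uncapped"), 3.3)
  # held at the band containing the validity limit far beyond it
  expect_equal(rr_at(cu, 1e5, "uncapped"), 3.3)

  expect_error(risk_curve("bad", "male", "categorical",
                          bands = data.frame(lo = c(0, 50),
                                             hi = c(40, Inf),
                                             rr = c(1, 2))),
               "contiguous")
  expect_error(risk_curve("bad", "male", "categorical",
                          bands = data.frame(lo = 10, hi = Inf, rr = 2)),
               "start at lo = 0")
  expect_error(risk_curve("bad", "male", "categorical", bands = NULL),
               "bands")
})

test_that("former-drinker risk is a dose-independent constant", {
  cu <- risk_curve("c", "male", "log_linear", beta1 = 0.01,
                   rr_former = 1.21)
  expect_equal(rr_former(cu), 1.21)
  cu$rr_former <- NULL
  expect_error(rr_former(cu), "former-drinker")
  expect_error(risk_curve("c", "male", "log_linear", beta1 = 0.01,
                          rr_former = -1), "rr_former")
})

test_that("the slope rule classifies extension policies", {
  bp <- extension_breakpoints()
  flat <- risk_curve("flat", "male", "log_linear", beta1 = 0)
  expect_equal(classify_extension(flat, bp), "linearize_then_cap")

  # log-quadratic with log-slope beta1 + 2*beta2*150 = 0.031 > 0.02
  fast <- risk_curve("fast", "male", "log_quadratic", beta1 = 0.001,
                     beta2 = 1e-4)
  expect_equal(classify_extension(fast, bp, slope_threshold = 0.02),
               "cap_immediately")
  expect_equal(fast$extension_policy, "cap_immediately") # via "auto"

  # an infinite threshold never calls a slope rapid
  expect_equal(classify_extension(fast, bp, slope_threshold = Inf),
               "linearize_then_cap")

  cat_cu <- risk_curve("tb", "male", "categorical",
                       bands = data.frame(lo = 0, hi = Inf, rr = 2))
  expect_equal(classify_extension(cat_cu, bp), "cap_at_valid_max")
})

test_that("risk configs survive a YAML write/read round trip", {
  curves <- structure(
    c(stats::setNames(curve_battery(),
                      vapply(curve_battery(),
                             function(cu) paste(cu$cause, cu$sex, sep = "|"),
                             "")),
      list("tb|male" = risk_curve("tb", "male", "categorical",
                                  bands = data.frame(lo = c(0, 60),
                                                     hi = c(60, Inf),
                                                     rr = c(1.5, 3)),
                                  rr_former = 1.1))),
    class = "risk_curve_set")
  path <- withr::local_tempfile(fileext = ".yaml")
  write_risk_config(curves, path)
  back <- read_risk_config(path)
  expect_setequal(names(back), names(curves))
  grid <- c(1, 20, 75, 149, 160, 250, 500)
  for (nm in names(curves)) {
    for (scen in c("capped", "uncapped")) {
      expect_equal(rr_at(back[[nm]], grid, scen),
                   rr_at(curves[[nm]], grid, scen), tolerance = 1e-12)
    }
    expect_equal(rr_former(back[[nm]]), rr_former(curves[[nm]]))
  }
})

test_that("risk config validation names the offending entry", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("curves:",
               "- cause: cirrhosis",
               "  sex: male",
               "  form: log_linear"), path)
  expect_error(read_risk_config(path), "curves\\[1\\].*beta1")

  writeLines(c("curves:",
               "- sex: male",
               "  form: log_linear",
               "  beta1: 0.01"), path)
  expect_error(read_risk_config(path), "missing required field 'cause'")

  writeLines("notcurves: []", path)
  expect_error(read_risk_config(path), "top-level 'curves'")

  writeLines(c("curves:",
               "- cause: a",
               "  sex: male",
               "  form: log_linear",
               "  beta1: 0.01",
               "- cause: a",
               "  sex: male",
               "  form: log_linear",
               "  beta1: 0.02"), path)
  expect_error(read_risk_config(path), "duplicate")
})
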