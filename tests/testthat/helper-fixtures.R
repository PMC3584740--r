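# Shared fixtures: the EU-male exposure model and the published
# attributable-death table columns used as arithmetic fixtures.

eu_male_model <- function() fit_gamma_exposure(31.97, sex = "male")

# Attributable deaths by cause (16 causes), by sex and scenario, as printed
# in the source tables; columns sum exactly to the printed totals.
aad_causes <- c(
  "oral cavity and pharynx cancer", "esophageal cancer",
  "colorectal cancer", "liver cancer", "breast cancer", "epilepsy",
  "lower respiratory infections", "stroke", "hypertension",
  "liver cirrhosis", "diabetes", "tuberculosis", "ischemic heart disease",
  "motor vehicle accidents", "suicide", "other injuries"
)

aad_male <- list(
  capped_capped = c(12935, 8492, 6884, 5259, 0, 1650, 8171, 22803, 9285,
                    41721, -637, 1830, -50684, 5386, 6990, 10467),
  uncapped_uncapped = c(13563, 9632, 7570, 5619, 0, 1993, 9138, 28097,
                        10878, 49549, 1877, 1889, -49698, 5551, 7203,
                        10787),
  uncapped_cappedRR = c(13499, 9206, 7351, 5553, 0, 1802, 8790, 26067,
                        10129, 45213, 312, 1889, -49698, 5551, 7203, 10787)
)

aad_female <- list(
  capped_capped = c(1719, 1235, 4008, 1459, 11048, 472, 5297, -3507, 5193,
                    13840, -3995, 238, -30117, 1067, 1379, 5006),
  uncapped_uncapped = c(1721, 1238, 4012, 1460, 11073, 473, 5304, -2895,
                        5396, 14019, -3893, 238, -30113, 1067, 1380, 5008),
  uncapped_cappedRR = c(1721, 1238, 4011, 1460, 11068, 473, 5303, -3189,
                        5322, 13926, -3893, 238, -30113, 1067, 1380, 5008)
)

# a small battery of parametric curves spanning the shapes the pipeline
# must handle: flat, monotone log-linear, steep log-linear, protective-J
# quadratic, rising quadratic, spline
curve_battery <- function() {
  list(
    risk_curve("flat", "male", "log_linear", beta1 = 0),
    risk_curve("mild", "male", "log_linear", beta1 = 0.004),
    risk_curve("steep", "male", "log_linear", beta1 = 0.013),
    risk_curve("jshape", "female", "log_quadratic",
               beta1 = -0.008, beta2 = 5e-05),
    risk_curve("rising", "male", "log_quadratic",
               beta1 = 0.002, beta2 = 2e-05),
    risk_curve("spline", "male", "log_spline",
               spline_x = c(0, 30, 80, 150),
               spline_logrr = c(0, 0.15, 0.5, 1.1))
  )
}

# Monte-Carlo attributable fraction and its standard error from individual
# draws: an oracle independent of the quadrature path.
mc_aaf <- function(record, model, curve, scenario, n = 1e6, seed = 1) {
  draws <- sample_drinkers(model, n, seed = seed)
  rr <- rr_at(curve, draws,
              scenario = if (scenario$rr_capped) "capped" else "uncapped",
              breakpoints = scenario$breakpoints)
  D <- record$p_lifetime_abstainer + record$p_former * rr_former(curve) +
    record$p_current * mean(rr)
  se_D <- record$p_current * stats::sd(rr) / sqrt(n)
  list(aaf = (D - 1) / D, se = se_D / D^2)
}
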