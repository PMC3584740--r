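#' Breakpoints governing relative-risk extension beyond the observed range
#'
#' Dose-response relative-risk (RR) curves come from meta-analyses of
#' cohorts whose heaviest drinkers rarely exceed 120-150 g/day, so the
#' fitted curves are not considered valid beyond that range. Two
#' conventions for extending them are supported: hold the curve constant
#' past its validity limit ("capped"), or continue it linearly from
#' `linear_start` (default 150 g/day) using the tangent slope there, and
#' hold it constant past `hard_cap` (default 300 g/day) to keep the
#' extension from becoming unrealistic.
#'
#' @param linear_start grams/day where the linear extension begins;
#'   default 150.
#' @param hard_cap grams/day beyond which the extended curve is constant;
#'   default 300. Must satisfy `0 < linear_start <= hard_cap`.
#' @return an object of class `"extension_breakpoints"`.
#' @export
extension_breakpoints <- function(linear_start = 150, hard_cap = 300) {
  if (!(is.numeric(linear_start) && is.numeric(hard_cap) &&
        linear_start > 0 && linear_start <= hard_cap)) {
    stop("breakpoints must satisfy 0 < linear_start <= hard_cap",
         call. = FALSE)
  }
  structure(list(linear_start = linear_start, hard_cap = hard_cap),
            class = "extension_breakpoints")
}

#' Construct a cause- and sex-specific relative-risk curve
#'
#' The curve gives the relative risk of death from `cause` for a current
#' drinker with average daily consumption `x` grams/day, relative to
#' lifetime abstainers (RR = 1). Supported functional forms, all specified
#' on the log-RR scale over the observed range:
#'
#' * `log_linear`: \eqn{\ln RR = \beta_1 x}
#' * `log_quadratic`: \eqn{\ln RR = \beta_1 x + \beta_2 x^2}
#'   (with \eqn{\beta_1 < 0 < \beta_2} this gives the J-shaped curves seen
#'   for ischemic heart disease, diabetes and stroke in women)
#' * `log_spline`: a natural cubic spline through `(spline_x, spline_logrr)`
#'   knots
#' * `categorical`: piecewise-constant RR over contiguous half-open bands
#'   `[lo, hi)` covering `(0, Inf)` (used where only categorical risk
#'   estimates exist, e.g. tuberculosis, myocardial infarction)
#'
#' `x_valid_max` is the validity limit of the underlying meta-analysis
#' (typically 120-150 g/day). `extension_policy` controls behaviour beyond
#' the observed range under the "uncapped" RR scenario:
#' `"linearize_then_cap"` continues linearly then holds constant past the
#' hard cap; `"cap_immediately"` holds the curve constant from the linear
#' start onwards; `"cap_at_valid_max"` holds it constant from
#' `x_valid_max` (always used for categorical curves); `"auto"` chooses
#' between the first two by the slope rule of [classify_extension()].
#'
#' @param cause cause-of-death label.
#' @param sex `"male"` or `"female"`.
#' @param form one of `"log_linear"`, `"log_quadratic"`, `"log_spline"`,
#'   `"categorical"`.
#' @param beta1,beta2 log-RR coefficients per gram/day (and per
#'   (gram/day)^2).
#' @param spline_x,spline_logrr knot locations (g/day) and log-RR values
#'   for `form = "log_spline"`.
#' @param bands for `form = "categorical"`: a data.frame with columns
#'   `lo`, `hi`, `rr`; bands must be contiguous, start at 0, end at `Inf`.
#' @param x_valid_max validity limit of the meta-analysis, grams/day.
#' @param rr_former constant relative risk for former drinkers (no dose
#'   dependence); typically above 1 (the "sick-quitter" effect).
#' @param extension_policy see Details; default `"auto"`.
#' @param slope_threshold log-RR slope (per gram) above which `"auto"`
#'   resolves to `"cap_immediately"`; default 0.02.
#' @param breakpoints an [extension_breakpoints()] object used to resolve
#'   `"auto"`.
#' @return an object of class `"risk_curve"`.
#' @examples
#' cir <- risk_curve("liver cirrhosis", "male", "log_linear", beta1 = 0.012)
#' rr_at(cir, c(20, 100, 200), scenario = "capped")
#' @export
risk_curve <- function(cause, sex,
                       form = c("log_linear", "log_quadratic", "log_spline",
                                "categorical"),
                       beta1 = NULL, beta2 = NULL,
                       spline_x = NULL, spline_logrr = NULL,
                       bands = NULL,
                       x_valid_max = 150, rr_former = 1,
                       extension_policy = c("auto", "linearize_then_cap",
                                            "cap_immediately",
                                            "cap_at_valid_max"),
                       slope_threshold = 0.02,
                       breakpoints = extension_breakpoints()) {
  form <- match.arg(form)
  extension_policy <- match.arg(extension_policy)
  if (!sex %in% c("male", "female")) {
    stop("sex must be 'male' or 'female'", call. = FALSE)
  }
  if (!is.numeric(x_valid_max) || x_valid_max <= 0) {
    stop("x_valid_max must be > 0", call. = FALSE)
  }
  if (!is.numeric(rr_former) || length(rr_former) != 1L || rr_former <= 0) {
    stop("rr_former must be a single positive relative risk", call. = FALSE)
  }
  curve <- structure(
    list(cause = cause, sex = sex, form = form,
         x_valid_max = x_valid_max, rr_former = rr_former),
    class = "risk_curve"
  )
  if (form == "log_linear") {
    if (is.null(beta1)) stop("log_linear form requires beta1", call. = FALSE)
    curve$beta1 <- beta1
  } else if (form == "log_quadratic") {
    if (is.null(beta1) || is.null(beta2)) {
      stop("log_quadratic form requires beta1 and beta2", call. = FALSE)
    }
    curve$beta1 <- beta1
    curve$beta2 <- beta2
  } else if (form == "log_spline") {
    if (is.null(spline_x) || is.null(spline_logrr) ||
        length(spline_x) != length(spline_logrr) || length(spline_x) < 3L) {
      stop("log_spline form requires matching spline_x and spline_logrr ",
           "with at least 3 knots", call. = FALSE)
    }
    curve$spline_x <- spline_x
    curve$spline_logrr <- spline_logrr
  } else { # categorical
    curve$bands <- validate_bands(bands)
  }
  if (form == "categorical") {
    curve$extension_policy <- "cap_at_valid_max"
  } else if (extension_policy == "auto") {
    curve$extension_policy <- classify_extension(curve, breakpoints,
                                                 slope_threshold)
  } else {
    curve$extension_policy <- extension_policy
  }
  curve
}

validate_bands <- function(bands) {
  if (is.null(bands) || !is.data.frame(bands) ||
      !all(c("lo", "hi", "rr") %in% names(bands))) {
    stop("categorical form requires a bands data.frame with columns ",
         "lo, hi, rr", call. = FALSE)
  }
  bands <- bands[order(bands$lo), , drop = FALSE]
  if (bands$lo[1] != 0 || !is.infinite(bands$hi[nrow(bands)])) {
    stop("categorical bands must start at lo = 0 and end at hi = Inf",
         call. = FALSE)
  }
  if (nrow(bands) > 1L &&
      any(abs(bands$hi[-nrow(bands)] - bands$lo[-1]) > 0)) {
    stop("categorical bands must be contiguous and non-overlapping",
         call. = FALSE)
  }
  if (any(bands$rr <= 0)) stop("band relative risks must be > 0",
                               call. = FALSE)
  bands
}

# log RR of the base parametric form (no extension), and its derivative
base_log_rr <- function(curve, x) {
  switch(curve$form,
    log_linear = curve$beta1 * x,
    log_quadratic = curve$beta1 * x + curve$beta2 * x^2,
    log_spline = spline_fun(curve)(x),
    stop("no parametric form for a categorical curve", call. = FALSE)
  )
}

base_log_rr_slope <- function(curve, x) {
  switch(curve$form,
    log_linear = rep(curve$beta1, length(x)),
    log_quadratic = curve$beta1 + 2 * curve$beta2 * x,
    log_spline = spline_fun(curve)(x, deriv = 1),
    stop("no parametric form for a categorical curve", call. = FALSE)
  )
}

spline_fun <- function(curve) {
  stats::splinefun(curve$spline_x, curve$spline_logrr, method = "natural")
}

categorical_rr <- function(curve, x) {
  # bands are half-open [lo, hi): a dose exactly at a cut belongs to the
  # upper band
  idx <- findInterval(x, curve$bands$lo)
  if (any(idx == 0)) stop("dose falls in no categorical band", call. = FALSE)
  curve$bands$rr[idx]
}

#' Evaluate a relative-risk curve at given consumption levels
#'
#' Under `scenario = "capped"` the base form is evaluated at
#' `min(x, x_valid_max)`: risks never grow beyond the range observed in
#' the source cohorts. Under `scenario = "uncapped"` behaviour beyond the
#' observed range follows the curve's extension policy (see
#' [risk_curve()]): the linear extension takes the value
#' `RR(linear_start) + RR'(linear_start) * (x - linear_start)` on
#' `(linear_start, hard_cap]`, with `RR'` the tangent slope of the RR
#' curve itself, and is constant beyond the hard cap. The extension is
#' continuous at both breakpoints by construction.
#'
#' @param curve a `"risk_curve"` object.
#' @param x consumption, grams/day, `>= 0`; vectorized.
#' @param scenario `"capped"` or `"uncapped"`.
#' @param breakpoints an [extension_breakpoints()] object.
#' @return relative risks (dimensionless, `> 0` for any valid curve).
#' @export
rr_at <- function(curve, x, scenario = c("capped", "uncapped"),
                  breakpoints = extension_breakpoints()) {
  stopifnot(inherits(curve, "risk_curve"))
  scenario <- match.arg(scenario)
  if (any(x < 0)) stop("consumption must be >= 0", call. = FALSE)
  if (curve$form == "categorical") {
    # categorical risks are held at the band containing x_valid_max beyond
    # the validity limit in both scenarios
    return(categorical_rr(curve, pmin(x, curve$x_valid_max)))
  }
  if (scenario == "capped") {
    return(exp(base_log_rr(curve, pmin(x, curve$x_valid_max))))
  }
  policy <- curve$extension_policy
  if (policy == "cap_at_valid_max") {
    return(exp(base_log_rr(curve, pmin(x, curve$x_valid_max))))
  }
  ls <- breakpoints$linear_start
  hc <- breakpoints$hard_cap
  if (policy == "cap_immediately") {
    return(exp(base_log_rr(curve, pmin(x, ls))))
  }
  # linearize_then_cap
  rr_ls <- exp(base_log_rr(curve, ls))
  slope <- rr_ls * base_log_rr_slope(curve, ls) # dRR/dx at linear_start
  xe <- pmin(x, hc)
  ifelse(x <= ls,
         exp(base_log_rr(curve, x)),
         rr_ls + slope * (xe - ls))
}

#' @export
predict.risk_curve <- function(object, x, scenario = "capped",
                               breakpoints = extension_breakpoints(), ...) {
  rr_at(object, x, scenario = scenario, breakpoints = breakpoints)
}

#' Relative risk for former drinkers
#'
#' Former drinkers carry a single dose-independent relative risk, usually
#' above 1 because many quit for health reasons.
#'
#' @param curve a `"risk_curve"` object.
#' @return the former-drinker relative risk.
#' @export
rr_former <- function(curve) {
  stopifnot(inherits(curve, "risk_curve"))
  if (is.null(curve$rr_former) || !is.finite(curve$rr_former)) {
    stop("curve for '", curve$cause, "' carries no former-drinker relative ",
         "risk", call. = FALSE)
  }
  curve$rr_former
}

#' Choose an extension policy from the curve's slope at the linear start
#'
#' A curve whose log-RR slope at `linear_start` exceeds `slope_threshold`
#' is growing so fast that even a linear continuation is implausible, and
#' is capped immediately; otherwise it is linearized first and capped at
#' the hard cap. The slope is the analytic derivative of the parametric
#' form. The classification is advisory: configurations may override it
#' per cause. Categorical curves have no slope and are always held at the
#' validity limit.
#'
#' @param curve a `"risk_curve"` object.
#' @param breakpoints an [extension_breakpoints()] object.
#' @param slope_threshold log-RR growth per gram above which the curve is
#'   capped immediately; default 0.02.
#' @return one of `"cap_immediately"`, `"linearize_then_cap"`,
#'   `"cap_at_valid_max"`.
#' @export
classify_extension <- function(curve, breakpoints = extension_breakpoints(),
                               slope_threshold = 0.02) {
  stopifnot(inherits(curve, "risk_curve"))
  if (curve$form == "categorical") return("cap_at_valid_max")
  slope <- base_log_rr_slope(curve, breakpoints$linear_start)
  if (is.finite(slope_threshold) && slope > slope_threshold) {
    "cap_immediately"
  } else {
    "linearize_then_cap"
  }
}

#' Non-smooth points of an (extended) relative-risk curve
#'
#' Returns the consumption levels at which the extended curve has a kink
#' or jump: the validity limit, the linear start and hard cap, and any
#' categorical band cuts. Integrals of density times RR are split at these
#' points so each piece is smooth.
#'
#' @keywords internal
rr_breakpoints <- function(curve, breakpoints = extension_breakpoints()) {
  if (curve$form == "categorical") {
    cuts <- curve$bands$lo[-1]
    return(sort(unique(c(cuts, curve$x_valid_max))))
  }
  sort(unique(c(curve$x_valid_max, breakpoints$linear_start,
                breakpoints$hard_cap)))
}

#' @export
print.risk_curve <- function(x, ...) {
  cat(sprintf("Relative-risk curve: %s (%s)\n", x$cause, x$sex))
  desc <- switch(x$form,
    log_linear = sprintf("ln RR = %g x", x$beta1),
    log_quadratic = sprintf("ln RR = %g x + %g x^2", x$beta1, x$beta2),
    log_spline = sprintf("natural spline on %d log-RR knots",
                         length(x$spline_x)),
    categorical = sprintf("categorical, %d bands", nrow(x$bands))
  )
  cat("  form: ", desc, "\n", sep = "")
  cat(sprintf("  valid to %g g/day; former-drinker RR %g; extension: %s\n",
              x$x_valid_max, x$rr_former, x$extension_policy))
  invisible(x)
}

#' Read a set of relative-risk curves from a YAML configuration
#'
#' The file holds a top-level list `curves`, each entry with fields
#' `cause`, `sex`, `form`, the form's coefficients (`beta1`, `beta2`,
#' `spline_x`/`spline_logrr`, or `bands` as a list of `[lo, hi, rr]`
#' triples), and optionally `x_valid_max`, `rr_former` and
#' `extension_policy` (default `"auto"`). Validation errors name the
#' offending entry and field.
#'
#' @param path path to a YAML file.
#' @param breakpoints an [extension_breakpoints()] object used to resolve
#'   `"auto"` policies.
#' @param slope_threshold passed to [classify_extension()].
#' @return a list of `"risk_curve"` objects, classed `"risk_curve_set"`,
#'   named `"<cause>|<sex>"`.
#' @export
read_risk_config <- function(path, breakpoints = extension_breakpoints(),
                             slope_threshold = 0.02) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$curves) || !is.list(raw$curves)) {
    stop("risk config must contain a top-level 'curves' list", call. = FALSE)
  }
  curves <- lapply(seq_along(raw$curves), function(i) {
    entry <- raw$curves[[i]]
    where <- sprintf("curves[%d]", i)
    for (fld in c("cause", "sex", "form")) {
      if (is.null(entry[[fld]])) {
        stop(where, " is missing required field '", fld, "'", call. = FALSE)
      }
    }
    bands <- NULL
    if (identical(entry$form, "categorical")) {
      if (is.null(entry$bands)) {
        stop(where, " (", entry$cause, "): categorical form requires ",
             "field 'bands'", call. = FALSE)
      }
      bands <- do.call(rbind, lapply(entry$bands, function(b) {
        if (length(b) != 3L) {
          stop(where, " (", entry$cause, "): each band must be ",
               "[lo, hi, rr]", call. = FALSE)
        }
        hi <- if (identical(b[[2]], "Inf") || is.infinite(b[[2]])) Inf
              else as.numeric(b[[2]])
        data.frame(lo = as.numeric(b[[1]]), hi = hi, rr = as.numeric(b[[3]]))
      }))
    }
    tryCatch(
      risk_curve(
        cause = entry$cause, sex = entry$sex, form = entry$form,
        beta1 = entry$beta1, beta2 = entry$beta2,
        spline_x = unlist(entry$spline_x),
        spline_logrr = unlist(entry$spline_logrr),
        bands = bands,
        x_valid_max = entry$x_valid_max %||% 150,
        rr_former = entry$rr_former %||% 1,
        extension_policy = entry$extension_policy %||% "auto",
        slope_threshold = slope_threshold,
        breakpoints = breakpoints
      ),
      error = function(e) {
        stop(where, " (", entry$cause %||% "?", "): ", conditionMessage(e),
             call. = FALSE)
      }
    )
  })
  names(curves) <- vapply(curves, function(cu) paste(cu$cause, cu$sex,
                                                     sep = "|"), "")
  if (anyDuplicated(names(curves))) {
    stop("duplicate (cause, sex) entries in risk config: ",
         paste(unique(names(curves)[duplicated(names(curves))]),
               collapse = ", "), call. = FALSE)
  }
  structure(curves, class = "risk_curve_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
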