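Package: alcaaf
Title: Alcohol-Attributable Fractions with Capped and Uncapped Exposure and
    Risk Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models population alcohol exposure among current drinkers as a
    gamma distribution fitted from adult per-capita consumption and drinker
    prevalence, with optional truncation (capping) at a maximum average daily
    intake. Represents cause- and sex-specific relative-risk curves of average
    daily consumption with configurable extension policies beyond the validity
    range of the underlying meta-analyses (hold constant, or linearize then
    cap). Computes alcohol-attributable fractions by integrating the exposure
    density against the relative-risk curve, applies them to cause-specific
    death counts, and decomposes the difference between capped and uncapped
    scenario totals into distribution-capping and risk-capping components. A
    seeded synthetic-data generator produces exposure tables, mortality tables
    and risk-curve configurations with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
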