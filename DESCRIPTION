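Package: capricurve
Title: Growth-Curve Modelling of Body and Digestive-Tract Development in Goat Kids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits eight classical growth-model families (Logistic, Gompertz,
    Ratkowsky, Morgan-Mercer-Flodin, Weibull, Richards, Quadratic, Cubic) to
    cross-sectional age-series measurements of young ruminants by damped
    (Levenberg-Marquardt) or exact least squares, selects the best family per
    variable by small-sample information criteria (MSE, AIC, AICc, BIC),
    derives closed-form inflection points and stage-windowed areas under the
    fitted curve, and tabulates Pearson correlations of each trait against age
    and body weight. Includes a seeded synthetic-data generator emulating an
    eight-age, six-replicate slaughter design so the whole pipeline is testable
    without animal data, and a command-line entry point for reproducible runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    minpack.lm,
    optparse
Config/testthat/edition: 3
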