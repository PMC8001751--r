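# Shared fixtures: the published best-model parameter sets (body and
# digestive-tract variables) and the study design ages. Built in code — no
# data files.

design_ages <- c(1, 7, 14, 28, 42, 56, 70, 84)

published_fits <- list(
  body_weight   = list(family = "Gompertz",
                       params = c(a = 18.61, b = 0.62, c = 0.0135), sd = 1.22),
  carcass       = list(family = "Logistic",
                       params = c(a = 5.44, b = 2.89, c = 0.039), sd = 0.79),
  dressing      = list(family = "Quadratic",
                       params = c(a = 47.61, b = 0.24, c = -2.82e-3), sd = 3.39),
  height        = list(family = "Logistic",
                       params = c(a = 54.57, b = 0.77, c = 0.0146), sd = 3.24),
  chest_depth   = list(family = "MMF",
                       params = c(a = 8.21, b = 6.3e3, c = 21.45, d = 2.68), sd = 3.05),
  reticulum_g   = list(family = "Weibull",
                       params = c(a = 30.22, b = 25.36, c = 2.8e-6, d = 3.25), sd = 4.76),
  rumen_ph      = list(family = "Cubic",
                       params = c(a = 6.12, b = 0.04, c = -1.5e-3, d = 1.3e-5), sd = 0.52),
  rumen_pct     = list(family = "MMF",
                       params = c(a = 22.52, b = 1.9e3, c = 61.55, d = 2.26), sd = 6.64),
  omasum_pct    = list(family = "Weibull",
                       params = c(a = 10.06, b = 4.69, c = 3.7e-10, d = 5.21), sd = 1.96),
  abomasum_pct  = list(family = "MMF",
                       params = c(a = 60.93, b = 1.1e4, c = 17.99, d = 2.70), sd = 6.43)
)

# Valid random parameter draw per family, for property-style loops.
random_params <- function(family) {
  fam <- growth_family(family)
  switch(fam$name,
    Logistic  = c(a = runif(1, 2, 60), b = runif(1, 0.3, 8), c = runif(1, 0.01, 0.1)),
    Gompertz  = c(a = runif(1, 2, 60), b = runif(1, -1, 1.8), c = runif(1, 0.01, 0.1)),
    Ratkowsky = c(a = runif(1, 2, 60), b = runif(1, -1, 2), c = runif(1, 0.01, 0.1)),
    Richards  = c(a = runif(1, 2, 60), b = runif(1, -1, 2),
                  c = runif(1, 0.01, 0.1), d = runif(1, 0.3, 3)),
    MMF       = c(a = runif(1, 1, 10), b = runif(1, 50, 5000),
                  c = runif(1, 15, 80), d = runif(1, 1.3, 3.5)),
    Weibull   = c(a = runif(1, 10, 60), b = runif(1, 5, 30),
                  c = exp(runif(1, -12, -4)), d = runif(1, 1.3, 4)),
    Quadratic = c(a = runif(1, -5, 50), b = runif(1, -1, 5), c = runif(1, -0.05, 0.05)),
    Cubic     = c(a = runif(1, -5, 50), b = runif(1, -1, 5),
                  c = runif(1, -0.05, 0.05), d = runif(1, 1e-4, 1e-2))
  )
}

# Simulated slice of the 8-age x 6-replicate design for one generating curve.
simulate_slice <- function(family, params, sd = 0, replicates = 6) {
  x <- rep(design_ages, each = replicates)
  y <- growth_evaluate(family, params, x) + rnorm(length(x), 0, sd)
  list(x = x, y = y)
}
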