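test_that("family metadata matches the model inventory", {
  expect_length(growth_families(), 8)
  counts <- vapply(growth_families(), function(f) growth_family(f)$param_count, integer(1))
  expect_equal(unname(counts[c("Logistic", "Gompertz", "Ratkowsky", "Quadratic")]),
               rep(3L, 4))
  expect_equal(unname(counts[c("MMF", "Weibull", "Richards", "Cubic")]),
               rep(4L, 4))
  kinds <- vapply(growth_families(), function(f) growth_family(f)$kind, character(1))
  expect_setequal(names(kinds)[kinds == "polynomial"], c("Quadratic", "Cubic"))
  expect_false(growth_family("Quadratic")$has_closed_inflection)
  expect_error(growth_family("Brody"), class = "capricurve_invalid_input")
})

test_that("curve evaluation matches the closed equations at anchor points", {
  # MMF at the origin: x^d terms cancel, y = ab/b = a
  expect_equal(growth_evaluate("MMF", published_fits$chest_depth$params, 0), 8.21)
  # Logistic midpoint symmetry: y = a/2 at x = ln(b)/c
  pc <- published_fits$carcass$params
  expect_equal(growth_evaluate("Logistic", pc, log(pc[["b"]]) / pc[["c"]]),
               5.44 / 2)
  # Weibull at the origin with d > 0: y = a - b
  pr <- published_fits$reticulum_g$params
  expect_equal(growth_evaluate("Weibull", pr, 0), 30.22 - 25.36)
  # independent scalar-arithmetic oracle for the Gompertz equation
  expect_equal(growth_evaluate("Gompertz", published_fits$body_weight$params, 84),
               10.232824858452, tolerance = 1e-10)
})

test_that("domain violations and bad parameter vectors are classed errors", {
  expect_error(growth_evaluate("MMF", c(a = 1, b = 2, c = 3, d = 2.5), -1),
               class = "capricurve_domain_error")
  expect_error(growth_evaluate("MMF", c(a = 1, b = 2, c = 3, d = 2.5), -1),
               regexp = "MMF.*x")
  expect_error(growth_evaluate("Logistic", c(a = 1, b = 2), 1),
               class = "capricurve_invalid_input")
  expect_error(growth_evaluate("Logistic", c(a = 1, b = 2, c = NaN), 1),
               class = "capricurve_invalid_input")
  # negative x with integer d is fine
  expect_silent(growth_evaluate("Weibull", c(a = 1, b = 1, c = 0.1, d = 2), -3))
})

test_that("analytic gradients agree with central finite differences", {
  set.seed(42)
  for (fam in growth_families()) {
    for (rep in 1:5) {
      p <- random_params(fam)
      x <- c(0.5, sample(design_ages, 4))
      g <- growth_gradient(fam, p, x)
      expect_equal(dim(g), c(length(x), growth_family(fam)$param_count))
      for (j in seq_along(p)) {
        h <- 1e-6 * max(abs(p[j]), 1e-3)
        pp <- p; pp[j] <- p[j] + h
        pm <- p; pm[j] <- p[j] - h
        fd <- (growth_evaluate(fam, pp, x) - growth_evaluate(fam, pm, x)) / (2 * h)
        # relative to the column scale: FD itself loses all accuracy on
        # entries deep in saturation where the true partial underflows
        expect_lt(max(abs(g[, j] - fd)) / max(max(abs(fd)), 1e-8), 1e-4,
                  label = sprintf("%s d/d%s mismatch", fam, names(p)[j]))
      }
    }
  }
  # spot anchors: Gompertz is linear in a; Quadratic gradient is the power basis
  p <- published_fits$body_weight$params
  expect_equal(unname(growth_gradient("Gompertz", p, 30)[, "a"]),
               growth_evaluate("Gompertz", p, 30) / p[["a"]])
  expect_equal(unname(growth_gradient("Quadratic", c(a = 1, b = 1, c = 1), 2)),
               matrix(c(1, 2, 4), 1))
})

test_that("closed-form inflection points sit where the curvature changes sign", {
  set.seed(7)
  for (fam in setdiff(growth_families(), "Quadratic")) {
    for (rep in 1:10) {
      p <- random_params(fam)
      ip <- tryCatch(inflection_point(fam, p), capricurve_error = function(e) NULL)
      if (is.null(ip)) next  # undefined closed form for this draw
      # curve passes through (IPx, IPy)
      if (!(fam %in% c("MMF", "Weibull") && ip$IPx < 0)) {
        expect_equal(growth_evaluate(fam, p, ip$IPx), ip$IPy,
                     tolerance = 1e-8, label = sprintf("%s IPy", fam))
      }
      # root of the central-difference second derivative within 1e-6 of IPx
      d2h <- function(x, h) {
        (growth_evaluate(fam, p, x + h) - 2 * growth_evaluate(fam, p, x) +
           growth_evaluate(fam, p, x - h)) / h^2
      }
      h <- 0.1  # large enough that roundoff in the second difference is negligible
      # Richardson-extrapolated central difference (kills the O(h^2) bias)
      d2 <- function(x) (4 * d2h(x, h / 2) - d2h(x, h)) / 3
      x0 <- ip$IPx
      w <- max(1, 0.05 * abs(x0))
      lo <- x0 - w; hi <- x0 + w
      if (fam %in% c("MMF", "Weibull")) {
        if (x0 <= 2 * h) next                # inflection too close to the origin
        lo <- max(lo, 2 * h)
      }
      if (sign(d2(lo)) * sign(d2(hi)) < 0) {
        root <- uniroot(d2, c(lo, hi), tol = 1e-10)$root
        expect_lt(abs(root - x0), 1e-6,
                  label = sprintf("%s numeric inflection at %g vs closed form %g",
                                  fam, root, x0))
      }
    }
  }
})

test_that("inflection closed forms reproduce published anchor values", {
  ip <- inflection_point("Logistic", published_fits$height$params)
  expect_equal(round_half_up(ip$IPy), 27.29)
  expect_equal(round_half_up(ip$IPx), -17.90)
  ip <- inflection_point("Weibull", published_fits$reticulum_g$params)
  expect_equal(ip$IPy, 17.54, tolerance = 0.005)
  expect_equal(ip$IPx, 45.61, tolerance = 0.005)
  expect_null(inflection_point("Quadratic", c(a = 1, b = 2, c = 3)))
  # Ratkowsky reports its inflection via the logistic equivalence, flagged
  ipr <- inflection_point("Ratkowsky", c(a = 10, b = 1.2, c = 0.04))
  expect_equal(ipr$method, "logistic_equivalence")
  expect_equal(ipr$IPy, 5)
  expect_equal(ipr$IPx, 30)
})

test_that("undefined inflection closed forms signal invalid parameters", {
  expect_error(inflection_point("Weibull", c(a = 1, b = 1, c = 0.1, d = 0.8)),
               class = "capricurve_invalid_params")
  expect_error(inflection_point("MMF", c(a = 1, b = 10, c = 3, d = 1)),
               class = "capricurve_invalid_params")
  expect_error(inflection_point("Cubic", c(a = 1, b = 1, c = 1, d = 0)),
               class = "capricurve_invalid_params")
  expect_error(inflection_point("Logistic", c(a = 1, b = 2, c = 0)),
               class = "capricurve_invalid_params")
})

test_that("Ratkowsky is a Logistic reparameterization and Richards(d=1) a Logistic", {
  set.seed(11)
  x <- seq(0, 100, by = 0.5)
  for (rep in 1:10) {
    p <- random_params("Ratkowsky")
    y_rat <- growth_evaluate("Ratkowsky", p, x)
    y_log <- growth_evaluate("Logistic",
                             c(a = p[["a"]], b = exp(p[["b"]]), c = p[["c"]]), x)
    expect_equal(y_rat, y_log, tolerance = 1e-12)
    y_ric <- growth_evaluate("Richards", c(p, d = 1), x)
    expect_equal(y_ric, y_rat, tolerance = 1e-12)
  }
})

test_that("MMF starts at its intercept and saturates at its asymptote", {
  p <- published_fits$rumen_pct$params
  expect_equal(growth_evaluate("MMF", p, 0), p[["a"]])
  expect_equal(growth_evaluate("MMF", p, 1e6), p[["c"]], tolerance = 1e-3)
})

test_that("initial guesses are usable start points", {
  # exact least squares on constant data
  expect_equal(initial_guess("Quadratic", 1:8, rep(5, 8)),
               c(a = 5, b = 0, c = 0))
  # constant data yields a flat-curve guess for every sigmoid, not an error
  for (fam in setdiff(growth_families(), c("Quadratic", "Cubic"))) {
    g <- initial_guess(fam, design_ages, rep(5, 8))
    expect_true(all(is.finite(g)), label = fam)
    expect_equal(unname(growth_evaluate(fam, g, 40)), 5, tolerance = 0.01,
                 label = sprintf("%s flat guess", fam))
  }
  # strictly increasing data: asymptote-role parameter at least max(y)
  sl <- simulate_slice("Logistic", published_fits$carcass$params)
  for (fam in setdiff(growth_families(), c("Quadratic", "Cubic"))) {
    g <- initial_guess(fam, sl$x, sl$y)
    asym <- if (fam == "MMF") g[["c"]] else g[["a"]]
    expect_gte(asym, max(sl$y))
  }
  # recovery: the fitter reaches the generating parameters from the guess
  fit <- fit_curve("Logistic", sl$x, sl$y)
  expect_true(fit$converged)
  expect_equal(fit$params, published_fits$carcass$params, tolerance = 1e-6)
  expect_error(initial_guess("Cubic", c(1, 2, 3), c(1, 2, 3)),
               class = "capricurve_insufficient_data")
})
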