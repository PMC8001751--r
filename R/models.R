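#' The eight growth-model families
#'
#' The model inventory used throughout the package: six sigmoidal families —
#' Logistic, Gompertz, Ratkowsky, MMF (Morgan-Mercer-Flodin), Weibull and
#' Richards — and two polynomial baselines (Quadratic, Cubic). Three-parameter
#' families use parameters `a, b, c`; four-parameter families add a shape
#' parameter `d`.
#'
#' Parameter semantics for the sigmoidal families: `a` is the curve scale
#' (asymptote for all families except MMF, where `a` is the intercept at age 0
#' and `c` is the asymptote), `b` a scaling constant of integration, `c` the
#' maturing (rate) index per day, `d` a shape parameter governing where the
#' inflection sits. For polynomials the parameters are ordinary regression
#' coefficients on the power basis.
#'
#' @param name one of `growth_families()` (case-insensitive).
#' @return `growth_family()` returns a `"growth_family"` object with fields
#'   `name`, `kind` (`"sigmoidal"` or `"polynomial"`), `param_count`,
#'   `param_names`, and `has_closed_inflection`. `growth_families()` returns
#'   the eight family names in the package's fixed tie-break order.
#' @export
#' @examples
#' growth_families()
#' growth_family("Gompertz")
growth_family <- function(name) {
  name <- match.arg0(name)
  p <- if (name %in% c("MMF", "Weibull", "Richards", "Cubic")) 4L else 3L
  structure(
    list(
      name = name,
      kind = if (name %in% c("Quadratic", "Cubic")) "polynomial" else "sigmoidal",
      param_count = p,
      param_names = c("a", "b", "c", "d")[seq_len(p)],
      has_closed_inflection = name != "Quadratic"
    ),
    class = "growth_family"
  )
}

#' @rdname growth_family
#' @export
growth_families <- function() {
  c("Logistic", "Gompertz", "Ratkowsky", "Quadratic", "Cubic",
    "MMF", "Weibull", "Richards")
}

match.arg0 <- function(name) {
  hit <- match(tolower(name[1]), tolower(growth_families()))
  if (is.na(hit)) {
    cc_stop(sprintf("unknown model family '%s'", name), "capricurve_invalid_input")
  }
  growth_families()[hit]
}

#' @export
print.growth_family <- function(x, ...) {
  cat(sprintf("<growth_family> %s (%s, %d parameters: %s)\n",
              x$name, x$kind, x$param_count,
              paste(x$param_names, collapse = ", ")))
  invisible(x)
}

as_family <- function(family) {
  if (inherits(family, "growth_family")) family else growth_family(family)
}

check_params <- function(family, params) {
  family <- as_family(family)
  if (is.list(params)) params <- unlist(params)
  need <- family$param_names
  if (!is.null(names(params)) && all(need %in% names(params))) {
    params <- params[need]
  } else if (length(params) == family$param_count) {
    names(params) <- need
  } else {
    cc_stop(sprintf("%s needs %d parameters (%s), got %d",
                    family$name, family$param_count,
                    paste(need, collapse = ","), length(params)),
            "capricurve_invalid_input")
  }
  if (!all(is.finite(params))) {
    cc_stop(sprintf("non-finite parameter for %s", family$name),
            "capricurve_invalid_input")
  }
  params
}

## x^d in log space where possible (numerical stability at large d); signals a
## domain error for negative x with fractional d, where x^d is undefined.
pow_xd <- function(x, d, family) {
  out <- numeric(length(x))
  neg <- x < 0
  if (any(neg) && abs(d - round(d)) > 1e-12) {
    cc_stop(sprintf("%s undefined for x < 0 with non-integer shape d = %g (offending argument: x)",
                    family, d),
            "capricurve_domain_error")
  }
  pos <- x > 0
  out[pos] <- exp(d * log(x[pos]))
  out[neg] <- x[neg]^d
  out[x == 0] <- if (d > 0) 0 else if (d == 0) 1 else Inf
  out
}

#' Evaluate a growth curve
#'
#' Evaluates the family's equation at ages `x`:
#' \describe{
#'   \item{Logistic}{\eqn{y = a / (1 + b e^{-cx})}}
#'   \item{Gompertz}{\eqn{y = a \exp(-\exp(b - cx))}}
#'   \item{Ratkowsky}{\eqn{y = a / (1 + e^{b - cx})} (a Logistic
#'     reparameterization with \eqn{b_{logis} = e^{b}})}
#'   \item{MMF}{\eqn{y = (ab + cx^d) / (b + x^d)}}
#'   \item{Weibull}{\eqn{y = a - b \exp(-c x^d)}}
#'   \item{Richards}{\eqn{y = a / (1 + e^{b - cx})^{1/d}}}
#'   \item{Quadratic / Cubic}{power-basis polynomials}
#' }
#'
#' @param family a `"growth_family"` or family name.
#' @param params named numeric vector of parameters `a, b, c` (and `d` for
#'   four-parameter families).
#' @param x numeric vector of ages in days.
#' @return numeric vector of curve values in the response's units.
#' @seealso [growth_gradient()], [inflection_point()], [area_under_curve()]
#' @export
#' @examples
#' growth_evaluate("Gompertz", c(a = 18.61, b = 0.62, c = 0.0135), x = c(1, 42, 84))
growth_evaluate <- function(family, params, x) {
  family <- as_family(family)
  p <- check_params(family, params)
  if (!all(is.finite(x))) {
    cc_stop(sprintf("%s: non-finite age x", family$name), "capricurve_invalid_input")
  }
  a <- p[["a"]]; b <- p[["b"]]; cc <- p[["c"]]
  d <- if (family$param_count == 4L) p[["d"]] else NA_real_
  switch(family$name,
    Logistic  = a / (1 + b * exp(-cc * x)),
    Gompertz  = a * exp(-exp(b - cc * x)),
    Ratkowsky = a / (1 + exp(b - cc * x)),
    Richards  = a / (1 + exp(b - cc * x))^(1 / d),
    MMF       = { t <- pow_xd(x, d, "MMF"); (a * b + cc * t) / (b + t) },
    Weibull   = { t <- pow_xd(x, d, "Weibull"); a - b * exp(-cc * t) },
    Quadratic = a + b * x + cc * x^2,
    Cubic     = a + b * x + cc * x^2 + d * x^3
  )
}

#' Analytic parameter gradient of a growth curve
#'
#' Partial derivatives of the curve value with respect to each parameter,
#' needed as the Jacobian of the damped least-squares fitter. MMF and Weibull
#' evaluate \eqn{x^d} in log space for stability at large shape values.
#'
#' @inheritParams growth_evaluate
#' @return a `length(x)` by `param_count` matrix with columns named after the
#'   parameters.
#' @export
growth_gradient <- function(family, params, x) {
  family <- as_family(family)
  p <- check_params(family, params)
  a <- p[["a"]]; b <- p[["b"]]; cc <- p[["c"]]
  d <- if (family$param_count == 4L) p[["d"]] else NA_real_
  n <- length(x)
  g <- switch(family$name,
    Logistic = {
      E <- exp(-cc * x); D <- 1 + b * E
      cbind(a = 1 / D, b = -a * E / D^2, c = a * b * x * E / D^2)
    },
    Gompertz = {
      u <- exp(b - cc * x); E <- exp(-u)
      cbind(a = E, b = -a * E * u, c = a * E * u * x)
    },
    Ratkowsky = {
      E <- exp(b - cc * x); D <- 1 + E
      cbind(a = 1 / D, b = -a * E / D^2, c = a * x * E / D^2)
    },
    Richards = {
      E <- exp(b - cc * x); D <- 1 + E
      y <- a * D^(-1 / d)
      cbind(a = D^(-1 / d),
            b = -a / d * D^(-1 / d - 1) * E,
            c = a / d * D^(-1 / d - 1) * E * x,
            d = y * log(D) / d^2)
    },
    MMF = {
      t <- pow_xd(x, d, "MMF"); D <- b + t
      dt_dd <- ifelse(x > 0, t * log(x), 0)
      cbind(a = b / D,
            b = t * (a - cc) / D^2,
            c = t / D,
            d = b * (cc - a) / D^2 * dt_dd)
    },
    Weibull = {
      t <- pow_xd(x, d, "Weibull"); E <- exp(-cc * t)
      dt_dd <- ifelse(x > 0, t * log(x), 0)
      cbind(a = rep(1, n), b = -E, c = b * t * E, d = b * cc * E * dt_dd)
    },
    Quadratic = cbind(a = rep(1, n), b = x, c = x^2),
    Cubic     = cbind(a = rep(1, n), b = x, c = x^2, d = x^3)
  )
  g
}

#' Closed-form inflection point
#'
#' Age (`IPx`, days) and response value (`IPy`) at which the curve's concavity
#' changes — biologically, the age of peak growth rate. Closed forms per
#' family:
#' \tabular{lll}{
#'   Logistic \tab \eqn{IPx = \ln(b)/c} \tab \eqn{IPy = a/2} \cr
#'   Gompertz \tab \eqn{IPx = b/c} \tab \eqn{IPy = a/e} \cr
#'   Ratkowsky \tab \eqn{IPx = b/c} \tab \eqn{IPy = a/2} (via its Logistic form) \cr
#'   Richards \tab \eqn{IPx = (b - \ln d)/c} \tab \eqn{IPy = a(1+d)^{-1/d}} \cr
#'   MMF \tab \eqn{IPx = (b(d-1)/(d+1))^{1/d}} \tab \eqn{IPy = (d(c+a)+(a-c))/(2d)} \cr
#'   Weibull \tab \eqn{IPx = ((d-1)/(cd))^{1/d}} \tab \eqn{IPy = a - b e^{(1-d)/d}} \cr
#'   Cubic \tab \eqn{IPx = -c/(3d)} \tab \eqn{IPy} by evaluation \cr
#' }
#' The Quadratic has a constant second derivative and no inflection (`NULL`).
#' A negative `IPx` (inflection before birth) is returned as-is: for traits
#' already decelerating at birth the fitted inflection legitimately precedes
#' the observation window.
#'
#' @inheritParams growth_evaluate
#' @return an `"inflection_point"` list with `IPx`, `IPy` and `method`
#'   (`"closed_form"` or, for Ratkowsky, `"logistic_equivalence"`), or `NULL`
#'   for the Quadratic family.
#' @export
#' @examples
#' inflection_point("Logistic", c(a = 54.57, b = 0.77, c = 0.0146))
inflection_point <- function(family, params) {
  family <- as_family(family)
  p <- check_params(family, params)
  a <- p[["a"]]; b <- p[["b"]]; cc <- p[["c"]]
  d <- if (family$param_count == 4L) p[["d"]] else NA_real_
  bad <- function(msg) cc_stop(sprintf("%s inflection undefined: %s", family$name, msg),
                               "capricurve_invalid_params")
  method <- "closed_form"
  ip <- switch(family$name,
    Quadratic = return(NULL),
    Logistic = {
      if (b <= 0) bad("requires b > 0")
      if (cc == 0) bad("c = 0")
      list(IPx = log(b) / cc, IPy = a / 2)
    },
    Gompertz = {
      if (cc == 0) bad("c = 0")
      list(IPx = b / cc, IPy = a / exp(1))
    },
    Ratkowsky = {
      if (cc == 0) bad("c = 0")
      method <- "logistic_equivalence"
      list(IPx = b / cc, IPy = a / 2)
    },
    Richards = {
      if (cc == 0) bad("c = 0")
      if (d <= 0) bad("requires d > 0")
      list(IPx = (b - log(d)) / cc, IPy = a * (1 + d)^(-1 / d))
    },
    MMF = {
      if (b <= 0) bad("requires b > 0")
      if (d <= 1) bad("requires d > 1")
      list(IPx = (b * (d - 1) / (d + 1))^(1 / d),
           IPy = (d * (cc + a) + (a - cc)) / (2 * d))
    },
    Weibull = {
      if (d <= 1) bad("requires d > 1")
      if (cc <= 0) bad("requires c > 0")
      list(IPx = ((d - 1) / (cc * d))^(1 / d),
           IPy = a - b * exp((1 - d) / d))
    },
    Cubic = {
      if (d == 0) bad("d = 0 (no cubic term)")
      ipx <- -cc / (3 * d)
      list(IPx = ipx, IPy = growth_evaluate(family, p, ipx))
    }
  )
  structure(c(ip, list(method = method)), class = "inflection_point")
}

#' @export
print.inflection_point <- function(x, ...) {
  cat(sprintf("Inflection point: IPx = %.4g d, IPy = %.4g (%s)\n",
              x$IPx, x$IPy, x$method))
  invisible(x)
}

## ---- initial guesses ------------------------------------------------------

## Linearized-transform slope/intercept, guarded against degenerate designs.
.safe_line <- function(x, z) {
  ok <- is.finite(z) & is.finite(x)
  if (sum(ok) < 2 || stats::sd(x[ok]) == 0) return(c(intercept = mean(z[ok]), slope = 0))
  fit <- stats::lm.fit(cbind(1, x[ok]), z[ok])
  c(intercept = unname(fit$coefficients[1]), slope = unname(fit$coefficients[2]))
}

.poly_guess <- function(x, y, degree) {
  X <- stats::poly(x, degree = degree, raw = TRUE, simple = TRUE)
  X <- cbind(1, X)
  co <- qr.coef(qr(X), y)
  co[is.na(co)] <- 0
  stats::setNames(co, c("a", "b", "c", "d")[seq_len(degree + 1)])
}

#' Heuristic starting values for curve fitting
#'
#' Produces the start point for the damped least-squares fitter. Polynomial
#' families are initialized at their exact least-squares solution (no
#' iteration needed). Sigmoidal families set the asymptote-role parameter
#' from `1.05 * max(y)` (or the data minimum for decreasing series), take the
#' rate `c` from the slope of the family's linearizing transform, and default
#' the shape `d` to 1.5. Constant data yields a flat-curve guess rather than
#' an error.
#'
#' @inheritParams growth_evaluate
#' @param x,y numeric vectors of ages (days) and responses; at least
#'   `param_count + 1` observations over at least `param_count` distinct ages.
#' @return named numeric parameter vector suitable for [fit_curve()].
#' @export
initial_guess <- function(family, x, y) {
  family <- as_family(family)
  stopifnot(length(x) == length(y))
  if (length(y) < family$param_count + 1 ||
      length(unique(x)) < family$param_count) {
    cc_stop(sprintf("%s needs >= %d observations over >= %d distinct ages",
                    family$name, family$param_count + 1, family$param_count),
            "capricurve_insufficient_data")
  }
  if (family$kind == "polynomial") {
    return(.poly_guess(x, y, degree = family$param_count - 1L))
  }
  if (stats::sd(y) == 0) {
    ybar <- mean(y)
    return(switch(family$name,
      Logistic  = c(a = ybar, b = 1e-6, c = 0),
      Gompertz  = c(a = ybar * exp(exp(-6)), b = -6, c = 0),
      Ratkowsky = c(a = ybar, b = -12, c = 0),
      Richards  = c(a = ybar, b = -12, c = 0, d = 1),
      MMF       = c(a = ybar, b = 1, c = ybar, d = 1.5),
      Weibull   = c(a = ybar, b = 1e-8, c = 1e-3, d = 1.5)
    ))
  }
  increasing <- stats::cor(x, y) >= 0
  top <- 1.05 * max(y)
  if (top <= 0) top <- max(y) + abs(max(y)) + 1
  eps <- 1e-3 * diff(range(y))
  yc <- pmin(pmax(y, eps), top - eps)  # keep linearizing transforms finite
  switch(family$name,
    Logistic = {
      z <- log(pmax(top / yc - 1, 1e-8))
      ln <- .safe_line(x, z)                  # z = ln b - c x
      c(a = top, b = exp(ln[["intercept"]]), c = -ln[["slope"]])
    },
    Ratkowsky = {
      z <- log(pmax(top / yc - 1, 1e-8))
      ln <- .safe_line(x, z)                  # z = b - c x
      c(a = top, b = ln[["intercept"]], c = -ln[["slope"]])
    },
    Gompertz = {
      z <- log(pmax(-log(pmin(pmax(yc / top, 1e-8), 1 - 1e-8)), 1e-8))
      ln <- .safe_line(x, z)                  # z = b - c x
      c(a = top, b = ln[["intercept"]], c = -ln[["slope"]])
    },
    Richards = {
      z <- log(pmax(top / yc - 1, 1e-8))
      ln <- .safe_line(x, z)
      c(a = top, b = ln[["intercept"]], c = -ln[["slope"]], d = 1.5)
    },
    Weibull = {
      b0 <- max(top - min(y), eps)
      frac <- pmin(pmax((top - yc) / b0, 1e-8), 1 - 1e-8)
      pos <- x > 0
      z <- log(-log(frac[pos]))               # z = log c + d log x
      ln <- .safe_line(log(x[pos]), z)
      d0 <- ln[["slope"]]
      if (!is.finite(d0) || d0 <= 0.2) d0 <- 1.5
      c0 <- exp(ln[["intercept"]])
      if (!is.finite(c0) || c0 <= 0) c0 <- 1e-3
      c(a = top, b = b0, c = c0, d = d0)
    },
    MMF = {
      a0 <- mean(y[x == min(x)])              # intercept role
      c0 <- if (increasing) top else 0.95 * min(y)  # asymptote role
      d0 <- 1.5
      xm <- max(stats::median(x), 1)          # half-saturation age guess
      c(a = a0, b = xm^d0, c = c0, d = d0)
    }
  )
}
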