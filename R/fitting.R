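#' Read a long-format measurement table
#'
#' The package's input format is a long CSV with header
#' `animal_id,age_days,variable,value` — one row per observation of one
#' variable on one animal (UTF-8, decimal point). The design is
#' cross-sectional: each animal appears at a single age.
#'
#' @param path path to a CSV file.
#' @return a validated `data.frame` with columns `animal_id` (character),
#'   `age_days` (numeric), `variable` (character), `value` (numeric).
#' @export
read_measurements <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  validate_measurements(df)
}

#' @rdname read_measurements
#' @param data a data.frame to validate in place of a file.
#' @export
validate_measurements <- function(data) {
  need <- c("animal_id", "age_days", "variable", "value")
  if (!all(need %in% names(data))) {
    cc_stop(sprintf("measurement table must have columns %s",
                    paste(need, collapse = ", ")),
            "capricurve_invalid_input")
  }
  data <- data[need]
  data$animal_id <- as.character(data$animal_id)
  data$variable <- as.character(data$variable)
  data$age_days <- as.numeric(data$age_days)
  data$value <- as.numeric(data$value)
  if (!all(is.finite(data$age_days)) || any(data$age_days < 0)) {
    cc_stop("age_days must be finite and non-negative", "capricurve_invalid_input")
  }
  dup <- duplicated(data[c("animal_id", "variable", "age_days")])
  if (any(dup)) {
    cc_stop("duplicated (animal_id, variable) observation at one age",
            "capricurve_invalid_input")
  }
  for (v in unique(data$variable)) {
    if (length(unique(data$age_days[data$variable == v])) < 3) {
      cc_stop(sprintf("variable '%s' has fewer than 3 distinct ages", v),
              "capricurve_invalid_input")
    }
  }
  data
}

#' Residual fit statistics
#'
#' Sums of squares and derived statistics for a fitted curve: the residual sum
#' of squares `SSR`, total sum of squares `SST` about the mean, coefficient of
#' determination `R2 = 1 - SSR/SST`, the residual variance `s2 = SSR/(n - p)`
#' used for parameter standard errors, and the report-style mean square error
#' `MSE = SSR/(n - 2)` (its denominator is n - 2 for every family, including
#' four-parameter ones — kept verbatim under its own name).
#'
#' A constant response (`SST = 0`) yields `R2 = 0` with a warning rather than
#' NaN.
#'
#' @param observed,fitted numeric vectors of equal length.
#' @param p number of estimated parameters.
#' @return list with `SSR`, `SST`, `R2`, `s2`, `MSE`, `n`.
#' @export
fit_stats <- function(observed, fitted, p) {
  stopifnot(length(observed) == length(fitted))
  n <- length(observed)
  if (n <= p) cc_stop("need n > p observations", "capricurve_insufficient_data")
  r <- observed - fitted
  SSR <- sum(r^2)
  SST <- sum((observed - mean(observed))^2)
  R2 <- if (SST == 0) {
    cc_warn("constant response: R2 defined as 0", "capricurve_constant_response")
    0
  } else 1 - SSR / SST
  list(SSR = SSR, SST = SST, R2 = R2, s2 = SSR / (n - p),
       MSE = SSR / (n - 2), n = n)
}

## ---- Levenberg-Marquardt core ---------------------------------------------

## Damped least squares with the conventional Marquardt schedule:
## solve (J'J + lambda diag(J'J)) step = J'r; lambda x10 on a rejected step,
## /10 on an accepted one, lambda0 = 1e-3. Converged when the relative SSR
## drop or the relative parameter step falls below tol. Only improving steps
## are accepted, so the SSR path is monotone non-increasing.
lm_minimize <- function(fn, jac, start, max_iter = 500L, tol = 1e-10,
                        lambda0 = 1e-3, lower = NULL, upper = NULL) {
  theta <- start
  clamp <- function(th) {
    if (!is.null(lower)) th <- pmax(th, lower)
    if (!is.null(upper)) th <- pmin(th, upper)
    th
  }
  theta <- clamp(theta)
  r <- fn(theta)
  ssr <- sum(r^2)
  lambda <- lambda0
  iter <- 0L
  converged <- FALSE
  while (iter < max_iter) {
    iter <- iter + 1L
    J <- jac(theta)
    if (!all(is.finite(J)) || !all(is.finite(r))) break
    A <- crossprod(J)
    g <- crossprod(J, r)
    dg <- diag(A)
    dg[dg < 1e-12] <- 1e-12
    improved <- FALSE
    for (inner in 1:25) {
      step <- tryCatch(
        solve(A + lambda * diag(dg, nrow = length(dg)), g),
        error = function(e) NULL
      )
      if (is.null(step)) { lambda <- lambda * 10; next }
      cand <- clamp(theta - drop(step))  # r = y - f, J = dr/dtheta
      rc <- tryCatch(fn(cand), error = function(e) NULL)
      if (!is.null(rc) && all(is.finite(rc)) && sum(rc^2) < ssr) {
        rel_drop <- (ssr - sum(rc^2)) / max(ssr, 1e-300)
        rel_step <- max(abs(cand - theta) / pmax(abs(theta), 1e-8))
        theta <- cand; r <- rc; ssr <- sum(rc^2)
        lambda <- max(lambda / 10, 1e-14)
        improved <- TRUE
        if (rel_drop < tol || rel_step < tol) converged <- TRUE
        break
      }
      lambda <- lambda * 10
    }
    if (!improved) { converged <- ssr < Inf; break }
    if (converged) break
  }
  list(par = theta, ssr = ssr, iterations = iter, converged = converged)
}

## ---- public fitting interface ---------------------------------------------

#' Fitting options
#'
#' @param max_iter iteration cap for the damped least-squares loop.
#' @param tol convergence tolerance on the relative SSR change and relative
#'   parameter step.
#' @param lambda0 initial Marquardt damping factor.
#' @param multistart number of seeded +/-20 percent perturbations of the
#'   initial guess tried when the first attempt fails to converge or is beaten
#'   by an equal-parameter polynomial baseline.
#' @param retry_seed seed for the multistart perturbations (kept fixed so fits
#'   are reproducible run to run).
#' @param lower,upper optional named box constraints (none by default; the
#'   fitted tables legitimately contain negative `b` and `c` values).
#' @param use_means fit age-group means instead of individual animals
#'   (default `FALSE`: individual-level fitting).
#' @return a list of options for [fit_curve()] / [fit_growth()].
#' @export
fit_options <- function(max_iter = 500L, tol = 1e-10, lambda0 = 1e-3,
                        multistart = 5L, retry_seed = 101L,
                        lower = NULL, upper = NULL, use_means = FALSE) {
  list(max_iter = as.integer(max_iter), tol = tol, lambda0 = lambda0,
       multistart = as.integer(multistart), retry_seed = as.integer(retry_seed),
       lower = lower, upper = upper, use_means = isTRUE(use_means))
}

#' Fit one growth-model family to an age series
#'
#' Sigmoidal families are fitted by damped (Levenberg-Marquardt) least squares
#' from [initial_guess()], using the analytic Jacobian from
#' [growth_gradient()]; polynomial families are solved exactly by the normal
#' equations in one step. Parameter standard errors come from the estimated
#' covariance \eqn{s^2 (J'J)^{-1}} with \eqn{s^2 = SSR/(n - p)}.
#'
#' Non-convergence is not an error: the returned fit carries
#' `converged = FALSE` and the best parameters seen. If the first attempt
#' fails to converge, or a sigmoidal fit is beaten by the polynomial baseline
#' with the same parameter count, up to `multistart` seeded perturbations
#' (+/-20 percent) of the initial guess are tried and the best kept.
#'
#' @inheritParams growth_evaluate
#' @param x,y ages (days) and responses.
#' @param options see [fit_options()].
#' @param start optional explicit start values (overrides [initial_guess()]).
#' @return a `"growth_fit"` object: `family`, `params`, `se`, `vcov`, `SSR`,
#'   `R2`, `MSE`, `s2`, `n`, `converged`, `iterations`, plus the tolerances
#'   used (`control`) for reproducibility.
#' @export
#' @examples
#' x <- rep(c(1, 7, 14, 28, 42, 56, 70, 84), each = 2)
#' y <- growth_evaluate("Logistic", c(a = 5.44, b = 2.89, c = 0.039), x)
#' fit_curve("Logistic", x, y)
fit_curve <- function(family, x, y, options = fit_options(), start = NULL) {
  family <- as_family(family)
  p <- family$param_count
  if (length(x) != length(y)) {
    cc_stop("x and y lengths differ", "capricurve_invalid_input")
  }
  n <- length(y)
  if (n <= p) {
    cc_stop(sprintf("%s: need n > %d observations, got %d", family$name, p, n),
            "capricurve_insufficient_data")
  }

  if (family$kind == "polynomial") {
    X <- growth_gradient(family, stats::setNames(rep(0, p), family$param_names), x)
    qx <- qr(X)
    if (qx$rank < p) {
      cc_stop(sprintf("%s: singular design (collinear ages)", family$name),
              "capricurve_degenerate_design")
    }
    theta <- stats::setNames(drop(qr.coef(qx, y)), family$param_names)
    res <- list(par = theta, iterations = 0L, converged = TRUE)
  } else {
    if (is.null(start)) start <- initial_guess(family, x, y)
    start <- check_params(family, start)
    fn <- function(th) y - growth_evaluate(family, th, x)
    jc <- function(th) -growth_gradient(family, th, x)
    res <- lm_minimize(fn, jc, start, max_iter = options$max_iter,
                       tol = options$tol, lambda0 = options$lambda0,
                       lower = options$lower, upper = options$upper)
    res$par <- stats::setNames(res$par, family$param_names)

    # fallback: retry from perturbed starts when unconverged or beaten by the
    # equal-parameter polynomial baseline
    baseline <- tryCatch({
      pb <- if (p == 3) "Quadratic" else "Cubic"
      bf <- fit_curve(pb, x, y, options)
      bf$SSR
    }, error = function(e) Inf)
    if ((!res$converged || res$ssr > baseline) && options$multistart > 0) {
      perturb <- with_seed(options$retry_seed, {
        matrix(stats::runif(options$multistart * p, 0.8, 1.2),
               nrow = options$multistart)
      })
      for (i in seq_len(options$multistart)) {
        st2 <- start * perturb[i, ]
        st2[start == 0] <- perturb[i, start == 0] - 1  # perturb zeros additively
        r2 <- tryCatch(
          lm_minimize(fn, jc, st2, max_iter = options$max_iter,
                      tol = options$tol, lambda0 = options$lambda0,
                      lower = options$lower, upper = options$upper),
          error = function(e) NULL
        )
        if (!is.null(r2) &&
            (r2$ssr < res$ssr || (!res$converged && r2$converged))) {
          r2$par <- stats::setNames(r2$par, family$param_names)
          res <- r2
        }
      }
    }
  }

  yhat <- growth_evaluate(family, res$par, x)
  st <- withCallingHandlers(
    fit_stats(y, yhat, p),
    capricurve_constant_response = function(w) invokeRestart("muffleWarning")
  )
  J <- growth_gradient(family, res$par, x)
  vc <- tryCatch({
    st$s2 * solve(crossprod(J))
  }, error = function(e) matrix(NA_real_, p, p))
  se <- sqrt(pmax(diag(vc), 0))
  names(se) <- family$param_names

  structure(
    list(family = family, params = res$par, se = se, vcov = vc,
         SSR = st$SSR, R2 = st$R2, MSE = st$MSE, s2 = st$s2, n = st$n,
         converged = isTRUE(res$converged), iterations = res$iterations,
         control = options[c("max_iter", "tol", "lambda0", "multistart")]),
    class = "growth_fit"
  )
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("<growth_fit> %s: n = %d, SSR = %.6g, R2 = %.4f, %s (%d iter)\n",
              x$family$name, x$n, x$SSR, x$R2,
              if (x$converged) "converged" else "NOT converged", x$iterations))
  tab <- rbind(estimate = x$params, se = x$se)
  print(round(tab, 6))
  invisible(x)
}

#' Fit a family (or all families) to one variable of a measurement table
#'
#' `fit_growth()` slices one variable out of a long measurement table and fits
#' one family; `fit_all_families()` fits every requested family and returns a
#' named list of fits (non-fatal per-family failures are kept as condition
#' objects so the caller can flag them).
#'
#' @param data a measurement table (see [read_measurements()]).
#' @param variable variable name present in `data$variable`.
#' @inheritParams fit_curve
#' @export
fit_growth <- function(data, variable, family, options = fit_options()) {
  data <- validate_measurements(data)
  sl <- data[data$variable == variable, ]
  if (nrow(sl) == 0) {
    cc_stop(sprintf("variable '%s' not present", variable), "capricurve_invalid_input")
  }
  if (isTRUE(options$use_means)) {
    agg <- stats::aggregate(value ~ age_days, data = sl, FUN = mean)
    fit_curve(family, agg$age_days, agg$value, options)
  } else {
    fit_curve(family, sl$age_days, sl$value, options)
  }
}

#' @rdname fit_growth
#' @param families character vector of family names (default all eight).
#' @export
fit_all_families <- function(data, variable, families = growth_families(),
                             options = fit_options()) {
  fits <- lapply(families, function(f) {
    tryCatch(fit_growth(data, variable, f, options), capricurve_error = function(e) e)
  })
  stats::setNames(fits, families)
}
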