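#' Area under a fitted growth curve
#'
#' Definite integral of the curve over an age window, used as a cumulative
#' growth summary. Polynomial families integrate in closed form via the
#' antiderivative; sigmoidal families use adaptive (Gauss-Kronrod) quadrature
#' at relative tolerance 1e-8 with an absolute floor of 1e-12.
#'
#' @inheritParams growth_evaluate
#' @param lo,hi integration limits in days, `lo < hi`; the curve must be
#'   defined on the whole interval (MMF/Weibull with fractional shape `d`
#'   require `lo >= 0`).
#' @return the integral, in response-units x days.
#' @export
#' @examples
#' area_under_curve("Quadratic", c(a = 47.61, b = 0.24, c = -2.82e-3), 1, 28)
area_under_curve <- function(family, params, lo, hi) {
  family <- as_family(family)
  p <- check_params(family, params)
  if (!is.finite(lo) || !is.finite(hi) || lo >= hi) {
    cc_stop("need finite lo < hi", "capricurve_invalid_input")
  }
  if (family$kind == "polynomial") {
    co <- unname(p)                      # a + b x + c x^2 (+ d x^3)
    F <- function(x) sum(co * x^seq_along(co) / seq_along(co))
    return(F(hi) - F(lo))
  }
  if (family$name %in% c("MMF", "Weibull")) {
    d <- p[["d"]]
    if (lo < 0 && abs(d - round(d)) > 1e-12) {
      cc_stop(sprintf("%s curve undefined on [%g, %g] with non-integer d",
                      family$name, lo, hi),
              "capricurve_invalid_domain")
    }
  }
  q <- stats::integrate(function(x) growth_evaluate(family, p, x),
                        lower = lo, upper = hi,
                        rel.tol = 1e-8, abs.tol = 1e-12,
                        subdivisions = 500L)
  q$value
}

#' Default stage windows
#'
#' The three equal-width rearing-stage windows used by the summary tables:
#' pre-weaning milk stage (1-28 d), transition (29-56 d) and post-weaning
#' (57-84 d), integrated as the real intervals \[1,28\], \[29,56\], \[57,84\].
#' The deliberate one-day gaps at (28,29) and (56,57) mirror the reporting
#' convention of staged slaughter designs.
#'
#' @return list of three `c(lo, hi)` pairs.
#' @export
stage_windows <- function() {
  list(c(1, 28), c(29, 56), c(57, 84))
}

#' Inflection point and stage AUCs for one fitted model
#'
#' Assembles the per-variable summary of a selected fit: parameters with
#' standard errors, R2, the closed-form inflection point (absent for the
#' Quadratic), and one AUC per stage window. Inflection or AUC failures for
#' individual entries are recorded as `NA` with a note, without aborting the
#' rest of the summary.
#'
#' @param fit a `"growth_fit"` from [fit_curve()] / [fit_growth()]
#'   (`converged` must be `TRUE`).
#' @param windows list of `c(lo, hi)` stage windows (default
#'   [stage_windows()]).
#' @param variable optional variable name carried into the summary.
#' @return a `"derived_summary"` list: `variable`, `family`, `params`, `se`,
#'   `R2`, `inflection` (or `NULL`), `auc` (named numeric, one per window),
#'   `windows`, `notes`.
#' @export
stage_summary <- function(fit, windows = stage_windows(), variable = "") {
  stopifnot(inherits(fit, "growth_fit"))
  if (!isTRUE(fit$converged)) {
    cc_stop("stage_summary requires a converged fit", "capricurve_invalid_input")
  }
  notes <- character()
  ip <- tryCatch(
    inflection_point(fit$family, fit$params),
    capricurve_error = function(e) {
      notes <<- c(notes, conditionMessage(e))
      NULL
    }
  )
  auc <- vapply(windows, function(w) {
    tryCatch(area_under_curve(fit$family, fit$params, w[1], w[2]),
             capricurve_error = function(e) {
               notes <<- c(notes, conditionMessage(e))
               NA_real_
             })
  }, numeric(1))
  names(auc) <- vapply(windows, function(w) sprintf("AUC_%g_%g", w[1], w[2]),
                       character(1))
  structure(
    list(variable = variable, family = fit$family$name,
         params = fit$params, se = fit$se, R2 = fit$R2,
         inflection = ip, auc = auc, windows = windows, notes = notes),
    class = "derived_summary"
  )
}

#' @export
print.derived_summary <- function(x, ...) {
  cat(sprintf("<derived_summary> %s ~ %s, R2 = %.3f\n",
              if (nzchar(x$variable)) x$variable else "(variable)",
              x$family, x$R2))
  if (!is.null(x$inflection)) {
    cat(sprintf("  inflection: IPy = %.4g at IPx = %.4g d\n",
                x$inflection$IPy, x$inflection$IPx))
  } else cat("  inflection: none (constant second derivative)\n")
  cat("  ", paste(sprintf("%s = %.2f", names(x$auc), x$auc), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Flatten derived summaries to a report table
#'
#' One row per variable mirroring a best-model summary table: parameter
#' estimates with standard errors, R2, IPy, IPx and the three stage AUCs.
#'
#' @param summaries list of `"derived_summary"` objects.
#' @param digits decimals for the rounded report (full precision kept when
#'   `digits = NULL`).
#' @return a `data.frame`.
#' @export
summary_table <- function(summaries, digits = NULL) {
  rows <- lapply(summaries, function(s) {
    pm <- stats::setNames(rep(NA_real_, 4), c("a", "b", "c", "d"))
    sm <- pm
    pm[names(s$params)] <- s$params
    sm[names(s$se)] <- s$se
    df <- data.frame(
      variable = s$variable, model = s$family,
      a = pm[["a"]], a_se = sm[["a"]], b = pm[["b"]], b_se = sm[["b"]],
      c = pm[["c"]], c_se = sm[["c"]], d = pm[["d"]], d_se = sm[["d"]],
      R2 = s$R2,
      IPy = if (is.null(s$inflection)) NA_real_ else s$inflection$IPy,
      IPx = if (is.null(s$inflection)) NA_real_ else s$inflection$IPx
    )
    cbind(df, as.data.frame(as.list(s$auc)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(digits)) {
    num <- vapply(out, is.numeric, logical(1))
    out[num] <- lapply(out[num], round_half_up, digits = digits)
  }
  out
}
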