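#' Pipeline run configuration
#'
#' @param input path to a measurement CSV, a measurement `data.frame`, or
#'   `NULL` to simulate a synthetic study from `synthetic`.
#' @param synthetic a [synthetic_config()] used when `input` is `NULL`.
#' @param families families to fit (default all eight).
#' @param criterion primary selection criterion (default `"AICc"`).
#' @param mode criteria counting convention, `"standard"` or `"published"`
#'   (see [information_criteria()]); both are written to the report, `mode`
#'   decides which drives selection.
#' @param windows AUC stage windows (default [stage_windows()]).
#' @param outdir output directory (created if missing); `NULL` for no files.
#' @param seed master seed recorded in the manifest and used for simulation.
#' @param bw_variable body-weight variable name for the correlation table.
#' @param options [fit_options()] passed to every fit.
#' @param verbose print progress messages.
#' @return a `"run_config"` list for [run_pipeline()].
#' @export
run_config <- function(input = NULL, synthetic = NULL,
                       families = growth_families(),
                       criterion = "AICc", mode = c("standard", "published"),
                       windows = stage_windows(), outdir = NULL,
                       seed = 1L, bw_variable = "body_weight_kg",
                       options = fit_options(), verbose = FALSE) {
  mode <- match.arg(mode)
  bad <- setdiff(families, growth_families())
  if (length(bad)) {
    cc_stop(sprintf("unknown families: %s", paste(bad, collapse = ", ")),
            "capricurve_invalid_input")
  }
  for (w in windows) {
    if (length(w) != 2 || !all(is.finite(w)) || w[1] >= w[2]) {
      cc_stop("windows must be finite (lo, hi) pairs with lo < hi",
              "capricurve_invalid_input")
    }
  }
  if (is.null(input) && is.null(synthetic)) synthetic <- synthetic_config(seed = seed)
  structure(
    list(input = input, synthetic = synthetic, families = families,
         criterion = criterion, mode = mode, windows = windows,
         outdir = outdir, seed = as.integer(seed), bw_variable = bw_variable,
         options = options, verbose = isTRUE(verbose)),
    class = "run_config"
  )
}

log_line <- function(config, con, fmt, ...) {
  msg <- sprintf(fmt, ...)
  if (config$verbose) message(msg)
  if (!is.null(con)) writeLines(paste(format(Sys.time(), "%H:%M:%S"), msg), con)
}

#' Run the full growth-curve analysis pipeline
#'
#' simulate (or load) -> fit all families per variable -> compute criteria and
#' select the best -> derive inflection points and stage AUCs -> correlate
#' every variable against age and body weight. Per-variable failures are
#' logged and flagged without aborting other variables.
#'
#' When `config$outdir` is set, the run writes, per variable,
#' `criteria_<variable>.csv` (both counting conventions) and
#' `curves_<variable>.csv` (fitted values at integer ages 1-84 for every
#' family), plus study-level `summary_best_models.csv` (rounded to two
#' decimals, half away from zero) alongside the full-precision
#' `summary_best_models_full.csv`, `correlations.csv`, a `fit_store.json`
#' with every fitted parameter set (so reports can be re-rendered without
#' refitting), a `manifest.json` run record (seed, tolerances, criteria mode,
#' package version), and `run.log`.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with `data`, per-variable `fits`, `criteria`,
#'   `best`, `summaries`, `correlations`, `failures`, and `manifest`.
#' @export
#' @examples
#' cfg <- synthetic_config(seed = 7,
#'   variables = default_study_config()[c(1, 2), ])
#' res <- run_pipeline(run_config(synthetic = cfg, seed = 7))
#' res$best
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  con <- NULL
  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    con <- file(file.path(config$outdir, "run.log"), open = "wt")
    on.exit(close(con), add = TRUE)
  }
  data <- if (is.data.frame(config$input)) {
    validate_measurements(config$input)
  } else if (is.character(config$input)) {
    read_measurements(config$input)
  } else {
    log_line(config, con, "simulating synthetic study (seed %d)",
             config$synthetic$seed)
    generate_study(config$synthetic)
  }
  vars <- unique(data$variable)
  log_line(config, con, "fitting %d families to %d variables",
           length(config$families), length(vars))

  fits <- list(); criteria <- list(); best <- character()
  summaries <- list(); failures <- list()
  for (v in vars) {
    res <- tryCatch({
      fv <- fit_all_families(data, v, config$families, config$options)
      tab_std <- criteria_table(fv, v, mode = "standard")
      tab_pap <- criteria_table(fv, v, mode = "published")
      tab <- if (config$mode == "published") tab_pap else tab_std
      b <- select_best(tab, config$criterion)
      sm <- stage_summary(fv[[b]], config$windows, variable = v)
      list(fits = fv, std = tab_std, pap = tab_pap, best = b, summary = sm)
    }, capricurve_error = function(e) e)
    if (inherits(res, "condition")) {
      failures[[v]] <- conditionMessage(res)
      log_line(config, con, "variable %s FAILED: %s", v, conditionMessage(res))
      next
    }
    fits[[v]] <- res$fits
    criteria[[v]] <- res$std
    best[v] <- res$best
    summaries[[v]] <- res$summary
    log_line(config, con, "variable %s: best = %s (%s, %s mode)",
             v, res$best, config$criterion, config$mode)
    if (!is.null(config$outdir)) {
      both <- rbind(cbind(res$std, mode = "standard"),
                    cbind(res$pap, mode = "published"))
      utils::write.csv(both,
                       file.path(config$outdir, paste0("criteria_", v, ".csv")),
                       row.names = FALSE)
      utils::write.csv(curve_table(res$fits),
                       file.path(config$outdir, paste0("curves_", v, ".csv")),
                       row.names = FALSE)
    }
  }

  correlations <- tryCatch({
    covs <- if (config$bw_variable %in% vars) c("age", "body_weight") else "age"
    correlation_table(data, covs, config$bw_variable)
  }, capricurve_error = function(e) {
    failures[["correlations"]] <- conditionMessage(e)
    NULL
  })

  manifest <- list(
    package = "capricurve",
    version = as.character(utils::packageVersion("capricurve")),
    seed = config$seed, criterion = config$criterion, mode = config$mode,
    families = config$families,
    windows = lapply(config$windows, as.numeric),
    tolerances = config$options[c("max_iter", "tol", "lambda0", "multistart")],
    n_variables = length(vars), failures = names(failures),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )

  if (!is.null(config$outdir)) {
    st <- summary_table(summaries)
    utils::write.csv(summary_table(summaries, digits = 2),
                     file.path(config$outdir, "summary_best_models.csv"),
                     row.names = FALSE)
    utils::write.csv(st,
                     file.path(config$outdir, "summary_best_models_full.csv"),
                     row.names = FALSE)
    if (!is.null(correlations)) {
      utils::write.csv(correlations,
                       file.path(config$outdir, "correlations.csv"),
                       row.names = FALSE)
    }
    jsonlite::write_json(fit_store(fits),
                         file.path(config$outdir, "fit_store.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    log_line(config, con, "report written to %s", config$outdir)
  }

  invisible(list(data = data, fits = fits, criteria = criteria, best = best,
                 summaries = summaries, correlations = correlations,
                 failures = failures, manifest = manifest))
}

## Fitted-curve evaluations at integer ages 1-84 for every family — the data
## behind published fitted-curve figures.
curve_table <- function(fits, ages = 1:84) {
  out <- data.frame(age_days = ages)
  for (fam in names(fits)) {
    fit <- fits[[fam]]
    out[[fam]] <- if (inherits(fit, "condition")) NA_real_ else {
      tryCatch(growth_evaluate(fit$family, fit$params, ages),
               error = function(e) rep(NA_real_, length(ages)))
    }
  }
  out
}

## Plain machine-readable store of every fit, enough to re-render reports
## without refitting.
fit_store <- function(fits) {
  lapply(fits, function(fv) {
    lapply(fv, function(fit) {
      if (inherits(fit, "condition")) {
        list(error = conditionMessage(fit))
      } else {
        list(family = fit$family$name, params = as.list(fit$params),
             se = as.list(fit$se), SSR = fit$SSR, R2 = fit$R2,
             n = fit$n, converged = fit$converged,
             iterations = fit$iterations)
      }
    })
  })
}

#' Re-render report tables from a saved fit store
#'
#' Reads the `fit_store.json` written by [run_pipeline()] and regenerates the
#' best-model summary table without refitting anything.
#'
#' @param store_path path to a `fit_store.json`.
#' @param criterion,mode,windows as in [run_config()].
#' @param n number of observations per fit (used for criteria when refreshing
#'   selection from stored SSRs).
#' @return a `data.frame` like [summary_table()].
#' @export
report_from_store <- function(store_path, criterion = "AICc",
                              mode = c("standard", "published"),
                              windows = stage_windows(), n = NULL) {
  mode <- match.arg(mode)
  store <- jsonlite::read_json(store_path)
  summaries <- list()
  for (v in names(store)) {
    rows <- lapply(names(store[[v]]), function(fam) {
      rec <- store[[v]][[fam]]
      if (!is.null(rec$error)) {
        return(data.frame(variable = v, family = fam, k = NA_integer_,
                          SEM = NA_real_, MSE = NA_real_, AICc = NA_real_,
                          AIC = NA_real_, BIC = NA_real_, converged = FALSE))
      }
      fam_obj <- growth_family(rec$family)
      n_eff <- if (is.null(n)) rec$n else n
      cr <- if (mode == "published") {
        information_criteria(rec$SSR, 47L, fam_obj$param_count - 1L)
      } else {
        information_criteria(rec$SSR, n_eff, fam_obj$param_count)
      }
      data.frame(variable = v, family = fam, k = fam_obj$param_count,
                 SEM = sqrt(rec$SSR / (rec$n - fam_obj$param_count)),
                 MSE = cr$MSE, AICc = cr$AICc, AIC = cr$AIC, BIC = cr$BIC,
                 converged = isTRUE(rec$converged))
    })
    tab <- do.call(rbind, rows)
    b <- select_best(tab, criterion)
    rec <- store[[v]][[b]]
    fit <- structure(
      list(family = growth_family(rec$family),
           params = unlist(rec$params), se = unlist(rec$se),
           SSR = rec$SSR, R2 = rec$R2, n = rec$n,
           converged = isTRUE(rec$converged), iterations = rec$iterations),
      class = "growth_fit")
    summaries[[v]] <- stage_summary(fit, windows, variable = v)
  }
  summary_table(summaries)
}
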