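#' Synthetic study configuration
#'
#' Builds the configuration for the synthetic-data generator: the
#' cross-sectional slaughter design (which ages, how many animals per age),
#' plus one generating curve and residual noise scale per variable.
#'
#' `default_study_config()` loads the packaged variable list
#' (`inst/extdata/study_config.csv`, editable by users): eighteen body and
#' digestive-tract variables of young goat kids, each with its best-fitting
#' family, published parameter estimates, and a homoscedastic Gaussian
#' residual scale equal to the corresponding residual standard error. The
#' default design is ages 1, 7, 14, 28, 42, 56, 70, 84 d with 6 replicate
#' animals per age (48 animals).
#'
#' @param ages strictly increasing vector of slaughter ages in days.
#' @param replicates animals per age (>= 1).
#' @param drop_count observations removed at random per variable (set 1 to
#'   mimic an effective n of 47).
#' @param variables a `data.frame` with columns `variable`, `family`, `a`,
#'   `b`, `c`, `d` (NA where unused) and `noise_sd`.
#' @param seed master seed; every variable consumes its own substream derived
#'   from it, so generation is reproducible per variable and as a whole.
#' @return a `"synthetic_config"` list.
#' @export
#' @examples
#' cfg <- synthetic_config(seed = 1)
#' nrow(generate_study(cfg))
synthetic_config <- function(ages = c(1, 7, 14, 28, 42, 56, 70, 84),
                             replicates = 6L, drop_count = 0L,
                             variables = default_study_config(),
                             seed = 1L) {
  if (any(diff(ages) <= 0)) {
    cc_stop("ages must be strictly increasing", "capricurve_invalid_input")
  }
  if (replicates < 1) cc_stop("replicates must be >= 1", "capricurve_invalid_input")
  if (any(variables$noise_sd < 0, na.rm = TRUE)) {
    cc_stop("noise_sd must be non-negative", "capricurve_invalid_input")
  }
  structure(
    list(ages = as.numeric(ages), replicates = as.integer(replicates),
         drop_count = as.integer(drop_count), variables = variables,
         seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

#' @rdname synthetic_config
#' @param path optional path to an alternative variable-config CSV with the
#'   same columns as the packaged default.
#' @export
default_study_config <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "study_config.csv", package = "capricurve",
                        mustWork = TRUE)
  }
  cfg <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("variable", "family", "a", "b", "c", "d", "noise_sd")
  if (!all(need %in% names(cfg))) {
    cc_stop(sprintf("study config needs columns %s", paste(need, collapse = ", ")),
            "capricurve_config_error")
  }
  cfg
}

config_params <- function(row) {
  fam <- growth_family(row$family)
  p <- unlist(row[c("a", "b", "c", "d")[seq_len(fam$param_count)]])
  names(p) <- fam$param_names
  check_params(fam, p)
}

#' Generate synthetic measurements
#'
#' `generate_variable()` draws one variable: for every (age, replicate) cell,
#' `value = curve(age) + N(0, noise_sd)`. Animal ids are shared across
#' variables (each animal is "measured" for everything at its slaughter age),
#' and each variable consumes an RNG substream derived deterministically from
#' the master seed and the variable name, so the same seed always yields
#' byte-identical tables regardless of generation order. Values are not
#' truncated at zero: the shipped parameter/noise combinations make negative
#' draws vanishingly rare at the design ages, and truncation would bias
#' downstream recovery checks.
#'
#' `generate_study()` concatenates all configured variables.
#'
#' @param config a [synthetic_config()].
#' @param variable variable name present in `config$variables$variable`.
#' @return a long measurement `data.frame` (`animal_id`, `age_days`,
#'   `variable`, `value`) in the same dialect [read_measurements()] reads.
#' @export
generate_variable <- function(config, variable) {
  stopifnot(inherits(config, "synthetic_config"))
  i <- match(variable, config$variables$variable)
  if (is.na(i)) {
    cc_stop(sprintf("unknown variable '%s'", variable), "capricurve_invalid_input")
  }
  row <- config$variables[i, ]
  fam <- growth_family(row$family)
  params <- config_params(row)
  ages <- rep(config$ages, each = config$replicates)
  ids <- sprintf("A%03d", seq_along(ages))
  mu <- growth_evaluate(fam, params, ages)
  sub_seed <- (config$seed + hash31(variable)) %% 2147483647
  vals <- with_seed(sub_seed, {
    v <- mu + stats::rnorm(length(mu), 0, row$noise_sd)
    keep <- seq_along(v)
    if (config$drop_count > 0) {
      keep <- sort(sample(seq_along(v), length(v) - config$drop_count))
    }
    list(v = v, keep = keep)
  })
  data.frame(animal_id = ids[vals$keep], age_days = ages[vals$keep],
             variable = variable, value = vals$v[vals$keep],
             stringsAsFactors = FALSE)
}

#' @rdname generate_variable
#' @export
generate_study <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  if (nrow(config$variables) < 1) {
    cc_stop("config lists no variables", "capricurve_invalid_input")
  }
  out <- lapply(config$variables$variable, function(v) generate_variable(config, v))
  do.call(rbind, out)
}
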