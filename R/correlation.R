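#' Pearson correlation with two-sided significance
#'
#' Sample Pearson r with the usual t transform
#' \eqn{t = r\sqrt{(n-2)/(1-r^2)}} against a t distribution on n - 2 degrees
#' of freedom, two-sided (as computed by [stats::cor.test()]). Significance
#' is flagged at the 0.01 level, the threshold used for starred correlation
#' tables in this design.
#'
#' @param xs,ys numeric vectors of equal length >= 3, both non-constant.
#' @return list with `r`, `p_value`, `n`, `significant_01`, `stars` (`"**"`
#'   when p < 0.01, `""` otherwise).
#' @export
#' @examples
#' pearson_correlation(1:10, (1:10)^2)
pearson_correlation <- function(xs, ys) {
  if (length(xs) != length(ys)) {
    cc_stop("input vectors differ in length", "capricurve_invalid_input")
  }
  ok <- is.finite(xs) & is.finite(ys)
  xs <- xs[ok]; ys <- ys[ok]
  if (length(xs) < 3) {
    cc_stop("need at least 3 complete pairs", "capricurve_insufficient_data")
  }
  if (stats::sd(xs) == 0 || stats::sd(ys) == 0) {
    cc_stop("correlation undefined for constant input",
            "capricurve_undefined_correlation")
  }
  ct <- stats::cor.test(xs, ys, method = "pearson", alternative = "two.sided")
  r <- unname(ct$estimate)
  p <- if (abs(r) >= 1) 0 else ct$p.value
  list(r = r, p_value = p, n = length(xs),
       significant_01 = p < 0.01, stars = if (p < 0.01) "**" else "")
}

#' Correlation table of every variable against age and body weight
#'
#' For each variable in a long measurement table, the Pearson correlation
#' against age and (optionally) against each animal's own body weight. The
#' design is cross-sectional — each animal is measured once, at slaughter —
#' so body-weight pairing joins on `animal_id`.
#'
#' @param data a measurement table (see [read_measurements()]).
#' @param covariates subset of `c("age", "body_weight")`.
#' @param bw_variable name of the body-weight variable in `data` (required
#'   when `"body_weight"` is among the covariates).
#' @return a `data.frame` with columns `variable`, `covariate`, `r`,
#'   `p_value`, `n`, `stars`.
#' @export
correlation_table <- function(data, covariates = c("age", "body_weight"),
                              bw_variable = "body_weight_kg") {
  data <- validate_measurements(data)
  covariates <- match.arg(covariates, several.ok = TRUE)
  bw <- NULL
  if ("body_weight" %in% covariates) {
    bw <- data[data$variable == bw_variable, c("animal_id", "value")]
    if (nrow(bw) == 0) {
      cc_stop(sprintf("body-weight variable '%s' not present", bw_variable),
              "capricurve_config_error")
    }
    names(bw)[2] <- "bw"
  }
  rows <- list()
  for (v in unique(data$variable)) {
    sl <- data[data$variable == v, ]
    if ("age" %in% covariates) {
      pc <- pearson_correlation(sl$age_days, sl$value)
      rows[[length(rows) + 1]] <- data.frame(
        variable = v, covariate = "age", r = pc$r, p_value = pc$p_value,
        n = pc$n, stars = pc$stars)
    }
    if ("body_weight" %in% covariates) {
      m <- merge(sl, bw, by = "animal_id")
      pc <- pearson_correlation(m$bw, m$value)
      rows[[length(rows) + 1]] <- data.frame(
        variable = v, covariate = "body_weight", r = pc$r,
        p_value = pc$p_value, n = pc$n, stars = pc$stars)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
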