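#' @keywords internal
"_PACKAGE"

## Classed error/warning helpers so callers can condition on failure modes.

cc_stop <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "capricurve_error")))
}

cc_warn <- function(msg, class) {
  warning(warningCondition(msg, class = c(class, "capricurve_warning")))
}

#' Round half away from zero
#'
#' Report tables round to a fixed number of decimals with ties going away from
#' zero (so 27.285 -> 27.29), the convention used in printed summary tables,
#' rather than the IEEE round-half-even of [round()]. A tiny relative epsilon
#' absorbs binary-float representation error of decimal inputs before the tie
#' is resolved.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places (default 2).
#' @return `x` rounded to `digits` decimals.
#' @export
#' @examples
#' round_half_up(27.285)   # 27.29
#' round_half_up(-59.507)  # -59.51
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  z <- abs(x) * p
  sign(x) * floor(z + 0.5 + 1e-9 * pmax(z, 1)) / p
}

## Deterministic 31-bit string hash, used to give every variable its own
## reproducible RNG substream derived from the master seed.
hash31 <- function(s) {
  h <- 0
  for (k in utf8ToInt(s)) h <- (h * 31 + k) %% 2147483647
  as.integer(h)
}

## Run code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
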