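#' Round half away from zero
#'
#' Commercial rounding used at all reporting boundaries: ties are rounded
#' away from zero (so 0.125 -> 0.13 and -0.125 -> -0.13), unlike base
#' [round()], which rounds half to even. All internal arithmetic is carried
#' at full double precision; this is applied only when figures are printed
#' or written to reports.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 2, i.e. cents).
#' @return `x` rounded to `digits` decimals.
#' @export
#' @examples
#' round_half_away(2.675)   # 2.68
#' round_half_away(-2.675)  # -2.68
round_half_away <- function(x, digits = 2) {
  p <- 10^digits
  # nudge by half an ulp so values that are exactly representable ties
  # (e.g. 16683.635 stored as 16683.63499999...) still round away from zero
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

#' Wilson score interval for a binomial proportion
#'
#' @param x event count.
#' @param n trials.
#' @param level confidence level (default 0.95).
#' @return numeric vector `c(lower, upper)`.
#' @export
wilson_ci <- function(x, n, level = 0.95) {
  stopifnot(n >= 1, x >= 0, x <= n, level > 0, level < 1)
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(lower = max(0, centre - half), upper = min(1, centre + half))
}

#' Jeffreys point estimate for a binomial proportion
#'
#' `(x + 0.5) / (n + 1)`; used for zero cells so that PSA beta
#' distributions stay proper (a beta(0, b) is degenerate).
#'
#' @param x event count.
#' @param n trials.
#' @return point estimate in (0, 1).
#' @export
jeffreys_estimate <- function(x, n) (x + 0.5) / (n + 1)

# evaluate `expr` with a temporary RNG seed, restoring global RNG state
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  withr::with_seed(as.integer(seed), expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_ceatree <- function(msg, class) {
  rlang::abort(msg, class = c(class, "ceatree_error"))
}
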