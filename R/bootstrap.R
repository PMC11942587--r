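#' Bias-corrected bootstrap confidence interval
#'
#' Resamples `data` with replacement `B` times at the original size and
#' forms the bias-corrected (BC) percentile interval of the statistic:
#' the bias-correction constant is `z0 = qnorm(mean(theta* < theta_hat))`
#' and the interval endpoints are the bootstrap quantiles at adjusted
#' levels `pnorm(2 * z0 + qnorm((1 -/+ level) / 2))`. With `z0 = 0` this
#' reduces to the plain percentile interval. The stronger BCa variant
#' (jackknife acceleration) is available with `accelerated = TRUE`.
#'
#' @param data numeric vector of per-patient values.
#' @param statistic one of `"mean"`, `"median"`, `"total"`.
#' @param B resample count (10,000 in the bundled analysis; intervals
#'   from fewer than 1000 resamples are flagged in the result).
#' @param level confidence level, default 0.95.
#' @param seed integer seed for reproducibility.
#' @param accelerated use BCa (jackknife acceleration) instead of BC.
#' @return a list of class `cea_bootstrap`: `statistic`, `estimate`,
#'   `B`, `level`, `z0`, `acceleration`, `lower`, `upper`, `seed`.
#' @export
#' @examples
#' bc_bootstrap(rgamma(100, 2), "mean", B = 2000, seed = 1)
bc_bootstrap <- function(data, statistic = c("mean", "median", "total"),
                         B = 10000, level = 0.95, seed = NULL,
                         accelerated = FALSE) {
  statistic <- match.arg(statistic)
  if (!length(data)) abort_ceatree("empty data", "ceatree_input_error")
  stopifnot(B >= 1, level > 0, level < 1)
  fn <- switch(statistic, mean = mean, median = stats::median, total = sum)
  obs <- fn(data)
  n <- length(data)
  if (length(unique(data)) == 1) {
    warning("all data values identical; degenerate interval, z0 set to 0")
    return(structure(list(statistic = statistic, estimate = obs, B = B,
                          level = level, z0 = 0, acceleration = 0,
                          lower = obs, upper = obs, seed = seed),
                     class = "cea_bootstrap"))
  }
  boots <- with_seed(seed, {
    idx <- matrix(sample.int(n, n * B, replace = TRUE), nrow = n)
    m <- matrix(data[idx], nrow = n)
    switch(statistic,
           mean = colMeans(m),
           total = colSums(m),
           median = apply(m, 2, stats::median))
  })
  # clamp the below-observed fraction away from {0, 1} so z0 stays finite
  frac <- min(max(mean(boots < obs), 1 / (B + 1)), B / (B + 1))
  z0 <- stats::qnorm(frac)
  a <- 0
  if (accelerated) {
    jack <- vapply(seq_len(n), function(i) fn(data[-i]), numeric(1))
    d <- mean(jack) - jack
    a <- sum(d^3) / (6 * sum(d^2)^1.5)
  }
  alpha <- c((1 - level) / 2, (1 + level) / 2)
  zq <- stats::qnorm(alpha)
  adj <- stats::pnorm(z0 + (z0 + zq) / (1 - a * (z0 + zq)))
  ends <- stats::quantile(boots, adj, names = FALSE)
  structure(list(statistic = statistic, estimate = obs, B = B, level = level,
                 z0 = z0, acceleration = a,
                 lower = ends[1], upper = ends[2], seed = seed),
            class = "cea_bootstrap")
}

#' @export
print.cea_bootstrap <- function(x, ...) {
  cat(sprintf("<cea_bootstrap> %s = %.4f, %d%% %s interval [%.4f, %.4f] (B = %d, z0 = %.4f)\n",
              x$statistic, x$estimate, round(100 * x$level),
              if (x$acceleration != 0) "BCa" else "BC",
              x$lower, x$upper, x$B, x$z0))
  invisible(x)
}

#' Bootstrap confidence intervals for every cost component
#'
#' Applies [bc_bootstrap()] to each per-patient cost category within each
#' trial arm (arms are independent samples, so resampling is within-arm),
#' and to the per-patient total cost per arm. The cohort table must carry
#' the seven cost-category columns of the bundled model's schema (see
#' [generate_cohort()]).
#'
#' @param cohort tibble of patient records with an `arm` column and the
#'   cost-category columns.
#' @param B resamples per interval (default 10,000).
#' @param level confidence level.
#' @param seed integer seed; each arm-by-category interval consumes its
#'   own deterministic substream derived from it.
#' @param categories cost-category column names.
#' @return tibble: `arm`, `category` (including `"total"`), `estimate`,
#'   `lower`, `upper`, `z0`, `B`, `level`.
#' @export
cost_component_cis <- function(cohort, B = 10000, level = 0.95, seed = NULL,
                               categories = cost_categories()) {
  missing <- setdiff(categories, names(cohort))
  if (length(missing))
    abort_ceatree(sprintf("missing cost category column(s): %s",
                          paste(missing, collapse = ", ")),
                  "ceatree_schema_error")
  if (!"arm" %in% names(cohort))
    abort_ceatree("cohort has no 'arm' column", "ceatree_schema_error")
  arms <- unique(cohort$arm)
  combos <- expand.grid(arm = arms, category = c(categories, "total"),
                        stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    a <- combos$arm[i]
    cat_i <- combos$category[i]
    x <- if (cat_i == "total") {
      rowSums(cohort[cohort$arm == a, categories])
    } else {
      cohort[[cat_i]][cohort$arm == a]
    }
    sub_seed <- if (is.null(seed)) NULL else seed + i
    ci <- bc_bootstrap(x, "mean", B = B, level = level, seed = sub_seed)
    tibble::tibble(arm = a, category = cat_i, estimate = ci$estimate,
                   lower = ci$lower, upper = ci$upper, z0 = ci$z0,
                   B = B, level = level)
  })
  dplyr::bind_rows(rows)
}

#' The seven per-patient cost categories
#'
#' Column names of the per-patient cost breakdown used throughout the
#' package: laboratory tests, in-hospital care, follow-up, catheter
#' maintenance, catheter expenses, complication treatment, and other
#' treatments.
#'
#' @return character vector of column names.
#' @export
cost_categories <- function() {
  c("laboratory_tests", "inpatient_care", "follow_up",
    "catheter_maintenance", "catheter_expenses",
    "complication_treatment", "other_treatments")
}
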