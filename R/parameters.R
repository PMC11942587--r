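#' Define one model parameter
#'
#' A parameter is a named model input — a branch probability, a
#' per-category cost (RMB), or a utility — with a base value, an optional
#' uncertainty distribution for probabilistic sensitivity analysis, and an
#' optional one-way sensitivity range.
#'
#' Supported distributions, given as a list with a `type` element:
#' \describe{
#'   \item{`none`}{held at `base` in every PSA draw (the default).}
#'   \item{`beta(shape1, shape2)`}{for probabilities.}
#'   \item{`gamma(shape, scale)`}{for non-negative costs.}
#'   \item{`lognormal(meanlog, sdlog)`}{for right-skewed costs.}
#'   \item{`uniform(min, max)`}{for bounded quantities.}
#'   \item{`dirichlet(group, alpha)`}{one component of a multinomial branch
#'     set; all parameters sharing `group` are drawn jointly from a
#'     Dirichlet with concentration vector built from their `alpha` values,
#'     so sampled branch probabilities always sum to 1.}
#' }
#'
#' @param name unique identifier used in branch-probability and payoff
#'   expressions.
#' @param kind one of `"probability"`, `"cost"`, `"utility"`.
#' @param base base-case value: probabilities and utilities in `[0, 1]`,
#'   costs in RMB `>= 0`.
#' @param distribution distribution spec list (see Details), or `NULL`.
#' @param owsa_range length-2 numeric `c(low, high)` for one-way
#'   sensitivity analysis, or `NULL`.
#' @param note free-text provenance note carried into reports.
#' @return an object of class `cea_parameter`.
#' @export
#' @examples
#' parameter_spec("p_clabsi", "probability", 3 / 111,
#'   distribution = list(type = "beta", shape1 = 3, shape2 = 108)
#' )
parameter_spec <- function(name, kind = c("probability", "cost", "utility"),
                           base, distribution = NULL, owsa_range = NULL,
                           note = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.character(name), length(name) == 1, nzchar(name),
            is.numeric(base), length(base) == 1, is.finite(base))
  distribution <- distribution %||% list(type = "none")
  structure(
    list(name = name, kind = kind, base = base,
         distribution = distribution, owsa_range = owsa_range,
         note = note),
    class = "cea_parameter"
  )
}

#' Bundle parameters into a parameter set
#'
#' @param ... `cea_parameter` objects, or a single list of them.
#' @return a named list of class `cea_parameter_set`.
#' @export
parameter_set <- function(...) {
  ps <- list(...)
  if (length(ps) == 1 && !inherits(ps[[1]], "cea_parameter")) ps <- ps[[1]]
  ok <- vapply(ps, inherits, logical(1), "cea_parameter")
  if (!all(ok)) abort_ceatree("all elements must be cea_parameter objects",
                              "ceatree_type_error")
  nm <- vapply(ps, `[[`, character(1), "name")
  if (anyDuplicated(nm))
    abort_ceatree(paste0("duplicate parameter name(s): ",
                         paste(unique(nm[duplicated(nm)]), collapse = ", ")),
                  "ceatree_schema_error")
  names(ps) <- nm
  structure(ps, class = "cea_parameter_set")
}

#' Validate a parameter set
#'
#' Checks every parameter invariant and returns all violations (never
#' fail-fast): probabilities and utilities in `[0, 1]` with in-range OWSA
#' bounds, non-negative costs, well-formed distribution hyperparameters,
#' and distribution means lying inside the OWSA range when both are given.
#'
#' @param params a `cea_parameter_set`.
#' @return character vector of violation messages; empty if valid.
#' @export
validate_parameters <- function(params) {
  out <- character(0)
  for (p in params) {
    if (p$kind %in% c("probability", "utility") &&
        (p$base < 0 || p$base > 1))
      out <- c(out, sprintf("parameter '%s': %s base %.6g outside [0, 1]",
                            p$name, p$kind, p$base))
    if (p$kind == "cost" && p$base < 0)
      out <- c(out, sprintf("parameter '%s': cost base %.6g is negative",
                            p$name, p$base))
    if (!is.null(p$owsa_range)) {
      r <- p$owsa_range
      if (length(r) != 2 || !is.numeric(r) || r[1] > r[2])
        out <- c(out, sprintf("parameter '%s': malformed owsa_range", p$name))
      else if (p$kind == "probability" && (r[1] < 0 || r[2] > 1))
        out <- c(out, sprintf(
          "parameter '%s': owsa_range [%.4g, %.4g] outside [0, 1]",
          p$name, r[1], r[2]))
    }
    msg <- check_distribution(p)
    if (!is.null(msg)) out <- c(out, sprintf("parameter '%s': %s", p$name, msg))
  }
  out
}

# NULL if fine, otherwise a message; also checks mean-in-owsa-range
check_distribution <- function(p) {
  d <- p$distribution
  if (is.null(d$type)) return("distribution without a type")
  mean_d <- switch(
    d$type,
    none = p$base,
    beta = {
      if (is.null(d$shape1) || is.null(d$shape2) ||
          d$shape1 <= 0 || d$shape2 <= 0)
        return("beta requires shape1 > 0 and shape2 > 0")
      d$shape1 / (d$shape1 + d$shape2)
    },
    gamma = {
      if (is.null(d$shape) || is.null(d$scale) || d$shape <= 0 || d$scale <= 0)
        return("gamma requires shape > 0 and scale > 0")
      d$shape * d$scale
    },
    lognormal = {
      if (is.null(d$meanlog) || is.null(d$sdlog) || d$sdlog < 0)
        return("lognormal requires meanlog and sdlog >= 0")
      exp(d$meanlog + d$sdlog^2 / 2)
    },
    uniform = {
      if (is.null(d$min) || is.null(d$max) || d$min > d$max)
        return("uniform requires min <= max")
      (d$min + d$max) / 2
    },
    dirichlet = {
      if (is.null(d$group) || is.null(d$alpha) || d$alpha <= 0)
        return("dirichlet requires a group name and alpha > 0")
      NA_real_ # mean depends on the whole group; checked at sampling time
    },
    return(sprintf("unknown distribution type '%s'", d$type))
  )
  if (!is.null(p$owsa_range) && length(p$owsa_range) == 2 &&
      is.finite(mean_d) &&
      (mean_d < p$owsa_range[1] - 1e-9 || mean_d > p$owsa_range[2] + 1e-9))
    return(sprintf("distribution mean %.6g outside owsa_range [%.6g, %.6g]",
                   mean_d, p$owsa_range[1], p$owsa_range[2]))
  NULL
}

#' Base-case assignment of a parameter set
#'
#' @param params a `cea_parameter_set`.
#' @return named numeric vector of base values.
#' @export
base_values <- function(params) {
  vapply(params, `[[`, numeric(1), "base")
}

#' @export
print.cea_parameter_set <- function(x, ...) {
  cat(sprintf("<cea_parameter_set> %d parameters\n", length(x)))
  print(as_tibble(x), ...)
  invisible(x)
}

#' @importFrom tibble as_tibble
#' @method as_tibble cea_parameter_set
#' @export
as_tibble.cea_parameter_set <- function(x, ...) {
  tibble::tibble(
    name = vapply(x, `[[`, character(1), "name"),
    kind = vapply(x, `[[`, character(1), "kind"),
    base = vapply(x, `[[`, numeric(1), "base"),
    distribution = vapply(x, function(p) p$distribution$type, character(1)),
    owsa_low = vapply(x, function(p) p$owsa_range[1] %||% NA_real_, numeric(1)),
    owsa_high = vapply(x, function(p) p$owsa_range[2] %||% NA_real_, numeric(1))
  )
}
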