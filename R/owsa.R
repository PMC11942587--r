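#' One-way deterministic sensitivity analysis
#'
#' Varies a single parameter over an evenly spaced grid spanning its
#' `owsa_range` (endpoints included, base value inserted if not on the
#' grid), holding every other parameter at base, and re-evaluates the
#' tree at each grid point. The row at the base value reproduces the
#' base-case rollback exactly.
#'
#' @param tree a `cea_decision_tree`.
#' @param params a `cea_parameter_set`.
#' @param target name of the parameter to vary (must have an
#'   `owsa_range`).
#' @param n_points grid size before base-value insertion (default 11).
#' @param lambda willingness-to-pay used for the per-row incremental NMB
#'   when the tree has exactly two strategies (first strategy is taken as
#'   the intervention).
#' @return tibble: `parameter`, `value`, one row per grid point and
#'   strategy with `expected_cost`, `expected_effect`, and (two-strategy
#'   trees) `icer`, `status`, `inmb` of strategy 1 vs strategy 2.
#' @export
one_way <- function(tree, params, target, n_points = 11, lambda = NULL) {
  if (!target %in% names(params))
    abort_ceatree(sprintf("unknown parameter '%s'", target),
                  "ceatree_input_error")
  rng <- params[[target]]$owsa_range
  if (is.null(rng))
    abort_ceatree(sprintf("parameter '%s' has no owsa_range", target),
                  "ceatree_input_error")
  report <- validate_tree(tree, params)
  if (length(report))
    abort_ceatree(c("tree validation failed:", report),
                  "ceatree_validation_error")
  base <- base_values(params)
  grid <- sort(unique(c(seq(rng[1], rng[2], length.out = n_points),
                        base[[target]])))
  rows <- lapply(grid, function(v) {
    vals <- base
    vals[[target]] <- v
    out <- rollback(tree, vals, check = FALSE)
    out$parameter <- target
    out$value <- v
    if (length(tree$strategies) == 2 && !is.null(lambda)) {
      inc <- incremental(out[1, ], out[2, ], lambda)
      out$icer <- inc$icer
      out$status <- inc$status
      out$inmb <- inc$inmb
    }
    out
  })
  dplyr::bind_rows(rows) |>
    dplyr::relocate("parameter", "value")
}

#' Willingness-to-pay sweep of base-case outcomes
#'
#' For each lambda on the grid: every strategy's net monetary benefit,
#' the NMB-maximising strategy, and — for two-strategy models — the
#' incremental decision (`ICER < lambda` when the intervention gains
#' effect, equivalently incremental NMB > 0).
#'
#' @param outcomes base-case strategy outcomes ([rollback()] output),
#'   at least two strategies; the first row is taken as the intervention
#'   and the second as the comparator for the incremental decision.
#' @param lambdas numeric grid of willingness-to-pay values.
#' @return tibble: `lambda`, per-strategy `nmb_<strategy>` columns,
#'   `best_strategy`, and for two strategies `cost_effective` (the
#'   intervention's incremental decision at that lambda).
#' @export
wtp_sweep <- function(outcomes, lambdas) {
  if (!length(lambdas)) abort_ceatree("empty lambda grid", "ceatree_input_error")
  if (nrow(outcomes) < 2)
    abort_ceatree("wtp_sweep needs >= 2 strategies", "ceatree_input_error")
  rows <- lapply(lambdas, function(l) {
    b <- nmb(outcomes$expected_cost, outcomes$expected_effect, l)
    row <- tibble::tibble(lambda = l)
    for (i in seq_len(nrow(outcomes)))
      row[[paste0("nmb_", outcomes$strategy[i])]] <- b[i]
    row$best_strategy <- outcomes$strategy[which.max(b)]
    if (nrow(outcomes) == 2) {
      inc <- incremental(outcomes[1, ], outcomes[2, ], l)
      row$cost_effective <- inc$cost_effective
    }
    row
  })
  dplyr::bind_rows(rows)
}

#' Tornado diagram table
#'
#' Evaluates a chosen outcome at the low and high end of each target
#' parameter's `owsa_range` (all others at base) and ranks parameters by
#' the absolute span they induce. The default outcome is the incremental
#' net monetary benefit of strategy 1 vs strategy 2 at `lambda`.
#'
#' @param tree a `cea_decision_tree`.
#' @param params a `cea_parameter_set`.
#' @param targets parameter names to include (default: all with an
#'   `owsa_range`).
#' @param lambda willingness-to-pay for the default incremental-NMB
#'   outcome.
#' @param outcome function `(outcomes_tibble) -> scalar` to rank on;
#'   overrides the default.
#' @return tibble sorted by decreasing `span`: `parameter`, `low`,
#'   `high` (parameter values), `outcome_low`, `outcome_high`, `span`.
#' @export
tornado <- function(tree, params, targets = NULL, lambda = 113120,
                    outcome = NULL) {
  if (is.null(targets))
    targets <- names(params)[!vapply(params, function(p)
      is.null(p$owsa_range), logical(1))]
  missing <- setdiff(targets, names(params))
  if (length(missing))
    abort_ceatree(sprintf("unknown parameter(s): %s",
                          paste(missing, collapse = ", ")),
                  "ceatree_input_error")
  if (is.null(outcome)) {
    outcome <- function(out) {
      if (nrow(out) < 2) return(out$expected_cost[1])
      incremental(out[1, ], out[2, ], lambda)$inmb
    }
  }
  base <- base_values(params)
  rows <- lapply(targets, function(tg) {
    rng <- params[[tg]]$owsa_range
    if (is.null(rng))
      abort_ceatree(sprintf("parameter '%s' has no owsa_range", tg),
                    "ceatree_input_error")
    at <- function(v) {
      vals <- base
      vals[[tg]] <- v
      outcome(rollback(tree, vals, check = FALSE))
    }
    lo <- at(rng[1])
    hi <- at(rng[2])
    tibble::tibble(parameter = tg, low = rng[1], high = rng[2],
                   outcome_low = lo, outcome_high = hi,
                   span = abs(hi - lo))
  })
  out <- dplyr::bind_rows(rows)
  out[order(-out$span, out$parameter), ]
}
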