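#' Incremental cost-effectiveness ratio
#'
#' `delta_cost / delta_effect` when the ratio is meaningful. When the
#' intervention is cheaper and more effective (`delta_cost < 0`,
#' `delta_effect > 0`) it is *dominant* and the negative ratio is
#' suppressed; more costly and less effective is *dominated*; equal
#' effects give status `"equal-effect"` and no division.
#'
#' @param delta_cost incremental cost (RMB), intervention minus comparator.
#' @param delta_effect incremental effect (QALY).
#' @return a list with `icer` (numeric or `NA`) and `status` (one of
#'   `"icer"`, `"dominant"`, `"dominated"`, `"equal-effect"`).
#' @export
#' @examples
#' icer(2291.10, 0.05)  # 45822 RMB per QALY
#' icer(-2291.09, 0.05) # dominant
icer <- function(delta_cost, delta_effect) {
  stopifnot(is.numeric(delta_cost), is.numeric(delta_effect))
  if (delta_effect == 0)
    return(list(icer = NA_real_, status = "equal-effect"))
  if (delta_cost < 0 && delta_effect > 0)
    return(list(icer = NA_real_, status = "dominant"))
  if (delta_cost > 0 && delta_effect < 0)
    return(list(icer = NA_real_, status = "dominated"))
  list(icer = delta_cost / delta_effect, status = "icer")
}

#' Net monetary benefit
#'
#' `NMB = lambda * effect - cost`: the monetary value of the health
#' produced at willingness-to-pay `lambda`, net of cost. The strategy
#' with the highest NMB at a given `lambda` is the cost-effective choice;
#' for `delta_effect > 0` this is equivalent to the `ICER < lambda` rule.
#'
#' @param cost cost (RMB).
#' @param effect effect (QALY).
#' @param lambda willingness-to-pay threshold (RMB per QALY).
#' @return NMB in RMB (vectorised).
#' @export
nmb <- function(cost, effect, lambda) {
  stopifnot(lambda >= 0)
  lambda * effect - cost
}

#' Incremental analysis of two strategies
#'
#' Signed cost and effect differences, ICER or dominance status, and the
#' incremental net monetary benefit at the willingness-to-pay threshold.
#' The intervention is deemed cost-effective at `lambda` iff its
#' incremental NMB (`lambda * delta_effect - delta_cost`) is positive.
#'
#' @param intervention,comparator one-row strategy outcomes as returned by
#'   [rollback()] (columns `strategy`, `expected_cost`, `expected_effect`).
#' @param lambda willingness-to-pay threshold (RMB per QALY).
#' @return a one-row tibble: `intervention`, `comparator`, `delta_cost`,
#'   `delta_effect`, `icer`, `status`, `inmb`, `cost_effective`.
#' @export
incremental <- function(intervention, comparator, lambda) {
  stopifnot(nrow(intervention) == 1, nrow(comparator) == 1)
  dc <- intervention$expected_cost - comparator$expected_cost
  de <- intervention$expected_effect - comparator$expected_effect
  r <- icer(dc, de)
  inmb <- lambda * de - dc
  tibble::tibble(
    intervention = intervention$strategy,
    comparator = comparator$strategy,
    delta_cost = dc, delta_effect = de,
    icer = r$icer, status = r$status,
    inmb = inmb, cost_effective = inmb > 0
  )
}

#' Currency conversion at a fixed RMB-per-100-USD rate
#'
#' All modelling is carried out in RMB; USD figures are a presentation
#' layer. Conversion uses round-half-away-from-zero at 2 decimals, the
#' convention under which the bundled model's published figures reproduce
#' exactly.
#'
#' @param amount amount in RMB (or USD for `usd_to_rmb`).
#' @param rmb_per_100_usd exchange rate as RMB per 100 USD (default
#'   678.03, the 2020-2023 average central-bank rate bundled with the
#'   PICC model).
#' @return converted amount, rounded to 2 decimals.
#' @export
#' @examples
#' rmb_to_usd(21987.32) # 3242.82
#' rmb_to_usd(113120)   # 16683.63
rmb_to_usd <- function(amount, rmb_per_100_usd = 678.03) {
  stopifnot(rmb_per_100_usd > 0)
  round_half_away(amount * 100 / rmb_per_100_usd, 2)
}

#' @rdname rmb_to_usd
#' @export
usd_to_rmb <- function(amount, rmb_per_100_usd = 678.03) {
  stopifnot(rmb_per_100_usd > 0)
  round_half_away(amount * rmb_per_100_usd / 100, 2)
}

#' Cost-effectiveness efficient frontier
#'
#' Sorts strategies by effect, removes strictly dominated strategies
#' (some other strategy is at least as effective and cheaper), then
#' removes extendedly dominated ones (a convex combination of two others
#' does better, detected as a non-monotone sequence of pairwise ICERs),
#' and reports the ICER of each remaining strategy against its
#' predecessor on the frontier.
#'
#' @param outcomes tibble of strategy outcomes ([rollback()] output).
#' @return tibble of frontier strategies in increasing effect order with
#'   column `icer` (NA for the anchor strategy).
#' @export
dominance_frontier <- function(outcomes) {
  stopifnot(nrow(outcomes) >= 1)
  o <- outcomes[order(outcomes$expected_cost, -outcomes$expected_effect), ]
  # strict dominance: walk in cost order, keep strategies that raise effect
  keep <- logical(nrow(o))
  best <- -Inf
  for (i in seq_len(nrow(o))) {
    if (o$expected_effect[i] > best) {
      keep[i] <- TRUE
      best <- o$expected_effect[i]
    }
  }
  o <- o[keep, ]
  # extended dominance: enforce increasing pairwise ICERs
  repeat {
    if (nrow(o) <= 2) break
    ic <- diff(o$expected_cost) / diff(o$expected_effect)
    drop <- which(diff(ic) < 0)
    if (!length(drop)) break
    o <- o[-(drop[1] + 1), ]
  }
  o$icer <- c(NA_real_,
              if (nrow(o) > 1) diff(o$expected_cost) / diff(o$expected_effect))
  o
}
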