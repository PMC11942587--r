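#' Configure a synthetic two-arm catheter trial cohort
#'
#' Describes the generative model for patient-level data with the
#' structure the decision tree assumes: per-arm sizes, a second-puncture
#' probability, a complication multinomial (CLABSI, unknown fever, local
#' complication, or none), a resolution multinomial conditional on having
#' a complication (resolved without catheter removal, resolved with
#' removal, worsened), right-skewed gamma per-category costs whose means
#' depend on the pathway, and per-state utilities read off as the 90-day
#' QALY accrual. [picc_cohort_config()] returns the trial-calibrated
#' default.
#'
#' Pathway cost structure (shared with the bundled decision tree):
#' laboratory tests double on any complication pathway (confirmatory
#' testing); catheter expenses scale with the number of catheters used
#' (1 + second puncture + removal); complication treatment applies only
#' on complication pathways, scaled by severity (1, 1.8, 4 for resolved
#' without removal / with removal / worsened); all other categories are
#' pathway-independent.
#'
#' @param arms named integer vector of arm sizes.
#' @param p_second_puncture named per-arm probability of a failed first
#'   insertion attempt.
#' @param p_complication per-arm list of named probabilities over
#'   `c("CLABSI", "unknown_fever", "local", "none")`, each summing to 1.
#' @param p_resolution per-arm list of named probabilities over
#'   `c("resolved_no_removal", "resolved_with_removal", "worsened")`.
#' @param cost_means per-arm list of named baseline (complication-free)
#'   per-category mean costs in RMB over [cost_categories()].
#' @param cost_cv coefficient of variation of every gamma cost category
#'   (default 0.3).
#' @param utilities named utilities over states `c("none",
#'   "resolved_no_removal", "resolved_with_removal", "worsened")`, on the
#'   90-day QALY scale.
#' @return a validated list of class `cea_cohort_config`.
#' @export
cohort_config <- function(arms, p_second_puncture, p_complication,
                          p_resolution, cost_means, cost_cv = 0.3,
                          utilities) {
  cfg <- structure(
    list(arms = arms, p_second_puncture = p_second_puncture,
         p_complication = p_complication, p_resolution = p_resolution,
         cost_means = cost_means, cost_cv = cost_cv, utilities = utilities),
    class = "cea_cohort_config")
  bad <- validate_cohort_config(cfg)
  if (length(bad))
    abort_ceatree(c("invalid cohort config:", bad), "ceatree_validation_error")
  cfg
}

complication_states <- function() c("CLABSI", "unknown_fever", "local", "none")
resolution_states <- function() {
  c("resolved_no_removal", "resolved_with_removal", "worsened")
}
severity_multiplier <- function() {
  c(resolved_no_removal = 1, resolved_with_removal = 1.8, worsened = 4)
}

validate_cohort_config <- function(cfg) {
  out <- character(0)
  arm_names <- names(cfg$arms)
  if (is.null(arm_names) || any(!nzchar(arm_names)))
    return("arms must be a named integer vector")
  if (any(cfg$arms < 1)) out <- c(out, "arm sizes must be >= 1")
  for (a in arm_names) {
    p2 <- cfg$p_second_puncture[[a]]
    if (is.null(p2) || p2 < 0 || p2 > 1)
      out <- c(out, sprintf("arm '%s': p_second_puncture outside [0, 1]", a))
    pc <- cfg$p_complication[[a]]
    if (is.null(pc) || !setequal(names(pc), complication_states()))
      out <- c(out, sprintf("arm '%s': p_complication must cover %s", a,
                            paste(complication_states(), collapse = ", ")))
    else {
      if (any(pc < 0)) out <- c(out, sprintf(
        "arm '%s': negative complication probability", a))
      if (abs(sum(pc) - 1) > 1e-9)
        out <- c(out, sprintf(
          "arm '%s': complication probabilities sum to %.10g, not 1",
          a, sum(pc)))
    }
    pr <- cfg$p_resolution[[a]]
    if (is.null(pr) || !setequal(names(pr), resolution_states()))
      out <- c(out, sprintf("arm '%s': p_resolution must cover %s", a,
                            paste(resolution_states(), collapse = ", ")))
    else if (abs(sum(pr) - 1) > 1e-9 || any(pr < 0))
      out <- c(out, sprintf("arm '%s': invalid resolution probabilities", a))
    cm <- cfg$cost_means[[a]]
    if (is.null(cm) || !all(cost_categories() %in% names(cm)))
      out <- c(out, sprintf("arm '%s': cost_means must cover %s", a,
                            paste(cost_categories(), collapse = ", ")))
    else if (any(cm < 0))
      out <- c(out, sprintf("arm '%s': negative cost mean", a))
  }
  if (cfg$cost_cv <= 0) out <- c(out, "cost_cv must be > 0")
  states <- c("none", resolution_states())
  if (!all(states %in% names(cfg$utilities)))
    out <- c(out, "utilities must cover none and the three resolution states")
  else if (any(cfg$utilities < 0 | cfg$utilities > 1))
    out <- c(out, "utilities must lie in [0, 1]")
  out
}

#' Generate a synthetic patient-level cohort
#'
#' Draws one row per patient: arm, puncture attempts, complication state
#' (multinomial), resolution state (conditional on a complication),
#' per-category gamma costs whose means follow the pathway structure
#' described in [cohort_config()], and the 90-day QALY accrual of the
#' terminal state. Arm sizes are exact by construction; draws are
#' reproducible by seed.
#'
#' @param config a `cea_cohort_config`.
#' @param seed integer seed.
#' @return tibble of patient records with columns `patient_id`, `arm`,
#'   `puncture_attempts`, `complication`, `resolution`, the seven cost
#'   categories, `total_cost`, `qaly`.
#' @export
generate_cohort <- function(config, seed = NULL) {
  bad <- validate_cohort_config(config)
  if (length(bad))
    abort_ceatree(c("invalid cohort config:", bad), "ceatree_validation_error")
  cv <- config$cost_cv
  shape <- 1 / cv^2
  with_seed(seed, {
    per_arm <- lapply(names(config$arms), function(a) {
      n <- config$arms[[a]]
      second <- stats::rbinom(n, 1, config$p_second_puncture[[a]])
      pc <- config$p_complication[[a]][complication_states()]
      compl <- sample(complication_states(), n, replace = TRUE, prob = pc)
      pr <- config$p_resolution[[a]][resolution_states()]
      resol <- ifelse(
        compl == "none", "n/a",
        sample(resolution_states(), n, replace = TRUE, prob = pr))
      has_comp <- compl != "none"
      removed <- resol == "resolved_with_removal"
      mult <- list(
        laboratory_tests = ifelse(has_comp, 2, 1),
        inpatient_care = rep(1, n),
        follow_up = rep(1, n),
        catheter_maintenance = rep(1, n),
        catheter_expenses = 1 + second + removed,
        complication_treatment = ifelse(
          has_comp, unname(severity_multiplier()[resol]), 0),
        other_treatments = rep(1, n)
      )
      costs <- lapply(cost_categories(), function(cat_i) {
        m <- config$cost_means[[a]][[cat_i]] * mult[[cat_i]]
        out <- numeric(n)
        pos <- m > 0
        # scale = mean * cv^2 so that E = mean and CV = cv per patient
        out[pos] <- stats::rgamma(sum(pos), shape = shape,
                                  scale = m[pos] * cv^2)
        out
      })
      names(costs) <- cost_categories()
      state <- ifelse(compl == "none", "none", resol)
      tibble::tibble(
        arm = a, puncture_attempts = 1L + second,
        complication = compl, resolution = resol,
        !!!costs,
        qaly = unname(config$utilities[state])
      )
    })
    out <- dplyr::bind_rows(per_arm)
    out$patient_id <- sprintf("P%04d", seq_len(nrow(out)))
    out$total_cost <- rowSums(out[, cost_categories()])
    dplyr::relocate(out, "patient_id")
  })
}

#' Estimate event probabilities from a cohort table
#'
#' Per-arm point estimates (`count / n`) with Wilson 95% score intervals
#' for second puncture, each complication type, and each resolution type
#' (as a fraction of the arm). Zero cells are reported at the Jeffreys
#' point estimate `(x + 0.5) / (n + 1)` and flagged, matching how the
#' decision-tree model handles the zero CLABSI count.
#'
#' @param cohort tibble of patient records ([generate_cohort()] schema).
#' @param level confidence level for the Wilson intervals.
#' @return tibble: `arm`, `event`, `count`, `n`, `estimate`, `lower`,
#'   `upper`, `zero_cell`.
#' @export
estimate_probabilities <- function(cohort, level = 0.95) {
  if (!nrow(cohort)) abort_ceatree("empty cohort", "ceatree_input_error")
  rows <- lapply(unique(cohort$arm), function(a) {
    sub <- cohort[cohort$arm == a, ]
    n <- nrow(sub)
    events <- c(second_puncture = sum(sub$puncture_attempts > 1),
                vapply(complication_states()[1:3], function(s)
                  as.numeric(sum(sub$complication == s)), numeric(1)),
                vapply(resolution_states(), function(s)
                  as.numeric(sum(sub$resolution == s)), numeric(1)))
    dplyr::bind_rows(lapply(names(events), function(e) {
      x <- events[[e]]
      ci <- wilson_ci(x, n, level)
      tibble::tibble(
        arm = a, event = e, count = x, n = n,
        estimate = if (x == 0) jeffreys_estimate(0, n) else x / n,
        lower = ci[["lower"]], upper = ci[["upper"]],
        zero_cell = x == 0)
    }))
  })
  dplyr::bind_rows(rows)
}

#' Analytic expected per-patient total cost of a cohort config
#'
#' The closed-form expectation of the per-patient total under the
#' pathway cost structure, used by [calibrate_costs()] and as the truth
#' in consistency tests of the generator.
#'
#' @param config a `cea_cohort_config`.
#' @param exclude cost categories to leave out (used during calibration).
#' @return named numeric vector of per-arm expected totals (RMB).
#' @export
expected_arm_cost <- function(config, exclude = character(0)) {
  vapply(names(config$arms), function(a) {
    pc <- config$p_complication[[a]]
    pr <- config$p_resolution[[a]]
    p_comp <- 1 - pc[["none"]]
    sev <- severity_multiplier()
    emult <- c(
      laboratory_tests = 1 + p_comp, # doubles on complication pathways
      inpatient_care = 1, follow_up = 1, catheter_maintenance = 1,
      catheter_expenses = 1 + config$p_second_puncture[[a]] +
        p_comp * pr[["resolved_with_removal"]],
      complication_treatment = p_comp * sum(pr[resolution_states()] *
                                              sev[resolution_states()]),
      other_treatments = 1
    )
    cats <- setdiff(cost_categories(), exclude)
    sum(unlist(config$cost_means[[a]])[cats] * emult[cats])
  }, numeric(1))
}

#' Calibrate the residual cost category to target arm means
#'
#' Sets each arm's `other_treatments` mean so the analytic expectation of
#' the per-patient total equals the target to the cent. Errors if a
#' target lies below the expectation of the non-residual categories
#' (infeasible without a negative cost).
#'
#' @param config a `cea_cohort_config`.
#' @param targets named per-arm target mean total costs (RMB).
#' @return the adjusted config, with attribute `achieved` carrying the
#'   analytic per-arm expectations (equal to the targets).
#' @export
calibrate_costs <- function(config, targets) {
  stopifnot(all(names(config$arms) %in% names(targets)))
  fixed <- expected_arm_cost(config, exclude = "other_treatments")
  for (a in names(config$arms)) {
    resid <- targets[[a]] - fixed[[a]]
    if (resid < 0)
      abort_ceatree(sprintf(
        "arm '%s': target %.2f below non-residual expectation %.2f",
        a, targets[[a]], fixed[[a]]), "ceatree_infeasible_error")
    config$cost_means[[a]][["other_treatments"]] <- resid
  }
  attr(config, "achieved") <- expected_arm_cost(config)
  config
}
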