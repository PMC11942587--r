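#' Build the bundled AGBA vs standard PICC decision-tree model
#'
#' Constructs the two-strategy decision tree comparing chlorhexidine-
#' coated (AGBA) and standard peripherally inserted central catheters
#' over a 90-day horizon, parameterised from the source trial's
#' aggregate counts (113 AGBA / 111 standard patients; 1 vs 3 second
#' punctures; 0 vs 3 CLABSI; 36 unknown-fever cases overall) and
#' calibrated so that base-case rollback reproduces the trial's printed
#' per-patient arm means (RMB 19,696.23 / 0.73 QALY for AGBA; RMB
#' 21,987.32 / 0.68 QALY for standard) to the cent.
#'
#' Structure per strategy: a first-insertion chance node (success vs
#' second puncture), then a complication chance node (CLABSI, unknown
#' fever, local complication, or none — a Dirichlet branch set in PSA),
#' then for each complication a resolution chance node (resolved without
#' catheter removal, resolved with removal, worsened). Terminal cost
#' payoffs sum the seven per-category cost parameters with pathway
#' multipliers (extra laboratory tests on complication pathways, an
#' extra catheter after a second puncture or a removal, severity-scaled
#' complication treatment); the terminal effect is the utility of the
#' final health state.
#'
#' Calibration (recorded in `metadata$calibration`): the per-arm
#' `other_treatments` residual mean is solved so expected cost hits the
#' printed arm means exactly, and two of the four state utilities
#' (complication-free and resolved-with-removal) are solved from a 2x2
#' linear system so expected effect hits the printed QALYs exactly.
#' Quantities the trial never published — the per-arm split of the 36
#' unknown-fever cases (default: equal probability 36/224 in both arms),
#' local-complication probabilities, and the resolution mixes — are
#' configurable assumptions, not trial results.
#'
#' @param fever_prob per-arm unknown-fever probability (default
#'   `36/224` in both arms: the 36 cases split in proportion to arm
#'   size, the no-information default).
#' @param local_prob per-arm local-complication probability (assumed;
#'   the trial reports no counts).
#' @param resolution per-arm resolution mixes over
#'   `c(resolved_no_removal, resolved_with_removal, worsened)`
#'   (assumed; calibration gives the standard arm the worse mix).
#' @param cost_targets printed per-patient mean total costs (RMB).
#' @param effect_targets printed per-patient QALYs.
#' @param u_res_nr,u_worse the two utilities held fixed while the other
#'   two are solved.
#' @param cost_cv coefficient of variation of gamma cost distributions.
#' @return an object of class `cea_model`: list with `tree`, `params`,
#'   `wtp`, `exchange_rate`, `metadata`.
#' @export
#' @examples
#' model <- build_picc_model()
#' rollback(model$tree, model$params)
build_picc_model <- function(
    fever_prob = c(AGBA = 36 / 224, standard = 36 / 224),
    local_prob = c(AGBA = 0.04, standard = 0.06),
    resolution = list(
      AGBA = c(resolved_no_removal = 0.70, resolved_with_removal = 0.25,
               worsened = 0.05),
      standard = c(resolved_no_removal = 0.40, resolved_with_removal = 0.40,
                   worsened = 0.20)),
    cost_targets = c(AGBA = 19696.23, standard = 21987.32),
    effect_targets = c(AGBA = 0.73, standard = 0.68),
    u_res_nr = 0.70, u_worse = 0.05,
    cost_cv = 0.3) {

  arms <- c(AGBA = 113L, standard = 111L)
  second <- c(AGBA = 1, standard = 3)
  clabsi_counts <- c(AGBA = 0, standard = 3)
  # zero cell: Jeffreys point estimate keeps the PSA beta proper
  p_clabsi <- ifelse(clabsi_counts == 0,
                     jeffreys_estimate(clabsi_counts, arms),
                     clabsi_counts / arms)
  p_second <- second / arms

  probs <- lapply(names(arms), function(a) {
    pc <- c(CLABSI = p_clabsi[[a]], unknown_fever = fever_prob[[a]],
            local = local_prob[[a]])
    c(as.list(pc), list(none = 1 - sum(pc)))
  })
  names(probs) <- names(arms)

  # --- utility calibration: solve the 2x2 linear system -------------------
  # E[effect | arm] = w_free*u_free + w_nr*u_nr + w_rm*u_rm + w_w*u_w,
  # weights from the complication/resolution mixes (insertion node does
  # not change the health state). Unknowns: u_free, u_rm.
  weights <- vapply(names(arms), function(a) {
    p_comp <- 1 - probs[[a]]$none
    c(free = probs[[a]]$none,
      nr = p_comp * resolution[[a]][["resolved_no_removal"]],
      rm = p_comp * resolution[[a]][["resolved_with_removal"]],
      w = p_comp * resolution[[a]][["worsened"]])
  }, numeric(4))
  A <- t(weights[c("free", "rm"), ])
  b <- effect_targets[colnames(weights)] -
    weights["nr", ] * u_res_nr - weights["w", ] * u_worse
  sol <- solve(A, b)
  u_free <- sol[[1]]
  u_res_rm <- sol[[2]]
  utilities <- c(none = u_free, resolved_no_removal = u_res_nr,
                 resolved_with_removal = u_res_rm, worsened = u_worse)
  if (any(utilities < 0 | utilities > 1) ||
      !(u_free > u_res_nr && u_res_nr > u_res_rm && u_res_rm > u_worse))
    abort_ceatree(
      c("utility calibration infeasible under the given assumptions:",
        sprintf("solved utilities: %s",
                paste(sprintf("%s=%.4f", names(utilities), utilities),
                      collapse = ", "))),
      "ceatree_infeasible_error")

  # --- baseline (complication-free) cost category means, RMB --------------
  # Plausible Beijing-tariff magnitudes; the residual 'other_treatments'
  # absorbs whatever the printed arm means require (solved below).
  cost_means <- list(
    AGBA = c(laboratory_tests = 1200, inpatient_care = 8500, follow_up = 800,
             catheter_maintenance = 1500, catheter_expenses = 2600,
             complication_treatment = 3500, other_treatments = 0),
    standard = c(laboratory_tests = 1200, inpatient_care = 9500,
                 follow_up = 800, catheter_maintenance = 1500,
                 catheter_expenses = 1600, complication_treatment = 4500,
                 other_treatments = 0)
  )

  cfg <- cohort_config(
    arms = arms,
    p_second_puncture = as.list(p_second),
    p_complication = lapply(probs, function(p) unlist(p)),
    p_resolution = resolution,
    cost_means = cost_means,
    cost_cv = cost_cv,
    utilities = utilities)
  cfg <- calibrate_costs(cfg, cost_targets)

  params <- picc_parameters(cfg, arms, second, clabsi_counts)
  tree <- picc_tree(names(arms))

  metadata <- list(
    title = "Chlorhexidine-coated (AGBA) vs standard PICC, 90-day decision tree",
    currency = "RMB",
    horizon_days = 90,
    calibration = list(
      solved = c("agba_c_other", "std_c_other", "u_nocomp", "u_res_rm"),
      note = paste(
        "Base-case rollback reproduces the trial's printed per-patient arm",
        "means by construction: the per-arm 'other treatments' residual",
        "mean and the complication-free / resolved-with-removal utilities",
        "are solved against the printed totals. Reproducing those means is",
        "therefore a calibration check of model construction, not an",
        "independent validation of the trial."),
      assumptions = c(
        "unknown-fever cases (36 overall) split in proportion to arm size; per-arm counts were never published",
        "local-complication probabilities assumed (AGBA 0.04, standard 0.06); no counts published",
        "resolution mixes assumed, standard arm worse; no counts published",
        "zero CLABSI count in the AGBA arm replaced by the Jeffreys point estimate 0.5/114",
        "baseline cost-category means are assumed tariff magnitudes; only arm totals were published")
    ),
    paper_reported = list(
      note = paste(
        "Figures reported verbatim by the source analysis. Its ICER",
        "(RMB 4271.31, USD 629.96) does not equal the ratio of its own",
        "printed increments (2291.10 / 0.05 = 45,822), and USD 428.44 is",
        "not the stated-rate conversion of RMB 2291.10 (337.91). This",
        "package reports the self-consistent arithmetic alongside these",
        "verbatim figures and does not silently pick a side."),
      mean_cost_rmb = list(AGBA = 19696.23, standard = 21987.32),
      mean_cost_usd = list(AGBA = 2904.92, standard = 3242.82),
      qaly = list(AGBA = 0.73, standard = 0.68),
      incremental_cost_rmb = -2291.10,
      incremental_cost_usd = -428.44,
      incremental_effect_qaly = 0.05,
      icer_rmb_per_qaly = 4271.31,
      icer_usd_per_qaly = 629.96,
      wtp_usd_reported = c(16884, 16683.63)
    )
  )

  structure(list(tree = tree, params = params,
                 wtp = list(lambda = 113120,
                            provenance = "1.76 x GDP per capita, non-life-saving technology"),
                 exchange_rate = list(rmb_per_100_usd = 678.03),
                 metadata = metadata),
            class = "cea_model")
}

# parameter set of the PICC model from a calibrated cohort config
picc_parameters <- function(cfg, arms, second, clabsi_counts) {
  ps <- list()
  add <- function(p) ps[[length(ps) + 1]] <<- p
  owsa_prob <- function(base) c(max(0, base * 0.5), min(1, base * 1.5))
  for (a in names(arms)) {
    pre <- if (a == "AGBA") "agba" else "std"
    n <- arms[[a]]
    x2 <- second[[a]]
    add(parameter_spec(
      paste0(pre, "_p_second"), "probability", cfg$p_second_puncture[[a]],
      distribution = list(type = "beta", shape1 = x2, shape2 = n - x2),
      owsa_range = unname(wilson_ci(x2, n)),
      note = sprintf("second puncture, %d/%d in trial", x2, n)))
    pc <- cfg$p_complication[[a]]
    grp <- paste0(pre, "_complication")
    add(parameter_spec(
      paste0(pre, "_p_clabsi"), "probability", pc[["CLABSI"]],
      distribution = list(type = "dirichlet", group = grp,
                          alpha = pc[["CLABSI"]] * n),
      owsa_range = unname(wilson_ci(clabsi_counts[[a]], n)),
      note = if (clabsi_counts[[a]] == 0)
        "zero trial count; Jeffreys point estimate 0.5/(n+1)"
      else sprintf("CLABSI, %d/%d in trial", clabsi_counts[[a]], n)))
    add(parameter_spec(
      paste0(pre, "_p_fever"), "probability", pc[["unknown_fever"]],
      distribution = list(type = "dirichlet", group = grp,
                          alpha = pc[["unknown_fever"]] * n),
      owsa_range = owsa_prob(pc[["unknown_fever"]]),
      note = "36 unknown-fever cases overall; per-arm split assumed proportional to arm size"))
    add(parameter_spec(
      paste0(pre, "_p_local"), "probability", pc[["local"]],
      distribution = list(type = "dirichlet", group = grp,
                          alpha = pc[["local"]] * n),
      owsa_range = owsa_prob(pc[["local"]]),
      note = "local complications; probability assumed, no counts published"))
    add(parameter_spec(
      paste0(pre, "_p_nocomp"), "probability", pc[["none"]],
      distribution = list(type = "dirichlet", group = grp,
                          alpha = pc[["none"]] * n),
      note = "complication-free; complement branch of the dirichlet set"))
    pr <- cfg$p_resolution[[a]]
    rgrp <- paste0(pre, "_resolution")
    ess <- 50 # effective sample size of the assumed resolution mix
    add(parameter_spec(
      paste0(pre, "_p_res_rm"), "probability", pr[["resolved_with_removal"]],
      distribution = list(type = "dirichlet", group = rgrp,
                          alpha = pr[["resolved_with_removal"]] * ess),
      owsa_range = owsa_prob(pr[["resolved_with_removal"]]),
      note = "resolved with catheter removal; mix assumed"))
    add(parameter_spec(
      paste0(pre, "_p_worse"), "probability", pr[["worsened"]],
      distribution = list(type = "dirichlet", group = rgrp,
                          alpha = pr[["worsened"]] * ess),
      owsa_range = owsa_prob(pr[["worsened"]]),
      note = "worsened; mix assumed"))
    add(parameter_spec(
      paste0(pre, "_p_res_nr"), "probability", pr[["resolved_no_removal"]],
      distribution = list(type = "dirichlet", group = rgrp,
                          alpha = pr[["resolved_no_removal"]] * ess),
      note = "resolved without removal; complement branch"))
    cm <- cfg$cost_means[[a]]
    short <- c(laboratory_tests = "lab", inpatient_care = "inpatient",
               follow_up = "followup", catheter_maintenance = "maint",
               catheter_expenses = "catheter",
               complication_treatment = "comptreat",
               other_treatments = "other")
    for (cat_i in cost_categories()) {
      m <- cm[[cat_i]]
      shape <- 1 / cfg$cost_cv^2
      add(parameter_spec(
        paste0(pre, "_c_", short[[cat_i]]), "cost", m,
        distribution = if (m > 0)
          list(type = "gamma", shape = shape, scale = m / shape)
        else list(type = "none"),
        owsa_range = c(m * 0.75, m * 1.25),
        note = if (cat_i == "other_treatments")
          "residual category, solved so expected arm cost matches the printed mean"
        else sprintf("baseline %s mean (assumed tariff magnitude), CV %.2f",
                     cat_i, cfg$cost_cv)))
    }
  }
  for (s in c("none", resolution_states())) {
    nm <- switch(s, none = "u_nocomp", resolved_no_removal = "u_res_nr",
                 resolved_with_removal = "u_res_rm", worsened = "u_worse")
    u <- cfg$utilities[[s]]
    add(parameter_spec(
      nm, "utility", u,
      owsa_range = c(max(0, u * 0.9), min(1, u * 1.1)),
      note = if (nm %in% c("u_nocomp", "u_res_rm"))
        "solved so expected arm QALYs match the printed values"
      else "held fixed during calibration"))
  }
  parameter_set(ps)
}

# the two-strategy out-tree; parameter names must match picc_parameters()
picc_tree <- function(arm_names) {
  strategies <- lapply(arm_names, function(a) {
    pre <- if (a == "AGBA") "agba" else "std"
    p <- function(x) paste0(pre, "_", x)
    terminal <- function(state, second_puncture) {
      u <- switch(state, none = "u_nocomp",
                  resolved_no_removal = "u_res_nr",
                  resolved_with_removal = "u_res_rm", worsened = "u_worse")
      has_comp <- state != "none"
      cost <- c(
        if (has_comp) 2 else 1,                         # laboratory tests
        1, 1, 1,                                        # inpatient, follow-up, maintenance
        1 + second_puncture +                           # catheters used
          (state == "resolved_with_removal"),
        if (has_comp) unname(severity_multiplier()[state]) else 0,
        1)                                              # other treatments
      names(cost) <- p(c("c_lab", "c_inpatient", "c_followup", "c_maint",
                         "c_catheter", "c_comptreat", "c_other"))
      terminal_node(state, cost = cost, effect = u)
    }
    resolution_node <- function(compl, second_puncture) {
      chance_node(
        paste0(compl, "_resolution"),
        branch(p("p_res_rm"), terminal("resolved_with_removal", second_puncture)),
        branch(p("p_worse"), terminal("worsened", second_puncture)),
        branch(complement(), terminal("resolved_no_removal", second_puncture)))
    }
    complication_node <- function(second_puncture) {
      chance_node(
        if (second_puncture) "complication_after_second_puncture"
        else "complication",
        branch(p("p_clabsi"), resolution_node("clabsi", second_puncture)),
        branch(p("p_fever"), resolution_node("fever", second_puncture)),
        branch(p("p_local"), resolution_node("local", second_puncture)),
        branch(complement(), terminal("none", second_puncture)))
    }
    chance_node("insertion",
                branch(p("p_second"), complication_node(TRUE)),
                branch(complement(), complication_node(FALSE)))
  })
  names(strategies) <- arm_names
  decision_tree(strategies)
}

#' Trial-calibrated synthetic cohort configuration
#'
#' The [cohort_config()] matching the bundled PICC model: arm sizes 113
#' (AGBA) and 111 (standard), event probabilities from the trial counts
#' (zero cells Jeffreys-adjusted), gamma cost categories whose analytic
#' per-arm expected totals equal the printed per-patient means, and the
#' calibrated state utilities.
#'
#' @param ... passed through to [build_picc_model()].
#' @return a `cea_cohort_config`.
#' @export
picc_cohort_config <- function(...) {
  model <- build_picc_model(...)
  v <- base_values(model$params)
  arm_cfg <- function(pre, arm_n) {
    list(
      p_second = v[[paste0(pre, "_p_second")]],
      pc = c(CLABSI = v[[paste0(pre, "_p_clabsi")]],
             unknown_fever = v[[paste0(pre, "_p_fever")]],
             local = v[[paste0(pre, "_p_local")]],
             none = v[[paste0(pre, "_p_nocomp")]]),
      pr = c(resolved_no_removal = v[[paste0(pre, "_p_res_nr")]],
             resolved_with_removal = v[[paste0(pre, "_p_res_rm")]],
             worsened = v[[paste0(pre, "_p_worse")]]),
      cm = stats::setNames(
        v[paste0(pre, "_c_", c("lab", "inpatient", "followup", "maint",
                               "catheter", "comptreat", "other"))],
        cost_categories())
    )
  }
  ag <- arm_cfg("agba", 113L)
  st <- arm_cfg("std", 111L)
  cohort_config(
    arms = c(AGBA = 113L, standard = 111L),
    p_second_puncture = list(AGBA = ag$p_second, standard = st$p_second),
    p_complication = list(AGBA = ag$pc, standard = st$pc),
    p_resolution = list(AGBA = ag$pr, standard = st$pr),
    cost_means = list(AGBA = ag$cm, standard = st$cm),
    cost_cv = 0.3,
    utilities = c(none = v[["u_nocomp"]],
                  resolved_no_removal = v[["u_res_nr"]],
                  resolved_with_removal = v[["u_res_rm"]],
                  worsened = v[["u_worse"]]))
}

#' Path to the bundled PICC model file
#'
#' @return path to `picc_agba_vs_standard.json` in the installed package.
#' @export
picc_model_file <- function() {
  system.file("extdata", "picc_agba_vs_standard.json", package = "ceatree",
              mustWork = TRUE)
}
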