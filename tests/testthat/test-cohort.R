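test_that("the default trial config generates exact arm sizes", {
  cohort <- generate_cohort(picc_cohort_config(), seed = 1)
  expect_equal(nrow(cohort), 224)
  expect_equal(sum(cohort$arm == "AGBA"), 113)
  expect_equal(sum(cohort$arm == "standard"), 111)
})

test_that("generated cohorts satisfy the record invariants row-wise", {
  cohort <- generate_cohort(picc_cohort_config(), seed = 2)
  none <- cohort$complication == "none"
  expect_true(all(cohort$resolution[none] == "n/a"))
  expect_true(all(cohort$complication_treatment[none] == 0))
  expect_true(all(cohort$resolution[!none] %in%
                    c("resolved_no_removal", "resolved_with_removal",
                      "worsened")))
  expect_true(all(cohort$puncture_attempts %in% 1:2))
  costs <- as.matrix(cohort[, cost_categories()])
  expect_true(all(costs >= 0))
  expect_equal(cohort$total_cost, rowSums(costs))
  expect_true(all(cohort$qaly >= 0 & cohort$qaly <= 1))
})

test_that("zero event probabilities produce complication-free cohorts", {
  cfg <- picc_cohort_config()
  for (a in names(cfg$arms)) {
    cfg$p_complication[[a]] <- c(CLABSI = 0, unknown_fever = 0, local = 0,
                                 none = 1)
    cfg$p_second_puncture[[a]] <- 0
  }
  cohort <- generate_cohort(cfg, seed = 3)
  expect_true(all(cohort$complication == "none"))
  expect_true(all(cohort$complication_treatment == 0))
  expect_true(all(cohort$puncture_attempts == 1))
})

test_that("cohort generation is reproducible by seed", {
  cfg <- picc_cohort_config()
  expect_identical(generate_cohort(cfg, seed = 4), generate_cohort(cfg, seed = 4))
  expect_false(identical(generate_cohort(cfg, seed = 4),
                         generate_cohort(cfg, seed = 5)))
})

test_that("large-cohort event frequencies match the configured probabilities", {
  cfg <- picc_cohort_config()
  cfg$arms <- c(AGBA = 100000L, standard = 100000L)
  cohort <- generate_cohort(cfg, seed = 6)
  for (a in names(cfg$arms)) {
    p <- cfg$p_complication[[a]][["CLABSI"]]
    n <- cfg$arms[[a]]
    freq <- sum(cohort$complication == "CLABSI" & cohort$arm == a) / n
    expect_lt(abs(freq - p), 3 * sqrt(p * (1 - p) / n))
  }
})

test_that("estimate_probabilities reproduces counts and flags zero cells", {
  cohort <- tibble::tibble(
    arm = rep("standard", 111),
    puncture_attempts = rep(1L, 111),
    complication = c(rep("CLABSI", 3), rep("none", 108)),
    resolution = c(rep("resolved_with_removal", 3), rep("n/a", 108)))
  est <- estimate_probabilities(cohort)
  clabsi <- est[est$event == "CLABSI", ]
  expect_equal(clabsi$estimate, 3 / 111)
  expect_false(clabsi$zero_cell)
  fever <- est[est$event == "unknown_fever", ]
  expect_true(fever$zero_cell)
  expect_equal(fever$estimate, 0.5 / 112) # Jeffreys point estimate
  expect_error(estimate_probabilities(cohort[0, ]),
               class = "ceatree_input_error")
})

test_that("calibrate_costs solves the residual category to the target", {
  cfg <- picc_cohort_config()
  fixed <- expected_arm_cost(cfg, exclude = "other_treatments")
  cal <- calibrate_costs(cfg, c(AGBA = 19696.23, standard = 21987.32))
  expect_equal(unname(attr(cal, "achieved")),
               c(19696.23, 21987.32), tolerance = 1e-9)
  expect_equal(cal$cost_means$standard[["other_treatments"]],
               21987.32 - fixed[["standard"]], tolerance = 1e-9)
  # an unreachable target errors rather than going negative
  expect_error(calibrate_costs(cfg, c(AGBA = 100, standard = 21987.32)),
               class = "ceatree_infeasible_error")
})

test_that("simulated arm means converge to the calibrated analytic targets", {
  cfg <- picc_cohort_config()
  cfg$arms <- c(AGBA = 200000L, standard = 1000L)
  cohort <- generate_cohort(cfg, seed = 8)
  agba <- cohort[cohort$arm == "AGBA", ]
  se <- stats::sd(agba$total_cost) / sqrt(nrow(agba))
  expect_lt(abs(mean(agba$total_cost) - 19696.23), 3 * se)
})

test_that("two-stage estimation round-trips the generating probabilities", {
  cfg <- picc_cohort_config()
  cfg$arms <- c(AGBA = 50000L, standard = 50000L)
  est1 <- estimate_probabilities(generate_cohort(cfg, seed = 13))
  # feed estimates back in as the generating probabilities
  cfg2 <- cfg
  for (a in names(cfg$arms)) {
    e <- est1[est1$arm == a, ]
    pc <- c(CLABSI = e$estimate[e$event == "CLABSI"],
            unknown_fever = e$estimate[e$event == "unknown_fever"],
            local = e$estimate[e$event == "local"])
    cfg2$p_complication[[a]] <- c(pc, none = 1 - sum(pc))
  }
  est2 <- estimate_probabilities(generate_cohort(cfg2, seed = 14))
  for (a in names(cfg$arms)) {
    for (ev in c("CLABSI", "unknown_fever", "local")) {
      p1 <- est1$estimate[est1$arm == a & est1$event == ev]
      p2 <- est2$estimate[est2$arm == a & est2$event == ev]
      se <- sqrt(p1 * (1 - p1) / 50000)
      expect_lt(abs(p2 - p1), 4 * se)
    }
  }
})

test_that("invalid configs are rejected with every violation listed", {
  cfg <- picc_cohort_config()
  cfg$p_complication$AGBA[["CLABSI"]] <- 0.5 # sum now != 1
  cfg$cost_cv <- -1
  err <- tryCatch(generate_cohort(cfg, seed = 1), error = identity)
  expect_s3_class(err, "ceatree_validation_error")
  expect_match(conditionMessage(err), "sum")
  expect_match(conditionMessage(err), "cost_cv")
})
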