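test_that("degenerate distributions reproduce base values in every draw", {
  params <- parameter_set(
    parameter_spec("p", "probability", 0.3),
    parameter_spec("c", "cost", 1000))
  draws <- sample_parameters(params, 5, seed = 1)
  expect_equal(dim(draws), c(5, 2))
  expect_true(all(draws[, "p"] == 0.3))
  expect_true(all(draws[, "c"] == 1000))
})

test_that("beta draws match their closed-form mean", {
  params <- parameter_set(parameter_spec(
    "p", "probability", 0.5,
    distribution = list(type = "beta", shape1 = 2, shape2 = 2)))
  draws <- sample_parameters(params, 1e5, seed = 42)
  se <- sqrt(1 / 20) / sqrt(1e5) # var of beta(2,2) is 1/20
  expect_lt(abs(mean(draws[, "p"]) - 0.5), 3 * se)
  expect_true(all(draws >= 0 & draws <= 1))
})

test_that("dirichlet branch sets stay on the simplex in every draw", {
  params <- parameter_set(
    parameter_spec("a", "probability", 0.2,
                   distribution = list(type = "dirichlet", group = "g", alpha = 2)),
    parameter_spec("b", "probability", 0.3,
                   distribution = list(type = "dirichlet", group = "g", alpha = 3)),
    parameter_spec("c", "probability", 0.5,
                   distribution = list(type = "dirichlet", group = "g", alpha = 5)))
  draws <- sample_parameters(params, 1000, seed = 7)
  expect_true(all(abs(rowSums(draws) - 1) < 1e-12))
  expect_true(all(draws >= 0))
})

test_that("invalid hyperparameters error before any sampling", {
  params <- parameter_set(parameter_spec(
    "p", "probability", 0.5,
    distribution = list(type = "beta", shape1 = -1, shape2 = 2)))
  expect_error(sample_parameters(params, 10, seed = 1),
               class = "ceatree_validation_error")
  expect_error(
    parameter_set(parameter_spec("q", "probability", 0.5,
                                 distribution = list(type = "wibble"))) |>
      sample_parameters(10, seed = 1),
    class = "ceatree_validation_error")
})

test_that("PSA with degenerate distributions equals the base case bitwise", {
  params <- parameter_set(
    parameter_spec("p", "probability", 0.25),
    parameter_spec("c_bad", "cost", 1000),
    parameter_spec("c_good", "cost", 200))
  tree <- decision_tree(list(
    S = chance_node("n",
      branch("p", terminal_node("bad", c(c_bad = 1), 0.6)),
      branch(complement(), terminal_node("good", c(c_good = 1), 0.8)))
  ))
  base <- rollback(tree, params)
  psa <- run_psa(tree, params, n = 100, seed = 3)
  expect_identical(unique(psa$outcomes$cost), base$expected_cost)
  expect_identical(unique(psa$outcomes$effect), base$expected_effect)
})

test_that("PSA is reproducible by seed and differs across seeds", {
  model <- read_model(picc_fixture_path())
  a <- run_psa(model$tree, model$params, n = 200, seed = 10)
  b <- run_psa(model$tree, model$params, n = 200, seed = 10)
  c <- run_psa(model$tree, model$params, n = 200, seed = 11)
  expect_identical(a$outcomes, b$outcomes)
  expect_identical(psa_summary(a), psa_summary(b))
  expect_false(identical(a$outcomes, c$outcomes))
})

test_that("PSA means converge to the base case on the bundled model", {
  model <- read_model(picc_fixture_path())
  base <- rollback(model$tree, model$params)
  psa <- run_psa(model$tree, model$params, n = 10000, seed = 123)
  s <- psa_summary(psa)
  for (strat in base$strategy) {
    b <- base[base$strategy == strat, ]
    m <- s[s$strategy == strat, ]
    expect_lt(abs(m$mean_cost - b$expected_cost), 3 * m$mcse_cost)
    expect_lt(abs(m$mean_effect - b$expected_effect), 3 * m$mcse_effect)
  }
})

test_that("every sampled probability is in [0,1] and every cost non-negative", {
  model <- read_model(picc_fixture_path())
  draws <- sample_parameters(model$params, 2000, seed = 99)
  kinds <- vapply(model$params, `[[`, character(1), "kind")
  pcols <- names(kinds)[kinds %in% c("probability", "utility")]
  ccols <- names(kinds)[kinds == "cost"]
  expect_true(all(draws[, pcols] >= 0 & draws[, pcols] <= 1))
  expect_true(all(draws[, ccols] >= 0))
})

# hand-built two-strategy cloud used by the CEAC cases below
toy_cloud <- function(cost_a, eff_a, cost_b, eff_b) {
  n <- length(cost_a)
  structure(list(
    outcomes = tibble::tibble(
      iteration = rep(seq_len(n), 2),
      strategy = rep(c("A", "B"), each = n),
      cost = c(cost_a, cost_b),
      effect = c(eff_a, eff_b)),
    n = n, seed = NULL, n_excluded = 0L), class = "cea_psa")
}

test_that("a strategy dominant in every iteration has CEAC identically 1", {
  cloud <- toy_cloud(cost_a = c(100, 110), eff_a = c(0.9, 0.8),
                     cost_b = c(200, 220), eff_b = c(0.5, 0.4))
  curve <- ceac(cloud, lambdas = c(0, 1e3, 1e5, 1e7))
  expect_true(all(curve$probability[curve$strategy == "A"] == 1))
  expect_true(all(curve$probability[curve$strategy == "B"] == 0))
})

test_that("at lambda 0 the CEAC is the fraction of iterations with lowest cost", {
  cloud <- toy_cloud(cost_a = c(1, 3, 1, 1), eff_a = rep(0.2, 4),
                     cost_b = c(2, 2, 2, 2), eff_b = rep(0.9, 4))
  curve <- ceac(cloud, lambdas = 0)
  expect_equal(curve$probability[curve$strategy == "A"], 0.75)
  # and as lambda grows only effect matters
  high <- ceac(cloud, lambdas = 1e9)
  expect_equal(high$probability[high$strategy == "B"], 1)
})

test_that("a two-iteration cloud split between strategies gives (0.5, 0.5)", {
  # iteration 1 favours A, iteration 2 favours B at lambda = 113120
  cloud <- toy_cloud(cost_a = c(100, 5000), eff_a = c(0.8, 0.5),
                     cost_b = c(5000, 100), eff_b = c(0.5, 0.8))
  curve <- ceac(cloud, lambdas = 113120)
  expect_equal(sort(curve$probability), c(0.5, 0.5))
  # probabilities always sum to 1 across strategies
  expect_equal(sum(curve$probability), 1, tolerance = 1e-9)
})

test_that("exact NMB ties are split equally", {
  cloud <- toy_cloud(cost_a = c(10, 10), eff_a = c(0.5, 0.5),
                     cost_b = c(10, 10), eff_b = c(0.5, 0.5))
  curve <- ceac(cloud, lambdas = c(0, 50000))
  expect_true(all(curve$probability == 0.5))
})

test_that("ceac rejects empty grids and single-strategy clouds", {
  cloud <- toy_cloud(1, 0.1, 2, 0.2)
  expect_error(ceac(cloud, numeric(0)), class = "ceatree_input_error")
  one <- cloud
  one$outcomes <- one$outcomes[one$outcomes$strategy == "A", ]
  expect_error(ceac(one, 1e4), class = "ceatree_input_error")
})

test_that("prediction intervals match closed-form quantiles and behave monotonically", {
  n <- 1e5
  cloud <- withr::with_seed(8, toy_cloud(runif(n), runif(n),
                                         runif(n) + 1, runif(n)))
  pi95 <- prediction_interval(cloud, "cost", level = 0.95)
  a <- pi95[pi95$strategy == "A", ]
  expect_lt(abs(a$lower - 0.025), 0.01)
  expect_lt(abs(a$upper - 0.975), 0.01)
  # constant cloud: zero width
  const <- toy_cloud(rep(5, 10), rep(0.5, 10), rep(7, 10), rep(0.6, 10))
  pc <- prediction_interval(const, "cost")
  expect_equal(pc$lower, pc$upper)
  # widening the level never narrows the interval
  pi50 <- prediction_interval(cloud, "cost", level = 0.50)
  a50 <- pi50[pi50$strategy == "A", ]
  expect_lte(a$lower, a50$lower)
  expect_gte(a$upper, a50$upper)
  expect_error(prediction_interval(cloud, "cost", level = 1.2),
               class = "ceatree_input_error")
})
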