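test_that("validation accepts complement trees and reports bad sums with node id", {
  params <- parameter_set(parameter_spec("p", "probability", 0.6))
  good <- decision_tree(list(
    S = chance_node("n1",
      branch("p", terminal_node("a", 10, 0.5)),
      branch(complement(), terminal_node("b", 20, 0.6)))
  ))
  expect_length(validate_tree(good, params), 0)

  bad <- decision_tree(list(
    S = chance_node("n1",
      branch(0.6, terminal_node("a", 10, 0.5)),
      branch(0.5, terminal_node("b", 20, 0.6)))
  ))
  report <- validate_tree(bad, params)
  expect_length(report, 1)
  expect_match(report, "n1")
  expect_match(report, "1\\.1")
})

test_that("validation names unresolved references and double complements", {
  tree <- decision_tree(list(
    S = chance_node("n1",
      branch("p_missing", terminal_node("a", c(c_missing = 1), "u_missing")),
      branch(complement(), terminal_node("b", 20, 0.6)),
      branch(complement(), terminal_node("c", 30, 0.7)))
  ))
  report <- validate_tree(tree, parameter_set(list()))
  expect_true(any(grepl("p_missing", report)))
  expect_true(any(grepl("c_missing", report)))
  expect_true(any(grepl("u_missing", report)))
  expect_true(any(grepl("more than one complement", report)))
})

test_that("rollback computes probability-weighted payoffs", {
  # degenerate tree: a single terminal passes its payoffs through
  single <- decision_tree(list(S = terminal_node("only", 100, 0.5)))
  out <- rollback(single, empty_params())
  expect_equal(out$expected_cost, 100)
  expect_equal(out$expected_effect, 0.5)

  # hand arithmetic: 0.25*1000 + 0.75*200 = 400; 0.25*0.6 + 0.75*0.8 = 0.75
  out2 <- rollback(two_branch_tree(), empty_params())
  expect_equal(out2$expected_cost, 400)
  expect_equal(out2$expected_effect, 0.75)
})

test_that("rollback refuses an invalid tree", {
  bad <- decision_tree(list(
    S = chance_node("n1",
      branch(0.6, terminal_node("a", 10, 0.5)),
      branch(0.5, terminal_node("b", 20, 0.6)))
  ))
  expect_error(rollback(bad, empty_params()), class = "ceatree_validation_error")
})

test_that("enumerate_paths lists every path with the right probabilities", {
  p <- enumerate_paths(two_branch_tree(), empty_params())
  expect_equal(nrow(p), 2)
  expect_equal(sort(p$probability), c(0.25, 0.75))
  expect_equal(sum(p$probability), 1)

  single <- decision_tree(list(S = terminal_node("only", 100, 0.5)))
  p1 <- enumerate_paths(single, empty_params())
  expect_equal(p1$probability, 1)
})

test_that("rollback equals path-enumeration aggregation on random trees", {
  withr::with_seed(42, {
    for (i in 1:200) {
      tr <- random_tree(depth = sample(1:4, 1), max_branch = 4)
      paths <- enumerate_paths(tr, empty_params())
      expect_equal(sum(paths$probability), 1, tolerance = 1e-9)
      out <- rollback(tr, empty_params())
      expect_equal(out$expected_cost, sum(paths$probability * paths$cost),
                   tolerance = 1e-9)
      expect_equal(out$expected_effect, sum(paths$probability * paths$effect),
                   tolerance = 1e-9)
    }
  })
})

test_that("expected cost is linear in terminal costs; effects unchanged", {
  withr::with_seed(7, {
    for (i in 1:20) {
      tr <- random_tree(depth = 3)
      base <- rollback(tr, empty_params())
      scaled <- rollback(scale_tree_costs(tr, 3.5), empty_params())
      expect_equal(scaled$expected_cost, 3.5 * base$expected_cost)
      expect_equal(scaled$expected_effect, base$expected_effect)
    }
  })
})

test_that("merging sibling branches with identical terminals preserves rollback", {
  merged <- decision_tree(list(
    S = chance_node("n",
      branch(0.4, terminal_node("t", 500, 0.3)),
      branch(complement(), terminal_node("u", 100, 0.9)))
  ))
  split <- decision_tree(list(
    S = chance_node("n",
      branch(0.25, terminal_node("t", 500, 0.3)),
      branch(0.15, terminal_node("t", 500, 0.3)),
      branch(complement(), terminal_node("u", 100, 0.9)))
  ))
  expect_equal(rollback(merged, empty_params())[, -1],
               rollback(split, empty_params())[, -1])
})

test_that("the bundled PICC model validates and reproduces its calibration targets", {
  model <- read_model(picc_fixture_path())
  expect_length(validate_tree(model$tree, model$params), 0)
  out <- rollback(model$tree, model$params)
  agba <- out[out$strategy == "AGBA", ]
  std <- out[out$strategy == "standard", ]
  expect_equal(agba$expected_cost, 19696.23, tolerance = 1e-9)
  expect_equal(std$expected_cost, 21987.32, tolerance = 1e-9)
  expect_equal(agba$expected_effect, 0.73, tolerance = 1e-9)
  expect_equal(std$expected_effect, 0.68, tolerance = 1e-9)
  # oracle equivalence on the bundled model
  paths <- enumerate_paths(model$tree, model$params)
  agg <- tapply(paths$probability * paths$cost, paths$strategy, sum)
  expect_equal(as.numeric(agg[out$strategy]), out$expected_cost,
               tolerance = 1e-9)
})

test_that("calibrated utilities respect the severity ordering", {
  v <- base_values(read_model(picc_fixture_path())$params)
  expect_true(v[["u_nocomp"]] > v[["u_res_nr"]])
  expect_true(v[["u_res_nr"]] > v[["u_res_rm"]])
  expect_true(v[["u_res_rm"]] > v[["u_worse"]])
  expect_true(all(v[c("u_nocomp", "u_res_nr", "u_res_rm", "u_worse")] >= 0))
  expect_true(all(v[c("u_nocomp", "u_res_nr", "u_res_rm", "u_worse")] <= 1))
})
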