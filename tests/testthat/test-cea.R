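test_that("icer handles ratio, dominance, and equal-effect cases", {
  r <- icer(2291.10, 0.05)
  expect_equal(r$icer, 45822, tolerance = 1e-9)
  expect_equal(r$status, "icer")
  expect_equal(icer(0, 0.05)$icer, 0)
  expect_equal(icer(5656.00, 0.05)$icer, 113120)
  expect_equal(icer(-2291.09, 0.05)$status, "dominant")
  expect_equal(icer(50, -0.1)$status, "dominated")
  eq <- icer(10, 0)
  expect_equal(eq$status, "equal-effect")
  expect_true(is.na(eq$icer))
})

test_that("nmb is lambda * effect - cost", {
  expect_equal(nmb(19696.23, 0.73, 113120), 62881.37)
  expect_equal(nmb(21987.32, 0.68, 113120), 54934.28)
  expect_equal(nmb(0, 0, 113120), 0)
})

test_that("incremental analysis flags the cheaper-and-more-effective case as dominant", {
  agba <- tibble::tibble(strategy = "AGBA", expected_cost = 19696.23,
                         expected_effect = 0.73)
  std <- tibble::tibble(strategy = "standard", expected_cost = 21987.32,
                        expected_effect = 0.68)
  inc <- incremental(agba, std, 113120)
  expect_equal(inc$delta_cost, -2291.09, tolerance = 1e-9)
  expect_equal(inc$delta_effect, 0.05, tolerance = 1e-9)
  expect_equal(inc$status, "dominant")
  expect_true(is.na(inc$icer))
  expect_equal(inc$inmb, 0.05 * 113120 + 2291.09, tolerance = 1e-6)
  expect_true(inc$cost_effective)

  same <- incremental(agba, agba, 113120)
  expect_equal(same$status, "equal-effect")
  expect_equal(same$delta_cost, 0)

  a <- tibble::tibble(strategy = "a", expected_cost = 100, expected_effect = 0.5)
  b <- tibble::tibble(strategy = "b", expected_cost = 50, expected_effect = 0.6)
  expect_equal(incremental(a, b, 113120)$status, "dominated")
})

test_that("incremental is antisymmetric in its increments", {
  withr::with_seed(11, {
    for (i in 1:20) {
      a <- tibble::tibble(strategy = "a", expected_cost = runif(1, 0, 1e5),
                          expected_effect = runif(1))
      b <- tibble::tibble(strategy = "b", expected_cost = runif(1, 0, 1e5),
                          expected_effect = runif(1))
      ab <- incremental(a, b, 113120)
      ba <- incremental(b, a, 113120)
      expect_equal(ab$delta_cost, -ba$delta_cost)
      expect_equal(ab$delta_effect, -ba$delta_effect)
    }
  })
})

test_that("currency conversion reproduces the published figures exactly", {
  expect_identical(rmb_to_usd(21987.32), 3242.82)
  expect_identical(rmb_to_usd(19696.23), 2904.92)
  expect_identical(rmb_to_usd(4271.31), 629.96)
  expect_identical(rmb_to_usd(113120), 16683.63)
  expect_identical(rmb_to_usd(41000), 6046.93)
  expect_identical(rmb_to_usd(42000), 6194.42)
  expect_identical(rmb_to_usd(0), 0)
  # the printed-cost difference converts to 337.91, not the printed 428.44
  expect_identical(rmb_to_usd(2291.10), 337.91)
})

test_that("currency round trip is within half-cent-at-rate accuracy", {
  withr::with_seed(3, {
    x <- c(0, 0.01, runif(200, 0, 1e7))
    back <- usd_to_rmb(rmb_to_usd(x))
    expect_true(all(abs(back - x) <= 0.005 * 678.03 + 1e-9))
  })
})

test_that("NMB ranking and the ICER < lambda rule agree when effect is gained", {
  withr::with_seed(5, {
    for (i in 1:200) {
      dc <- runif(1, -1e4, 1e4)
      de <- runif(1, 1e-4, 0.5) # effect gained
      lambda <- runif(1, 1, 2e5)
      nmb_rule <- (lambda * de - dc) > 0
      r <- icer(dc, de)
      icer_rule <- if (r$status == "dominant") TRUE else r$icer < lambda
      expect_equal(nmb_rule, icer_rule)
    }
  })
})

test_that("dominance frontier removes strict and extended dominance", {
  # fixture case: one strategy cheaper and more effective
  out <- tibble::tibble(strategy = c("AGBA", "standard"),
                        expected_cost = c(19696.23, 21987.32),
                        expected_effect = c(0.73, 0.68))
  f <- dominance_frontier(out)
  expect_equal(f$strategy, "AGBA")

  three <- tibble::tibble(strategy = c("a", "b", "c"),
                          expected_cost = c(0, 10, 100),
                          expected_effect = c(0, 0.5, 0.6))
  f3 <- dominance_frontier(three)
  expect_equal(f3$strategy, c("a", "b", "c"))
  expect_equal(f3$icer, c(NA, 20, 900))

  ext <- tibble::tibble(strategy = c("a", "b", "c"),
                        expected_cost = c(0, 50, 60),
                        expected_effect = c(0, 0.1, 0.5))
  fe <- dominance_frontier(ext)
  expect_equal(fe$strategy, c("a", "c"))
  expect_equal(fe$icer, c(NA, 120))
})

test_that("the frontier is invariant to input ordering", {
  withr::with_seed(9, {
    out <- tibble::tibble(strategy = letters[1:6],
                          expected_cost = runif(6, 0, 1e4),
                          expected_effect = runif(6))
    ref <- dominance_frontier(out)
    for (i in 1:5) {
      perm <- out[sample.int(6), ]
      expect_equal(dominance_frontier(perm), ref)
    }
  })
})
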