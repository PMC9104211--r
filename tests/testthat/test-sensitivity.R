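test_that("parameter sampling recovers the requested moments", {
  set.seed(11)
  expect_equal(sample_parameter(dist_spec("fixed", 233), 5), rep(233, 5))
  # beta: mean recovery within 3 Monte Carlo SEs
  n <- 30000
  x <- sample_parameter(dist_spec("beta", 0.75, 0.2), n)
  se <- sd(x) / sqrt(n)
  expect_lt(abs(mean(x) - 0.75), 3 * se)
  expect_true(all(x > 0 & x < 1))
  # gamma: mean and coefficient of variation
  y <- sample_parameter(dist_spec("gamma", 4231, 0.2), n)
  expect_lt(abs(mean(y) - 4231), 3 * sd(y) / sqrt(n))
  expect_equal(sd(y) / mean(y), 0.2, tolerance = 0.02)
  expect_true(all(y > 0))
  # infeasible beta dispersion errors and names the parameter
  expect_error(sample_parameter(dist_spec("beta", 0.991, 0.2), 1,
                                name = "sensitivity_CEUS"),
               "sensitivity_CEUS")
})

test_that("one-way DSA pins parameters and measures the outcome span", {
  ps <- baseline_ps()
  lt <- baseline_lt()
  # a collapsed range has zero span and reproduces the base case
  e <- one_way_dsa(ps, lt, "cost_biopsy", 1375, 1375)
  expect_equal(e$span, 0)
  # a parameter with no pathway influence: zero everywhere
  e2 <- one_way_dsa(ps, lt, "cost_no_action", 0, 0)
  expect_equal(e2$span, 0)
  expect_equal(e2$outcome_at_low, e$outcome_at_low, tolerance = 1e-9)
  # sweeping the CEUS exam cost +/-20% leaves CEUS NMB-optimal at both ends
  e3 <- one_way_dsa(ps, lt, "exam_cost_CEUS", 285 * 0.8, 285 * 1.2)
  expect_gt(e3$outcome_at_low, 0)
  expect_gt(e3$outcome_at_high, 0)
  expect_equal(e3$span, abs(e3$outcome_at_high - e3$outcome_at_low))
  expect_error(one_way_dsa(ps, lt, "cost_biopsy", 10, 5), "low must be")
  expect_error(one_way_dsa(ps, lt, "sensitivity_CEUS", 0.5, 1.4),
               "sensitivity")
})

test_that("tornado sorts by span and validates its range table", {
  ps <- baseline_ps()
  lt <- baseline_lt()
  empty <- tornado(ps, lt, range_spec = data.frame(parameter = character(),
                                                   low = numeric(),
                                                   high = numeric()))
  expect_identical(nrow(empty), 0L)
  dup <- data.frame(parameter = c("cost_biopsy", "cost_biopsy"),
                    low = c(1, 1), high = c(2, 2))
  expect_error(tornado(ps, lt, range_spec = dup), "duplicated parameter")
  # collapsed ranges: every span zero
  rs <- default_dsa_ranges(ps)
  rs$low <- rs$high <- vapply(rs$parameter, get_parameter, numeric(1),
                              ps = ps)
  tor0 <- tornado(ps, lt, range_spec = rs)
  expect_true(all(tor0$span < 1e-9))
  # a small real sweep comes back span-sorted
  rs2 <- default_dsa_ranges(ps)[c(1, 5, 9), ]
  tor <- tornado(ps, lt, range_spec = rs2)
  expect_identical(nrow(tor), 3L)
  expect_true(all(diff(tor$span) <= 0))
})

test_that("default DSA ranges cover accuracies and costs, clipped to [0,1]", {
  rs <- default_dsa_ranges(baseline_ps())
  expect_true(all(paste0("sensitivity_", c("CEUS", "CT", "MRI"))
                  %in% rs$parameter))
  expect_true(all(c("cost_biopsy", "monthly_cost_metastatic_y1",
                    "exam_cost_MRI") %in% rs$parameter))
  expect_lte(rs$high[rs$parameter == "sensitivity_CEUS"], 1)  # 0.991 * 1.2
  expect_equal(rs$low[rs$parameter == "cost_biopsy"], 1375 * 0.8)
})

test_that("the PSA is bit-identical under a fixed seed", {
  ps <- baseline_ps()
  lt <- baseline_lt()
  p1 <- run_psa(ps, lt, n_iterations = 50, seed = 123)
  p2 <- run_psa(ps, lt, n_iterations = 50, seed = 123)
  expect_identical(p1$cost, p2$cost)
  expect_identical(p1$effect, p2$effect)
  expect_identical(p1$ceac, p2$ceac)
  p3 <- run_psa(ps, lt, n_iterations = 50, seed = 124)
  expect_false(identical(p1$cost, p3$cost))
})

test_that("an all-fixed PSA reproduces the base case every iteration", {
  # this also cross-validates the vectorized PSA engine against the scalar
  # cohort engine
  lt <- baseline_lt()
  for (top in c("specified", "reconciled")) {
    opts <- model_options(top)
    ps <- baseline_ps()
    ps$psa_dist <- lapply(ps$psa_dist, function(d)
      dist_spec("fixed", d$mean))
    psa <- run_psa(ps, lt, n_iterations = 7, seed = 5, opts = opts)
    base <- evaluate_strategies(ps, lt, opts = opts)
    for (s in psa$strategies) {
      expect_equal(unname(psa$cost[, s]),
                   rep(base[[s]]$expected_cost, 7), tolerance = 1e-9,
                   info = paste(top, s))
      expect_equal(unname(psa$effect[, s]),
                   rep(base[[s]]$expected_effect, 7), tolerance = 1e-9,
                   info = paste(top, s))
    }
  }
})

test_that("acceptability curves normalize and resolve ties by cost", {
  ps <- baseline_ps()
  lt <- baseline_lt()
  psa <- run_psa(ps, lt, n_iterations = 300, seed = 42)
  grid <- seq(0, 200000, by = 10000)
  curves <- ceac(psa, grid)
  agg <- as.numeric(tapply(curves$acceptance, curves$wtp, sum))
  expect_equal(agg, rep(1, length(grid)), tolerance = 1e-12)
  expect_true(all(curves$acceptance >= 0 & curves$acceptance <= 1))
  # at wtp 0 acceptance is the fraction of iterations a strategy is cheapest
  at0 <- curves[curves$wtp == 0, ]
  cheapest <- apply(psa$cost, 1, function(x) names(which.min(x)))
  for (s in psa$strategies)
    expect_equal(at0$acceptance[at0$strategy == s],
                 mean(cheapest == s), tolerance = 1e-12)
  # a single iteration puts full weight on its winner
  one <- run_psa(ps, lt, n_iterations = 1, seed = 9)
  c1 <- ceac(one, 100000)
  expect_equal(sort(c1$acceptance), c(0, 0, 1))
  # CEUS is the modal winner at the working threshold
  at1e5 <- curves[curves$wtp == 100000, ]
  expect_gt(at1e5$acceptance[at1e5$strategy == "CEUS"], 0.5)
})
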