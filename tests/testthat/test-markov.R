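test_that("probability conversions follow the constant-hazard closed forms", {
  expect_equal(annual_to_monthly_prob(0), 0)
  expect_equal(annual_to_monthly_prob(1), 1)
  m <- annual_to_monthly_prob(0.13)
  expect_equal(m, 1 - 0.87^(1 / 12), tolerance = 1e-15)
  expect_equal(1 - (1 - m)^12, 0.13, tolerance = 1e-12)  # 12-fold composition
  expect_error(annual_to_monthly_prob(1.01), "out of")
  expect_error(annual_to_monthly_prob(-0.1), "out of")

  expect_equal(combine_competing_risks(0, 0.4), 0.4)
  expect_equal(combine_competing_risks(1, 0.4), 1)
  expect_equal(combine_competing_risks(0.01, 0.02), 0.0298,
               tolerance = 1e-12)
  expect_error(combine_competing_risks(2, 0.1), "out of")

  expect_equal(discount_factor(0, 0.03), 1)
  expect_equal(discount_factor(12, 0.03), 1 / 1.03, tolerance = 1e-15)
  expect_equal(discount_factor(c(0, 7, 300), 0), c(1, 1, 1))
  expect_error(discount_factor(3, -0.01), ">= 0")
})

test_that("transition matrices are row-stochastic with the expected structure", {
  ps <- baseline_ps()
  lt <- baseline_lt()
  for (opts in list(model_options("specified"), model_options("reconciled"))) {
    for (pw in c("timely", "delayed", "none")) {
      M <- build_transition_matrix(ps, lt, 62 * 12, pathway = pw, opts = opts)
      expect_equal(rowSums(M), setNames(rep(1, 4), markov_states),
                   tolerance = 1e-12)
      expect_true(all(M >= 0))
      expect_equal(M["DEAD", ], setNames(c(0, 0, 0, 1), markov_states))
    }
  }
  # 35% metastatic excess risk dwarfs the 3.5% localized one
  M <- build_transition_matrix(ps, lt, 62 * 12)
  expect_gt(M["METASTATIC", "DEAD"], M["LOCALIZED", "DEAD"])

  # no disease, no background mortality: identity matrix
  ps0 <- toy_chain_ps(1e-9, 1, 0, 0)
  ps0$excess_death_metastatic <- 0
  M0 <- build_transition_matrix(ps0, flat_life_table(0), 40 * 12)
  expect_equal(unname(M0), diag(4), tolerance = 1e-12)

  # at the life-table cap everyone dies, and rows still normalize
  Mcap <- build_transition_matrix(ps, lt, 100 * 12)
  expect_equal(unname(Mcap[, "DEAD"]), rep(1, 4))
  expect_equal(rowSums(Mcap), setNames(rep(1, 4), markov_states))
})

test_that("state rewards apply the first-year regime and utility weights", {
  ps <- baseline_ps()
  expect_equal(state_reward("DEAD", 3, "timely", ps), c(cost = 0, qaly = 0))
  expect_equal(state_reward("METASTATIC", 5, "delayed", ps),
               c(cost = 2086.42, qaly = 0.055))
  expect_equal(state_reward("LOCALIZED", 14, "timely", ps),
               c(cost = 212.67, qaly = 0.0625))
  expect_equal(state_reward("LOCALIZED", 11, "timely", ps)[["cost"]], 2148.25)
  expect_equal(state_reward("NO_TUMOR", 0, "none", ps),
               c(cost = 108.50, qaly = 1 / 12))
  # metastatic cost regime switches at one year
  expect_equal(state_reward("METASTATIC", 12, "delayed", ps)[["cost"]],
               810.58)
  # reconciled delayed pathway carries the metastatic rows in the
  # localized slot
  rec <- model_options("reconciled")
  expect_equal(state_reward("LOCALIZED", 2, "delayed", ps, rec),
               c(cost = 2086.42, qaly = 0.055))
  expect_equal(state_reward("LOCALIZED", 2, "timely", ps, rec)[["cost"]],
               212.67)
})

test_that("the cohort engine matches the two-state closed form to 1e-9", {
  lt <- flat_life_table(0, 0, 300)
  cases <- expand.grid(q = c(0.002, 0.05, 0.5, 1), disc = c(0, 0.03, 0.1))
  for (i in seq_len(nrow(cases))) {
    q <- cases$q[i]; disc <- cases$disc[i]
    ps <- toy_chain_ps(q, utility = 0.66, monthly_cost = 810.58,
                       discount = disc)
    tr <- run_cohort("METASTATIC", ps, lt, horizon_months = 240)
    cf <- toy_closed_form(q, 0.66, 810.58, disc, 240)
    expect_equal(tr$total_cost, cf[["cost"]], tolerance = 1e-9)
    expect_equal(tr$total_qaly, cf[["qalys"]], tolerance = 1e-9)
  }
  # undiscounted infinite-horizon geometric limit: QALYs = (u/12) / q
  ps <- toy_chain_ps(0.05, 1, 0, 0)
  tr <- run_cohort("METASTATIC", ps, lt, horizon_months = 2000)
  expect_equal(tr$total_qaly, (1 / 12) / 0.05, tolerance = 1e-9)
})

test_that("entering dead yields zero totals and a degenerate trace", {
  tr <- run_cohort("DEAD", baseline_ps(), baseline_lt())
  expect_equal(tr$total_cost, 0)
  expect_equal(tr$total_qaly, 0)
  expect_identical(nrow(tr$cycles), 1L)  # stops once absorption is complete
})

test_that("occupancy is conserved, nonnegative and absorbed monotonically", {
  lt <- baseline_lt()
  for (seed in 1:5) {
    ps <- random_parameter_set(seed = seed)
    for (opts in list(model_options("specified"),
                      model_options("reconciled"))) {
      for (pw in c("timely", "delayed", "none")) {
        entry <- c(0.4, 0.3, 0.2, 0.1)
        tr <- run_cohort(entry, ps, lt, pathway = pw, horizon_months = 200,
                         opts = opts)
        occ <- as.matrix(tr$cycles[, markov_states])
        expect_true(all(abs(rowSums(occ) - 1) < 1e-10))
        expect_true(all(occ >= -1e-15))
        expect_true(all(diff(occ[, "DEAD"]) >= -1e-12))
      }
    }
  }
})

test_that("stronger discounting never increases the totals", {
  lt <- baseline_lt()
  for (seed in 1:3) {
    ps <- random_parameter_set(seed = seed)
    rates <- c(0, 0.015, 0.05)
    runs <- lapply(rates, function(r) {
      ps$annual_discount <- r
      run_cohort("LOCALIZED", ps, lt, pathway = "timely",
                 horizon_months = 240)
    })
    costs <- vapply(runs, `[[`, numeric(1), "total_cost")
    qalys <- vapply(runs, `[[`, numeric(1), "total_qaly")
    expect_true(all(diff(costs) <= 1e-9))
    expect_true(all(diff(qalys) <= 1e-9))
  }
})

test_that("traces export as per-cycle CSV", {
  tr <- run_cohort("NO_TUMOR", baseline_ps(), baseline_lt(),
                   horizon_months = 24)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace(tr, path)
  back <- read.csv(path)
  expect_identical(nrow(back), 24L)
  expect_true(all(c("cycle", markov_states, "cycle_cost", "cycle_qaly")
                  %in% names(back)))
  expect_equal(sum(back$cycle_cost), tr$total_cost, tolerance = 1e-9)
})
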