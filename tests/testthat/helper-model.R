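# Shared fixtures, all built in code.

baseline_ps <- local({
  ps <- NULL
  function() {
    if (is.null(ps)) ps <<- default_parameter_set()
    ps
  }
})

baseline_lt <- local({
  lt <- NULL
  function() {
    if (is.null(lt)) lt <<- default_life_table(quiet = TRUE)
    lt
  }
})

# Flat-mortality life table: constant annual qx until the cap.
flat_life_table <- function(q = 0, min_age = 0, max_age = 200) {
  ages <- min_age:max_age
  life_table(ages, c(rep(q, length(ages) - 1L), 1))
}

# Embed the two-state alive/dead toy chain in the full engine: start in the
# metastatic state with a chosen constant monthly death probability and no
# other transitions or background mortality.
toy_chain_ps <- function(q_monthly, utility, monthly_cost, discount) {
  q_annual <- 1 - (1 - q_monthly)^12
  parameter_set(
    pretest_malignant = 0.5, start_age_years = 30, wtp = 1e5,
    annual_discount = discount,
    cost_biopsy = 0, cost_timely_treatment = 0, cost_delayed_treatment = 0,
    cost_unnecessary_biopsy = 0, cost_no_action = 0,
    monthly_cost_no_tumor = 0, monthly_cost_localized_y1 = 0,
    monthly_cost_localized_later = 0,
    monthly_cost_metastatic_y1 = monthly_cost,
    monthly_cost_metastatic_later = monthly_cost,
    utility_no_tumor = 1, utility_localized = 1,
    utility_metastatic = utility, utility_dead = 0,
    p_non_r0 = 0, p_local_recurrence = 0, p_metastases_no_tumor = 0,
    p_metastases_localized = 0, p_successful_recurrence_surgery = 0,
    excess_death_metastatic = q_annual, excess_death_localized = 0,
    tests = list(diagnostic_test("T1", 0.9, 0.9, 100)))
}

# Naive all-pairs strict-dominance oracle.
brute_force_dominated <- function(cost, effect) {
  n <- length(cost)
  vapply(seq_len(n), function(i) {
    any(cost <= cost[i] & effect >= effect[i] &
          (cost < cost[i] | effect > effect[i]))
  }, logical(1))
}
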