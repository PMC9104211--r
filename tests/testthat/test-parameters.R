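test_that("baseline parameter set carries the published point estimates", {
  ps <- baseline_ps()
  expect_equal(ps$pretest_malignant, 0.831)
  expect_equal(ps$start_age_years, 62)
  expect_equal(ps$wtp, 100000)
  expect_equal(ps$annual_discount, 0.03)
  expect_equal(ps$tests$CEUS$sensitivity, 0.991)
  expect_equal(ps$tests$CEUS$specificity, 0.805)
  expect_equal(ps$tests$CEUS$exam_cost, 285.00)
  expect_equal(ps$tests$CT$sensitivity, 0.75)
  expect_equal(ps$tests$CT$specificity, 0.72)
  expect_equal(ps$tests$CT$exam_cost, 233.00)
  expect_equal(ps$tests$MRI$sensitivity, 0.90)
  expect_equal(ps$tests$MRI$specificity, 0.96)
  expect_equal(ps$tests$MRI$exam_cost, 381.00)
  expect_equal(ps$cost_timely_treatment, 4231.00)
  expect_equal(ps$cost_delayed_treatment, 6346.50)
  expect_equal(ps$cost_biopsy, 1375.00)
  expect_equal(ps$cost_unnecessary_biopsy, 1375.00)
  expect_equal(ps$cost_no_action, 0)
  expect_equal(ps$monthly_cost_no_tumor, 108.50)
  expect_equal(ps$monthly_cost_localized_y1, 2148.25)
  expect_equal(ps$monthly_cost_localized_later, 212.67)
  expect_equal(ps$monthly_cost_metastatic_y1, 2086.42)
  expect_equal(ps$monthly_cost_metastatic_later, 810.58)
  expect_equal(ps$utility_no_tumor, 1)
  expect_equal(ps$utility_localized, 0.75)
  expect_equal(ps$utility_metastatic, 0.66)
  expect_equal(ps$utility_dead, 0)
  expect_equal(ps$p_non_r0, 0.0573)
  expect_equal(ps$p_local_recurrence, 0.1075)
  expect_equal(ps$p_metastases_no_tumor, 0.01)
  expect_equal(ps$p_metastases_localized, 0.13)
  expect_equal(ps$p_successful_recurrence_surgery, 0.412)
  expect_equal(ps$excess_death_metastatic, 0.35)
  expect_equal(ps$excess_death_localized, 0.035)
  expect_identical(nrow(validate_parameter_set(ps)), 0L)
})

test_that("every published model input maps to a populated field", {
  ps <- baseline_ps()
  # one entry per input row of the published table; age-dependent mortality
  # maps to the life-table module and the 1-year model-time row to the
  # first-year reward regime
  mapped <- list(
    pretest_probability = ps$pretest_malignant,
    age_at_diagnosis = ps$start_age_years,
    willingness_to_pay = ps$wtp,
    discount_rate = ps$annual_discount,
    first_year_regime_cycles = {
      y1 <- state_reward("LOCALIZED", 11, "timely", ps)
      later <- state_reward("LOCALIZED", 12, "timely", ps)
      y1[["cost"]] - later[["cost"]]  # regime switch exists at cycle 12
    },
    sensitivity_ct = ps$tests$CT$sensitivity,
    specificity_ct = ps$tests$CT$specificity,
    sensitivity_mri = ps$tests$MRI$sensitivity,
    specificity_mri = ps$tests$MRI$specificity,
    sensitivity_ceus = ps$tests$CEUS$sensitivity,
    specificity_ceus = ps$tests$CEUS$specificity,
    exam_ct = ps$tests$CT$exam_cost,
    exam_mri = ps$tests$MRI$exam_cost,
    exam_ceus = ps$tests$CEUS$exam_cost,
    biopsy = ps$cost_biopsy,
    in_time_surgery = ps$cost_timely_treatment,
    delayed_surgery = ps$cost_delayed_treatment,
    unnecessary_biopsy = ps$cost_unnecessary_biopsy,
    no_further_action = ps$cost_no_action,
    monthly_no_tumor = ps$monthly_cost_no_tumor,
    monthly_detected_y1 = ps$monthly_cost_localized_y1,
    monthly_detected_later = ps$monthly_cost_localized_later,
    monthly_metastatic_y1 = ps$monthly_cost_metastatic_y1,
    monthly_metastatic_later = ps$monthly_cost_metastatic_later,
    qol_no_tumor = ps$utility_no_tumor,
    qol_metastatic = ps$utility_metastatic,
    qol_detected = ps$utility_localized,
    qol_dead = ps$utility_dead,
    non_r0_resection = ps$p_non_r0,
    local_recurrence = ps$p_local_recurrence,
    metastases_without_tumor = ps$p_metastases_no_tumor,
    metastases_occurrence = ps$p_metastases_localized,
    successful_recurrence_surgery = ps$p_successful_recurrence_surgery,
    excess_death_metastases = ps$excess_death_metastatic,
    excess_death_localized = ps$excess_death_localized,
    age_dependent_death = monthly_background_death_prob(baseline_lt(), 62 * 12))
  expect_true(all(vapply(mapped, function(x)
    is.numeric(x) && length(x) == 1L && is.finite(x), logical(1))))
  expect_gte(length(mapped), 28L)
  # every addressable parameter id resolves
  for (id in parameter_ids(ps))
    expect_true(is.finite(get_parameter(ps, id)))
})

test_that("config serialization round-trips field-for-field", {
  ps <- baseline_ps()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_parameter_set(ps, path)
  ps2 <- load_parameter_set(path)
  for (id in parameter_ids(ps))
    expect_equal(get_parameter(ps2, id), get_parameter(ps, id), info = id)
  expect_equal(names(ps2$tests), names(ps$tests))
  for (id in names(ps$psa_dist)) {
    expect_equal(ps2$psa_dist[[id]]$family, ps$psa_dist[[id]]$family, info = id)
    expect_equal(ps2$psa_dist[[id]]$mean, ps$psa_dist[[id]]$mean, info = id)
    expect_equal(ps2$psa_dist[[id]]$cv, ps$psa_dist[[id]]$cv, info = id)
  }
})

test_that("config loading rejects bad documents with named errors", {
  ok <- "schema_version: '1.0'\nwtp: 100000\n"
  expect_error(load_parameter_set("no/such/config.yaml"), "not found")
  expect_error(load_parameter_set(paste0(ok, "bogus_key: 3\n")),
               "bogus_key")
  # out-of-bound sensitivity is rejected and names the field
  cfg <- withr::local_tempfile(fileext = ".yaml")
  write_parameter_set(baseline_ps(), cfg)
  txt <- sub("sensitivity: 0.991", "sensitivity: 1.2", readLines(cfg))
  writeLines(txt, cfg)
  expect_error(load_parameter_set(cfg), "sensitivity")
  # missing keys: error by default, baseline fallback when allowed
  expect_error(load_parameter_set(ok), "missing config key")
  ps <- load_parameter_set("schema_version: '1.0'\npretest_malignant: 0.5\n",
                           allow_defaults = TRUE)
  expect_equal(ps$wtp, 100000)
  expect_equal(ps$pretest_malignant, 0.5)
  expect_error(load_parameter_set("schema_version: '9.9'\n",
                                  allow_defaults = TRUE), "schema_version")
})

test_that("validation reports violations as data, ordering only as warning", {
  ps <- baseline_ps()
  ps_bad <- ps
  ps_bad$p_metastases_localized <- -0.1
  v <- validate_parameter_set(ps_bad)
  expect_identical(nrow(v), 1L)
  expect_identical(v$field, "p_metastases_localized")
  # unusual utility ordering is not a violation, only a soft warning
  ps_odd <- ps
  ps_odd$utility_localized <- 0.75
  ps_odd$utility_metastatic <- 0.8
  v2 <- validate_parameter_set(ps_odd)
  expect_identical(nrow(v2), 0L)
  expect_match(attr(v2, "warnings"), "ordering")
  ps_dead <- ps
  ps_dead$utility_dead <- 0.1
  expect_identical(validate_parameter_set(ps_dead)$field, "utility_dead")
})

test_that("default PSA distributions follow the published family assignments", {
  ps <- baseline_ps()
  d <- ps$psa_dist
  expect_identical(d$pretest_malignant$family, "beta")
  expect_identical(d$utility_localized$family, "beta")
  expect_identical(d$p_metastases_localized$family, "beta")
  expect_identical(d$cost_timely_treatment$family, "gamma")
  expect_identical(d$monthly_cost_metastatic_y1$family, "gamma")
  expect_identical(d$sensitivity_CEUS$family, "beta")
  expect_identical(d$exam_cost_CT$family, "gamma")
  # structural values are fixed
  for (id in c("wtp", "annual_discount", "start_age_years",
               "utility_no_tumor", "utility_dead", "cost_no_action"))
    expect_identical(d[[id]]$family, "fixed")
  # dispersions stay inside the beta feasibility bound even for means near 1
  for (id in names(d)) {
    if (d[[id]]$family == "beta") {
      m <- d[[id]]$mean
      expect_lt(d[[id]]$cv, sqrt((1 - m) / m))
    }
  }
})

test_that("parameters are addressable by id, with domain-checked updates", {
  ps <- baseline_ps()
  ps2 <- set_parameter(ps, "sensitivity_CEUS", 0.9)
  expect_equal(get_parameter(ps2, "sensitivity_CEUS"), 0.9)
  expect_equal(get_parameter(ps, "sensitivity_CEUS"), 0.991)  # copy semantics
  ps3 <- set_parameter(ps, "cost_biopsy", 99)
  expect_equal(ps3$cost_biopsy, 99)
  expect_error(set_parameter(ps, "sensitivity_CEUS", 1.4), "sensitivity")
  expect_error(set_parameter(ps, "no_such_param", 1), "unknown parameter id")
  expect_error(get_parameter(ps, "sensitivity_PET"), "unknown parameter id")
})
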