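# Synthetic inputs and validation oracles: randomized valid parameter sets,
# a patient-level microsimulation that replays the decision tree and
# transition process by direct draws (no occupancy algebra), and the
# closed-form two-state toy model.

.default_bounds <- list(
  pretest_malignant = c(0.05, 0.95),
  start_age_years = c(50, 75),
  wtp = c(50000, 200000),
  annual_discount = c(0, 0.05),
  cost_biopsy = c(200, 3000),
  cost_timely_treatment = c(1000, 10000),
  cost_delayed_treatment = c(1000, 12000),
  cost_unnecessary_biopsy = c(200, 3000),
  cost_no_action = c(0, 0),
  monthly_cost_no_tumor = c(0, 500),
  monthly_cost_localized_y1 = c(500, 4000),
  monthly_cost_localized_later = c(50, 1000),
  monthly_cost_metastatic_y1 = c(500, 4000),
  monthly_cost_metastatic_later = c(100, 2000),
  utility_no_tumor = c(1, 1),
  utility_localized = c(0.4, 0.95),
  utility_metastatic = c(0.3, 0.9),
  utility_dead = c(0, 0),
  p_non_r0 = c(0, 0.3),
  p_local_recurrence = c(0, 0.4),
  p_metastases_no_tumor = c(0, 0.1),
  p_metastases_localized = c(0, 0.4),
  p_successful_recurrence_surgery = c(0.1, 0.9),
  excess_death_metastatic = c(0, 0.6),
  excess_death_localized = c(0, 0.2),
  sensitivity = c(0.5, 0.99),
  specificity = c(0.5, 0.99),
  exam_cost = c(50, 1500))

#' Draw a random valid parameter set
#'
#' Samples every field uniformly within a bounds profile chosen to respect
#' the type invariants, so the result always passes
#' [validate_parameter_set()] with zero violations. Used to drive
#' property-style tests of the engine.
#'
#' @param seed Optional integer seed (the global RNG state is restored on
#'   exit when given).
#' @param bounds Named list of `c(low, high)` ranges overriding the default
#'   profile; test-profile entries use the keys `sensitivity`,
#'   `specificity`, `exam_cost`.
#' @param n_tests Number of diagnostic strategies to generate.
#' @return A [parameter_set()].
#' @export
random_parameter_set <- function(seed = NULL, bounds = list(), n_tests = 3L) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old_seed <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old_seed, envir = globalenv()),
              add = TRUE)
    }
    set.seed(seed)
  }
  b <- utils::modifyList(.default_bounds, bounds)
  draw <- function(id) stats::runif(1, b[[id]][1], b[[id]][2])
  scalars <- lapply(stats::setNames(names(.ps_scalar_fields),
                                    names(.ps_scalar_fields)), draw)
  scalars$start_age_years <- round(scalars$start_age_years)
  tests <- lapply(seq_len(n_tests), function(i)
    diagnostic_test(paste0("T", i), draw("sensitivity"),
                    draw("specificity"), draw("exam_cost")))
  do.call(parameter_set, c(scalars, list(tests = tests)))
}

#' Patient-level microsimulation oracle
#'
#' Simulates individual patients through the same decision tree and monthly
#' transition process as the cohort engine, but by direct random draws on
#' each patient instead of occupancy-vector propagation. Serves as an
#' independent estimate of a strategy's expected discounted cost and QALYs;
#' the cohort engine should agree within Monte Carlo error.
#'
#' @param ps A [parameter_set()].
#' @param lt A [life_table()].
#' @param test A [diagnostic_test()].
#' @param n_patients Number of simulated patients.
#' @param seed Integer seed (global RNG state restored on exit).
#' @param horizon_months Horizon; defaults to lifetime.
#' @param opts A [model_options()].
#' @return Object of class `microsim_estimate`: `n_patients`, `mean_cost`,
#'   `mean_qalys`, `se_cost`, `se_qalys`.
#' @export
microsim_oracle <- function(ps, lt, test, n_patients, seed = 1L,
                            horizon_months = NULL, opts = model_options()) {
  stopifnot(n_patients >= 1)
  n <- as.integer(n_patients)
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)

  diseased <- stats::runif(n) < ps$pretest_malignant
  pos <- logical(n)
  pos[diseased] <- stats::runif(sum(diseased)) < test$sensitivity
  pos[!diseased] <- stats::runif(sum(!diseased)) < (1 - test$specificity)
  branch <- ifelse(diseased & pos, "TP",
                   ifelse(diseased & !pos, "FN",
                          ifelse(!diseased & !pos, "TN", "FP")))

  entry_costs <- vapply(stats::setNames(.branches, .branches),
                        branch_entry_cost, numeric(1), test = test, ps = ps)
  cost <- unname(entry_costs[branch])
  qaly <- numeric(n)
  entry <- lapply(stats::setNames(.branches, .branches),
                  branch_entry_state, opts = opts)
  state <- integer(n)  # 1 NT, 2 LOC, 3 MET, 4 DEAD
  for (br in .branches)
    state[branch == br] <- match(entry[[br]]$state, markov_states)
  delayed <- branch == "FN" & opts$topology == "reconciled"
  inert <- branch %in% c("TN", "FP") & opts$topology == "reconciled"

  max_age <- attr(lt, "max_age")
  if (is.null(horizon_months))
    horizon_months <- max(1L, ceiling((max_age - ps$start_age_years) * 12))
  horizon_months <- as.integer(horizon_months)
  age_months <- ps$start_age_years * 12 + seq_len(horizon_months) - 1L
  q_bg <- monthly_background_death_prob(lt, age_months)
  disc <- discount_factor(seq_len(horizon_months) - 1L, ps$annual_discount)

  p_std <- .cycle_probs(ps, 0, "timely", opts)  # survival-conditional moves
  reconciled <- opts$topology == "reconciled"
  ex_loc_m <- annual_to_monthly_prob(ps$excess_death_localized)
  ex_met_m <- annual_to_monthly_prob(ps$excess_death_metastatic)

  for (t in seq_len(horizon_months)) {
    first_year <- (t - 1L) < 12
    in_nt <- state == 1L; in_loc <- state == 2L; in_met <- state == 3L
    if (!any(in_nt | in_loc | in_met)) break
    # rewards at cycle start
    c_loc_std <- if (reconciled) ps$monthly_cost_localized_later
                 else if (first_year) ps$monthly_cost_localized_y1
                 else ps$monthly_cost_localized_later
    c_met <- if (first_year) ps$monthly_cost_metastatic_y1
             else ps$monthly_cost_metastatic_later
    if ((t - 1L) < opts$cost_accrual_months) {
      cost[in_nt] <- cost[in_nt] + disc[t] * ps$monthly_cost_no_tumor
      cost[in_loc & !delayed] <- cost[in_loc & !delayed] + disc[t] * c_loc_std
      cost[in_loc & delayed] <- cost[in_loc & delayed] + disc[t] * c_met
      cost[in_met] <- cost[in_met] + disc[t] * c_met
    }
    qaly[in_nt] <- qaly[in_nt] + disc[t] * ps$utility_no_tumor / 12
    qaly[in_loc & !delayed] <- qaly[in_loc & !delayed] +
      disc[t] * ps$utility_localized / 12
    qaly[in_loc & delayed] <- qaly[in_loc & delayed] +
      disc[t] * ps$utility_metastatic / 12
    qaly[in_met] <- qaly[in_met] + disc[t] * ps$utility_metastatic / 12

    # death first (background combined with disease excess), then movement
    d <- numeric(n)
    d[in_nt] <- q_bg[t]
    d[in_loc & !delayed] <- combine_competing_risks(q_bg[t], ex_loc_m)
    d[in_loc & delayed] <- q_bg[t]
    d[in_met] <- combine_competing_risks(q_bg[t], ex_met_m)
    alive <- state != 4L
    dies <- alive & stats::runif(n) < d
    state[dies] <- 4L

    u <- stats::runif(n)
    mv_nt <- state == 1L & !dies & !inert
    state[mv_nt & u < p_std$m_nt_loc] <- 2L
    state[mv_nt & u >= p_std$m_nt_loc &
            u < p_std$m_nt_loc + p_std$m_nt_met] <- 3L
    mv_loc <- state == 2L & !dies & !delayed & !mv_nt
    state[mv_loc & u < p_std$m_loc_nt] <- 1L
    state[mv_loc & u >= p_std$m_loc_nt &
            u < p_std$m_loc_nt + p_std$m_loc_met] <- 3L
  }
  structure(list(n_patients = n,
                 mean_cost = mean(cost),
                 mean_qalys = mean(qaly),
                 se_cost = stats::sd(cost) / sqrt(n),
                 se_qalys = stats::sd(qaly) / sqrt(n)),
            class = "microsim_estimate")
}

#' @export
print.microsim_estimate <- function(x, ...) {
  cat(sprintf(
    "Microsimulation (%d patients): %.2f USD (SE %.2f), %.4f QALYs (SE %.4f)\n",
    x$n_patients, x$mean_cost, x$se_cost, x$mean_qalys, x$se_qalys))
  invisible(x)
}

#' Closed-form two-state (alive/dead) chain
#'
#' Analytic totals for a chain with constant monthly death probability `q`,
#' rewards accrued at cycle start (cycle 0 included) and monthly discounting
#' at the annual rate: a geometric series in `x = (1 - q) / (1 + r)^(1/12)`.
#' Matches the cohort engine embedding of the same chain exactly.
#'
#' @param q_monthly Constant monthly death probability in (0, 1\].
#' @param utility Annual utility weight of the alive state.
#' @param monthly_cost Cost per cycle of the alive state.
#' @param discount Annual discount rate.
#' @param horizon Number of cycles; may be `Inf` when `x < 1`.
#' @return Named vector `c(cost = , qalys = )`.
#' @export
toy_closed_form <- function(q_monthly, utility, monthly_cost, discount,
                            horizon) {
  stopifnot(q_monthly > 0, q_monthly <= 1, discount >= 0)
  x <- (1 - q_monthly) * (1 + discount)^(-1 / 12)
  s <- if (is.infinite(horizon)) {
    if (x >= 1) stop("infinite horizon needs x < 1", call. = FALSE)
    1 / (1 - x)
  } else if (x == 1) {
    horizon
  } else {
    (1 - x^horizon) / (1 - x)
  }
  c(cost = monthly_cost * s, qalys = utility / 12 * s)
}

#' Write the shipped fixtures
#'
#' Produces the baseline configuration (`baseline_params.yaml`) and the
#' synthetic Gompertz life table (`synthetic_life_table.csv`) into a
#' directory, exactly as shipped under `inst/extdata/`.
#'
#' @param dir Target directory (created if absent).
#' @return Character vector of the written paths, invisibly.
#' @export
write_fixtures <- function(dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- file.path(dir, "baseline_params.yaml")
  write_parameter_set(default_parameter_set(), cfg)
  lt <- default_life_table(quiet = TRUE)
  csv <- file.path(dir, "synthetic_life_table.csv")
  utils::write.csv(data.frame(age = lt$age, qx = signif(lt$qx, 8)), csv,
                   row.names = FALSE)
  invisible(c(cfg, csv))
}
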