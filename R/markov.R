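# Four-state monthly-cycle Markov cohort engine.
#
# States: alive with no renal malignancy, alive with localized renal
# malignancy, alive with metastatic renal malignancy, dead (absorbing).
# Rewards (costs in USD/cycle, utilities accrued pro rata at 1/12 of the
# annual QALY weight) are earned at cycle start and discounted at the annual
# rate; background mortality is read from a life table at the attained age
# each cycle and combined with disease-specific excess risks as competing
# hazards.

#' Health-state labels of the cohort model
#' @export
markov_states <- c("NO_TUMOR", "LOCALIZED", "METASTATIC", "DEAD")

#' Model topology options
#'
#' Two wirings of the decision-tree-to-Markov hand-off are provided:
#'
#' * `"specified"` (default): the documented baseline topology. True
#'   positives enter the localized state on the timely-treatment pathway and
#'   can be cured into the no-tumor state; false negatives enter the
#'   metastatic state (delayed-treatment costs and utility equal the
#'   metastatic-state rows); costs and QALYs both accrue over the lifetime
#'   horizon.
#' * `"reconciled"`: a calibration variant reverse-engineered from the
#'   published strategy totals (see the methods vignette). Timely treatment
#'   returns the patient to the no-tumor state on a post-resection
#'   trajectory that keeps the recurrence dynamics; true negatives and
#'   false positives are plain background survivors (local recurrence is a
#'   post-resection phenomenon and does not apply to them); the
#'   false-negative pathway is an absorbing delayed-treatment trajectory
#'   carrying the metastatic cost rows and utility with background-only
#'   mortality; monthly costs accrue during the one-year Markov window
#'   only, while QALYs accrue over the lifetime horizon.
#'
#' @param topology `"specified"` or `"reconciled"`.
#' @param cost_accrual_months Number of cycles during which monthly state
#'   costs accrue; `Inf` for the whole horizon. Defaults to `Inf` for the
#'   specified topology and 12 for the reconciled one.
#' @return An object of class `model_options`.
#' @export
model_options <- function(topology = c("specified", "reconciled"),
                          cost_accrual_months = NULL) {
  topology <- match.arg(topology)
  if (is.null(cost_accrual_months))
    cost_accrual_months <- if (topology == "reconciled") 12 else Inf
  structure(list(topology = topology,
                 cost_accrual_months = cost_accrual_months),
            class = "model_options")
}

#' Convert an annual to a monthly probability
#'
#' Assumes a constant hazard within the year: `1 - (1 - p)^(1/12)`, so that
#' compounding the monthly probability over 12 cycles recovers the annual
#' one.
#'
#' @param p_annual Annual probability in \[0, 1\].
#' @return Monthly probability.
#' @export
annual_to_monthly_prob <- function(p_annual) {
  if (any(!is.finite(p_annual) | p_annual < 0 | p_annual > 1))
    stop("annual probability out of [0, 1]", call. = FALSE)
  1 - (1 - p_annual)^(1 / 12)
}

#' Combine two competing risks of the same period
#'
#' Independent competing risks acting within one cycle combine as
#' `1 - (1 - p1) * (1 - p2)`; used to merge background mortality with a
#' disease-specific excess death probability.
#'
#' @param p1,p2 Probabilities in \[0, 1\].
#' @return Combined probability.
#' @export
combine_competing_risks <- function(p1, p2) {
  if (any(!is.finite(p1) | p1 < 0 | p1 > 1) ||
      any(!is.finite(p2) | p2 < 0 | p2 > 1))
    stop("probabilities out of [0, 1]", call. = FALSE)
  1 - (1 - p1) * (1 - p2)
}

#' Discount factor for a monthly cycle index
#'
#' `(1 + annual_rate)^(-cycle_index / 12)`; cycle 0 (the model start) is
#' undiscounted.
#'
#' @param cycle_index Cycle index in months (>= 0).
#' @param annual_rate Annual discount rate (>= 0).
#' @return Discount factor in (0, 1\].
#' @export
discount_factor <- function(cycle_index, annual_rate) {
  if (any(annual_rate < 0)) stop("discount rate must be >= 0", call. = FALSE)
  (1 + annual_rate)^(-cycle_index / 12)
}

# Monthly transition probabilities shared by the matrix builder, the cohort
# engine and the microsimulation. Vectorized over q_bg (one entry per cycle).
# Returns conditional-on-survival movement probabilities plus per-state death
# probabilities; the "delayed" pathway under the reconciled topology locks
# the localized slot into the delayed-treatment trajectory (no exits,
# background-only mortality).
.cycle_probs <- function(ps, q_bg, pathway, opts) {
  m_nt_loc <- annual_to_monthly_prob(ps$p_local_recurrence)
  m_nt_met <- annual_to_monthly_prob(ps$p_metastases_no_tumor)
  m_loc_met <- annual_to_monthly_prob(ps$p_metastases_localized)
  cure_episode <- (1 - ps$p_non_r0) * ps$p_successful_recurrence_surgery
  m_loc_nt <- annual_to_monthly_prob(cure_episode)
  d_nt <- q_bg
  d_loc <- combine_competing_risks(q_bg,
                                   annual_to_monthly_prob(ps$excess_death_localized))
  d_met <- combine_competing_risks(q_bg,
                                   annual_to_monthly_prob(ps$excess_death_metastatic))
  if (opts$topology == "reconciled" && identical(pathway, "delayed")) {
    m_loc_nt <- 0
    m_loc_met <- 0
    d_loc <- q_bg
  }
  if (opts$topology == "reconciled" && identical(pathway, "none")) {
    # disease-free branches: recurrence is a post-resection phenomenon and
    # does not apply to patients who never had a malignancy
    m_nt_loc <- 0
    m_nt_met <- 0
  }
  if (m_nt_loc + m_nt_met > 1 + 1e-12)
    stop("no-tumor row fails to normalize: exit probabilities exceed 1",
         call. = FALSE)
  if (m_loc_nt + m_loc_met > 1 + 1e-12)
    stop("localized row fails to normalize: exit probabilities exceed 1",
         call. = FALSE)
  list(m_nt_loc = m_nt_loc, m_nt_met = m_nt_met,
       m_loc_nt = m_loc_nt, m_loc_met = m_loc_met,
       d_nt = d_nt, d_loc = d_loc, d_met = d_met)
}

#' Build the one-cycle transition matrix
#'
#' Rows and columns follow [markov_states]. State changes are conditioned on
#' surviving the cycle (death is resolved first), which keeps every row
#' stochastic for any valid inputs, including the forced death at the
#' life-table cap. The dead row is the identity row.
#'
#' @param ps A [parameter_set()].
#' @param lt A [life_table()].
#' @param age_months Attained age in months at the start of the cycle.
#' @param pathway One of `"timely"`, `"delayed"`, `"none"` (only relevant
#'   under the reconciled topology).
#' @param opts A [model_options()].
#' @return A 4x4 row-stochastic matrix.
#' @export
build_transition_matrix <- function(ps, lt, age_months,
                                    pathway = "timely",
                                    opts = model_options()) {
  q_bg <- monthly_background_death_prob(lt, age_months)
  p <- .cycle_probs(ps, q_bg, pathway, opts)
  M <- matrix(0, 4, 4, dimnames = list(markov_states, markov_states))
  M["NO_TUMOR", "LOCALIZED"] <- (1 - p$d_nt) * p$m_nt_loc
  M["NO_TUMOR", "METASTATIC"] <- (1 - p$d_nt) * p$m_nt_met
  M["NO_TUMOR", "DEAD"] <- p$d_nt
  M["NO_TUMOR", "NO_TUMOR"] <- (1 - p$d_nt) * (1 - p$m_nt_loc - p$m_nt_met)
  M["LOCALIZED", "NO_TUMOR"] <- (1 - p$d_loc) * p$m_loc_nt
  M["LOCALIZED", "METASTATIC"] <- (1 - p$d_loc) * p$m_loc_met
  M["LOCALIZED", "DEAD"] <- p$d_loc
  M["LOCALIZED", "LOCALIZED"] <- (1 - p$d_loc) * (1 - p$m_loc_nt - p$m_loc_met)
  M["METASTATIC", "DEAD"] <- p$d_met
  M["METASTATIC", "METASTATIC"] <- 1 - p$d_met
  M["DEAD", "DEAD"] <- 1
  rs <- rowSums(M)
  if (any(abs(rs - 1) > 1e-12) || any(M < -1e-15))
    stop("transition matrix row fails to normalize", call. = FALSE)
  M
}

#' Per-cycle state rewards before discounting
#'
#' Monthly cost (USD) and QALY accrual (annual utility weight / 12) for one
#' state at one cycle. Localized and metastatic costs switch from the
#' first-year to the later-years rate at cycle 12. Under the reconciled
#' topology the localized slot on the delayed pathway carries the metastatic
#' cost rows and utility, and recurrent localized disease on the other
#' pathways is charged at the later-years detected-tumor rate.
#'
#' @param state One of [markov_states].
#' @param cycle_index Cycle index in months (>= 0).
#' @param pathway `"timely"`, `"delayed"` or `"none"`.
#' @param ps A [parameter_set()].
#' @param opts A [model_options()].
#' @return Named numeric vector `c(cost = , qaly = )`.
#' @export
state_reward <- function(state, cycle_index, pathway = "timely", ps,
                         opts = model_options()) {
  state <- match.arg(state, markov_states)
  stopifnot(cycle_index >= 0)
  first_year <- cycle_index < 12
  reconciled <- opts$topology == "reconciled"
  out <- switch(state,
    NO_TUMOR = c(cost = ps$monthly_cost_no_tumor,
                 qaly = ps$utility_no_tumor / 12),
    LOCALIZED = {
      if (reconciled && identical(pathway, "delayed")) {
        c(cost = if (first_year) ps$monthly_cost_metastatic_y1
                 else ps$monthly_cost_metastatic_later,
          qaly = ps$utility_metastatic / 12)
      } else if (reconciled) {
        c(cost = ps$monthly_cost_localized_later,
          qaly = ps$utility_localized / 12)
      } else {
        c(cost = if (first_year) ps$monthly_cost_localized_y1
                 else ps$monthly_cost_localized_later,
          qaly = ps$utility_localized / 12)
      }
    },
    METASTATIC = c(cost = if (first_year) ps$monthly_cost_metastatic_y1
                          else ps$monthly_cost_metastatic_later,
                   qaly = ps$utility_metastatic / 12),
    DEAD = c(cost = 0, qaly = 0))
  out
}

# Per-cycle reward matrices for the whole horizon (H x 4 costs, 4 utilities).
.reward_profile <- function(ps, horizon, pathway, opts) {
  cyc <- seq_len(horizon) - 1L
  first_year <- cyc < 12
  costs <- matrix(0, horizon, 4, dimnames = list(NULL, markov_states))
  utils <- c(NO_TUMOR = ps$utility_no_tumor,
             LOCALIZED = ps$utility_localized,
             METASTATIC = ps$utility_metastatic,
             DEAD = 0)
  costs[, "NO_TUMOR"] <- ps$monthly_cost_no_tumor
  reconciled <- opts$topology == "reconciled"
  if (reconciled && identical(pathway, "delayed")) {
    costs[, "LOCALIZED"] <- ifelse(first_year, ps$monthly_cost_metastatic_y1,
                                   ps$monthly_cost_metastatic_later)
    utils["LOCALIZED"] <- ps$utility_metastatic
  } else if (reconciled) {
    costs[, "LOCALIZED"] <- ps$monthly_cost_localized_later
  } else {
    costs[, "LOCALIZED"] <- ifelse(first_year, ps$monthly_cost_localized_y1,
                                   ps$monthly_cost_localized_later)
  }
  costs[, "METASTATIC"] <- ifelse(first_year, ps$monthly_cost_metastatic_y1,
                                  ps$monthly_cost_metastatic_later)
  # cost-accrual window (costs only; QALYs always run the full horizon)
  costs[cyc >= opts$cost_accrual_months, ] <- 0
  list(costs = costs, utils = utils)
}

#' Run the Markov cohort model
#'
#' Propagates a cohort's state-occupancy distribution cycle by cycle,
#' accruing discounted costs and QALYs at cycle start (no half-cycle
#' correction; cycle 0 is discounted by 1). Background mortality is re-read
#' from the life table at the attained integer age every cycle. The run stops
#' at the horizon or as soon as the dead-state occupancy exceeds
#' `1 - 1e-9`.
#'
#' @param entry Entry state name (one of [markov_states]) or a 4-vector of
#'   occupancy probabilities summing to 1.
#' @param ps A [parameter_set()].
#' @param lt A [life_table()].
#' @param pathway `"timely"`, `"delayed"` or `"none"`.
#' @param horizon_months Number of monthly cycles; defaults to the lifetime
#'   horizon `(max_age - start_age) * 12`.
#' @param start_age_years Cohort age at cycle 0.
#' @param opts A [model_options()].
#' @return An object of class `markov_trace`: list with `cycles` (data frame
#'   of per-cycle occupancy and discounted accruals), `total_cost` and
#'   `total_qaly`.
#' @export
run_cohort <- function(entry, ps, lt, pathway = "none",
                       horizon_months = NULL,
                       start_age_years = ps$start_age_years,
                       opts = model_options()) {
  if (is.character(entry)) {
    entry <- match.arg(entry, markov_states)
    occ <- stats::setNames(as.numeric(markov_states == entry), markov_states)
  } else {
    occ <- stats::setNames(as.numeric(entry), markov_states)
    if (abs(sum(occ) - 1) > 1e-9 || any(occ < 0))
      stop("entry distribution must be nonnegative and sum to 1",
           call. = FALSE)
  }
  max_age <- attr(lt, "max_age")
  if (is.null(horizon_months))
    horizon_months <- max(1L, ceiling((max_age - start_age_years) * 12))
  horizon_months <- as.integer(horizon_months)
  if (horizon_months < 1L) stop("horizon must be >= 1 cycle", call. = FALSE)

  age_months <- start_age_years * 12 + seq_len(horizon_months) - 1L
  q_bg <- monthly_background_death_prob(lt, age_months)
  p <- .cycle_probs(ps, q_bg, pathway, opts)
  rw <- .reward_profile(ps, horizon_months, pathway, opts)
  disc <- discount_factor(seq_len(horizon_months) - 1L, ps$annual_discount)

  occ_mat <- matrix(NA_real_, horizon_months, 4,
                    dimnames = list(NULL, markov_states))
  cycle_cost <- numeric(horizon_months)
  cycle_qaly <- numeric(horizon_months)
  nt <- occ[["NO_TUMOR"]]; loc <- occ[["LOCALIZED"]]
  met <- occ[["METASTATIC"]]; dead <- occ[["DEAD"]]
  n_used <- horizon_months
  for (t in seq_len(horizon_months)) {
    occ_mat[t, ] <- c(nt, loc, met, dead)
    cycle_cost[t] <- disc[t] * (nt * rw$costs[t, 1L] + loc * rw$costs[t, 2L] +
                                  met * rw$costs[t, 3L])
    cycle_qaly[t] <- disc[t] / 12 * (nt * rw$utils[[1L]] +
                                       loc * rw$utils[[2L]] +
                                       met * rw$utils[[3L]])
    if (dead > 1 - 1e-9) { n_used <- t; break }
    s_nt <- 1 - p$d_nt[t]; s_loc <- 1 - p$d_loc[t]; s_met <- 1 - p$d_met[t]
    nt2 <- nt * s_nt * (1 - p$m_nt_loc - p$m_nt_met) + loc * s_loc * p$m_loc_nt
    loc2 <- nt * s_nt * p$m_nt_loc + loc * s_loc * (1 - p$m_loc_nt - p$m_loc_met)
    met2 <- nt * s_nt * p$m_nt_met + loc * s_loc * p$m_loc_met + met * s_met
    dead2 <- dead + nt * p$d_nt[t] + loc * p$d_loc[t] + met * p$d_met[t]
    nt <- nt2; loc <- loc2; met <- met2; dead <- dead2
  }
  keep <- seq_len(n_used)
  trace <- data.frame(cycle = keep - 1L, occ_mat[keep, , drop = FALSE],
                      cycle_cost = cycle_cost[keep],
                      cycle_qaly = cycle_qaly[keep])
  structure(list(cycles = trace,
                 total_cost = sum(cycle_cost[keep]),
                 total_qaly = sum(cycle_qaly[keep]),
                 pathway = pathway,
                 start_age_years = start_age_years,
                 horizon_months = horizon_months),
            class = "markov_trace")
}

#' @export
print.markov_trace <- function(x, ...) {
  cat(sprintf(
    "Markov trace: %d cycles from age %g (pathway %s)\n",
    nrow(x$cycles), x$start_age_years, x$pathway))
  cat(sprintf("  discounted totals: %.2f USD, %.4f QALYs\n",
              x$total_cost, x$total_qaly))
  invisible(x)
}

#' Export a cohort trace as per-cycle CSV
#'
#' Columns: cycle, the four state occupancies, discounted cycle cost and
#' discounted cycle QALYs.
#'
#' @param trace A `markov_trace` from [run_cohort()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(trace$cycles, path, row.names = FALSE)
  invisible(path)
}
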