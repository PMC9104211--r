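# Deterministic (one-way / tornado) and probabilistic sensitivity analysis.
#
# The PSA draws every non-fixed parameter independently from its assigned
# beta/gamma distribution (method-of-moments conversion from mean and
# coefficient of variation) and re-evaluates all strategies per iteration.
# The per-iteration Markov stages are propagated vectorized across
# iterations, which is exact: iterations are independent and the cohort
# recursion is elementwise in the iteration dimension.

#' Draw from a parameter's assigned distribution
#'
#' `beta` and `gamma` draws use method-of-moments parameters derived from
#' the requested mean and coefficient of variation; `fixed` returns the
#' mean. A beta distribution whose dispersion is infeasible for its mean
#' (requires
#' `cv^2 < (1 - mean) / mean`) raises an error naming the parameter.
#'
#' @param spec A [dist_spec()].
#' @param n Number of draws.
#' @param name Parameter id used in error messages.
#' @return Numeric vector of length `n`; uses the global RNG stream.
#' @export
sample_parameter <- function(spec, n = 1L, name = "parameter") {
  stopifnot(inherits(spec, "dist_spec"))
  switch(spec$family,
    fixed = rep(spec$mean, n),
    beta = {
      m <- spec$mean
      v <- (spec$cv * m)^2
      if (v >= m * (1 - m))
        stop("infeasible beta moment match for '", name,
             "': cv ", spec$cv, " too large for mean ", m, call. = FALSE)
      shape1 <- m * (m * (1 - m) / v - 1)
      shape2 <- (1 - m) * (m * (1 - m) / v - 1)
      stats::rbeta(n, shape1, shape2)
    },
    gamma = {
      shape <- 1 / spec$cv^2
      stats::rgamma(n, shape = shape, scale = spec$mean * spec$cv^2)
    })
}

# All costs plus every test sensitivity/specificity, swept +/- frac around
# base, probabilities clipped to [0, 1].
#' Default one-way sensitivity ranges
#'
#' @param ps A [parameter_set()].
#' @param frac Relative half-width of the range around the base value.
#' @return Data frame with columns `parameter`, `low`, `high`.
#' @export
default_dsa_ranges <- function(ps, frac = 0.2) {
  cost_ids <- c(grep("^(cost_|monthly_cost_)", names(.ps_scalar_fields),
                     value = TRUE),
                paste0("exam_cost_", names(ps$tests)))
  prob_ids <- c(paste0("sensitivity_", names(ps$tests)),
                paste0("specificity_", names(ps$tests)))
  ids <- c(prob_ids, cost_ids)
  base <- vapply(ids, get_parameter, numeric(1), ps = ps)
  low <- base * (1 - frac)
  high <- base * (1 + frac)
  is_prob <- ids %in% prob_ids
  low[is_prob] <- pmax(0, low[is_prob])
  high[is_prob] <- pmin(1, high[is_prob])
  data.frame(parameter = ids, low = low, high = high,
             row.names = NULL, stringsAsFactors = FALSE)
}

.dsa_outcome <- function(ps, lt, metric, reference, wtp, horizon_months, opts) {
  results <- evaluate_strategies(ps, lt, horizon_months = horizon_months,
                                 opts = opts)
  if (!(reference %in% names(results)))
    stop("reference strategy '", reference, "' not among the tests",
         call. = FALSE)
  nmb <- vapply(results, net_monetary_benefit, numeric(1), wtp = wtp)
  others <- setdiff(names(results), reference)
  if (length(others) == 0L)
    stop("need at least one comparator strategy", call. = FALSE)
  if (metric == "nmb_diff") {
    nmb[[reference]] - max(nmb[others])
  } else {
    best <- others[which.max(nmb[others])]
    icer(results[[reference]], results[[best]])$value
  }
}

#' One-way deterministic sensitivity analysis of a single parameter
#'
#' Re-runs the full base-case pipeline with the parameter pinned at its low
#' and at its high value and records the outcome metric at both ends. The
#' default metric is the net-monetary-benefit margin of the reference
#' strategy over its best alternative at the willingness-to-pay; `"icer"`
#' reports instead the ICER of the reference versus its highest-NMB
#' alternative (the tornado-diagram convention).
#'
#' @param ps A [parameter_set()].
#' @param lt A [life_table()].
#' @param parameter_id Parameter id (see [parameter_ids()]).
#' @param low,high Range endpoints on the parameter's natural scale
#'   (`low <= high`; values must respect the parameter's domain).
#' @param metric `"nmb_diff"` or `"icer"`.
#' @param reference Reference strategy name.
#' @param wtp Willingness-to-pay in USD/QALY.
#' @param horizon_months Markov horizon (default lifetime).
#' @param opts A [model_options()].
#' @return One-row data frame: `parameter`, `low`, `high`, `outcome_at_low`,
#'   `outcome_at_high`, `span`.
#' @export
one_way_dsa <- function(ps, lt, parameter_id, low, high,
                        metric = c("nmb_diff", "icer"),
                        reference = "CEUS", wtp = ps$wtp,
                        horizon_months = NULL, opts = model_options()) {
  metric <- match.arg(metric)
  if (low > high) stop("low must be <= high", call. = FALSE)
  out <- vapply(c(low, high), function(v) {
    ps_v <- set_parameter(ps, parameter_id, v)
    .dsa_outcome(ps_v, lt, metric, reference, wtp, horizon_months, opts)
  }, numeric(1))
  data.frame(parameter = parameter_id, low = low, high = high,
             outcome_at_low = out[1], outcome_at_high = out[2],
             span = abs(out[2] - out[1]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Tornado analysis over a set of parameter ranges
#'
#' Runs [one_way_dsa()] for every row of `range_spec` and returns the
#' entries sorted by descending outcome span.
#'
#' @inheritParams one_way_dsa
#' @param range_spec Data frame with columns `parameter`, `low`, `high`;
#'   defaults to [default_dsa_ranges()]. Duplicated parameters are an error.
#' @return Data frame of tornado entries sorted by descending `span`.
#' @export
tornado <- function(ps, lt, range_spec = default_dsa_ranges(ps),
                    metric = c("nmb_diff", "icer"), reference = "CEUS",
                    wtp = ps$wtp, horizon_months = NULL,
                    opts = model_options()) {
  metric <- match.arg(metric)
  stopifnot(is.data.frame(range_spec),
            all(c("parameter", "low", "high") %in% names(range_spec)))
  if (anyDuplicated(range_spec$parameter))
    stop("duplicated parameter in range_spec: ",
         paste(unique(range_spec$parameter[duplicated(range_spec$parameter)]),
               collapse = ", "), call. = FALSE)
  if (nrow(range_spec) == 0L)
    return(data.frame(parameter = character(), low = numeric(),
                      high = numeric(), outcome_at_low = numeric(),
                      outcome_at_high = numeric(), span = numeric(),
                      stringsAsFactors = FALSE))
  rows <- lapply(seq_len(nrow(range_spec)), function(i)
    one_way_dsa(ps, lt, range_spec$parameter[i], range_spec$low[i],
                range_spec$high[i], metric = metric, reference = reference,
                wtp = wtp, horizon_months = horizon_months, opts = opts))
  out <- do.call(rbind, rows)
  out <- out[order(-out$span), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# ---- probabilistic sensitivity analysis ------------------------------------

# Vectorized-across-iterations cohort propagation. par holds length-n (or
# scalar) vectors of per-iteration monthly transition probabilities, costs
# and utilities; q_bg and disc are per-cycle scalars shared by iterations.
.psa_cohort <- function(entry_state, pathway, par, q_bg, disc, opts, horizon) {
  n <- length(par$u_loc)
  nt <- rep(as.numeric(entry_state == "NO_TUMOR"), n)
  loc <- rep(as.numeric(entry_state == "LOCALIZED"), n)
  met <- rep(as.numeric(entry_state == "METASTATIC"), n)
  cost <- numeric(n); qaly <- numeric(n)
  reconciled <- opts$topology == "reconciled"
  delayed <- reconciled && identical(pathway, "delayed")
  inert <- reconciled && identical(pathway, "none")
  m_nt_loc <- if (inert) 0 else par$m_nt_loc
  m_nt_met <- if (inert) 0 else par$m_nt_met
  m_loc_nt <- if (delayed) 0 else par$m_loc_nt
  m_loc_met <- if (delayed) 0 else par$m_loc_met
  ex_loc <- if (delayed) 0 else par$ex_loc_m
  u_loc <- if (delayed) par$u_met else par$u_loc
  acc <- opts$cost_accrual_months
  for (t in seq_len(horizon)) {
    first_year <- (t - 1L) < 12
    if ((t - 1L) < acc) {
      c_loc <- if (delayed) {
        if (first_year) par$c_met_y1 else par$c_met_later
      } else if (reconciled) {
        par$c_loc_later
      } else {
        if (first_year) par$c_loc_y1 else par$c_loc_later
      }
      c_met <- if (first_year) par$c_met_y1 else par$c_met_later
      cost <- cost + disc[t] * (nt * par$c_nt + loc * c_loc + met * c_met)
    }
    qaly <- qaly + disc[t] / 12 * (nt * par$u_nt + loc * u_loc + met * par$u_met)
    s_nt <- 1 - q_bg[t]
    s_loc <- (1 - q_bg[t]) * (1 - ex_loc)
    s_met <- (1 - q_bg[t]) * (1 - par$ex_met_m)
    nt2 <- nt * s_nt * (1 - m_nt_loc - m_nt_met) + loc * s_loc * m_loc_nt
    loc2 <- nt * s_nt * m_nt_loc + loc * s_loc * (1 - m_loc_nt - m_loc_met)
    met2 <- nt * s_nt * m_nt_met + loc * s_loc * m_loc_met + met * s_met
    nt <- nt2; loc <- loc2; met <- met2
  }
  list(cost = cost, qaly = qaly)
}

#' Probabilistic sensitivity analysis
#'
#' Per iteration, draws every parameter with a non-fixed distribution from
#' `ps$psa_dist`, re-evaluates all strategies (branch probabilities, entry
#' costs and Markov stages) and records the (cost, effect) pair of each
#' strategy. All draws come from one seeded RNG stream in a fixed parameter
#' order, so results are bit-identical for identical seeds.
#'
#' @param ps A [parameter_set()].
#' @param lt A [life_table()] (background mortality is not sampled).
#' @param n_iterations Number of Monte Carlo repetitions.
#' @param seed Integer seed.
#' @param wtp_grid Willingness-to-pay grid for the acceptability curves.
#' @param horizon_months Markov horizon (default lifetime).
#' @param opts A [model_options()].
#' @return Object of class `psa_result`: `n_iterations`, `seed`,
#'   `strategies`, `cost` and `effect` (iteration x strategy matrices), and
#'   `ceac` (acceptability fractions over `wtp_grid`).
#' @export
run_psa <- function(ps, lt, n_iterations = 30000L, seed = 1L,
                    wtp_grid = seq(0, 200000, by = 10000),
                    horizon_months = NULL, opts = model_options()) {
  stopifnot(n_iterations >= 1)
  n <- as.integer(n_iterations)
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)

  ids <- parameter_ids(ps)
  draws <- list()
  for (id in ids) {
    spec <- ps$psa_dist[[id]]
    draws[[id]] <- if (is.null(spec)) {
      rep(get_parameter(ps, id), n)
    } else {
      sample_parameter(spec, n, name = id)
    }
  }

  max_age <- attr(lt, "max_age")
  if (is.null(horizon_months))
    horizon_months <- max(1L, ceiling((max_age - ps$start_age_years) * 12))
  horizon_months <- as.integer(horizon_months)
  age_months <- ps$start_age_years * 12 + seq_len(horizon_months) - 1L
  q_bg <- monthly_background_death_prob(lt, age_months)
  disc <- discount_factor(seq_len(horizon_months) - 1L, ps$annual_discount)

  a2m <- function(p) 1 - (1 - p)^(1 / 12)
  par <- list(
    m_nt_loc = a2m(draws$p_local_recurrence),
    m_nt_met = a2m(draws$p_metastases_no_tumor),
    m_loc_met = a2m(draws$p_metastases_localized),
    m_loc_nt = a2m((1 - draws$p_non_r0) *
                     draws$p_successful_recurrence_surgery),
    ex_loc_m = a2m(draws$excess_death_localized),
    ex_met_m = a2m(draws$excess_death_metastatic),
    c_nt = draws$monthly_cost_no_tumor,
    c_loc_y1 = draws$monthly_cost_localized_y1,
    c_loc_later = draws$monthly_cost_localized_later,
    c_met_y1 = draws$monthly_cost_metastatic_y1,
    c_met_later = draws$monthly_cost_metastatic_later,
    u_nt = draws$utility_no_tumor,
    u_loc = draws$utility_localized,
    u_met = draws$utility_metastatic)

  entries <- lapply(stats::setNames(.branches, .branches),
                    branch_entry_state, opts = opts)
  chains <- list()
  for (entry in entries) {
    key <- paste(entry$state, entry$pathway)
    if (is.null(chains[[key]]))
      chains[[key]] <- .psa_cohort(entry$state, entry$pathway, par, q_bg,
                                   disc, opts, horizon_months)
  }

  strategies <- names(ps$tests)
  cost <- matrix(NA_real_, n, length(strategies),
                 dimnames = list(NULL, strategies))
  effect <- cost
  prev <- draws$pretest_malignant
  entry_cost_extra <- list(TP = draws$cost_timely_treatment,
                           FN = draws$cost_delayed_treatment,
                           TN = draws$cost_no_action,
                           FP = draws$cost_unnecessary_biopsy)
  for (s in strategies) {
    se <- draws[[paste0("sensitivity_", s)]]
    sp <- draws[[paste0("specificity_", s)]]
    exam <- draws[[paste0("exam_cost_", s)]]
    bp <- list(TP = prev * se, FN = prev * (1 - se),
               TN = (1 - prev) * sp, FP = (1 - prev) * (1 - sp))
    cs <- numeric(n); es <- numeric(n)
    for (branch in .branches) {
      ch <- chains[[paste(entries[[branch]]$state,
                          entries[[branch]]$pathway)]]
      cs <- cs + bp[[branch]] * (exam + entry_cost_extra[[branch]] + ch$cost)
      es <- es + bp[[branch]] * ch$qaly
    }
    cost[, s] <- cs
    effect[, s] <- es
  }

  res <- structure(list(n_iterations = n, seed = seed,
                        strategies = strategies, cost = cost,
                        effect = effect, wtp_grid = wtp_grid),
                   class = "psa_result")
  res$ceac <- ceac(res, wtp_grid)
  res
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("PSA: %d iterations (seed %s), strategies %s\n",
              x$n_iterations, x$seed, paste(x$strategies, collapse = ", ")))
  cat("  mean cost / effect:\n")
  for (s in x$strategies)
    cat(sprintf("    %-6s %12.2f USD  %8.4f QALYs\n", s,
                mean(x$cost[, s]), mean(x$effect[, s])))
  invisible(x)
}

#' Cost-effectiveness acceptability curves
#'
#' For each willingness-to-pay value, the fraction of PSA iterations in
#' which each strategy attains the maximal net monetary benefit. NMB ties
#' within an iteration are resolved in favour of the cheaper strategy; exact
#' ties on both NMB and cost split the iteration equally, so the fractions
#' sum to 1 at every grid point.
#'
#' @param psa A `psa_result` from [run_psa()].
#' @param wtp_grid Non-empty numeric vector of WTP thresholds (USD/QALY).
#' @return Data frame with columns `wtp`, `strategy`, `acceptance`.
#' @export
ceac <- function(psa, wtp_grid) {
  stopifnot(inherits(psa, "psa_result"), length(wtp_grid) >= 1)
  S <- length(psa$strategies)
  out <- vector("list", length(wtp_grid))
  for (k in seq_along(wtp_grid)) {
    wtp <- wtp_grid[k]
    nmb <- wtp * psa$effect - psa$cost
    best <- nmb[, 1L]
    for (j in seq_len(S)[-1L]) best <- pmax(best, nmb[, j])
    is_best <- nmb == best
    cost_best <- psa$cost
    cost_best[!is_best] <- Inf
    cheapest <- cost_best[, 1L]
    for (j in seq_len(S)[-1L]) cheapest <- pmin(cheapest, cost_best[, j])
    win <- is_best & (psa$cost == cheapest)
    ties <- rowSums(win)
    frac <- colSums(win / ties) / psa$n_iterations
    out[[k]] <- data.frame(wtp = wtp, strategy = psa$strategies,
                           acceptance = as.numeric(frac),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
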