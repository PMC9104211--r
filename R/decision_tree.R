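# Diagnostic decision tree: each strategy splits the cohort into the four
# initial branches (true/false positive/negative), each with an entry cost,
# an entry health state and a treatment pathway for the Markov stage.

.branches <- c("TP", "FN", "TN", "FP")

#' Branch probabilities of a diagnostic strategy
#'
#' Splits a cohort with the given disease prevalence by the test's
#' sensitivity and specificity: `TP = prev * Se`, `FN = prev * (1 - Se)`,
#' `TN = (1 - prev) * Sp`, `FP = (1 - prev) * (1 - Sp)`.
#'
#' @param prevalence Pre-test probability of malignancy in \[0, 1\].
#' @param test A [diagnostic_test()].
#' @return Named numeric vector over `TP, FN, TN, FP`, summing to 1.
#' @examples
#' branch_probabilities(0.831, diagnostic_test("CEUS", 0.991, 0.805, 285))
#' @export
branch_probabilities <- function(prevalence, test) {
  if (!is.finite(prevalence) || prevalence < 0 || prevalence > 1)
    stop("prevalence must lie in [0, 1]", call. = FALSE)
  viol <- validate_diagnostic_test(test)
  if (nrow(viol) > 0L)
    stop("invalid diagnostic test: ",
         paste(viol$field, viol$rule, collapse = "; "), call. = FALSE)
  c(TP = prevalence * test$sensitivity,
    FN = prevalence * (1 - test$sensitivity),
    TN = (1 - prevalence) * test$specificity,
    FP = (1 - prevalence) * (1 - test$specificity))
}

#' Acute entry cost of a decision-tree branch
#'
#' Every branch pays the examination cost; true positives add the timely
#' surgery-plus-treatment cost, false negatives the delayed treatment cost
#' (charged at model start, as no detection delay duration is modelled),
#' false positives the unnecessary-biopsy cost and true negatives the
#' no-further-action cost.
#'
#' @param branch One of `"TP"`, `"FN"`, `"TN"`, `"FP"`.
#' @param test A [diagnostic_test()].
#' @param ps A [parameter_set()].
#' @return Entry cost in USD.
#' @export
branch_entry_cost <- function(branch, test, ps) {
  branch <- match.arg(branch, .branches)
  test$exam_cost + switch(branch,
    TP = ps$cost_timely_treatment,
    FN = ps$cost_delayed_treatment,
    TN = ps$cost_no_action,
    FP = ps$cost_unnecessary_biopsy)
}

#' Markov entry state and pathway of a branch
#'
#' Under the specified topology, true positives enter the localized state on
#' the timely pathway and false negatives the metastatic state on the delayed
#' pathway; under the reconciled topology, timely treatment returns the
#' patient to the no-tumor state and false negatives enter the delayed
#' trajectory (see [model_options()]). True negatives and false positives are
#' disease-free and enter the no-tumor state.
#'
#' @inheritParams branch_entry_cost
#' @param opts A [model_options()].
#' @return List with `state` (a [markov_states] label) and `pathway`.
#' @export
branch_entry_state <- function(branch, opts = model_options()) {
  branch <- match.arg(branch, .branches)
  reconciled <- opts$topology == "reconciled"
  switch(branch,
    TP = list(state = if (reconciled) "NO_TUMOR" else "LOCALIZED",
              pathway = "timely"),
    FN = list(state = if (reconciled) "LOCALIZED" else "METASTATIC",
              pathway = "delayed"),
    TN = list(state = "NO_TUMOR", pathway = "none"),
    FP = list(state = "NO_TUMOR", pathway = "none"))
}

#' Evaluate one diagnostic strategy
#'
#' Expected lifetime discounted cost and effectiveness of a strategy:
#' branch probabilities weight the branch entry cost plus the discounted
#' Markov totals of the branch's pathway.
#'
#' @param test A [diagnostic_test()].
#' @param ps A [parameter_set()].
#' @param lt A [life_table()].
#' @param horizon_months Markov horizon; defaults to lifetime (to the
#'   life-table cap).
#' @param opts A [model_options()].
#' @return A [strategy_result()].
#' @export
evaluate_strategy <- function(test, ps, lt, horizon_months = NULL,
                              opts = model_options()) {
  bp <- branch_probabilities(ps$pretest_malignant, test)
  runs <- list()
  cost <- 0; effect <- 0
  for (branch in .branches) {
    entry <- branch_entry_state(branch, opts)
    key <- paste(entry$state, entry$pathway)
    if (is.null(runs[[key]]))
      runs[[key]] <- run_cohort(entry$state, ps, lt, pathway = entry$pathway,
                                horizon_months = horizon_months, opts = opts)
    tr <- runs[[key]]
    cost <- cost + bp[[branch]] * (branch_entry_cost(branch, test, ps) +
                                     tr$total_cost)
    effect <- effect + bp[[branch]] * tr$total_qaly
  }
  strategy_result(test$name, cost, effect)
}

#' Evaluate every strategy of a parameter set
#'
#' Runs the shared Markov stages once per distinct (entry state, pathway)
#' pair and reuses them across strategies, which is exact because the
#' strategies differ only in branch probabilities and entry costs.
#'
#' @inheritParams evaluate_strategy
#' @return List of [strategy_result()] objects, one per test.
#' @export
evaluate_strategies <- function(ps, lt, horizon_months = NULL,
                                opts = model_options()) {
  runs <- list()
  entries <- lapply(stats::setNames(.branches, .branches),
                    branch_entry_state, opts = opts)
  for (entry in entries) {
    key <- paste(entry$state, entry$pathway)
    if (is.null(runs[[key]]))
      runs[[key]] <- run_cohort(entry$state, ps, lt, pathway = entry$pathway,
                                horizon_months = horizon_months, opts = opts)
  }
  lapply(ps$tests, function(test) {
    bp <- branch_probabilities(ps$pretest_malignant, test)
    cost <- 0; effect <- 0
    for (branch in .branches) {
      entry <- entries[[branch]]
      tr <- runs[[paste(entry$state, entry$pathway)]]
      cost <- cost + bp[[branch]] * (branch_entry_cost(branch, test, ps) +
                                       tr$total_cost)
      effect <- effect + bp[[branch]] * tr$total_qaly
    }
    strategy_result(test$name, cost, effect)
  })
}
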