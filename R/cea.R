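# Cost-effectiveness analysis: strategy ranking, ICERs, dominance frontier
# and net monetary benefit.

#' Expected cost and effectiveness of a strategy
#'
#' @param strategy Strategy label.
#' @param expected_cost Expected discounted lifetime cost in USD (>= 0).
#' @param expected_effect Expected discounted QALYs (>= 0).
#' @return An object of class `strategy_result`.
#' @export
strategy_result <- function(strategy, expected_cost, expected_effect) {
  stopifnot(is.character(strategy), length(strategy) == 1L)
  expected_cost <- as.numeric(expected_cost)
  expected_effect <- as.numeric(expected_effect)
  if (!is.finite(expected_cost) || expected_cost < 0)
    stop("expected_cost must be >= 0", call. = FALSE)
  if (!is.finite(expected_effect) || expected_effect < 0)
    stop("expected_effect must be >= 0", call. = FALSE)
  structure(list(strategy = strategy, expected_cost = expected_cost,
                 expected_effect = expected_effect),
            class = "strategy_result")
}

#' @export
print.strategy_result <- function(x, ...) {
  cat(sprintf("%s: %.2f USD, %.4f QALYs\n",
              x$strategy, x$expected_cost, x$expected_effect))
  invisible(x)
}

#' Incremental cost-effectiveness ratio of two strategies
#'
#' `(cost_a - cost_b) / (effect_a - effect_b)` in USD per QALY. When the
#' effects are equal no ratio exists: the comparison degenerates to costs
#' only and the result carries a flag (`"equal_effect"`, or `"identical"`
#' when the costs are equal too) with an `NA` value instead of a division
#' error. The ratio is invariant under swapping the arguments.
#'
#' @param a,b [strategy_result()] objects.
#' @return Object of class `icer`: list with `value` (USD/QALY or `NA`),
#'   `flag` (`"ok"`, `"equal_effect"`, `"identical"`), `incremental_cost`
#'   and `incremental_effect`.
#' @export
icer <- function(a, b) {
  dc <- a$expected_cost - b$expected_cost
  de <- a$expected_effect - b$expected_effect
  if (de == 0) {
    flag <- if (dc == 0) "identical" else "equal_effect"
    value <- NA_real_
  } else {
    flag <- "ok"
    value <- dc / de
  }
  structure(list(value = value, flag = flag,
                 incremental_cost = dc, incremental_effect = de,
                 strategies = c(a$strategy, b$strategy)),
            class = "icer")
}

#' @export
print.icer <- function(x, ...) {
  if (x$flag == "ok") {
    cat(sprintf("ICER %s vs %s: %.2f USD/QALY\n",
                x$strategies[1], x$strategies[2], x$value))
  } else {
    cat(sprintf("ICER %s vs %s: no ratio (%s; incremental cost %.2f)\n",
                x$strategies[1], x$strategies[2], x$flag, x$incremental_cost))
  }
  invisible(x)
}

#' Net monetary benefit of a strategy
#'
#' `wtp * expected_effect - expected_cost`, converting a (cost, effect) pair
#' into a single monetary score at a willingness-to-pay threshold.
#'
#' @param r A [strategy_result()].
#' @param wtp Willingness-to-pay in USD/QALY (>= 0).
#' @return Net monetary benefit in USD.
#' @export
net_monetary_benefit <- function(r, wtp) {
  if (!is.finite(wtp) || wtp < 0) stop("wtp must be >= 0", call. = FALSE)
  wtp * r$expected_effect - r$expected_cost
}

#' Rank strategies, flag dominance and compute the frontier
#'
#' Sorts strategies by cost, marks strict dominance (another strategy costs
#' no more and yields no fewer QALYs, with at least one strict) by a single
#' sweep over the cost-ordered list, then removes extended dominance
#' (strategies whose frontier ICER exceeds that of the next more effective
#' frontier member) iteratively. Strategies tied on both cost and effect are
#' kept on the frontier and flagged equivalent. ICERs are reported for all
#' pairs and between adjacent frontier members.
#'
#' @param results List of [strategy_result()] objects (>= 1).
#' @return Object of class `cea_result`: list with `results` (data frame:
#'   strategy, cost, effect, dominated, extended_dominated, on_frontier,
#'   equivalent), `icer_pairs` (all ordered pairs) and `frontier`
#'   (cost-ordered frontier with incremental ICERs).
#' @export
rank_and_dominance <- function(results) {
  if (inherits(results, "strategy_result")) results <- list(results)
  if (length(results) < 1L) stop("need at least one strategy", call. = FALSE)
  df <- data.frame(
    strategy = vapply(results, `[[`, character(1), "strategy"),
    cost = vapply(results, `[[`, numeric(1), "expected_cost"),
    effect = vapply(results, `[[`, numeric(1), "expected_effect"),
    stringsAsFactors = FALSE)
  n <- nrow(df)
  ord <- order(df$cost, -df$effect)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL

  # strict dominance sweep over the cost-ordered list: a strategy is
  # dominated iff some item sorted before it (cost <=, and effect >= by the
  # tie order) beats it with at least one strict inequality
  dominated <- logical(n)
  equivalent <- logical(n)
  best_effect <- -Inf; best_cost <- Inf
  for (i in seq_len(n)) {
    if (df$effect[i] < best_effect) {
      dominated[i] <- TRUE
    } else if (df$effect[i] == best_effect && df$cost[i] > best_cost) {
      dominated[i] <- TRUE
    }
    if (df$effect[i] > best_effect) {
      best_effect <- df$effect[i]
      best_cost <- df$cost[i]
    } else if (df$effect[i] == best_effect) {
      best_cost <- min(best_cost, df$cost[i])
    }
  }
  for (i in seq_len(n)) {
    if (dominated[i]) next
    same <- which(!dominated & df$cost == df$cost[i] &
                    df$effect == df$effect[i])
    if (length(same) > 1L) equivalent[i] <- TRUE
  }

  # extended dominance on the strictly non-dominated set: adjacent-ICER
  # monotonicity along increasing effect
  extended <- logical(n)
  repeat {
    cand <- which(!dominated & !extended)
    if (length(cand) < 3L) break
    eff <- df$effect[cand]; cost <- df$cost[cand]
    keep_order <- order(eff, cost)
    cand <- cand[keep_order]
    ic <- diff(df$cost[cand]) / diff(df$effect[cand])
    ic[is.nan(ic)] <- 0  # equivalent neighbours
    drop <- which(utils::head(ic, -1) >= utils::tail(ic, -1) &
                    is.finite(utils::head(ic, -1)))
    drop <- drop[df$effect[cand][drop + 1L] != df$effect[cand][drop]]
    if (length(drop) == 0L) break
    extended[cand[drop[1L] + 1L]] <- TRUE
  }

  df$dominated <- dominated
  df$extended_dominated <- extended
  df$on_frontier <- !dominated & !extended
  df$equivalent <- equivalent

  icer_pairs <- NULL
  if (n > 1L) {
    pairs <- expand.grid(i = seq_len(n), j = seq_len(n))
    pairs <- pairs[pairs$i != pairs$j, , drop = FALSE]
    icer_pairs <- data.frame(
      strategy = df$strategy[pairs$i],
      comparator = df$strategy[pairs$j],
      incremental_cost = df$cost[pairs$i] - df$cost[pairs$j],
      incremental_effect = df$effect[pairs$i] - df$effect[pairs$j],
      stringsAsFactors = FALSE)
    icer_pairs$icer <- ifelse(icer_pairs$incremental_effect == 0, NA_real_,
                              icer_pairs$incremental_cost /
                                icer_pairs$incremental_effect)
    rownames(icer_pairs) <- NULL
  } else {
    icer_pairs <- data.frame(strategy = character(), comparator = character(),
                             incremental_cost = numeric(),
                             incremental_effect = numeric(),
                             icer = numeric(), stringsAsFactors = FALSE)
  }

  fr <- df[df$on_frontier, c("strategy", "cost", "effect"), drop = FALSE]
  fr <- fr[order(fr$cost, fr$effect), , drop = FALSE]
  fr$icer_vs_previous <- c(NA_real_,
                           if (nrow(fr) > 1L)
                             diff(fr$cost) / diff(fr$effect) else NULL)
  rownames(fr) <- NULL

  structure(list(results = df, icer_pairs = icer_pairs, frontier = fr),
            class = "cea_result")
}

#' @export
print.cea_result <- function(x, ...) {
  cat("Cost-effectiveness ranking (by cost):\n")
  df <- x$results
  flag <- ifelse(df$dominated, "dominated",
                 ifelse(df$extended_dominated, "ext. dominated", "frontier"))
  flag[df$equivalent] <- paste0(flag[df$equivalent], " (tie)")
  for (i in seq_len(nrow(df)))
    cat(sprintf("  %-6s %12.2f USD  %8.4f QALYs  [%s]\n",
                df$strategy[i], df$cost[i], df$effect[i], flag[i]))
  if (nrow(x$frontier) > 1L) {
    cat("Frontier ICERs (vs previous frontier member):\n")
    for (i in 2:nrow(x$frontier))
      cat(sprintf("  %-6s %12.2f USD/QALY\n", x$frontier$strategy[i],
                  x$frontier$icer_vs_previous[i]))
  }
  invisible(x)
}
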