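# Report writers and command-line entry points tying the pipeline together.
# Monetary outputs are written with 2 decimals; internal arithmetic keeps
# full precision.

.pkg_version <- function() {
  as.character(utils::packageVersion("renalcea"))
}

.money <- function(x) round(x, 2)

#' Run manifest for reproducibility
#'
#' Records everything needed to reproduce a run bit-for-bit: the config path
#' and an MD5 hash of the effective parameter set, the life-table source and
#' hash, seed, horizon, topology, package version and a timestamp.
#'
#' @param ps A [parameter_set()].
#' @param config Config path or `NA` when built in code.
#' @param life_table_source Life-table path or `"synthetic"`.
#' @param seed Seed used (or `NA`).
#' @param horizon_months Horizon used (or `NA` for lifetime).
#' @param opts A [model_options()].
#' @return A named list (class `run_manifest`).
#' @export
run_manifest <- function(ps, config = NA_character_,
                         life_table_source = "synthetic",
                         seed = NA_integer_, horizon_months = NA_integer_,
                         opts = model_options()) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp), add = TRUE)
  write_parameter_set(ps, tmp)
  structure(list(
    config = config,
    config_hash = unname(tools::md5sum(tmp)),
    life_table_source = life_table_source,
    seed = seed,
    horizon_months = horizon_months,
    topology = opts$topology,
    cost_accrual_months = opts$cost_accrual_months,
    package_version = .pkg_version(),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)),
    class = "run_manifest")
}

.write_manifest <- function(manifest, out_dir) {
  jsonlite::write_json(unclass(manifest),
                       file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, na = "null")
}

.load_inputs <- function(config, life_table, allow_defaults = TRUE) {
  ps <- if (is.null(config)) {
    default_parameter_set()
  } else {
    if (!file.exists(config))
      stop("config file not found: ", config, call. = FALSE)
    load_parameter_set(config, allow_defaults = allow_defaults)
  }
  lt <- if (is.null(life_table)) {
    default_life_table()
  } else {
    load_life_table(life_table)
  }
  list(ps = ps, lt = lt,
       lt_source = if (is.null(life_table)) "synthetic" else life_table)
}

#' Base-case run: strategy table, dominance flags and ICERs
#'
#' Evaluates every strategy, ranks them, and writes `cea_results.csv`,
#' `icer_table.csv` and `run_manifest.json` into `out_dir`.
#'
#' @param config Path to a parameter config (YAML); `NULL` for the baseline.
#' @param life_table Path to a life-table CSV; `NULL` for the synthetic
#'   default.
#' @param horizon_months Markov horizon; `NULL` for lifetime.
#' @param out_dir Output directory (created if needed); `NULL` skips writing.
#' @param opts A [model_options()].
#' @return The `cea_result`, invisibly.
#' @export
cmd_run <- function(config = NULL, life_table = NULL, horizon_months = NULL,
                    out_dir = NULL, opts = model_options()) {
  inp <- .load_inputs(config, life_table)
  results <- evaluate_strategies(inp$ps, inp$lt,
                                 horizon_months = horizon_months, opts = opts)
  cea <- rank_and_dominance(results)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    df <- cea$results
    df$cost <- .money(df$cost)
    utils::write.csv(df, file.path(out_dir, "cea_results.csv"),
                     row.names = FALSE)
    ic <- cea$icer_pairs
    ic$incremental_cost <- .money(ic$incremental_cost)
    ic$icer <- .money(ic$icer)
    utils::write.csv(ic, file.path(out_dir, "icer_table.csv"),
                     row.names = FALSE)
    .write_manifest(run_manifest(inp$ps, config = config %||% NA_character_,
                                 life_table_source = inp$lt_source,
                                 horizon_months = horizon_months %||%
                                   NA_integer_,
                                 opts = opts),
                    out_dir)
  }
  invisible(cea)
}

#' Deterministic sensitivity (tornado) run
#'
#' @inheritParams cmd_run
#' @param range_spec Data frame of ranges (see [tornado()]); `NULL` uses
#'   the default +/-20% ranges.
#' @param metric Tornado outcome metric, `"nmb_diff"` or `"icer"`.
#' @param reference Reference strategy.
#' @return The tornado data frame, invisibly.
#' @export
cmd_dsa <- function(config = NULL, life_table = NULL, range_spec = NULL,
                    metric = "nmb_diff", reference = "CEUS",
                    horizon_months = NULL, out_dir = NULL,
                    opts = model_options()) {
  inp <- .load_inputs(config, life_table)
  if (is.null(range_spec)) range_spec <- default_dsa_ranges(inp$ps)
  tor <- tornado(inp$ps, inp$lt, range_spec, metric = metric,
                 reference = reference, horizon_months = horizon_months,
                 opts = opts)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    out <- tor
    for (col in c("outcome_at_low", "outcome_at_high", "span"))
      out[[col]] <- .money(out[[col]])
    utils::write.csv(out, file.path(out_dir, "tornado.csv"),
                     row.names = FALSE)
    .write_manifest(run_manifest(inp$ps, config = config %||% NA_character_,
                                 life_table_source = inp$lt_source,
                                 horizon_months = horizon_months %||%
                                   NA_integer_,
                                 opts = opts),
                    out_dir)
  }
  invisible(tor)
}

#' Probabilistic sensitivity run
#'
#' Writes the iteration-level table (`psa_iterations.csv`: iteration,
#' strategy, cost, effect), the acceptability curves (`ceac.csv`) and the
#' manifest.
#'
#' @inheritParams cmd_run
#' @param iterations Number of Monte Carlo repetitions.
#' @param seed Integer seed.
#' @param wtp_grid WTP grid for the acceptability curves.
#' @return The `psa_result`, invisibly.
#' @export
cmd_psa <- function(config = NULL, life_table = NULL, iterations = 30000L,
                    seed = 1L, wtp_grid = seq(0, 200000, by = 10000),
                    horizon_months = NULL, out_dir = NULL,
                    opts = model_options()) {
  inp <- .load_inputs(config, life_table)
  psa <- run_psa(inp$ps, inp$lt, n_iterations = iterations, seed = seed,
                 wtp_grid = wtp_grid, horizon_months = horizon_months,
                 opts = opts)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    iters <- data.frame(
      iteration = rep(seq_len(psa$n_iterations), times = length(psa$strategies)),
      strategy = rep(psa$strategies, each = psa$n_iterations),
      cost = .money(as.vector(psa$cost)),
      effect = as.vector(psa$effect),
      stringsAsFactors = FALSE)
    utils::write.csv(iters, file.path(out_dir, "psa_iterations.csv"),
                     row.names = FALSE)
    utils::write.csv(psa$ceac, file.path(out_dir, "ceac.csv"),
                     row.names = FALSE)
    .write_manifest(run_manifest(inp$ps, config = config %||% NA_character_,
                                 life_table_source = inp$lt_source,
                                 seed = seed,
                                 horizon_months = horizon_months %||%
                                   NA_integer_,
                                 opts = opts),
                    out_dir)
  }
  invisible(psa)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Command-line entry point
#'
#' Subcommands: `run`, `dsa`, `psa`, `validate`. Shared flags: `--config`,
#' `--life-table`, `--horizon-months`, `--out`, `--topology`; `psa` adds
#' `--iterations`, `--seed`, `--wtp`; `dsa` adds `--metric`, `--reference`.
#' Invoked by the `inst/cli/renalcea.R` script; validation failures raise
#' errors, giving the script a nonzero exit status.
#'
#' @param args Character vector of command-line arguments.
#' @return Exit status 0, invisibly, on success.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L || args[1] %in% c("-h", "--help"))
    stop("usage: renalcea <run|dsa|psa|validate> [options]", call. = FALSE)
  sub <- args[1]
  rest <- args[-1]
  opt_list <- list(
    optparse::make_option("--config", type = "character", default = NULL),
    optparse::make_option("--life-table", type = "character", default = NULL,
                          dest = "life_table"),
    optparse::make_option("--horizon-months", type = "integer",
                          default = NULL, dest = "horizon_months"),
    optparse::make_option("--iterations", type = "integer", default = 30000L),
    optparse::make_option("--seed", type = "integer", default = 1L),
    optparse::make_option("--wtp", type = "double", default = 100000),
    optparse::make_option("--metric", type = "character",
                          default = "nmb_diff"),
    optparse::make_option("--reference", type = "character",
                          default = "CEUS"),
    optparse::make_option("--topology", type = "character",
                          default = "specified"),
    optparse::make_option("--out", type = "character", default = "results"))
  opt <- optparse::parse_args(optparse::OptionParser(option_list = opt_list),
                              args = rest)
  opts <- model_options(topology = opt$topology)
  switch(sub,
    run = {
      cea <- cmd_run(opt$config, opt$life_table, opt$horizon_months,
                     opt$out, opts = opts)
      print(cea)
    },
    dsa = {
      tor <- cmd_dsa(opt$config, opt$life_table, metric = opt$metric,
                     reference = opt$reference,
                     horizon_months = opt$horizon_months, out_dir = opt$out,
                     opts = opts)
      message("tornado entries written: ", nrow(tor))
    },
    psa = {
      psa <- cmd_psa(opt$config, opt$life_table, iterations = opt$iterations,
                     seed = opt$seed, horizon_months = opt$horizon_months,
                     out_dir = opt$out, opts = opts)
      print(psa)
    },
    validate = {
      inp <- .load_inputs(opt$config, opt$life_table)
      viol <- validate_parameter_set(inp$ps)
      if (nrow(viol) > 0L) {
        print(viol)
        stop("parameter set invalid: ", nrow(viol), " violation(s)",
             call. = FALSE)
      }
      message("parameter set valid (", length(inp$ps$tests), " strategies)")
    },
    stop("unknown subcommand: ", sub, call. = FALSE))
  invisible(0L)
}
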