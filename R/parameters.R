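# Model parameterization: baseline inputs, validation, config (de)serialization,
# and the distribution assignments used by the probabilistic sensitivity analysis.

#' Define a diagnostic test strategy
#'
#' A diagnostic strategy is characterised by its name, sensitivity and
#' specificity for malignancy in a solid renal mass, and the acute cost of one
#' examination (2020 USD).
#'
#' @param name Strategy label, e.g. `"CEUS"`, `"CT"`, `"MRI"`.
#' @param sensitivity Probability that a malignant mass tests positive.
#' @param specificity Probability that a benign mass tests negative.
#' @param exam_cost Cost of one examination in USD (>= 0).
#' @return An object of class `diagnostic_test`.
#' @examples
#' diagnostic_test("CEUS", 0.991, 0.805, 285)
#' @export
diagnostic_test <- function(name, sensitivity, specificity, exam_cost) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  t <- structure(
    list(name = name,
         sensitivity = as.numeric(sensitivity),
         specificity = as.numeric(specificity),
         exam_cost = as.numeric(exam_cost)),
    class = "diagnostic_test")
  viol <- validate_diagnostic_test(t)
  if (nrow(viol) > 0L) {
    stop("invalid diagnostic test '", name, "': ",
         paste(viol$field, viol$rule, collapse = "; "), call. = FALSE)
  }
  t
}

validate_diagnostic_test <- function(t) {
  v <- list()
  chk <- function(field, value, ok, rule) {
    if (!isTRUE(ok)) v[[length(v) + 1L]] <<- data.frame(
      field = field, value = value, rule = rule, stringsAsFactors = FALSE)
  }
  chk("sensitivity", t$sensitivity,
      is.finite(t$sensitivity) && t$sensitivity >= 0 && t$sensitivity <= 1,
      "must be a probability in [0, 1]")
  chk("specificity", t$specificity,
      is.finite(t$specificity) && t$specificity >= 0 && t$specificity <= 1,
      "must be a probability in [0, 1]")
  chk("exam_cost", t$exam_cost,
      is.finite(t$exam_cost) && t$exam_cost >= 0, "must be >= 0")
  if (length(v) == 0L) {
    data.frame(field = character(), value = numeric(), rule = character(),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, v)
  }
}

#' @export
print.diagnostic_test <- function(x, ...) {
  cat(sprintf("Diagnostic strategy %s: Se %.3f, Sp %.3f, exam cost %.2f USD\n",
              x$name, x$sensitivity, x$specificity, x$exam_cost))
  invisible(x)
}

#' Specify a sampling distribution for one parameter
#'
#' Probabilistic sensitivity analysis assigns each parameter a distribution on
#' its natural scale: `beta` for probabilities and utilities, `gamma` for
#' costs, or `fixed` for values held at their point estimate. Dispersion is
#' given as a coefficient of variation and converted to distribution
#' parameters by the method of moments when sampling.
#'
#' @param family One of `"beta"`, `"gamma"`, `"fixed"`.
#' @param mean Mean on the parameter's natural scale.
#' @param cv Coefficient of variation (sd/mean); ignored for `fixed`.
#' @return An object of class `dist_spec`.
#' @export
dist_spec <- function(family = c("beta", "gamma", "fixed"), mean, cv = 0.2) {
  family <- match.arg(family)
  mean <- as.numeric(mean)
  cv <- as.numeric(cv)
  if (family == "beta" && !(is.finite(mean) && mean > 0 && mean < 1))
    stop("beta mean must lie in (0, 1), got ", mean, call. = FALSE)
  if (family == "gamma" && !(is.finite(mean) && mean > 0))
    stop("gamma mean must be > 0, got ", mean, call. = FALSE)
  if (family != "fixed" && !(is.finite(cv) && cv > 0))
    stop("cv must be > 0 for family '", family, "'", call. = FALSE)
  structure(list(family = family, mean = mean, cv = cv), class = "dist_spec")
}

# Scalar (non-test) fields of a parameter set, with their invariant class.
.ps_scalar_fields <- c(
  pretest_malignant = "prob",
  start_age_years = "age",
  wtp = "cost",
  annual_discount = "rate",
  cost_biopsy = "cost",
  cost_timely_treatment = "cost",
  cost_delayed_treatment = "cost",
  cost_unnecessary_biopsy = "cost",
  cost_no_action = "cost",
  monthly_cost_no_tumor = "cost",
  monthly_cost_localized_y1 = "cost",
  monthly_cost_localized_later = "cost",
  monthly_cost_metastatic_y1 = "cost",
  monthly_cost_metastatic_later = "cost",
  utility_no_tumor = "utility",
  utility_localized = "utility",
  utility_metastatic = "utility",
  utility_dead = "utility",
  p_non_r0 = "prob",
  p_local_recurrence = "prob",
  p_metastases_no_tumor = "prob",
  p_metastases_localized = "prob",
  p_successful_recurrence_surgery = "prob",
  excess_death_metastatic = "prob",
  excess_death_localized = "prob")

#' Construct a validated parameter set
#'
#' Bundles every input driving one model run: pre-test probability of
#' malignancy, the diagnostic strategies, acute and monthly costs, utilities,
#' annual transition probabilities, discount rate and willingness-to-pay.
#' Invalid inputs raise an error; see [validate_parameter_set()] for the
#' non-throwing variant.
#'
#' @param ... Named scalar fields (see [default_parameter_set()] for the full
#'   list and baseline values).
#' @param tests List of [diagnostic_test()] objects.
#' @param psa_dist Named list of [dist_spec()] objects keyed by parameter id;
#'   defaults are derived from the point estimates via [default_psa_dists()].
#' @return An object of class `parameter_set`.
#' @seealso [default_parameter_set()], [load_parameter_set()]
#' @export
parameter_set <- function(..., tests, psa_dist = NULL) {
  scalars <- list(...)
  unknown <- setdiff(names(scalars), names(.ps_scalar_fields))
  if (length(unknown) > 0L)
    stop("unknown parameter field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  missing <- setdiff(names(.ps_scalar_fields), names(scalars))
  if (length(missing) > 0L)
    stop("missing parameter field(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (!is.list(tests) || length(tests) == 0L ||
      !all(vapply(tests, inherits, logical(1), "diagnostic_test")))
    stop("tests must be a non-empty list of diagnostic_test objects",
         call. = FALSE)
  names(tests) <- vapply(tests, `[[`, character(1), "name")
  if (anyDuplicated(names(tests)))
    stop("duplicated test names: ",
         paste(unique(names(tests)[duplicated(names(tests))]), collapse = ", "),
         call. = FALSE)
  ps <- structure(
    c(lapply(scalars[names(.ps_scalar_fields)], as.numeric),
      list(tests = tests)),
    class = "parameter_set")
  ps$psa_dist <- if (is.null(psa_dist)) default_psa_dists(ps) else psa_dist
  viol <- validate_parameter_set(ps)
  if (nrow(viol) > 0L)
    stop("invalid parameter set:\n",
         paste(sprintf("  %s = %s: %s", viol$field, viol$value, viol$rule),
               collapse = "\n"), call. = FALSE)
  ps
}

#' Baseline model inputs
#'
#' Returns the published baseline parameterization of the renal-mass model:
#' a 62-year-old cohort with pre-test probability of malignancy 0.831,
#' CEUS/CT/MRI diagnostic performances, 2020 USD Medicare acute costs,
#' literature-derived monthly costs and utilities, annual transition
#' probabilities, a 3% annual discount rate and a willingness-to-pay of
#' USD 100,000 per QALY.
#'
#' @return A [parameter_set()] holding the baseline values.
#' @examples
#' ps <- default_parameter_set()
#' ps$pretest_malignant
#' ps$tests$CEUS
#' @export
default_parameter_set <- function() {
  parameter_set(
    pretest_malignant = 0.831,
    start_age_years = 62,
    wtp = 100000,
    annual_discount = 0.03,
    cost_biopsy = 1375.00,
    cost_timely_treatment = 4231.00,
    cost_delayed_treatment = 6346.50,
    cost_unnecessary_biopsy = 1375.00,
    cost_no_action = 0.00,
    monthly_cost_no_tumor = 108.50,
    monthly_cost_localized_y1 = 2148.25,
    monthly_cost_localized_later = 212.67,
    monthly_cost_metastatic_y1 = 2086.42,
    monthly_cost_metastatic_later = 810.58,
    utility_no_tumor = 1.00,
    utility_localized = 0.75,
    utility_metastatic = 0.66,
    utility_dead = 0.00,
    p_non_r0 = 0.0573,
    p_local_recurrence = 0.1075,
    p_metastases_no_tumor = 0.01,
    p_metastases_localized = 0.13,
    p_successful_recurrence_surgery = 0.412,
    excess_death_metastatic = 0.35,
    excess_death_localized = 0.035,
    tests = list(
      diagnostic_test("CEUS", 0.991, 0.805, 285.00),
      diagnostic_test("CT", 0.75, 0.72, 233.00),
      diagnostic_test("MRI", 0.90, 0.96, 381.00)))
}

# Largest feasible beta cv is sqrt((1-m)/m); stay at 70% of it so the
# method-of-moments shape parameters remain well away from the degenerate
# (bathtub) boundary for success probabilities near 1.
.beta_cv <- function(mean, cv = 0.2) min(cv, 0.7 * sqrt((1 - mean) / mean))

#' Default sampling distributions for a parameter set
#'
#' Assigns `beta` to probabilities and utilities strictly inside (0, 1),
#' `gamma` to strictly positive costs, and `fixed` to structural values
#' (willingness-to-pay, discount rate, cohort starting age, boundary
#' utilities, zero costs). The default coefficient of variation is 0.2,
#' truncated for beta parameters whose mean is too close to 1 for that
#' dispersion to be feasible.
#'
#' @param ps A `parameter_set` (the `psa_dist` element is ignored).
#' @param cv Default coefficient of variation.
#' @return Named list of [dist_spec()] objects keyed by parameter id.
#' @export
default_psa_dists <- function(ps, cv = 0.2) {
  out <- list()
  fixed_ids <- c("wtp", "annual_discount", "start_age_years")
  for (field in names(.ps_scalar_fields)) {
    value <- ps[[field]]
    cls <- .ps_scalar_fields[[field]]
    out[[field]] <-
      if (field %in% fixed_ids) {
        dist_spec("fixed", value)
      } else if (cls %in% c("prob", "utility")) {
        if (value > 0 && value < 1)
          dist_spec("beta", value, .beta_cv(value, cv))
        else
          dist_spec("fixed", value)     # boundary values (0 or 1)
      } else {                          # cost
        if (value > 0) dist_spec("gamma", value, cv) else dist_spec("fixed", value)
      }
  }
  for (tn in names(ps$tests)) {
    t <- ps$tests[[tn]]
    out[[paste0("sensitivity_", tn)]] <-
      dist_spec("beta", t$sensitivity, .beta_cv(t$sensitivity, cv))
    out[[paste0("specificity_", tn)]] <-
      dist_spec("beta", t$specificity, .beta_cv(t$specificity, cv))
    out[[paste0("exam_cost_", tn)]] <- dist_spec("gamma", t$exam_cost, cv)
  }
  out
}

#' Validate a parameter set
#'
#' Checks every type invariant (probabilities in \[0, 1\], costs >= 0,
#' utilities in \[0, 1\] with the dead-state utility equal to 0, discount rate
#' >= 0, test profiles valid) and returns the violations as data rather than
#' raising errors. A utility ordering in which the metastatic state scores
#' above the localized state is unusual but not forbidden; it is reported as
#' a warning attribute, not a violation.
#'
#' @param ps Object to check.
#' @return A data frame with columns `field`, `value`, `rule`; zero rows iff
#'   all invariants hold. Soft concerns are attached as a character vector in
#'   `attr(, "warnings")`.
#' @export
validate_parameter_set <- function(ps) {
  v <- list()
  add <- function(field, value, rule) {
    v[[length(v) + 1L]] <<- data.frame(
      field = field, value = as.numeric(value)[1], rule = rule,
      stringsAsFactors = FALSE)
  }
  for (field in names(.ps_scalar_fields)) {
    value <- ps[[field]]
    if (!is.numeric(value) || length(value) != 1L || !is.finite(value)) {
      add(field, NA_real_, "must be a finite numeric scalar")
      next
    }
    cls <- .ps_scalar_fields[[field]]
    if (cls %in% c("prob", "utility") && (value < 0 || value > 1))
      add(field, value, "must lie in [0, 1]")
    if (cls %in% c("cost", "rate") && value < 0)
      add(field, value, "must be >= 0")
    if (cls == "age" && (value < 0 || value >= 120))
      add(field, value, "must be a plausible age in [0, 120)")
  }
  if (is.numeric(ps$utility_dead) && length(ps$utility_dead) == 1L &&
      is.finite(ps$utility_dead) && ps$utility_dead != 0)
    add("utility_dead", ps$utility_dead, "must equal 0")
  if (!is.list(ps$tests) || length(ps$tests) == 0L) {
    add("tests", NA_real_, "must contain at least one diagnostic test")
  } else {
    for (t in ps$tests) {
      tv <- validate_diagnostic_test(t)
      if (nrow(tv) > 0L) {
        tv$field <- paste0(t$name, ".", tv$field)
        v[[length(v) + 1L]] <- tv
      }
    }
  }
  out <- if (length(v) == 0L) {
    data.frame(field = character(), value = numeric(), rule = character(),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, v)
  }
  warn <- character()
  if (is.numeric(ps$utility_metastatic) && is.numeric(ps$utility_localized) &&
      length(ps$utility_metastatic) == 1L && length(ps$utility_localized) == 1L &&
      isTRUE(ps$utility_metastatic > ps$utility_localized))
    warn <- c(warn, "utility_metastatic exceeds utility_localized (unusual ordering)")
  attr(out, "warnings") <- warn
  rownames(out) <- NULL
  out
}

#' @export
print.parameter_set <- function(x, ...) {
  cat("Renal-mass model parameter set\n")
  cat(sprintf("  cohort: start age %g y, pre-test P(malignant) %.3f\n",
              x$start_age_years, x$pretest_malignant))
  cat(sprintf("  discount %.1f%%/y, WTP %s USD/QALY\n",
              100 * x$annual_discount, format(x$wtp, big.mark = ",")))
  cat("  strategies:\n")
  for (t in x$tests)
    cat(sprintf("    %-5s Se %.3f  Sp %.3f  exam %.2f USD\n",
                t$name, t$sensitivity, t$specificity, t$exam_cost))
  invisible(x)
}

# ---- parameter ids: uniform access to scalar and per-test fields -----------

#' Enumerate addressable parameter ids
#'
#' Parameter ids name every scalar model input, including per-test fields in
#' the form `sensitivity_<name>`, `specificity_<name>`, `exam_cost_<name>`.
#' They key the PSA distribution map and the deterministic sensitivity ranges.
#'
#' @param ps A `parameter_set`.
#' @return Character vector of ids.
#' @export
parameter_ids <- function(ps) {
  c(names(.ps_scalar_fields),
    as.vector(outer(c("sensitivity_", "specificity_", "exam_cost_"),
                    names(ps$tests), paste0)))
}

.split_test_id <- function(ps, id) {
  for (prefix in c("sensitivity", "specificity", "exam_cost")) {
    p <- paste0(prefix, "_")
    if (startsWith(id, p)) {
      tn <- substring(id, nchar(p) + 1L)
      if (tn %in% names(ps$tests)) return(list(field = prefix, test = tn))
    }
  }
  NULL
}

#' Read a parameter by id
#' @param ps A `parameter_set`.
#' @param id A parameter id (see [parameter_ids()]).
#' @return The numeric value.
#' @export
get_parameter <- function(ps, id) {
  if (id %in% names(.ps_scalar_fields)) return(ps[[id]])
  hit <- .split_test_id(ps, id)
  if (is.null(hit)) stop("unknown parameter id: ", id, call. = FALSE)
  ps$tests[[hit$test]][[hit$field]]
}

#' Return a copy of a parameter set with one parameter replaced
#'
#' The modified set is re-validated; an out-of-domain value raises an error
#' naming the field.
#'
#' @inheritParams get_parameter
#' @param value New numeric value.
#' @return A `parameter_set`.
#' @export
set_parameter <- function(ps, id, value) {
  if (id %in% names(.ps_scalar_fields)) {
    ps[[id]] <- as.numeric(value)
  } else {
    hit <- .split_test_id(ps, id)
    if (is.null(hit)) stop("unknown parameter id: ", id, call. = FALSE)
    ps$tests[[hit$test]][[hit$field]] <- as.numeric(value)
  }
  viol <- validate_parameter_set(ps)
  if (nrow(viol) > 0L)
    stop("setting ", id, " = ", value, " violates: ",
         paste(viol$field, viol$rule, collapse = "; "), call. = FALSE)
  ps
}

# ---- config (de)serialization ----------------------------------------------

.schema_version <- "1.0"

#' Load a parameter set from a YAML/JSON configuration
#'
#' The configuration is a key-value document with the scalar fields of
#' [default_parameter_set()], a `tests` list of
#' `{name, sensitivity, specificity, exam_cost}` records, an optional `psa`
#' map of per-parameter `{family, mean, cv}` overrides and a `schema_version`
#' key. Unknown keys are rejected. Missing keys are an error unless
#' `allow_defaults = TRUE`, in which case they fall back to the baseline
#' values.
#'
#' @param source Path to a YAML (or JSON, a YAML subset) file, or a literal
#'   document as a single string containing a newline.
#' @param allow_defaults Fill missing keys from [default_parameter_set()]?
#' @return A validated `parameter_set`.
#' @seealso [write_parameter_set()] for the inverse.
#' @export
load_parameter_set <- function(source, allow_defaults = FALSE) {
  doc <- if (is.character(source) && length(source) == 1L &&
             !grepl("\n", source, fixed = TRUE)) {
    if (!file.exists(source))
      stop("config file not found: ", source, call. = FALSE)
    yaml::read_yaml(source)
  } else {
    yaml::yaml.load(paste(source, collapse = "\n"))
  }
  if (!is.list(doc)) stop("config must be a key-value document", call. = FALSE)
  known <- c(names(.ps_scalar_fields), "tests", "psa", "schema_version")
  unknown <- setdiff(names(doc), known)
  if (length(unknown) > 0L)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (!is.null(doc$schema_version) &&
      as.character(doc$schema_version) != .schema_version)
    stop("unsupported schema_version: ", doc$schema_version,
         " (expected ", .schema_version, ")", call. = FALSE)

  defaults <- default_parameter_set()
  scalars <- list()
  for (field in names(.ps_scalar_fields)) {
    if (!is.null(doc[[field]])) {
      value <- doc[[field]]
      if (!is.numeric(value) || length(value) != 1L)
        stop("config key '", field, "' must be a numeric scalar", call. = FALSE)
      scalars[[field]] <- value
    } else if (allow_defaults) {
      scalars[[field]] <- defaults[[field]]
    } else {
      stop("missing config key '", field,
           "' (set allow_defaults = TRUE to use the baseline value)",
           call. = FALSE)
    }
  }
  tests <- if (!is.null(doc$tests)) {
    lapply(doc$tests, function(t) {
      need <- c("name", "sensitivity", "specificity", "exam_cost")
      miss <- setdiff(need, names(t))
      if (length(miss) > 0L)
        stop("test entry missing key(s): ", paste(miss, collapse = ", "),
             call. = FALSE)
      extra <- setdiff(names(t), need)
      if (length(extra) > 0L)
        stop("unknown test key(s): ", paste(extra, collapse = ", "),
             call. = FALSE)
      diagnostic_test(t$name, t$sensitivity, t$specificity, t$exam_cost)
    })
  } else if (allow_defaults) {
    defaults$tests
  } else {
    stop("missing config key 'tests'", call. = FALSE)
  }

  ps <- do.call(parameter_set, c(scalars, list(tests = tests)))
  if (!is.null(doc$psa)) {
    ids <- parameter_ids(ps)
    for (id in names(doc$psa)) {
      if (!(id %in% ids))
        stop("psa override names unknown parameter id: ", id, call. = FALSE)
      o <- doc$psa[[id]]
      base <- ps$psa_dist[[id]]
      ps$psa_dist[[id]] <- dist_spec(
        family = if (is.null(o$family)) base$family else o$family,
        mean = if (is.null(o$mean)) get_parameter(ps, id) else o$mean,
        cv = if (is.null(o$cv)) base$cv else o$cv)
    }
  }
  ps
}

#' Serialize a parameter set to YAML
#'
#' Writes a configuration that [load_parameter_set()] reads back
#' field-for-field, including the PSA distribution map.
#'
#' @param ps A `parameter_set`.
#' @param path Output file; if `NULL` the YAML text is returned invisibly.
#' @return The YAML text, invisibly.
#' @export
write_parameter_set <- function(ps, path = NULL) {
  doc <- c(list(schema_version = .schema_version),
           lapply(stats::setNames(names(.ps_scalar_fields),
                                  names(.ps_scalar_fields)),
                  function(f) ps[[f]]))
  doc$tests <- lapply(unname(ps$tests), function(t)
    list(name = t$name, sensitivity = t$sensitivity,
         specificity = t$specificity, exam_cost = t$exam_cost))
  doc$psa <- lapply(ps$psa_dist, function(d)
    list(family = d$family, mean = d$mean, cv = d$cv))
  txt <- yaml::as.yaml(doc, precision = 15L)
  if (!is.null(path)) writeLines(txt, path)
  invisible(txt)
}
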