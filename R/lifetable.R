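# Age-specific background mortality: load a real life table, or synthesize a
# Gompertz stand-in, and convert annual to monthly death probabilities.

#' Construct a life table
#'
#' A life table is an age-indexed vector of annual probabilities of death
#' `qx`. Ages must be strictly increasing and contiguous integers; the final
#' age (`max_age`) is an absorbing cap at which `qx` is forced to 1, so every
#' simulated horizon is finite.
#'
#' @param age Integer ages, contiguous and increasing.
#' @param qx Annual death probability at each age, in \[0, 1\].
#' @return An object of class `life_table` (a data frame with columns
#'   `age`, `qx`, and a `max_age` attribute).
#' @export
life_table <- function(age, qx) {
  age <- as.numeric(age); qx <- as.numeric(qx)
  if (length(age) != length(qx) || length(age) < 2L)
    stop("life table needs matching age/qx vectors of length >= 2",
         call. = FALSE)
  if (anyNA(age) || anyNA(qx))
    stop("life table contains missing values", call. = FALSE)
  if (any(age != floor(age)))
    stop("ages must be integers", call. = FALSE)
  d <- diff(age)
  if (any(d <= 0)) {
    i <- which(d <= 0)[1]
    stop("ages must be strictly increasing (row ", i + 1L, ", age ",
         age[i + 1L], ")", call. = FALSE)
  }
  if (any(d > 1)) {
    i <- which(d > 1)[1]
    stop("gap at age ", age[i] + 1L, " (row ", i + 1L, ")", call. = FALSE)
  }
  bad <- which(qx < 0 | qx > 1)
  if (length(bad) > 0L)
    stop("qx out of [0, 1] at age ", age[bad[1]], " (row ", bad[1], "): ",
         qx[bad[1]], call. = FALSE)
  qx[length(qx)] <- 1  # absorbing cap
  structure(data.frame(age = age, qx = qx),
            max_age = age[length(age)],
            class = c("life_table", "data.frame"))
}

#' Load a life table from a delimited file
#'
#' Expects two columns, age and annual death probability `qx`, with an
#' optional header. Rows beyond `max_age` are clipped; gaps or out-of-range
#' probabilities raise an error naming the offending row.
#'
#' @param path CSV/TSV file path (or a connection readable by
#'   [utils::read.table()]).
#' @param max_age Clip and cap the table at this age.
#' @return A [life_table()].
#' @export
load_life_table <- function(path, max_age = 100) {
  if (is.character(path) && !file.exists(path))
    stop("life table file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  header <- !grepl("^\\s*[0-9]", first)
  tab <- utils::read.table(path, header = header, sep = ",",
                           strip.white = TRUE)
  if (ncol(tab) < 2L)
    stop("life table must have two columns (age, qx)", call. = FALSE)
  age <- tab[[1]]; qx <- tab[[2]]
  keep <- age <= max_age
  age <- age[keep]; qx <- qx[keep]
  if (length(age) == 0L || age[length(age)] < max_age)
    stop("life table must extend to max_age = ", max_age, call. = FALSE)
  life_table(age, qx)
}

#' Synthesize a Gompertz life table
#'
#' Annual death probability at age x is `1 - exp(-a * exp(b * x))`, capped at
#' 1, with the `max_age` entry forced to 1. This parametric stand-in replaces
#' a national life table when none is supplied; see [default_life_table()]
#' for the calibrated default.
#'
#' @param a Hazard scale (> 0).
#' @param b Hazard slope per year of age (> 0).
#' @param min_age,max_age Age span of the table.
#' @return A [life_table()].
#' @export
synthesize_life_table <- function(a, b, min_age = 0, max_age = 100) {
  if (!is.finite(a) || a <= 0) stop("a must be > 0", call. = FALSE)
  if (!is.finite(b) || b <= 0) stop("b must be > 0", call. = FALSE)
  if (min_age >= max_age) stop("min_age must be below max_age", call. = FALSE)
  age <- seq(floor(min_age), ceiling(max_age))
  qx <- pmin(1, 1 - exp(-a * exp(b * age)))
  life_table(age, qx)
}

#' Remaining life expectancy implied by a life table
#'
#' Curtate expectation plus one half year: `sum_k prod_{j<k} (1 - qx)` over
#' the remaining ages, + 0.5 for the part-year lived in the year of death.
#'
#' @param lt A [life_table()].
#' @param age Current (integer) age.
#' @return Expected remaining years of life.
#' @export
life_expectancy <- function(lt, age) {
  if (age < lt$age[1] || age > attr(lt, "max_age"))
    stop("age ", age, " outside life table range", call. = FALSE)
  q <- lt$qx[lt$age >= age]
  surv <- cumprod(1 - q)
  sum(surv) + 0.5
}

#' Fit the Gompertz scale to a life-expectancy target
#'
#' Solves for the hazard scale `a` such that the synthesized table has the
#' requested remaining life expectancy at a reference age, by bisection on
#' the (monotone) expectancy-in-`a` relationship.
#'
#' @param b Hazard slope per year.
#' @param target_le Target remaining life expectancy in years.
#' @param at_age Reference age.
#' @param max_age Cap of the synthesized table.
#' @return The fitted scale `a`.
#' @export
fit_gompertz_scale <- function(b = 0.085, target_le = 21, at_age = 62,
                               max_age = 100) {
  f <- function(log_a) {
    lt <- synthesize_life_table(exp(log_a), b, min_age = 0, max_age = max_age)
    life_expectancy(lt, at_age) - target_le
  }
  exp(stats::uniroot(f, c(log(1e-12), log(1e-1)), tol = 1e-12)$root)
}

#' Default synthetic life table
#'
#' A Gompertz table (slope 0.085/year, scale fitted so that remaining life
#' expectancy at age 62 is about 21 years) spanning ages 0-100. It stands in
#' for an official national life table so that all analyses run without
#' external data; reproducing published results that used the US Life Tables
#' 2015 exactly requires loading that table via [load_life_table()].
#'
#' @param quiet Suppress the provenance message.
#' @return A [life_table()].
#' @export
default_life_table <- function(quiet = FALSE) {
  if (!quiet)
    message("Using the synthetic Gompertz life table (LE at 62 ~ 21 y). ",
            "Supply a real national life table via load_life_table() to ",
            "reproduce published age-specific mortality exactly.")
  a <- fit_gompertz_scale(b = 0.085, target_le = 21, at_age = 62,
                          max_age = 100)
  synthesize_life_table(a, 0.085, min_age = 0, max_age = 100)
}

#' Monthly background death probability at an attained age
#'
#' Converts the annual probability for the attained integer age (the floor of
#' age in years) to a monthly probability under a constant hazard within the
#' year: `1 - (1 - q_annual)^(1/12)`. At or beyond the table cap the
#' probability is 1.
#'
#' @param lt A [life_table()].
#' @param age_months Current age in months.
#' @return Monthly probability of background death.
#' @export
monthly_background_death_prob <- function(lt, age_months) {
  age <- floor(age_months / 12)
  if (any(age < lt$age[1]))
    stop("age below life table start (", lt$age[1], ")", call. = FALSE)
  max_age <- attr(lt, "max_age")
  q <- numeric(length(age))
  over <- age >= max_age
  q[over] <- 1
  if (any(!over))
    q[!over] <- lt$qx[match(age[!over], lt$age)]
  1 - (1 - q)^(1 / 12)
}
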