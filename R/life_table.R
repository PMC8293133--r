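#' Construct a synthetic male life table from a Gompertz hazard
#'
#' Generates an age-indexed table of annual death probabilities
#' `q_annual(age) = min(1, a * exp(b * age))`. The Gompertz form is a
#' standard two-parameter description of adult all-cause mortality and
#' stands in for a national male life table: `a` sets the level, `b` the
#' log-linear increase with age.
#'
#' @param a Baseline hazard scale, > 0 (e.g. `3e-5`).
#' @param b Log-hazard slope per year of age, > 0 allowed to be 0 for a
#'   constant-hazard table.
#' @param age_min,age_max Integer age range covered (inclusive); must at
#'   least span the modelled cohort's ages.
#' @return A `life_table`: data frame with columns `age` (integer years)
#'   and `q_annual` (probability of death within the year).
#' @export
#' @examples
#' lt <- make_life_table(3e-5, 0.085, 40, 100)
#' lt$q_annual[lt$age == 60]  # ~0.0049
make_life_table <- function(a, b, age_min = 40L, age_max = 100L) {
  if (!is.numeric(a) || length(a) != 1L || !is.finite(a) || a <= 0)
    stop("`a` must be a single positive number", call. = FALSE)
  if (!is.numeric(b) || length(b) != 1L || !is.finite(b) || b < 0)
    stop("`b` must be a single non-negative number", call. = FALSE)
  if (age_min >= age_max)
    stop("`age_min` must be below `age_max`", call. = FALSE)
  age <- seq.int(as.integer(age_min), as.integer(age_max))
  q <- pmin(1, a * exp(b * age))
  life_table(data.frame(age = age, q_annual = q))
}

#' Validate and class a life table
#'
#' @param df Data frame with integer `age` and `q_annual` columns; ages must
#'   be strictly increasing and contiguous, probabilities in \[0, 1\].
#' @return The validated `life_table` object.
#' @export
life_table <- function(df) {
  stopifnot(is.data.frame(df), all(c("age", "q_annual") %in% names(df)))
  age <- df$age
  if (any(diff(age) != 1L))
    stop("life table ages must be strictly increasing and contiguous",
         call. = FALSE)
  if (any(df$q_annual < 0 | df$q_annual > 1))
    stop("life table q_annual values must lie in [0, 1]", call. = FALSE)
  out <- data.frame(age = as.integer(age), q_annual = as.numeric(df$q_annual))
  class(out) <- c("life_table", "data.frame")
  out
}

#' @rdname life_table
#' @param path CSV file with header `age,q_annual`.
#' @export
read_life_table <- function(path) {
  life_table(utils::read.csv(path))
}

#' @rdname life_table
#' @param lt A `life_table`.
#' @export
write_life_table <- function(lt, path) {
  stopifnot(inherits(lt, "life_table"))
  utils::write.csv(as.data.frame(lt), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Convert an annual probability to a shorter cycle
#'
#' Assumes a constant hazard within the year, so the per-cycle probability is
#' `1 - (1 - p_annual)^cycle_years`; two half-year cycles compose back to the
#' annual probability.
#'
#' @param p_annual Annual event probability, in \[0, 1\] (vectorised).
#' @param cycle_years Cycle length in years (default 0.5).
#' @return Per-cycle probability.
#' @export
#' @examples
#' annual_prob_to_cycle(0.01, 0.5)  # ~0.0050126
annual_prob_to_cycle <- function(p_annual, cycle_years = 0.5) {
  if (any(!is.finite(p_annual)) || any(p_annual < 0 | p_annual > 1))
    stop("`p_annual` must lie in [0, 1]", call. = FALSE)
  1 - (1 - p_annual)^cycle_years
}

# Annual death probability at (possibly fractional) age: looked up at the
# completed integer age. Errors when the table does not cover the age.
.q_annual_at <- function(lt, age) {
  idx <- match(floor(age), lt$age)
  if (anyNA(idx))
    stop("life table does not cover age(s) ",
         paste(unique(floor(age)[is.na(idx)]), collapse = ", "), call. = FALSE)
  lt$q_annual[idx]
}

# Per-cycle baseline death probabilities for cycles 1..n_cycles, including
# the modality's relative-risk multiplier (recycled to n_cycles), capped at 1.
.cycle_death_probs <- function(lt, cfg, mortality_rr = 1) {
  k <- seq_len(cfg$n_cycles)
  ages <- cfg$start_age + (k - 1) * cfg$cycle_years
  q <- .q_annual_at(lt, ages)
  rr <- rep_len(mortality_rr, cfg$n_cycles)
  if (any(rr <= 0)) stop("mortality_rr entries must be > 0", call. = FALSE)
  pmin(1, annual_prob_to_cycle(q, cfg$cycle_years) * rr)
}
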