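#' Markov model settings
#'
#' The base case follows Canadian economic evaluation practice for this
#' indication: 6-month cycles over a 20-year horizon for a cohort entering
#' at age 60, a 1.5% annual discount rate on both costs and QALYs, and a
#' half-cycle correction (trapezoid averaging of cycle-boundary occupancies
#' with discounting at cycle midpoints).
#'
#' @param cycle_years Cycle length in years (default 0.5).
#' @param horizon_years Time horizon in years (default 20); must be an
#'   integer multiple of `cycle_years`.
#' @param annual_discount Annual discount rate applied to costs and QALYs
#'   (default 0.015), >= 0.
#' @param start_age Cohort age at model entry (default 60).
#' @param half_cycle_correction Apply the half-cycle correction (default
#'   `TRUE`); when `FALSE`, end-of-cycle occupancy and end-of-cycle
#'   discounting are used.
#' @param late_to_recurrence May patients in a late-toxicity state move to
#'   recurrence (default `TRUE`, at the modality's per-cycle recurrence
#'   probability)?
#' @param late_resolution_prob Per-cycle probability that a late toxicity
#'   resolves back to healthy (default 0 = chronic/permanent).
#' @return A `model_config` object with derived field `n_cycles`.
#' @export
model_config <- function(cycle_years = 0.5, horizon_years = 20,
                         annual_discount = 0.015, start_age = 60,
                         half_cycle_correction = TRUE,
                         late_to_recurrence = TRUE,
                         late_resolution_prob = 0) {
  if (cycle_years <= 0 || horizon_years <= 0)
    stop("cycle and horizon must be positive", call. = FALSE)
  n_cycles <- horizon_years / cycle_years
  if (abs(n_cycles - round(n_cycles)) > 1e-9)
    stop("`horizon_years` must be an integer multiple of `cycle_years`",
         call. = FALSE)
  if (annual_discount < 0)
    stop("`annual_discount` must be >= 0", call. = FALSE)
  if (late_resolution_prob < 0 || late_resolution_prob > 1)
    stop("`late_resolution_prob` must lie in [0, 1]", call. = FALSE)
  structure(list(cycle_years = cycle_years, horizon_years = horizon_years,
                 n_cycles = as.integer(round(n_cycles)),
                 annual_discount = annual_discount, start_age = start_age,
                 half_cycle_correction = isTRUE(half_cycle_correction),
                 late_to_recurrence = isTRUE(late_to_recurrence),
                 late_resolution_prob = late_resolution_prob),
            class = "model_config")
}

# Conditional-on-survival transition matrix over the alive states (the dead
# row is the identity). Competing events within a row are combined as
# independent indicators with a fixed severity priority (recurrence, then GU,
# then GI toxicity); death is applied afterwards and takes precedence over
# everything, which matches exhaustive enumeration over independent event
# indicators.
.cond_matrix <- function(arm, cfg, first_cycle) {
  p <- arm$p
  A <- diag(7)
  dimnames(A) <- list(STATES, STATES)
  if (first_cycle) {
    pg <- p[["acute_gu"]]
    pi_ <- p[["acute_gi"]]
    A["healthy", ] <- 0
    A["healthy", "acute_gu"] <- pg
    A["healthy", "acute_gi"] <- (1 - pg) * pi_
    A["healthy", "healthy"] <- (1 - pg) * (1 - pi_)
  } else {
    pr <- p[["recurrence"]]
    pg <- p[["late_gu"]]
    pi_ <- p[["late_gi"]]
    A["healthy", ] <- 0
    A["healthy", "recurrence"] <- pr
    A["healthy", "late_gu"] <- (1 - pr) * pg
    A["healthy", "late_gi"] <- (1 - pr) * (1 - pg) * pi_
    A["healthy", "healthy"] <- (1 - pr) * (1 - pg) * (1 - pi_)
    # acute toxicity lasts exactly one cycle
    A["acute_gu", ] <- 0; A["acute_gu", "healthy"] <- 1
    A["acute_gi", ] <- 0; A["acute_gi", "healthy"] <- 1
    prl <- if (cfg$late_to_recurrence) pr else 0
    res <- cfg$late_resolution_prob
    for (s in c("late_gu", "late_gi")) {
      A[s, ] <- 0
      A[s, "recurrence"] <- prl
      A[s, "healthy"] <- (1 - prl) * res
      A[s, s] <- (1 - prl) * (1 - res)
    }
  }
  A
}

# Compose the conditional matrix with per-row survival probabilities:
# alive rows are scaled by their survival probability and the complement
# goes to DEAD. surv has length 7 with surv[dead] = 1.
.apply_death <- function(A, surv) {
  M <- A * surv          # recycles surv down columns = row scaling
  M[, "dead"] <- M[, "dead"] + (1 - surv)
  M
}

.row_surv <- function(d, d_rec) c(rep.int(1 - d, 5L), 1 - d_rec, 1)

#' Single-cycle transition matrix
#'
#' Builds the 7-state transition matrix (healthy, acute GU, acute GI, late
#' GU, late GI, recurrence, dead) for one cycle of one modality under one
#' parameter realization. In the first cycle the cohort can move from entry
#' to acute toxicity or death; from the second cycle on, acute states
#' return to healthy, healthy can move to late toxicity or recurrence, late
#' states persist (optionally resolving or progressing to recurrence), and
#' recurrence persists until death. Death competes with every event: the
#' per-cycle death probability is the age-specific annual rate converted to
#' the cycle length times the modality's relative risk (times the
#' recurrence-state multiplier in the recurrence row), capped at 1.
#'
#' @param arm Arm realization (see [spec_means()]).
#' @param shared Shared realization (for `recurrence_mortality_rr`).
#' @param cycle_index Cycle number, 1-based.
#' @param lt A [life_table()].
#' @param cfg A [model_config()].
#' @return 7 x 7 row-stochastic matrix with dimnames `STATES`.
#' @export
build_transition_matrix <- function(arm, shared, cycle_index, lt, cfg) {
  if (cycle_index < 1L || cycle_index > cfg$n_cycles)
    stop("`cycle_index` out of range", call. = FALSE)
  .check_probs(arm)
  d_all <- .cycle_death_probs(lt, cfg, arm$mortality_rr)
  d <- d_all[cycle_index]
  d_rec <- min(1, d * shared$recurrence_mortality_rr)
  A <- .cond_matrix(arm, cfg, first_cycle = (cycle_index == 1L))
  .apply_death(A, .row_surv(d, d_rec))
}

.check_probs <- function(arm) {
  p <- unlist(arm$p)
  bad <- names(p)[p < 0 | p > 1 | !is.finite(p)]
  if (length(bad))
    stop("infeasible event probabilities (outside [0, 1]) for ",
         arm$name %||% "arm", ": ", paste(bad, collapse = ", "),
         call. = FALSE)
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the cohort through the Markov model
#'
#' Starts the whole cohort in the healthy entry state and propagates it
#' through `cfg$n_cycles` transition matrices, recording state occupancy at
#' every cycle boundary and the per-cycle flow of patients newly entering
#' each state (the recurrence entry flow triggers the one-time salvage
#' cost).
#'
#' @inheritParams build_transition_matrix
#' @return A `cohort_trace`: list with `occupancy` ((n_cycles + 1) x 7
#'   matrix, rows = cycle boundaries 0..n), `entry_flows` (n_cycles x 7),
#'   and `cfg`.
#' @export
run_cohort <- function(arm, shared, lt, cfg) {
  .check_probs(arm)
  n <- cfg$n_cycles
  d <- .cycle_death_probs(lt, cfg, arm$mortality_rr)
  d_rec <- pmin(1, d * shared$recurrence_mortality_rr)
  A1 <- .cond_matrix(arm, cfg, first_cycle = TRUE)
  A2 <- .cond_matrix(arm, cfg, first_cycle = FALSE)
  occ <- matrix(0, n + 1L, 7L, dimnames = list(0:n, STATES))
  flows <- matrix(0, n, 7L, dimnames = list(1:n, STATES))
  occ[1L, "healthy"] <- 1
  v <- occ[1L, ]
  for (k in seq_len(n)) {
    M <- .apply_death(if (k == 1L) A1 else A2, .row_surv(d[k], d_rec[k]))
    nxt <- drop(v %*% M)
    flows[k, ] <- nxt - v * diag(M)
    occ[k + 1L, ] <- nxt
    v <- nxt
  }
  structure(list(occupancy = occ, entry_flows = flows, cfg = cfg),
            class = "cohort_trace")
}

#' @export
print.cohort_trace <- function(x, ...) {
  n <- nrow(x$occupancy) - 1L
  cat(sprintf("<cohort_trace> %d cycles; final: %.1f%% dead, %.1f%% in recurrence\n",
              n, 100 * x$occupancy[n + 1L, "dead"],
              100 * x$occupancy[n + 1L, "recurrence"]))
  invisible(x)
}

#' Export a cohort trace as a cycle-by-state table
#'
#' @param trace A `cohort_trace`.
#' @return Tibble with `cycle` (0..n), `years`, and one occupancy column
#'   per state.
#' @export
trace_table <- function(trace) {
  stopifnot(inherits(trace, "cohort_trace"))
  cyc <- seq_len(nrow(trace$occupancy)) - 1L
  tibble::as_tibble(cbind(
    data.frame(cycle = cyc, years = cyc * trace$cfg$cycle_years),
    as.data.frame(trace$occupancy, row.names = FALSE)))
}

#' Accumulate discounted costs and QALYs over a cohort trace
#'
#' Per-cycle accruals use the half-cycle correction: state occupancy is
#' averaged over the cycle's two boundaries (trapezoid rule) and discounted
#' at the cycle midpoint, `d(k) = (1 + r)^{-(k - 0.5) * cycle_years}`.
#' QALYs accrue `cycle_years * utility` per person-cycle; state costs are
#' 6-month management costs per person-cycle. The one-time salvage cost is
#' applied to the recurrence entry flow at the cycle it occurs; the index
#' treatment cost is applied at time 0 and is not discounted. Utilities are
#' `1 - disutility`, clamped to \[0, 1\], with dead = 0.
#'
#' @param trace A `cohort_trace` from [run_cohort()].
#' @param costs List with `state_costs` (named vector over `STATES`, CAD
#'   per cycle), `index_cost`, `salvage_cost`.
#' @param utilities Named vector of per-state utilities over `STATES`
#'   (dead must be 0).
#' @param cfg A [model_config()].
#' @return An `econ_result`: list with discounted `total_cost`,
#'   `total_qaly` and undiscounted counterparts, plus a cost breakdown.
#' @export
accumulate_outcomes <- function(trace, costs, utilities, cfg) {
  stopifnot(inherits(trace, "cohort_trace"))
  sc <- costs$state_costs[STATES]
  if (anyNA(sc) || any(sc < 0))
    stop("state costs must be defined and >= 0 for every state",
         call. = FALSE)
  u <- pmin(pmax(utilities[STATES], 0), 1)
  if (anyNA(u)) stop("utilities must be defined for every state",
                     call. = FALSE)
  if (u[["dead"]] != 0) stop("dead-state utility must be 0", call. = FALSE)
  n <- cfg$n_cycles
  occ <- trace$occupancy
  # per-cycle effective occupancy: trapezoid average of the boundaries under
  # the half-cycle correction, else end-of-cycle occupancy
  eff <- if (cfg$half_cycle_correction)
    (occ[seq_len(n), , drop = FALSE] + occ[seq_len(n) + 1L, , drop = FALSE]) / 2
  else occ[seq_len(n) + 1L, , drop = FALSE]
  k <- seq_len(n)
  t_disc <- if (cfg$half_cycle_correction) (k - 0.5) * cfg$cycle_years
            else k * cfg$cycle_years
  disc <- (1 + cfg$annual_discount)^(-t_disc)
  qaly_cycle <- cfg$cycle_years * drop(eff %*% u)
  state_cost_cycle <- drop(eff %*% sc)
  salvage_cycle <- trace$entry_flows[, "recurrence"] * costs$salvage_cost
  res <- list(
    total_cost = costs$index_cost + sum((state_cost_cycle + salvage_cycle) * disc),
    total_qaly = sum(qaly_cycle * disc),
    undiscounted_cost = costs$index_cost + sum(state_cost_cycle + salvage_cycle),
    undiscounted_qaly = sum(qaly_cycle),
    cost_breakdown = c(index = costs$index_cost,
                       state = sum(state_cost_cycle * disc),
                       salvage = sum(salvage_cycle * disc)))
  structure(res, class = "econ_result")
}

#' @export
print.econ_result <- function(x, ...) {
  cat(sprintf("<econ_result> cost $%.0f, %.3f QALYs (undiscounted $%.0f, %.3f)\n",
              x$total_cost, x$total_qaly, x$undiscounted_cost,
              x$undiscounted_qaly))
  invisible(x)
}

#' Run one modality arm end to end
#'
#' Convenience wrapper: builds the trace with [run_cohort()] and accumulates
#' outcomes with the shared realization's costs and dis-utilities.
#'
#' @inheritParams run_cohort
#' @return An `econ_result`.
#' @export
run_arm <- function(arm, shared, lt, cfg) {
  trace <- run_cohort(arm, shared, lt, cfg)
  du <- shared$disutilities
  u <- c(healthy = 1,
         acute_gu = 1 - du[["acute_gu"]], acute_gi = 1 - du[["acute_gi"]],
         late_gu = 1 - du[["late_gu"]], late_gi = 1 - du[["late_gi"]],
         recurrence = 1 - du[["recurrence"]], dead = 0)
  costs <- list(state_costs = shared$state_costs,
                index_cost = arm$index_cost,
                salvage_cost = shared$salvage_cost)
  accumulate_outcomes(trace, costs, u, cfg)
}

#' Deterministic model run at parameter means
#'
#' Runs all six modalities with every parameter fixed at its mean.
#'
#' @param spec A [parameter_spec()].
#' @param cfg A [model_config()].
#' @return Tibble with one row per modality: `name`, `cost`, `qaly`,
#'   `undiscounted_cost`, `undiscounted_qaly`.
#' @export
#' @examples
#' \donttest{
#' deterministic_run(calibrated_reference_spec())
#' }
deterministic_run <- function(spec, cfg = model_config()) {
  real <- spec_means(spec)
  rows <- lapply(real$arms, function(arm) {
    r <- run_arm(arm, real$shared, spec$life_table, cfg)
    tibble::tibble(name = arm$name, cost = r$total_cost,
                   qaly = r$total_qaly,
                   undiscounted_cost = r$undiscounted_cost,
                   undiscounted_qaly = r$undiscounted_qaly)
  })
  do.call(rbind, rows)
}
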