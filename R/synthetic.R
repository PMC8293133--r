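#' Published probabilistic averages for the six modalities
#'
#' The per-modality mean total cost (2018 CAD) and QALY totals reported by
#' the published Canadian cost-utility comparison of these six radiation
#' modalities (probabilistic averages over 20,000 Monte Carlo iterations).
#' They serve as calibration targets for [calibrated_reference_spec()] and
#' as the worked example for [icur_frontier()].
#'
#' @return Tibble with `name`, `cost`, `qaly`.
#' @export
#' @examples
#' reference_strategies()
reference_strategies <- function() {
  tibble::tibble(
    name = c("LDR-b", "SBRT", "HDR-b", "hfIMRT", "HDR-IMRT", "cfIMRT"),
    cost = c(8940, 10048, 9187, 14332, 16939, 19903),
    qaly = c(11.00, 11.38, 10.63, 10.86, 9.95, 10.59))
}

# Fixed plausible toxicity profiles used by the calibrated spec: first-cycle
# acute probabilities and per-cycle late probabilities, ordered roughly by
# the irradiated volume / fractionation of each technique.
.calibration_toxicity <- function() {
  list(
    cfIMRT     = c(acute_gu = 0.40, acute_gi = 0.30, late_gu = 0.006, late_gi = 0.005),
    hfIMRT     = c(acute_gu = 0.35, acute_gi = 0.25, late_gu = 0.005, late_gi = 0.004),
    "HDR-IMRT" = c(acute_gu = 0.45, acute_gi = 0.20, late_gu = 0.007, late_gi = 0.004),
    "HDR-b"    = c(acute_gu = 0.30, acute_gi = 0.10, late_gu = 0.005, late_gi = 0.002),
    "LDR-b"    = c(acute_gu = 0.35, acute_gi = 0.12, late_gu = 0.006, late_gi = 0.002),
    SBRT       = c(acute_gu = 0.25, acute_gi = 0.15, late_gu = 0.004, late_gi = 0.003))
}

.calibration_shared <- function(lt) {
  fx <- function(m) dist_spec("fixed", m)
  list(state_costs = list(healthy = fx(75), acute_gu = fx(1500),
                          acute_gi = fx(1200), late_gu = fx(500),
                          late_gi = fx(450), recurrence = fx(800)),
       salvage_cost = fx(5000),
       disutilities = list(acute_gu = fx(0.10), acute_gi = fx(0.08),
                           late_gu = fx(0.15), late_gi = fx(0.12),
                           recurrence = fx(0.30)),
       life_table = lt,
       recurrence_mortality_rr = 2)
}

# Arm realization for calibration: fixed toxicities, free recurrence
# probability and common mortality RR.
.calib_arm <- function(name, tox, p_rec, rr) {
  list(name = name,
       p = c(tox[c("acute_gu", "acute_gi", "late_gu", "late_gi")],
             recurrence = p_rec),
       mortality_rr = rr, index_cost = 0)
}

.calib_shared_real <- function(sh) {
  list(state_costs = c(.means_of(sh$state_costs), dead = 0),
       salvage_cost = sh$salvage_cost$mean,
       disutilities = .means_of(sh$disutilities),
       recurrence_mortality_rr = sh$recurrence_mortality_rr)
}

#' Zero-variance specification calibrated to the published averages
#'
#' Builds an all-fixed [parameter_spec()] whose deterministic model run
#' reproduces each modality's published mean total cost (within 1%) and
#' QALY total (within 0.02). Because the study's appendix inputs are not
#' published, the calibration treats the published outputs as the ground
#' truth and solves for inputs that reproduce them: a common mortality
#' relative risk is first solved so the least-toxic arm without recurrence
#' has a small QALY headroom above the highest target; each modality's
#' per-cycle recurrence probability is then solved by 1-D root finding to
#' hit its QALY target (QALYs are monotone decreasing in recurrence risk);
#' finally the index cost absorbs the cost residual,
#' `index = target cost - modelled downstream cost`, which is exact because
#' the index cost affects cost only (a triangular system).
#'
#' The result is cached for the session; the procedure is deterministic, so
#' repeated calls return identical specifications.
#'
#' @param targets Data frame `name`, `cost`, `qaly`; defaults to
#'   [reference_strategies()].
#' @param cfg A [model_config()].
#' @return A [parameter_spec()] with attribute `"calibration"`: a tibble of
#'   per-modality targets, modelled values and residuals.
#' @export
calibrated_reference_spec <- function(targets = reference_strategies(),
                                      cfg = model_config()) {
  is_default <- identical(targets, reference_strategies()) &&
    identical(cfg, model_config())
  if (is_default && !is.null(.cache$calibrated)) return(.cache$calibrated)
  lt <- make_life_table(3e-5, 0.085, 40, 100)
  sh <- .calibration_shared(lt)
  shared_real <- .calib_shared_real(sh)
  tox <- .calibration_toxicity()
  if (!all(targets$name %in% names(tox)))
    stop("targets must use the six canonical modality names", call. = FALSE)
  qaly_of <- function(arm) run_arm(arm, shared_real, lt, cfg)$total_qaly
  # common mortality RR: least-toxic arm with no recurrence sits a small
  # headroom above the largest QALY target
  top <- targets$name[which.max(targets$qaly)]
  q_goal <- max(targets$qaly) + 0.10
  f_rr <- function(r) qaly_of(.calib_arm(top, tox[[top]], 0, r)) - q_goal
  if (f_rr(0.05) < 0 || f_rr(60) > 0)
    stop("calibration failure: maximum QALY target ", max(targets$qaly),
         " outside attainable range [",
         round(qaly_of(.calib_arm(top, tox[[top]], 0, 60)), 3), ", ",
         round(qaly_of(.calib_arm(top, tox[[top]], 0, 0.05)), 3), "]",
         call. = FALSE)
  rr <- stats::uniroot(f_rr, c(0.05, 60), tol = 1e-10)$root
  mods <- vector("list", nrow(targets))
  names(mods) <- targets$name
  for (i in seq_len(nrow(targets))) {
    nm <- targets$name[i]
    f <- function(p) qaly_of(.calib_arm(nm, tox[[nm]], p, rr)) -
      targets$qaly[i]
    if (f(0) < 0 || f(0.6) > 0)
      stop("calibration failure for ", nm, ": QALY target ",
           targets$qaly[i], " outside attainable range [",
           round(qaly_of(.calib_arm(nm, tox[[nm]], 0.6, rr)), 3), ", ",
           round(qaly_of(.calib_arm(nm, tox[[nm]], 0, rr)), 3), "]",
           call. = FALSE)
    p_rec <- stats::uniroot(f, c(0, 0.6), tol = 1e-12)$root
    downstream <- run_arm(.calib_arm(nm, tox[[nm]], p_rec, rr),
                          shared_real, lt, cfg)$total_cost
    index <- targets$cost[i] - downstream
    if (index <= 0)
      stop("calibration failure for ", nm,
           ": downstream cost exceeds the target total", call. = FALSE)
    fx <- function(m) dist_spec("fixed", m)
    mods[[nm]] <- modality_profile(
      nm,
      event_probs = list(acute_gu = fx(tox[[nm]][["acute_gu"]]),
                         acute_gi = fx(tox[[nm]][["acute_gi"]]),
                         late_gu = fx(tox[[nm]][["late_gu"]]),
                         late_gi = fx(tox[[nm]][["late_gi"]]),
                         recurrence = fx(p_rec)),
      index_cost = fx(index),
      mortality_rr = rr)
  }
  spec <- parameter_spec(modalities = mods, state_costs = sh$state_costs,
                         salvage_cost = sh$salvage_cost,
                         disutilities = sh$disutilities, life_table = lt,
                         recurrence_mortality_rr = sh$recurrence_mortality_rr)
  resid <- calibration_residuals(spec, targets, cfg)
  if (any(resid$cost_rel_residual > 0.01) ||
      any(resid$qaly_abs_residual > 0.02))
    stop("calibration failed to converge; residuals:\n",
         paste(utils::capture.output(print(resid)), collapse = "\n"),
         call. = FALSE)
  attr(spec, "calibration") <- resid
  if (is_default) .cache$calibrated <- spec
  spec
}

#' Residuals of a specification against target costs and QALYs
#'
#' @param spec A [parameter_spec()].
#' @param targets Data frame `name`, `cost`, `qaly`.
#' @param cfg A [model_config()].
#' @return Tibble per modality: targets, modelled values, relative cost
#'   residual and absolute QALY residual.
#' @export
calibration_residuals <- function(spec, targets = reference_strategies(),
                                  cfg = model_config()) {
  det <- deterministic_run(spec, cfg)
  i <- match(targets$name, det$name)
  tibble::tibble(
    name = targets$name,
    target_cost = targets$cost, model_cost = det$cost[i],
    target_qaly = targets$qaly, model_qaly = det$qaly[i],
    cost_rel_residual = abs(det$cost[i] - targets$cost) / targets$cost,
    qaly_abs_residual = abs(det$qaly[i] - targets$qaly))
}

#' Seeded plausible parameter specification
#'
#' Generates a fully populated, internally consistent specification
#' emulating the structure of the study's appendix input tables: six
#' modality profiles with distinct acute/late toxicity and recurrence
#' probability means (beta-distributed), index costs built from the
#' micro-costing calculator with modest gamma uncertainty, shared 6-month
#' event and management costs with deliberately wide gamma uncertainty
#' (coefficient of variation 0.5, reflecting the high uncertainty of
#' post-treatment costs across health systems), and dis-utilities ranked
#' acute < late < recurrence in severity.
#'
#' @param seed Integer seed; the same seed always returns the same spec.
#' @return A [parameter_spec()].
#' @export
#' @examples
#' sp <- default_spec(1)
#' identical(sp, default_spec(1))
default_spec <- function(seed) {
  set.seed(seed)
  lt <- make_life_table(3e-5, 0.085, 40, 100)
  runifr <- function(lo, hi) stats::runif(1L, lo, hi)
  beta_cv <- function(m, cv = 0.2)
    dist_spec("beta", m, min(cv * m, 0.85 * sqrt(m * (1 - m))))
  gamma_cv <- function(m, cv) dist_spec("gamma", m, cv * m)
  # per-modality machine/staffing costing (illustrative 2018 CAD magnitudes)
  machine <- list(
    cfIMRT = costing_inputs(supply_cost = 300, oper = 1.2e6, amort = 5e5,
                            maint = 2e5, annual_fractions = 8000,
                            staffing_cost_per_course = 2500,
                            physician_fee = 3000),
    hfIMRT = costing_inputs(supply_cost = 300, oper = 1.2e6, amort = 5e5,
                            maint = 2e5, annual_fractions = 8000,
                            staffing_cost_per_course = 2200,
                            physician_fee = 2800),
    "HDR-IMRT" = costing_inputs(supply_cost = 1200, oper = 1.2e6,
                                amort = 5e5, maint = 2e5,
                                annual_fractions = 8000,
                                staffing_cost_per_course = 3500,
                                physician_fee = 3500, procedure_hours = 3,
                                hourly_procedure_rate = 800),
    "HDR-b" = costing_inputs(supply_cost = 1500, oper = 3e5, amort = 2e5,
                             maint = 1e5, annual_fractions = 600,
                             staffing_cost_per_course = 2000,
                             physician_fee = 2500, procedure_hours = 4,
                             hourly_procedure_rate = 800),
    "LDR-b" = costing_inputs(supply_cost = 4000, oper = 1e5, amort = 1e5,
                             maint = 5e4, annual_fractions = 400,
                             staffing_cost_per_course = 1800,
                             physician_fee = 2500, procedure_hours = 3,
                             hourly_procedure_rate = 800),
    SBRT = costing_inputs(supply_cost = 400, oper = 1.2e6, amort = 5e5,
                          maint = 2e5, annual_fractions = 4000,
                          staffing_cost_per_course = 2800,
                          physician_fee = 3200))
  mods <- lapply(.modality_names(), function(nm) {
    ep <- list(acute_gu = beta_cv(runifr(0.10, 0.45)),
               acute_gi = beta_cv(runifr(0.05, 0.30)),
               late_gu = beta_cv(runifr(0.002, 0.010)),
               late_gi = beta_cv(runifr(0.002, 0.008)),
               recurrence = beta_cv(runifr(0.004, 0.020)))
    ic_mean <- index_treatment_cost(modality_fractions()[[nm]], machine[[nm]])
    modality_profile(nm, event_probs = ep,
                     index_cost = gamma_cv(ic_mean, 0.10),
                     mortality_rr = 2.5, costing = machine[[nm]])
  })
  names(mods) <- .modality_names()
  jitter <- function(m) m * runifr(0.8, 1.2)
  state_costs <- list(healthy = gamma_cv(jitter(100), 0.5),
                      acute_gu = gamma_cv(jitter(1800), 0.5),
                      acute_gi = gamma_cv(jitter(1500), 0.5),
                      late_gu = gamma_cv(jitter(700), 0.5),
                      late_gi = gamma_cv(jitter(600), 0.5),
                      recurrence = gamma_cv(jitter(1200), 0.5))
  disutilities <- list(acute_gu = beta_cv(runifr(0.05, 0.12)),
                       acute_gi = beta_cv(runifr(0.04, 0.10)),
                       late_gu = beta_cv(runifr(0.12, 0.20)),
                       late_gi = beta_cv(runifr(0.10, 0.18)),
                       recurrence = beta_cv(runifr(0.25, 0.40)))
  parameter_spec(modalities = mods, state_costs = state_costs,
                 salvage_cost = gamma_cv(jitter(8000), 0.5),
                 disutilities = disutilities, life_table = lt,
                 recurrence_mortality_rr = 2)
}

#' Attach probabilistic uncertainty to a fixed specification
#'
#' Converts the fixed parameters of a specification (typically
#' [calibrated_reference_spec()]) into distributions for probabilistic
#' analysis: probabilities and dis-utilities become beta with the given
#' coefficient of variation (standard errors capped below the beta
#' feasibility bound), state/salvage costs become gamma with a wide CV, and
#' index costs gamma with a modest CV (micro-costed inputs are better
#' known than downstream management costs). Parameter means are unchanged.
#'
#' @param spec A [parameter_spec()].
#' @param cv_prob CV for event probabilities (default 0.2).
#' @param cv_cost CV for state, event and salvage costs (default 0.4).
#' @param cv_index CV for index treatment costs (default 0.1).
#' @param cv_disutility CV for dis-utilities (default 0.2).
#' @return A [parameter_spec()] with the same means and nonzero variances.
#' @export
add_default_uncertainty <- function(spec, cv_prob = 0.2, cv_cost = 0.4,
                                    cv_index = 0.1, cv_disutility = 0.2) {
  stopifnot(inherits(spec, "parameter_spec"))
  to_beta <- function(sp, cv) {
    m <- sp$mean
    if (m <= 0 || m >= 1) return(sp)
    dist_spec("beta", m, min(cv * m, 0.85 * sqrt(m * (1 - m))))
  }
  to_gamma <- function(sp, cv) {
    if (sp$mean <= 0) return(sp)
    dist_spec("gamma", sp$mean, cv * sp$mean)
  }
  mods <- lapply(spec$modalities, function(m) {
    modality_profile(m$name,
                     event_probs = lapply(m$event_probs, to_beta, cv = cv_prob),
                     index_cost = to_gamma(m$index_cost, cv_index),
                     n_fractions = m$n_fractions,
                     mortality_rr = m$mortality_rr, costing = m$costing)
  })
  parameter_spec(
    modalities = mods,
    state_costs = lapply(spec$state_costs, to_gamma, cv = cv_cost),
    salvage_cost = to_gamma(spec$salvage_cost, cv_cost),
    disutilities = lapply(spec$disutilities, to_beta, cv = cv_disutility),
    life_table = spec$life_table,
    recurrence_mortality_rr = spec$recurrence_mortality_rr)
}
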