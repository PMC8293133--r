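#' Radiotherapy micro-costing inputs for one modality
#'
#' Bundles the components of the index-treatment cost of one radiation
#' course: per-patient supplies, the machine's annualised operating cost
#' apportioned per fraction with an overhead factor, duration-priced
#' procedure time (brachytherapy theatre/anaesthesia time), course-level
#' staffing, and the physician fee-for-service remuneration.
#'
#' @param supply_cost Micro-costing supplies per patient per technique (CAD).
#' @param oper Annual machine operating cost (CAD/year).
#' @param amort Annual amortisation of the capital cost (CAD/year).
#' @param maint Annual maintenance cost (CAD/year).
#' @param overhead_factor Overhead multiplier applied to the annual machine
#'   costs; >= 1, default 1.2.
#' @param annual_fractions Fractions the machine delivers per year, >= 1.
#' @param staffing_cost_per_course Physics/planning plus therapy staffing
#'   cost per treatment course (CAD).
#' @param physician_fee Fee-for-service physician remuneration per course
#'   (CAD).
#' @param procedure_hours Procedure duration priced by the hour (e.g.
#'   brachytherapy implant time); 0 for purely fraction-based modalities.
#' @param hourly_procedure_rate Cost per procedure hour (CAD/hour).
#' @return A `costing_inputs` object.
#' @export
costing_inputs <- function(supply_cost = 0, oper = 0, amort = 0, maint = 0,
                           overhead_factor = 1.2, annual_fractions = 1L,
                           staffing_cost_per_course = 0, physician_fee = 0,
                           procedure_hours = 0, hourly_procedure_rate = 0) {
  money <- c(supply_cost = supply_cost, oper = oper, amort = amort,
             maint = maint, staffing_cost_per_course = staffing_cost_per_course,
             physician_fee = physician_fee,
             hourly_procedure_rate = hourly_procedure_rate)
  if (any(!is.finite(money)) || any(money < 0))
    stop("all monetary costing inputs must be finite and >= 0", call. = FALSE)
  if (overhead_factor < 1)
    stop("`overhead_factor` must be >= 1", call. = FALSE)
  if (annual_fractions < 1)
    stop("`annual_fractions` must be >= 1", call. = FALSE)
  if (procedure_hours < 0)
    stop("`procedure_hours` must be >= 0", call. = FALSE)
  structure(list(supply_cost = supply_cost, oper = oper, amort = amort,
                 maint = maint, overhead_factor = overhead_factor,
                 annual_fractions = as.integer(annual_fractions),
                 staffing_cost_per_course = staffing_cost_per_course,
                 physician_fee = physician_fee,
                 procedure_hours = procedure_hours,
                 hourly_procedure_rate = hourly_procedure_rate),
            class = "costing_inputs")
}

#' Operating cost per delivered fraction
#'
#' The machine's annual operating, amortisation and maintenance costs are
#' summed, inflated by the overhead factor, and divided by the number of
#' fractions the machine delivers per year:
#' `(oper + amort + maint) * overhead_factor / annual_fractions`.
#'
#' @inheritParams costing_inputs
#' @return Cost per fraction (CAD).
#' @export
#' @examples
#' operating_cost_per_fraction(1e6, 2e5, 1e5, 1.2, 8000)  # 195
operating_cost_per_fraction <- function(oper, amort, maint,
                                        overhead_factor = 1.2,
                                        annual_fractions) {
  if (any(c(oper, amort, maint) < 0))
    stop("annual machine costs must be >= 0", call. = FALSE)
  if (annual_fractions < 1)
    stop("`annual_fractions` must be >= 1", call. = FALSE)
  (oper + amort + maint) * overhead_factor / annual_fractions
}

#' Index radiation-treatment cost of a course
#'
#' Sums per-patient supplies, the per-fraction operating cost times the
#' regimen's fraction count, duration-priced procedure time, staffing per
#' course and the physician fee.
#'
#' @param profile A [modality_profile()] (its `n_fractions` prices the
#'   fraction-based component), or a bare positive integer fraction count.
#' @param ci A [costing_inputs()].
#' @return Index treatment cost (CAD).
#' @export
#' @examples
#' ci <- costing_inputs(supply_cost = 500, oper = 1e6, amort = 2e5,
#'                      maint = 1e5, annual_fractions = 8000,
#'                      staffing_cost_per_course = 800, physician_fee = 1200)
#' index_treatment_cost(5L, ci)  # 500 + 5*195 + 800 + 1200 = 3475
index_treatment_cost <- function(profile, ci) {
  stopifnot(inherits(ci, "costing_inputs"))
  n_fractions <- if (inherits(profile, "modality_profile"))
    profile$n_fractions else as.integer(profile)
  if (length(n_fractions) != 1L || is.na(n_fractions) || n_fractions < 1L)
    stop("`n_fractions` must be a positive integer", call. = FALSE)
  opf <- operating_cost_per_fraction(ci$oper, ci$amort, ci$maint,
                                     ci$overhead_factor, ci$annual_fractions)
  ci$supply_cost + opf * n_fractions +
    ci$procedure_hours * ci$hourly_procedure_rate +
    ci$staffing_cost_per_course + ci$physician_fee
}
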