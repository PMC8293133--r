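#' Treatment-arm profile: fractionation, event risks, index cost
#'
#' One modality's inputs to the Markov model: acute toxicity probabilities
#' (applied in the first 6-month cycle), per-cycle late toxicity and
#' recurrence probabilities (applied from the second cycle on), a
#' time-indexed relative-risk multiplier on background mortality, and the
#' index treatment cost.
#'
#' @param name One of `"cfIMRT"`, `"hfIMRT"`, `"HDR-IMRT"`, `"HDR-b"`,
#'   `"LDR-b"`, `"SBRT"`.
#' @param event_probs Named list of [dist_spec()] with entries `acute_gu`,
#'   `acute_gi` (first-cycle probabilities), `late_gu`, `late_gi`,
#'   `recurrence` (per-cycle probabilities); all means in \[0, 1\].
#' @param index_cost A [dist_spec()] for the index treatment cost, or a
#'   single number (treated as fixed).
#' @param n_fractions Fractions per course; defaults to, and for the five
#'   modalities with a stated schedule must equal, [modality_fractions()].
#' @param mortality_rr Relative-risk multiplier(s) on the age-specific
#'   background death probability; a scalar or a vector recycled over
#'   cycles; all entries > 0.
#' @param costing Optional [costing_inputs()] recording how `index_cost`
#'   was derived; when supplied and `index_cost` is missing, the fixed mean
#'   is computed with [index_treatment_cost()].
#' @return A `modality_profile` object.
#' @export
modality_profile <- function(name, event_probs, index_cost = NULL,
                             n_fractions = NULL, mortality_rr = 1,
                             costing = NULL) {
  sched <- modality_fractions()
  if (!name %in% names(sched))
    stop("unknown modality name: ", name, call. = FALSE)
  if (is.null(n_fractions)) n_fractions <- sched[[name]]
  n_fractions <- as.integer(n_fractions)
  if (name != "HDR-IMRT" && n_fractions != sched[[name]])
    stop(sprintf("%s must use %d fractions, got %d", name, sched[[name]],
                 n_fractions), call. = FALSE)
  if (n_fractions < 1L) stop("`n_fractions` must be >= 1", call. = FALSE)
  missing_ev <- setdiff(EVENTS, names(event_probs))
  if (length(missing_ev))
    stop("event_probs missing: ", paste(missing_ev, collapse = ", "),
         call. = FALSE)
  event_probs <- event_probs[EVENTS]
  for (ev in EVENTS) {
    sp <- event_probs[[ev]]
    if (!inherits(sp, "dist_spec"))
      stop("event_probs$", ev, " must be a dist_spec", call. = FALSE)
    if (sp$mean < 0 || sp$mean > 1)
      stop("event probability mean out of [0, 1]: ", ev, call. = FALSE)
  }
  if (is.null(index_cost)) {
    if (is.null(costing))
      stop("supply `index_cost` or `costing`", call. = FALSE)
    index_cost <- dist_spec("fixed",
                            index_treatment_cost(n_fractions, costing))
  }
  if (is.numeric(index_cost)) index_cost <- dist_spec("fixed", index_cost)
  stopifnot(inherits(index_cost, "dist_spec"))
  if (index_cost$mean < 0)
    stop("index cost mean must be >= 0", call. = FALSE)
  if (any(mortality_rr <= 0))
    stop("mortality_rr entries must be > 0", call. = FALSE)
  structure(list(name = name, n_fractions = n_fractions,
                 event_probs = event_probs, mortality_rr = mortality_rr,
                 index_cost = index_cost, costing = costing),
            class = "modality_profile")
}

.shared_cost_states <- c("healthy", "acute_gu", "acute_gi", "late_gu",
                         "late_gi", "recurrence")
.disutility_states <- c("acute_gu", "acute_gi", "late_gu", "late_gi",
                        "recurrence")

#' Full model parameter specification
#'
#' Bundles the six modality profiles with the parameters shared across
#' modalities: 6-month state management costs, the one-time salvage cost
#' triggered on entry to the recurrence state (identical across index
#' treatments), state dis-utilities on the 0-1 relative scale, the
#' multiplier on background mortality while in recurrence, and the life
#' table. Differences between modalities are therefore driven entirely by
#' each modality's event risks and index cost.
#'
#' @param modalities Named list of six [modality_profile()]s covering every
#'   canonical modality.
#' @param state_costs Named list of [dist_spec()]s: 6-month cost of
#'   `healthy` (long-term management), `acute_gu`, `acute_gi`, `late_gu`,
#'   `late_gi`, `recurrence` (post-salvage management).
#' @param salvage_cost [dist_spec()]: one-time salvage-treatment cost on
#'   recurrence entry.
#' @param disutilities Named list of [dist_spec()]s for `acute_gu`,
#'   `acute_gi`, `late_gu`, `late_gi`, `recurrence`; means in \[0, 1\].
#'   State utility is `1 - disutility` (healthy 1, dead 0).
#' @param life_table A [life_table()].
#' @param recurrence_mortality_rr Multiplier (>= 1) on the per-cycle death
#'   probability while in the recurrence state; default 1 (no excess).
#' @return A `parameter_spec` object.
#' @export
parameter_spec <- function(modalities, state_costs, salvage_cost,
                           disutilities, life_table,
                           recurrence_mortality_rr = 1) {
  if (!setequal(names(modalities), .modality_names()))
    stop("`modalities` must contain exactly the six canonical modalities",
         call. = FALSE)
  modalities <- modalities[.modality_names()]
  for (m in modalities) stopifnot(inherits(m, "modality_profile"))
  miss <- setdiff(.shared_cost_states, names(state_costs))
  if (length(miss))
    stop("state_costs missing: ", paste(miss, collapse = ", "), call. = FALSE)
  state_costs <- state_costs[.shared_cost_states]
  for (sc in state_costs) {
    stopifnot(inherits(sc, "dist_spec"))
    if (sc$mean < 0) stop("state cost means must be >= 0", call. = FALSE)
  }
  if (is.numeric(salvage_cost)) salvage_cost <- dist_spec("fixed", salvage_cost)
  stopifnot(inherits(salvage_cost, "dist_spec"))
  miss <- setdiff(.disutility_states, names(disutilities))
  if (length(miss))
    stop("disutilities missing: ", paste(miss, collapse = ", "),
         call. = FALSE)
  disutilities <- disutilities[.disutility_states]
  for (du in disutilities) {
    stopifnot(inherits(du, "dist_spec"))
    if (du$mean < 0 || du$mean > 1)
      stop("dis-utility means must lie in [0, 1]", call. = FALSE)
  }
  stopifnot(inherits(life_table, "life_table"))
  if (recurrence_mortality_rr < 1)
    stop("`recurrence_mortality_rr` must be >= 1", call. = FALSE)
  structure(list(modalities = modalities, state_costs = state_costs,
                 salvage_cost = salvage_cost, disutilities = disutilities,
                 life_table = life_table,
                 recurrence_mortality_rr = recurrence_mortality_rr),
            class = "parameter_spec")
}

#' @export
print.parameter_spec <- function(x, ...) {
  cat("<parameter_spec> 6 modalities:",
      paste(names(x$modalities), collapse = ", "), "\n")
  fixed <- all(vapply(.all_dist_specs(x), .is_fixed, logical(1)))
  cat(if (fixed) "  all parameters fixed (zero variance)\n"
      else "  probabilistic parameters present\n")
  cat(sprintf("  life table ages %d-%d; recurrence mortality RR %.2f\n",
              min(x$life_table$age), max(x$life_table$age),
              x$recurrence_mortality_rr))
  invisible(x)
}

# Flat list of every dist_spec in a parameter_spec.
.all_dist_specs <- function(spec) {
  out <- c(spec$state_costs, list(salvage = spec$salvage_cost),
           spec$disutilities)
  for (m in spec$modalities)
    out <- c(out, m$event_probs, list(m$index_cost))
  out
}

# ---- Realizations ---------------------------------------------------------
# A "realization" fixes every uncertain parameter at a number:
#   shared: state_costs (len 7 incl. dead = 0), salvage_cost, disutilities,
#           recurrence_mortality_rr
#   arm:    p (named event probabilities), mortality_rr, index_cost, name

.shared_realization <- function(spec, draw) {
  sc <- draw(spec$state_costs)
  du <- draw(spec$disutilities)
  list(state_costs = c(sc, dead = 0),
       salvage_cost = draw(list(s = spec$salvage_cost))[[1L]],
       disutilities = du,
       recurrence_mortality_rr = spec$recurrence_mortality_rr)
}

.arm_realization <- function(profile, draw) {
  list(name = profile$name,
       p = draw(profile$event_probs),
       mortality_rr = profile$mortality_rr,
       index_cost = draw(list(ic = profile$index_cost))[[1L]])
}

#' Fix every parameter at its mean
#'
#' @param spec A [parameter_spec()].
#' @return List with elements `shared` and `arms` (one realization per
#'   modality), as consumed by [run_arm()].
#' @export
spec_means <- function(spec) {
  stopifnot(inherits(spec, "parameter_spec"))
  list(shared = .shared_realization(spec, .means_of),
       arms = lapply(spec$modalities, .arm_realization, draw = .means_of))
}

#' Draw one probabilistic realization of every parameter
#'
#' Samples from the current RNG stream in a fixed order (shared costs,
#' salvage, dis-utilities, then each modality's event probabilities and
#' index cost), so results are reproducible under `set.seed()`. Shared
#' parameters are drawn once and reused by every arm (common random
#' numbers).
#'
#' @inheritParams spec_means
#' @return Same structure as [spec_means()].
#' @export
sample_realization <- function(spec) {
  stopifnot(inherits(spec, "parameter_spec"))
  list(shared = .shared_realization(spec, .sample1),
       arms = lapply(spec$modalities, .arm_realization, draw = .sample1))
}

# ---- YAML serialization ---------------------------------------------------

.dist_to_list <- function(sp) list(family = sp$family, mean = sp$mean,
                                   se = sp$se)
.dist_from_list <- function(x) dist_spec(x$family, x$mean, x$se)

#' Read and write parameter specifications as YAML
#'
#' The canonical on-disk schema is YAML with top-level keys
#' `schema_version`, `shared` (state_costs / salvage_cost / disutilities /
#' recurrence_mortality_rr), `modalities` (per modality: n_fractions,
#' mortality_rr, index_cost, event_probs) and `life_table` (either an
#' inline `age`/`q_annual` pair of arrays or a `path` to a two-column CSV,
#' resolved relative to the YAML file).
#'
#' @param spec A [parameter_spec()].
#' @param path File path.
#' @return `read_spec()` returns a [parameter_spec()]; `write_spec()`
#'   returns `path` invisibly.
#' @export
write_spec <- function(spec, path) {
  stopifnot(inherits(spec, "parameter_spec"))
  obj <- list(
    schema_version = 1L,
    shared = list(
      state_costs = lapply(spec$state_costs, .dist_to_list),
      salvage_cost = .dist_to_list(spec$salvage_cost),
      disutilities = lapply(spec$disutilities, .dist_to_list),
      recurrence_mortality_rr = spec$recurrence_mortality_rr),
    modalities = lapply(spec$modalities, function(m) list(
      n_fractions = m$n_fractions,
      mortality_rr = m$mortality_rr,
      index_cost = .dist_to_list(m$index_cost),
      event_probs = lapply(m$event_probs, .dist_to_list))),
    life_table = list(age = spec$life_table$age,
                      q_annual = spec$life_table$q_annual))
  yaml::write_yaml(obj, path, precision = 15L)
  invisible(path)
}

#' @rdname write_spec
#' @export
read_spec <- function(path) {
  obj <- yaml::read_yaml(path)
  if (is.null(obj$schema_version) || obj$schema_version != 1L)
    stop("unsupported or missing schema_version in ", path, call. = FALSE)
  lt <- if (!is.null(obj$life_table$path))
    read_life_table(file.path(dirname(path), obj$life_table$path))
  else
    life_table(data.frame(age = unlist(obj$life_table$age),
                          q_annual = unlist(obj$life_table$q_annual)))
  mods <- lapply(names(obj$modalities), function(nm) {
    m <- obj$modalities[[nm]]
    modality_profile(nm,
                     event_probs = lapply(m$event_probs, .dist_from_list),
                     index_cost = .dist_from_list(m$index_cost),
                     n_fractions = m$n_fractions,
                     mortality_rr = unlist(m$mortality_rr))
  })
  names(mods) <- names(obj$modalities)
  sh <- obj$shared
  parameter_spec(
    modalities = mods,
    state_costs = lapply(sh$state_costs, .dist_from_list),
    salvage_cost = .dist_from_list(sh$salvage_cost),
    disutilities = lapply(sh$disutilities, .dist_from_list),
    life_table = lt,
    recurrence_mortality_rr = sh$recurrence_mortality_rr)
}
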