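#' Net monetary benefit
#'
#' `NMB = wtp * qaly - cost`: a strategy's value at a willingness-to-pay
#' threshold, on the money scale. The strategy maximising NMB at a given
#' threshold is the cost-effective choice there.
#'
#' @param cost Cost(s), CAD.
#' @param qaly QALY total(s).
#' @param wtp Willingness to pay, CAD per QALY, >= 0.
#' @return Net monetary benefit (vectorised).
#' @export
#' @examples
#' nmb(10048, 11.38, 50000)  # 558952
nmb <- function(cost, qaly, wtp) {
  if (any(wtp < 0)) stop("`wtp` must be >= 0", call. = FALSE)
  wtp * qaly - cost
}

#' Sequential incremental cost-utility analysis with dominance
#'
#' Implements the standard sequential ICUR procedure: (1) strategies are
#' ranked by cost from smallest to largest; (2) any strategy at least as
#' costly as, and less effective than, another is strictly dominated and
#' excluded; (3) ICURs are computed between successive survivors and any
#' strategy whose ICUR is not below that of the next more effective option
#' is excluded by extended dominance (it is never the optimal choice at any
#' willingness-to-pay); (4) ICURs are recomputed among the survivors. The
#' least costly survivor is the reference.
#'
#' @param strategies Data frame with columns `name` (unique), `cost`,
#'   `qaly` (>= 0); or a `psa_result`, in which case per-modality PSA means
#'   are analysed.
#' @return A `frontier_result` tibble, ordered by cost, with `status`
#'   (`"reference"`, `"frontier"`, `"dominated"`, `"extended-dominated"`),
#'   `dominated_by` (lowest-cost dominating strategy, or `NA`),
#'   `incremental_cost`, `incremental_qaly` and `icur` (frontier rows only;
#'   `NA` for the reference).
#' @export
#' @examples
#' icur_frontier(reference_strategies())
icur_frontier <- function(strategies) {
  if (inherits(strategies, "psa_result")) {
    s <- summarize_psa(strategies)
    strategies <- data.frame(name = s$modality, cost = s$mean_cost,
                             qaly = s$mean_qaly)
  }
  stopifnot(is.data.frame(strategies),
            all(c("name", "cost", "qaly") %in% names(strategies)))
  df <- as.data.frame(strategies)[, c("name", "cost", "qaly")]
  if (nrow(df) < 1L) stop("at least one strategy is required", call. = FALSE)
  if (anyDuplicated(df$name))
    stop("strategy names must be unique", call. = FALSE)
  if (any(df$qaly < 0)) stop("`qaly` must be >= 0", call. = FALSE)
  # (1) rank by cost; ties by higher QALYs, then name
  ord <- order(df$cost, -df$qaly, df$name)
  df <- df[ord, , drop = FALSE]
  n <- nrow(df)
  status <- rep("frontier", n)
  dominated_by <- rep(NA_character_, n)
  # (2) strict dominance: costlier-or-equal and fewer QALYs than another
  # (exact cost/QALY duplicates keep the name-order winner)
  for (i in seq_len(n)) {
    dom <- which(df$cost <= df$cost[i] & df$qaly > df$qaly[i] |
                   (df$cost == df$cost[i] & df$qaly == df$qaly[i] &
                      seq_len(n) < i))
    if (length(dom)) {
      status[i] <- "dominated"
      dominated_by[i] <- df$name[dom[which.min(df$cost[dom])]]
    }
  }
  # (3) extended dominance: drop survivors whose ICUR does not improve on
  # the next more effective option's; repeat until ICURs strictly increase
  repeat {
    surv <- which(status == "frontier")
    if (length(surv) < 3L) break
    c_s <- df$cost[surv]; q_s <- df$qaly[surv]
    ic <- diff(c_s) / diff(q_s)          # ICUR of surv[i+1] vs surv[i]
    bad <- which(ic[-length(ic)] >= ic[-1L])
    if (!length(bad)) break
    drop_i <- surv[bad[1L] + 1L]         # the strategy owning the high ICUR
    status[drop_i] <- "extended-dominated"
    dominated_by[drop_i] <- NA_character_
  }
  # (4) final ICURs among survivors; least costly survivor is the reference
  surv <- which(status == "frontier")
  inc_cost <- inc_qaly <- icur <- rep(NA_real_, n)
  if (length(surv)) {
    status[surv[1L]] <- "reference"
    if (length(surv) > 1L) {
      i2 <- surv[-1L]; i1 <- surv[-length(surv)]
      inc_cost[i2] <- df$cost[i2] - df$cost[i1]
      inc_qaly[i2] <- df$qaly[i2] - df$qaly[i1]
      icur[i2] <- inc_cost[i2] / inc_qaly[i2]
    }
  }
  out <- tibble::tibble(name = df$name, cost = df$cost, qaly = df$qaly,
                        status = status, dominated_by = dominated_by,
                        incremental_cost = inc_cost,
                        incremental_qaly = inc_qaly, icur = icur)
  class(out) <- c("frontier_result", class(out))
  out
}

#' @export
print.frontier_result <- function(x, ...) {
  cat("<frontier_result>\n")
  NextMethod()
  invisible(x)
}

#' Cost-effectiveness acceptability curve
#'
#' For every willingness-to-pay value on the grid and every PSA iteration,
#' the strategy with maximal net monetary benefit wins (exact ties split
#' equally); the CEAC reports each strategy's win fraction as a function of
#' the threshold.
#'
#' @param r A `psa_result`.
#' @param wtp_grid Non-empty vector of thresholds, >= 0 (default 0 to
#'   200,000 CAD/QALY in steps of 500).
#' @return A `ceac_curve` tibble: `wtp` plus one probability column per
#'   modality; each row sums to 1.
#' @export
ceac <- function(r, wtp_grid = seq(0, 200000, by = 500)) {
  stopifnot(inherits(r, "psa_result"), length(wtp_grid) >= 1L)
  if (any(wtp_grid < 0)) stop("`wtp_grid` must be >= 0", call. = FALSE)
  m <- .psa_matrices(r)
  probs <- vapply(wtp_grid, function(w) {
    b <- w * m$qaly - m$cost
    best <- apply(b, 1L, max)
    win <- b == best
    colMeans(win / rowSums(win))
  }, numeric(ncol(m$cost)))
  if (is.null(dim(probs)))
    probs <- matrix(probs, nrow = 1L,
                    dimnames = list(colnames(m$cost), NULL))
  out <- tibble::as_tibble(cbind(data.frame(wtp = wtp_grid), t(probs)))
  class(out) <- c("ceac_curve", class(out))
  out
}

#' Incremental cost-effectiveness plane
#'
#' Per-iteration incremental (QALY, cost) pairs of every non-reference
#' strategy against the chosen reference, as scattered on a
#' cost-effectiveness plane.
#'
#' @param r A `psa_result`.
#' @param reference_name Modality used as comparator; must be present.
#' @return Tibble `iteration`, `modality`, `delta_qaly`, `delta_cost`.
#' @export
ce_plane <- function(r, reference_name) {
  stopifnot(inherits(r, "psa_result"))
  m <- .psa_matrices(r)
  mods <- colnames(m$cost)
  if (!reference_name %in% mods)
    stop("unknown reference: ", reference_name, call. = FALSE)
  others <- setdiff(mods, reference_name)
  tibble::tibble(
    iteration = rep(seq_len(r$n_iter), times = length(others)),
    modality = rep(others, each = r$n_iter),
    delta_qaly = as.vector(m$qaly[, others] - m$qaly[, reference_name]),
    delta_cost = as.vector(m$cost[, others] - m$cost[, reference_name]))
}
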