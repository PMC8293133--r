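# Independent oracles: implementations that deliberately do NOT share code
# with the package paths they check.

# Individual-level Monte Carlo microsimulation of the same transition
# matrices; returns the occupancy matrix (cycle boundaries x 7 states).
microsim_occupancy <- function(arm, shared, lt, cfg, n_patients, seed) {
  set.seed(seed)
  state <- rep.int(1L, n_patients)
  occ <- matrix(0, cfg$n_cycles + 1L, 7L)
  occ[1L, 1L] <- 1
  for (k in seq_len(cfg$n_cycles)) {
    M <- build_transition_matrix(arm, shared, k, lt, cfg)
    nxt <- state
    for (s in unique(state)) {
      idx <- which(state == s)
      nxt[idx] <- sample.int(7L, length(idx), replace = TRUE, prob = M[s, ])
    }
    state <- nxt
    occ[k + 1L, ] <- tabulate(state, 7L) / n_patients
  }
  occ
}

# First-cycle healthy-row transition probabilities by exhaustive enumeration
# over the 2^3 joint outcomes of independent acute-GU / acute-GI / death
# indicators, with death taking precedence and GU before GI.
enumerate_first_cycle_row <- function(p_agu, p_agi, p_death) {
  dest <- c(healthy = 0, acute_gu = 0, acute_gi = 0, dead = 0)
  for (gu in 0:1) for (gi in 0:1) for (dd in 0:1) {
    pr <- (if (gu) p_agu else 1 - p_agu) *
      (if (gi) p_agi else 1 - p_agi) *
      (if (dd) p_death else 1 - p_death)
    to <- if (dd) "dead" else if (gu) "acute_gu" else if (gi) "acute_gi"
          else "healthy"
    dest[to] <- dest[to] + pr
  }
  dest
}

# Type-7 percentile by hand (sorting-based), independent of stats::quantile.
brute_percentile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  x[lo] + (h - lo) * (x[min(lo + 1, n)] - x[lo])
}

# Is strategy j ever the unique NMB maximiser on the WTP grid?
unique_argmax_somewhere <- function(cost, qaly, j, wtp_grid) {
  for (w in wtp_grid) {
    b <- w * qaly - cost
    if (b[j] > max(b[-j])) return(TRUE)
  }
  FALSE
}
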