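#' Probabilistic sensitivity analysis
#'
#' Monte Carlo propagation of parameter uncertainty: each iteration draws
#' one realization of every uncertain parameter — shared costs and
#' dis-utilities once, reused across all six arms, so that between-modality
#' differences within an iteration are driven only by event risks and index
#' costs — runs all modalities, and records the discounted cost and QALY
#' pair. An iteration whose sampled probabilities fall outside \[0, 1\]
#' (possible only for non-beta overrides) is resampled and counted.
#'
#' @param spec A [parameter_spec()].
#' @param n_iter Number of Monte Carlo iterations, >= 1.
#' @param seed Integer seed; identical seeds give identical results.
#' @param cfg A [model_config()].
#' @return A `psa_result`: list with `draws` (tibble `iteration`,
#'   `modality`, `cost`, `qaly`), `n_iter`, `seed`, `n_resampled`.
#' @export
run_psa <- function(spec, n_iter, seed, cfg = model_config()) {
  stopifnot(inherits(spec, "parameter_spec"), n_iter >= 1)
  set.seed(seed)
  mods <- names(spec$modalities)
  nm <- length(mods)
  cost <- qaly <- matrix(NA_real_, n_iter, nm, dimnames = list(NULL, mods))
  n_resampled <- 0L
  for (i in seq_len(n_iter)) {
    for (attempt in seq_len(100L)) {
      real <- sample_realization(spec)
      ok <- all(vapply(real$arms, function(a)
        all(a$p >= 0 & a$p <= 1), logical(1)))
      if (ok) break
      n_resampled <- n_resampled + 1L
      if (attempt == 100L)
        stop("iteration ", i, ": could not sample feasible probabilities",
             call. = FALSE)
    }
    for (j in seq_len(nm)) {
      r <- run_arm(real$arms[[j]], real$shared, spec$life_table, cfg)
      cost[i, j] <- r$total_cost
      qaly[i, j] <- r$total_qaly
    }
  }
  draws <- tibble::tibble(
    iteration = rep(seq_len(n_iter), times = nm),
    modality = rep(mods, each = n_iter),
    cost = as.vector(cost),
    qaly = as.vector(qaly))
  structure(list(draws = draws, n_iter = as.integer(n_iter),
                 seed = as.integer(seed), n_resampled = n_resampled),
            class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("<psa_result> %d iterations x %d modalities (seed %d, %d resampled)\n",
              x$n_iter, length(unique(x$draws$modality)), x$seed,
              x$n_resampled))
  invisible(x)
}

# draws as iteration x modality matrices
.psa_matrices <- function(r) {
  mods <- unique(r$draws$modality)
  list(
    cost = matrix(r$draws$cost, nrow = r$n_iter, dimnames = list(NULL, mods)),
    qaly = matrix(r$draws$qaly, nrow = r$n_iter, dimnames = list(NULL, mods)))
}

#' Summarise PSA draws
#'
#' Per-modality arithmetic means with empirical 2.5th/97.5th percentile
#' intervals.
#'
#' @param r A `psa_result`.
#' @return Tibble with `modality`, `mean_cost`, `cost_lo`, `cost_hi`,
#'   `mean_qaly`, `qaly_lo`, `qaly_hi`.
#' @export
summarize_psa <- function(r) {
  stopifnot(inherits(r, "psa_result"))
  if (r$n_iter < 2)
    stop("intervals require n_iter >= 2", call. = FALSE)
  m <- .psa_matrices(r)
  qs <- function(x) stats::quantile(x, c(0.025, 0.975), names = FALSE)
  cost_q <- apply(m$cost, 2L, qs)
  qaly_q <- apply(m$qaly, 2L, qs)
  tibble::tibble(
    modality = colnames(m$cost),
    mean_cost = unname(colMeans(m$cost)), cost_lo = unname(cost_q[1L, ]),
    cost_hi = unname(cost_q[2L, ]),
    mean_qaly = unname(colMeans(m$qaly)), qaly_lo = unname(qaly_q[1L, ]),
    qaly_hi = unname(qaly_q[2L, ]))
}

#' Export PSA draws as long-format CSV
#'
#' @param r A `psa_result`.
#' @param path Output CSV path (columns `iteration,modality,cost,qaly`).
#' @export
write_psa_draws <- function(r, path) {
  stopifnot(inherits(r, "psa_result"))
  utils::write.csv(r$draws, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
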