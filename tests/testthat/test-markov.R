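cfg0 <- model_config()

test_that("model config derives the cycle count and validates inputs", {
  expect_equal(cfg0$n_cycles, 40L)
  expect_error(model_config(cycle_years = 0.5, horizon_years = 20.3),
               "integer multiple")
  expect_error(model_config(annual_discount = -0.01), ">= 0")
})

test_that("degenerate transition matrices behave as expected", {
  lt0 <- const_life_table(0)
  sh <- zero_shared()
  # no events, no death: every reachable state persists; acute states
  # (occupied only during cycle 1) return to healthy by construction
  M <- build_transition_matrix(make_arm(), sh, 2L, lt0, cfg0)
  for (s in c("healthy", "late_gu", "late_gi", "recurrence", "dead"))
    expect_equal(unname(M[s, s]), 1)
  expect_equal(unname(M["acute_gu", "healthy"]), 1)
  expect_equal(unname(M["acute_gi", "healthy"]), 1)
  # certain death sends every row's mass to the dead column
  lt1 <- const_life_table(1)
  M1 <- build_transition_matrix(make_arm(), sh, 1L, lt1, cfg0)
  expect_equal(unname(M1[, "dead"]), rep(1, 7))
  expect_equal(sum(M1[, -7]), 0)
})

test_that("first-cycle healthy row matches exhaustive competing-risk enumeration", {
  q <- 1 - (1 - 0.01)^2  # annual prob whose 6-month conversion is 0.01
  lt <- const_life_table(q)
  arm <- make_arm(acute_gu = 0.1, acute_gi = 0.05)
  M <- build_transition_matrix(arm, zero_shared(), 1L, lt, cfg0)
  oracle <- enumerate_first_cycle_row(0.1, 0.05, 0.01)
  expect_equal(M["healthy", c("healthy", "acute_gu", "acute_gi", "dead")],
               oracle, tolerance = 1e-12)
})

test_that("rows are stochastic and occupancy is conserved for random parameters", {
  set.seed(101)
  lt <- gompertz_lt()
  for (rep in 1:5) {
    arm <- random_arm()
    sh <- random_shared()
    for (k in c(1L, 2L, 17L, 40L)) {
      M <- build_transition_matrix(arm, sh, k, lt, cfg0)
      expect_true(all(M >= 0 & M <= 1))
      expect_equal(unname(rowSums(M)), rep(1, 7), tolerance = 1e-12)
      expect_equal(unname(M["dead", ]), c(rep(0, 6), 1))
    }
    tr <- run_cohort(arm, sh, lt, cfg0)
    expect_equal(unname(rowSums(tr$occupancy)), rep(1, 41),
                 tolerance = 1e-9)
    expect_true(all(diff(tr$occupancy[, "dead"]) >= -1e-12))
    # acute states are only occupied at the first cycle boundary
    expect_true(all(tr$occupancy[-2, c("acute_gu", "acute_gi")] < 1e-12))
  }
})

test_that("cohort propagation equals explicit matrix-product iteration", {
  set.seed(7)
  lt <- gompertz_lt()
  arm <- random_arm()
  sh <- random_shared()
  tr <- run_cohort(arm, sh, lt, cfg0)
  v <- c(1, rep(0, 6))
  for (k in seq_len(cfg0$n_cycles)) {
    v <- drop(v %*% build_transition_matrix(arm, sh, k, lt, cfg0))
    expect_equal(unname(tr$occupancy[k + 1L, ]), unname(v),
                 tolerance = 1e-12)
  }
})

test_that("trivial cohorts resolve exactly", {
  sh <- zero_shared()
  # zero-event, zero-death arm stays healthy forever
  tr <- run_cohort(make_arm(), sh, const_life_table(0), cfg0)
  expect_equal(unname(tr$occupancy[, "healthy"]), rep(1, 41))
  # certain first-cycle death absorbs everyone
  tr1 <- run_cohort(make_arm(), sh, const_life_table(1), cfg0)
  expect_equal(unname(tr1$occupancy[-1, "dead"]), rep(1, 40))
})

test_that("half-cycle-corrected QALYs match hand computations", {
  sh <- zero_shared()
  u1 <- c(healthy = 1, acute_gu = 1, acute_gi = 1, late_gu = 1,
          late_gi = 1, recurrence = 1, dead = 0)
  costs0 <- list(state_costs = sh$state_costs, index_cost = 0,
                 salvage_cost = 0)
  cfg_nodisc <- model_config(annual_discount = 0)
  # full survival, no discounting: exactly the horizon
  tr <- run_cohort(make_arm(), sh, const_life_table(0), cfg_nodisc)
  expect_equal(accumulate_outcomes(tr, costs0, u1, cfg_nodisc)$total_qaly, 20)
  # cohort entirely dead after cycle 1: half-cycle credit 0.5 * 0.5 years
  tr1 <- run_cohort(make_arm(), sh, const_life_table(1), cfg_nodisc)
  expect_equal(accumulate_outcomes(tr1, costs0, u1, cfg_nodisc)$total_qaly,
               0.25)
  # always-healthy discounted QALYs equal the closed-form geometric series
  cfg_disc <- model_config(annual_discount = 0.015)
  trd <- run_cohort(make_arm(), sh, const_life_table(0), cfg_disc)
  got <- accumulate_outcomes(trd, costs0, u1, cfg_disc)$total_qaly
  x <- 1.015^(-0.5)
  expect_equal(got, 0.5 * x^0.5 * (1 - x^40) / (1 - x), tolerance = 1e-10)
})

test_that("salvage costs discount at the recurrence entry cycle", {
  # recurrence certain at cycle 2; no deaths, no other costs
  arm <- make_arm(recurrence = 1)
  sh <- zero_shared()
  sh$salvage_cost <- 1000
  tr <- run_cohort(arm, sh, const_life_table(0), cfg0)
  expect_equal(unname(tr$entry_flows[2L, "recurrence"]), 1)
  costs <- list(state_costs = sh$state_costs, index_cost = 0,
                salvage_cost = 1000)
  u1 <- c(healthy = 1, acute_gu = 1, acute_gi = 1, late_gu = 1,
          late_gi = 1, recurrence = 1, dead = 0)
  r <- accumulate_outcomes(tr, costs, u1, cfg0)
  expect_equal(r$total_cost, 1000 * 1.015^(-(2 - 0.5) * 0.5),
               tolerance = 1e-12)
  expect_equal(r$undiscounted_cost, 1000)
})

test_that("zero dis-utilities and zero downstream costs reduce to index cost and life-years", {
  set.seed(55)
  lt <- gompertz_lt()
  arm <- random_arm()
  arm$index_cost <- 12345
  sh <- zero_shared(recurrence_mortality_rr = 2)
  r <- run_arm(arm, sh, lt, cfg0)
  expect_identical(r$total_cost, 12345)
  # QALYs equal discounted life-years computed independently from the trace
  tr <- run_cohort(arm, sh, lt, cfg0)
  alive <- 1 - tr$occupancy[, "dead"]
  k <- seq_len(cfg0$n_cycles)
  ly <- sum(0.5 * (alive[k] + alive[k + 1]) / 2 * 1.015^(-(k - 0.5) * 0.5))
  expect_equal(r$total_qaly, ly, tolerance = 1e-12)
})

test_that("discounting is monotone and bounded", {
  set.seed(9)
  lt <- gompertz_lt()
  arm <- random_arm()
  sh <- random_shared()
  res <- lapply(c(0, 0.015, 0.05), function(r)
    run_arm(arm, sh, lt, model_config(annual_discount = r)))
  qalys <- vapply(res, `[[`, numeric(1), "total_qaly")
  costs <- vapply(res, `[[`, numeric(1), "total_cost")
  expect_true(all(diff(qalys) < 0))
  expect_true(all(diff(costs) < 0))
  for (r in res) {
    expect_lte(r$total_qaly, r$undiscounted_qaly)
    expect_lte(r$total_cost, r$undiscounted_cost)
    expect_gte(r$total_qaly, 0)
    expect_lte(r$total_qaly, 20)
    expect_gte(r$total_cost, arm$index_cost)
  }
})

test_that("cohort traces match an individual-level microsimulation", {
  set.seed(31)
  lt <- gompertz_lt()
  n_pat <- 2e4L
  for (rep in 1:3) {
    arm <- random_arm()
    sh <- random_shared()
    tr <- run_cohort(arm, sh, lt, cfg0)
    occ_ms <- microsim_occupancy(arm, sh, lt, cfg0, n_pat,
                                 seed = 1000 + rep)
    for (k in c(10L, 40L)) {
      p <- tr$occupancy[k + 1L, ]
      se <- sqrt(p * (1 - p) / n_pat)
      expect_true(all(abs(occ_ms[k + 1L, ] - p) <= 3 * se + 1e-12),
                  label = sprintf("draw %d cycle %d within 3 SE", rep, k))
    }
  }
})

test_that("infeasible probabilities are rejected with the row named", {
  arm <- make_arm(acute_gu = 1.4)
  expect_error(run_cohort(arm, zero_shared(), const_life_table(0), cfg0),
               "acute_gu")
})

test_that("trace exports as a cycle-by-state table", {
  tr <- run_cohort(make_arm(), zero_shared(), const_life_table(0), cfg0)
  tab <- trace_table(tr)
  expect_equal(nrow(tab), 41L)
  expect_equal(tab$years, seq(0, 20, by = 0.5))
  expect_true(all(c("healthy", "dead") %in% names(tab)))
})
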