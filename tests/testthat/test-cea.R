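test_that("net monetary benefit arithmetic", {
  expect_equal(nmb(500, 2, 0), -500)
  expect_equal(nmb(10048, 11.38, 50000), 558952)
  # linear in wtp with slope qaly
  w <- c(0, 1000, 2000)
  expect_equal(diff(nmb(100, 3, w)), rep(3000, 2))
  expect_error(nmb(1, 1, -5), ">= 0")
})

test_that("equal-cost strategies resolve by effectiveness", {
  f <- icur_frontier(data.frame(name = c("A", "B"), cost = c(100, 100),
                                qaly = c(5, 6)))
  expect_equal(f$status[f$name == "A"], "dominated")
  expect_equal(f$dominated_by[f$name == "A"], "B")
  expect_equal(f$status[f$name == "B"], "reference")
})

test_that("extended dominance removes never-optimal strategies", {
  f <- icur_frontier(data.frame(name = c("A", "B", "C"),
                                cost = c(0, 10, 12), qaly = c(0, 1, 3)))
  expect_equal(f$status[f$name == "B"], "extended-dominated")
  expect_equal(f$status[f$name == "A"], "reference")
  expect_equal(f$icur[f$name == "C"], (12 - 0) / (3 - 0))
  # NMB-argmax oracle: B is never the unique winner at any threshold
  expect_false(unique_argmax_somewhere(c(0, 10, 12), c(0, 1, 3), 2L,
                                       seq(0, 200, by = 0.5)))
})

test_that("frontier classification agrees with the dense-grid NMB oracle", {
  set.seed(77)
  grid <- seq(0, 200000, by = 500)
  for (rep in 1:10) {
    n <- sample(2:8, 1)
    df <- data.frame(name = paste0("S", seq_len(n)),
                     cost = runif(n, 5000, 25000), qaly = runif(n, 8, 14))
    f <- icur_frontier(df)
    j_all <- match(f$name, df$name)
    for (i in seq_len(nrow(f))) {
      j <- j_all[i]
      on_frontier <- f$status[i] %in% c("reference", "frontier")
      if (!on_frontier) {
        expect_false(unique_argmax_somewhere(df$cost, df$qaly, j, grid),
                     label = paste("excluded", f$name[i], "never wins"))
      }
    }
    # every frontier strategy wins on some interval: probe between ICURs
    surv <- which(f$status %in% c("reference", "frontier"))
    ic <- f$icur[surv]
    for (s in seq_along(surv)) {
      lo <- if (s == 1) 0 else f$icur[surv[s]]
      hi <- if (s == length(surv)) lo * 2 + 1000 else f$icur[surv[s + 1]]
      w <- (lo + hi) / 2
      b <- w * df$qaly - df$cost
      expect_equal(which.max(b), j_all[surv[s]],
                   label = paste("frontier", f$name[surv[s]],
                                 "wins at wtp", w))
    }
    # frontier ICURs strictly increase
    if (sum(!is.na(ic)) > 1) expect_true(all(diff(ic[!is.na(ic)]) > 0))
  }
})

test_that("six-strategy worked example classifies and prices correctly", {
  f <- icur_frontier(reference_strategies())
  expect_equal(f$status[f$name == "LDR-b"], "reference")
  expect_equal(f$status[f$name == "SBRT"], "frontier")
  dominated <- c("HDR-b", "hfIMRT", "HDR-IMRT", "cfIMRT")
  expect_true(all(f$status[f$name %in% dominated] == "dominated"))
  expect_equal(f$icur[f$name == "SBRT"], (10048 - 8940) / (11.38 - 11.00),
               tolerance = 1e-12)
})

test_that("CEAC win fractions match exhaustive enumeration", {
  fake <- structure(list(
    draws = tibble::tibble(
      iteration = rep(1:4, 2), modality = rep(c("A", "B"), each = 4),
      cost = c(100, 100, 100, 100, 150, 90, 150, 100),
      qaly = c(1, 1, 1, 1, 2, 0.5, 1.5, 1)),
    n_iter = 4L, seed = 0L, n_resampled = 0L), class = "psa_result")
  cc <- ceac(fake, wtp_grid = c(0, 100))
  # wtp 0: A wins iters 1,3; B wins iter 2; iter 4 ties (split)
  expect_equal(cc$A[cc$wtp == 0], 2.5 / 4)
  expect_equal(cc$B[cc$wtp == 0], 1.5 / 4)
  # wtp 100: B wins iter 1, A wins iter 2, iters 3-4 tie
  expect_equal(cc$A[cc$wtp == 100], 2 / 4)
  expect_equal(cc$B[cc$wtp == 100], 2 / 4)
})

test_that("CEAC curves are proper probabilities", {
  r <- run_psa(add_default_uncertainty(calibrated_reference_spec()),
               n_iter = 200, seed = 3)
  cc <- ceac(r, wtp_grid = seq(0, 100000, by = 10000))
  probs <- as.matrix(cc[, -1])
  expect_true(all(probs >= 0 & probs <= 1))
  expect_equal(unname(rowSums(probs)), rep(1, nrow(cc)), tolerance = 1e-9)
  # at wtp 0 the curve equals the fraction of strictly-lowest-cost wins
  m <- matrix(r$draws$cost, nrow = r$n_iter)
  colnames(m) <- unique(r$draws$modality)
  lowest <- table(factor(colnames(m)[apply(m, 1, which.min)],
                         levels = colnames(m))) / r$n_iter
  expect_equal(unname(unlist(cc[cc$wtp == 0, colnames(m)])),
               unname(as.vector(lowest)), tolerance = 1e-12)
})

test_that("two-strategy CEAC of the more effective strategy is non-decreasing", {
  fake <- structure(list(
    draws = tibble::tibble(
      iteration = rep(1:50, 2), modality = rep(c("cheap", "eff"), each = 50),
      cost = c(runif(50, 90, 110), runif(50, 140, 180)),
      qaly = c(runif(50, 0.9, 1.1), runif(50, 1.4, 1.9))),
    n_iter = 50L, seed = 0L, n_resampled = 0L), class = "psa_result")
  cc <- ceac(fake, wtp_grid = seq(0, 500, by = 10))
  expect_true(all(diff(cc$eff) >= -1e-12))
})

test_that("single-strategy CEAC is 1 everywhere", {
  fake <- structure(list(
    draws = tibble::tibble(iteration = 1:3, modality = rep("A", 3),
                           cost = c(1, 2, 3), qaly = c(1, 1, 1)),
    n_iter = 3L, seed = 0L, n_resampled = 0L), class = "psa_result")
  cc <- ceac(fake, wtp_grid = c(0, 1000))
  expect_equal(cc$A, c(1, 1))
})

test_that("cost-effectiveness plane increments are consistent", {
  spec <- add_default_uncertainty(calibrated_reference_spec())
  r <- run_psa(spec, n_iter = 100, seed = 8)
  pl <- ce_plane(r, "LDR-b")
  expect_false("LDR-b" %in% pl$modality)
  expect_equal(nrow(pl), 100L * 5L)
  # mean of the scatter equals the difference of PSA means
  s <- summarize_psa(r)
  for (m in c("SBRT", "cfIMRT")) {
    expect_equal(mean(pl$delta_cost[pl$modality == m]),
                 s$mean_cost[s$modality == m] -
                   s$mean_cost[s$modality == "LDR-b"], tolerance = 1e-9)
  }
  # reference against itself is the zero point
  r0 <- run_psa(calibrated_reference_spec(), n_iter = 2, seed = 1)
  pl0 <- ce_plane(r0, "SBRT")
  det <- deterministic_run(calibrated_reference_spec())
  expect_equal(pl0$delta_cost[pl0$modality == "LDR-b"][1],
               det$cost[det$name == "LDR-b"] - det$cost[det$name == "SBRT"])
  expect_error(ce_plane(r0, "nope"), "unknown reference")
})
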