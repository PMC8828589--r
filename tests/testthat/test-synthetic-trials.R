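# Synthetic trial generator: parameter validation, determinism, degenerate
# structure, and statistical calibration of the stated design.

test_that("sim_params validates its inputs", {
  expect_error(sim_params(wt_mean_by_env = c(69)), "named")
  expect_error(
    sim_params(wt_mean_by_env = c(E = 69), line_var = -1, block_var = 0, resid_var = 0),
    "variance")
  expect_error(
    sim_params(wt_mean_by_env = c(E = 69), line_var = 0, block_var = 0, resid_var = 0,
               epi_mixture = list(fraction_up = 0.5, fraction_down = 0.6,
                                  fraction_null = 0.1, mean_up = 1, mean_down = 1)),
    "sum to 1")
  expect_error(
    sim_params(wt_mean_by_env = c(E = 69), line_var = 0, block_var = 0, resid_var = 0,
               reversion_rate = 1.5),
    "probability")
  expect_error(
    sim_params(wt_mean_by_env = c(E = 69), line_var = 0, block_var = 0, resid_var = 0,
               n_epi_lines = 0),
    "counts")
})

test_that("generators are byte-identical for identical params and seed", {
  p <- default_epiF2_params(seed = 5)
  expect_identical(simulate_epiF2_trial(p), simulate_epiF2_trial(p))
  p3 <- default_epiF3_params(seed = 5)
  expect_identical(simulate_epiF3_multienv_trial(p3), simulate_epiF3_multienv_trial(p3))
  delays <- c(A = 0, B = 3)
  expect_identical(simulate_emergence(p3, delays), simulate_emergence(p3, delays))
  expect_identical(simulate_reversion_counts(100, 0.3, seed = 9),
                   simulate_reversion_counts(100, 0.3, seed = 9))
  # and the generator does not disturb the caller's RNG state
  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(simulate_epiF2_trial(p)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("degenerate variances yield the exact structural means", {
  p <- sim_params(
    wt_mean_by_env = c(E = 69), line_var = 0, block_var = 0, resid_var = 0,
    epi_mixture = list(fraction_up = 0, fraction_down = 0, fraction_null = 1,
                       mean_up = 0, mean_down = 0),
    n_epi_lines = 12, plants_per_line_per_rep = 4, n_reps_by_env = c(E = 2),
    seed = 3)
  d <- simulate_epiF2_trial(p)
  expect_true(all(d$yield_g == 69))

  p3 <- sim_params(
    wt_mean_by_env = c(H = 6000, M = 2300), line_var = 0, block_var = 0,
    resid_var = 0,
    epi_mixture = list(fraction_up = 0, fraction_down = 0, fraction_null = 1,
                       mean_up = 0, mean_down = 0),
    gxe_scale = 0, n_epi_lines = 20, n_wt_lines = 3,
    plants_per_line_per_rep = 1, n_reps_by_env = c(H = 2, M = 2), seed = 3)
  d3 <- simulate_epiF3_multienv_trial(p3)
  expect_true(all(d3$yield_kg_ha_std[d3$environment_id == "H"] == 6000))
  expect_true(all(d3$yield_kg_ha_std[d3$environment_id == "M"] == 2300))
})

test_that("epi-F2 design structure matches the augmented layout", {
  p <- default_epiF2_params(seed = 2)
  d <- simulate_epiF2_trial(p)
  # every (line, rep) cell present with the full plant count
  tab <- table(d$line_id[d$cohort != "WT"], d$replication[d$cohort != "WT"])
  expect_true(all(tab == p$plants_per_line_per_rep))
  expect_equal(nrow(tab), p$n_epi_lines)
  # a WT check in every incomplete block
  blocks <- unique(d[c("replication", "block")])
  wt_blocks <- unique(d[d$cohort == "WT", c("replication", "block")])
  expect_equal(nrow(blocks), nrow(wt_blocks))
  # invariants on traits
  expect_true(all(d$yield_g >= 0))
  expect_true(all(d$tiller_count >= 0 & d$tiller_count == round(d$tiller_count)))
  expect_true(all(d$days_to_flowering >= 1))
})

test_that("tiller-yield correlation is calibrated to the target", {
  p <- default_epiF2_params(seed = 11)
  d <- simulate_epiF2_trial(p)
  expect_gte(nrow(d), 4500)
  expect_lt(abs(cor(d$tiller_count, d$yield_g) - p$tiller_yield_rho), 0.05)
})

test_that("epi-F3 WT means land on the environment targets", {
  p <- default_epiF3_params(seed = 1)
  d <- simulate_epiF3_multienv_trial(p)
  for (e in names(p$wt_mean_by_env)) {
    wt <- d$yield_kg_ha_std[d$cohort == "WT" & d$environment_id == e]
    se <- sd(wt) / sqrt(length(wt))
    expect_lt(abs(mean(wt) - p$wt_mean_by_env[[e]]), 3 * se)
  }
})

test_that("epi-F3 rejects unknown categories and environments", {
  p <- default_epiF3_params(seed = 1)
  expect_error(simulate_epiF3_multienv_trial(p, category_effects = list(XX.YY = 0.1)),
               "category")
  expect_error(simulate_epiF3_multienv_trial(p, category_effects = list(ML.HI = c(Nowhere = 0.1))),
               "environment")
})

test_that("emergence simulation honours delays and the day grid", {
  p <- default_epiF3_params(seed = 4)
  expect_error(simulate_emergence(p, c(A = 0), days = c(5, 5, 6)), "increasing")

  em <- simulate_emergence(p, c(A = 0, B = Inf), noise = FALSE)
  a <- em[em$line_id == "A", ]
  expect_identical(a$count[a$planting == "early"], a$count[a$planting == "standard"])
  expect_true(all(em$count[em$line_id == "B" & em$planting == "early"] == 0))

  # AUPEC strictly decreasing in delay
  delays <- c(D0 = 0, D2 = 2, D4 = 4, D6 = 6)
  em2 <- simulate_emergence(p, delays, noise = FALSE, n_seeds = 100)
  au <- aupec_by_line(em2)
  au <- au[match(names(delays), au$line_id), ]
  expect_true(all(diff(au$aupec) < 0))

  # counts are cumulative (non-decreasing in day) with per-seed noise
  em3 <- simulate_emergence(p, c(A = 1.5), noise = TRUE)
  for (pl in c("early", "standard")) {
    cc <- em3$count[em3$planting == pl]
    expect_true(all(diff(cc) >= 0))
  }
})

test_that("reversion counts follow the binomial model", {
  expect_equal(simulate_reversion_counts(500, 0, seed = 1), 0)
  expect_equal(simulate_reversion_counts(500, 1, seed = 1), 500)
  expect_error(simulate_reversion_counts(10, 1.2), "probability")
  # moment check against binomial mean 9.975, sd sqrt(n p (1-p))
  n <- 6650; rate <- 0.0015; reps <- 3000
  draws <- vapply(seq_len(reps), function(s) simulate_reversion_counts(n, rate, seed = s),
                  numeric(1))
  se <- sqrt(n * rate * (1 - rate) / reps)
  expect_lt(abs(mean(draws) - n * rate), 3 * se)
})
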