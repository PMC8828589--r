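# Percentile cutoffs, L/M/H classification and strategy evaluation.

test_that("compute_cutoffs matches a sort-and-interpolate oracle", {
  x <- 1:10
  cuts <- compute_cutoffs(x)
  expect_equal(cuts$p30, oracle_quantile_type7(x, 0.30))
  expect_equal(cuts$p70, oracle_quantile_type7(x, 0.70))
  set.seed(99)
  for (i in 1:5) {
    y <- runif(sample(5:200, 1), 0, 150)
    cuts <- compute_cutoffs(y)
    expect_equal(cuts$p30, oracle_quantile_type7(y, 0.30))
    expect_equal(cuts$p70, oracle_quantile_type7(y, 0.70))
  }
  expect_equal(cuts$source_n, length(y))
})

test_that("compute_cutoffs handles degenerate and bad input", {
  expect_equal(unclass(compute_cutoffs(rep(7, 5)))[c("p30", "p70")],
               list(p30 = 7, p70 = 7))
  expect_error(compute_cutoffs(numeric(0)), "at least 2")
  expect_error(suppressWarnings(compute_cutoffs(c(1, NA))), "at least 2")
  expect_error(yield_cutoffs(80, 58), "p30")
})

test_that("classification boundaries follow the printed inequalities", {
  cuts <- yield_cutoffs(58, 80)
  expect_equal(classify_value(c(57.9, 58, 69, 80, 80.01), cuts),
               c("L", "M", "M", "M", "H"))
  expect_error(classify_value(NaN, cuts), "finite")
})

test_that("classify_population produces the two-level categories", {
  cuts <- yield_cutoffs(58, 80)
  # line mean 70, individual 90 -> ML.HI
  d <- data.frame(line_id = "L1", cohort = "epiF2",
                  yield_g = c(90, 50, 70))  # mean 70
  cl <- classify_population(d, cuts)
  expect_equal(cl$category[cl$yield_g == 90], "ML.HI")
  # all identical at 60 -> ML.MI
  d2 <- data.frame(line_id = rep(c("A", "B"), each = 3), cohort = "epiF2",
                   yield_g = 60)
  expect_true(all(classify_population(d2, cuts)$category == "ML.MI"))
})

test_that("classification matches the brute-force oracle and partitions", {
  set.seed(7)
  n <- 1000
  d <- data.frame(line_id = sample(sprintf("L%02d", 1:40), n, replace = TRUE),
                  cohort = "epiF2",
                  yield_g = runif(n, 20, 130))
  cuts <- yield_cutoffs(58, 80)
  cl <- classify_population(d, cuts)
  expect_equal(cl$category, oracle_classify(cl$line_id, cl$yield_g, 58, 80))
  # total partition: every plant in exactly one of nine categories
  expect_equal(sum(table(cl$category)), n)
  expect_true(all(cl$category %in% paste0(rep(c("LL", "ML", "HL"), each = 3), ".",
                                          c("LI", "MI", "HI"))))
})

test_that("classification is monotone in yield", {
  cuts <- yield_cutoffs(58, 80)
  ord <- c(L = 1, M = 2, H = 3)
  y <- sort(runif(50, 0, 140))
  cls <- ord[classify_value(y, cuts)]
  expect_true(all(diff(cls) >= 0))
  # raising every yield in a line never lowers its line class
  d <- data.frame(line_id = rep("A", 5), cohort = "epiF2", yield_g = c(40, 50, 60, 70, 80))
  c1 <- classify_population(d, cuts)$line_class[1]
  d$yield_g <- d$yield_g + 25
  c2 <- classify_population(d, cuts)$line_class[1]
  expect_gte(ord[c2], ord[c1])
})

test_that("percent_increase reproduces printed values and rejects bad refs", {
  expect_equal(percent_increase(6565, 5999), 9.4)
  expect_equal(percent_increase(8126, 5999), 35.5)
  expect_equal(percent_increase(123.4, 123.4), 0)
  expect_equal(percent_increase(6565, 5999, digits = NULL), 100 * 566 / 5999)
  expect_error(percent_increase(10, 0), "> 0")
})

test_that("evaluate_strategies recovers an injected category effect", {
  p <- sim_params(
    wt_mean_by_env = c(Havelock = 5999, Mead = 2335),
    line_var = 100, block_var = 100, resid_var = 2500,
    epi_mixture = list(fraction_up = 0, fraction_down = 0, fraction_null = 1,
                       mean_up = 0, mean_down = 0),
    gxe_scale = 0, n_epi_lines = 150, n_wt_lines = 19,
    plants_per_line_per_rep = 1, n_reps_by_env = c(Havelock = 3, Mead = 2),
    seed = 11)
  d <- simulate_epiF3_multienv_trial(p, category_effects = list(ML.HI = 0.20))
  res <- evaluate_strategies(d, category_map_of(d), "Havelock")
  nine <- res[res$strategy == "line_and_individual", ]
  expect_lt(abs(nine$percent_increase[nine$group == "ML.HI"] - 20), 2)
  expect_true(all(abs(nine$percent_increase[nine$group != "ML.HI"]) < 2))
  # all three strategies reported, groups complete
  expect_setequal(unique(res$strategy),
                  c("unselected", "line_mean", "line_and_individual"))
  expect_equal(sum(res$strategy == "line_and_individual"), 9)
})

test_that("empty groups are flagged not-estimable, never dropped", {
  p <- default_epiF3_params(seed = 2)
  d <- simulate_epiF3_multienv_trial(p)
  cmap <- category_map_of(d)
  cmap[cmap == "LL.LI"] <- "LL.MI"  # empty one category
  res <- suppressWarnings(evaluate_strategies(d, cmap, "Mead"))
  row <- res[res$strategy == "line_and_individual" & res$group == "LL.LI", ]
  expect_false(row$estimable)
  expect_equal(row$n_plots, 0L)
})

test_that("unselected mean equals the plot-weighted mean of line-mean groups (raw mode)", {
  p <- default_epiF3_params(seed = 8)
  d <- simulate_epiF3_multienv_trial(p)
  res <- evaluate_strategies(d, category_map_of(d), "Havelock", mode = "raw")
  un <- res[res$strategy == "unselected", ]
  lm3 <- res[res$strategy == "line_mean", ]
  wmean <- sum(lm3$group_mean_yield * lm3$n_plots) / sum(lm3$n_plots)
  expect_equal(un$group_mean_yield, wmean, tolerance = 1e-10)
})

test_that("epi lines missing from the category map are dropped with a warning", {
  p <- default_epiF3_params(seed = 2)
  d <- simulate_epiF3_multienv_trial(p)
  cmap <- category_map_of(d)
  cmap <- cmap[-(1:5)]
  expect_warning(res <- evaluate_strategies(d, cmap, "Mead", mode = "raw"),
                 "dropping")
  expect_equal(res$n_lines[res$strategy == "unselected"],
               p$n_epi_lines - 5L)
})
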