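# Independent oracles used across tests. These deliberately avoid the package
# code paths they check.

# type-7 percentile by explicit sort-and-interpolate
oracle_quantile_type7 <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# brute-force double-loop nine-category classifier
oracle_classify <- function(line_id, yield, p30, p70) {
  cls <- function(v) if (v < p30) "L" else if (v > p70) "H" else "M"
  means <- tapply(yield, line_id, mean)
  out <- character(length(yield))
  for (i in seq_along(yield)) {
    lc <- cls(means[[line_id[i]]])
    ic <- cls(yield[i])
    out[i] <- paste0(lc, "L.", ic, "I")
  }
  out
}

# numerical integration of the piecewise-linear interpolant, one adaptive
# quadrature call per segment (robust and accurate to ~1e-12)
oracle_aupec_integrate <- function(days, values) {
  f <- stats::approxfun(days, values)
  sum(vapply(seq_len(length(days) - 1), function(i) {
    stats::integrate(f, days[i], days[i + 1])$value
  }, numeric(1)))
}

# closed-form simple-regression slope
oracle_slope <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

# balanced small plant trial with known genotype means, for LS-mean identity
make_balanced_trial <- function(genotype_means, n_blocks = 4, n_per_cell = 3,
                                block_sd = 2, resid_sd = 1, seed = 42) {
  set.seed(seed)
  g <- names(genotype_means)
  d <- expand.grid(line_id = g, block = paste0("B", seq_len(n_blocks)),
                   plant = seq_len(n_per_cell), stringsAsFactors = FALSE)
  b_eff <- stats::setNames(rnorm(n_blocks, 0, block_sd), paste0("B", seq_len(n_blocks)))
  d$yield_g <- genotype_means[d$line_id] + b_eff[d$block] + rnorm(nrow(d), 0, resid_sd)
  d$cohort <- ifelse(d$line_id == "WT", "WT", "epiF2")
  d$replication <- 1L
  d
}

# category map covering every epi line of a simulated plot trial
category_map_of <- function(plots) {
  epi <- plots[plots$cohort != "WT", ]
  m <- stats::setNames(epi$category, epi$line_id)
  m[!duplicated(names(m))]
}
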