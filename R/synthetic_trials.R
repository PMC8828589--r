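# Synthetic field-trial generator.
#
# Emulates the statistical structure of a two-stage epigenetic selection
# experiment: an augmented incomplete-block single-plant trial (epi-F2 stage,
# g/plant), a multi-location lattice plot trial (epi-F3 stage, kg/ha), a
# cold-stress emergence time course, and reversion-count draws. Everything is
# deterministic given the root seed; each operation draws from its own
# sub-stream so adding one stage never perturbs another.

#' Simulation parameters for synthetic trials
#'
#' Bundles the variance components, epi-effect mixture, genotype-by-environment
#' (GxE) and reversion parameters that govern the synthetic generators. Units
#' follow the trial being simulated: g/plant for the single-plant (F2-style)
#' trial, kg/ha for the plot (F3-style) trial.
#'
#' @param wt_mean_by_env named numeric vector, wild-type mean yield per
#'   environment (g/plant or kg/ha).
#' @param line_var between-line variance beyond the epi mixture (units^2).
#' @param block_var between-incomplete-block variance (units^2).
#' @param resid_var residual (within-plot / within-line) variance (units^2).
#' @param epi_mixture list with `fraction_up`, `fraction_down`, `fraction_null`
#'   (non-negative, summing to 1) and `mean_up`, `mean_down` (positive effect
#'   magnitudes in trait units). Lines draw their heritable epi effect from
#'   this three-component mixture; the skew (more up than down) mirrors the
#'   asymmetric line counts such populations show.
#' @param gxe_scale per-line multiplicative sensitivity s.d. to the low-input
#'   environment (dimensionless, >= 0). 0 switches GxE off.
#' @param tiller_yield_rho target plant-level correlation between tiller count
#'   and yield, in [-1, 1].
#' @param reversion_rate per-plant probability of carrying the revertant
#'   allele, in [0, 1].
#' @param n_epi_lines,n_wt_lines,plants_per_line_per_rep integer design counts.
#' @param n_reps_by_env named integer vector, replications per environment.
#' @param seed integer root seed.
#' @return an object of class `sim_params` (a validated list).
#' @seealso [default_epiF2_params()], [default_epiF3_params()]
#' @export
sim_params <- function(wt_mean_by_env,
                       line_var, block_var, resid_var,
                       epi_mixture = list(fraction_up = 0.09, fraction_down = 0.04,
                                          fraction_null = 0.87,
                                          mean_up = 11, mean_down = 9),
                       gxe_scale = 0.15,
                       tiller_yield_rho = 0.52,
                       reversion_rate = 0.0013,
                       n_epi_lines = 100, n_wt_lines = 1,
                       plants_per_line_per_rep = 15,
                       n_reps_by_env = NULL,
                       seed = 1L) {
  if (is.null(names(wt_mean_by_env)) || any(!nzchar(names(wt_mean_by_env)))) {
    stop_domain("`wt_mean_by_env` must be a named vector of environment means")
  }
  if (is.null(n_reps_by_env)) {
    n_reps_by_env <- stats::setNames(rep(3L, length(wt_mean_by_env)),
                                     names(wt_mean_by_env))
  }
  if (!all(names(n_reps_by_env) %in% names(wt_mean_by_env))) {
    stop_domain("`n_reps_by_env` names must match `wt_mean_by_env`")
  }
  for (v in c(line_var = line_var, block_var = block_var, resid_var = resid_var)) {
    if (!is.finite(v) || v < 0) stop_domain("variance components must be finite and >= 0")
  }
  fr <- c(epi_mixture$fraction_up, epi_mixture$fraction_down, epi_mixture$fraction_null)
  if (length(fr) != 3 || any(fr < 0) || abs(sum(fr) - 1) > 1e-9) {
    stop_domain("epi mixture fractions must be non-negative and sum to 1 (tol 1e-9)")
  }
  if (abs(tiller_yield_rho) > 1) stop_domain("`tiller_yield_rho` must be in [-1, 1]")
  assert_scalar_prob(reversion_rate, "reversion_rate")
  if (gxe_scale < 0) stop_domain("`gxe_scale` must be >= 0")
  counts <- c(n_epi_lines, n_wt_lines, plants_per_line_per_rep, n_reps_by_env)
  if (any(counts < 1) || any(counts != round(counts))) {
    stop_domain("design counts must be integers >= 1")
  }
  structure(list(
    wt_mean_by_env = wt_mean_by_env,
    line_var = line_var, block_var = block_var, resid_var = resid_var,
    epi_mixture = epi_mixture, gxe_scale = gxe_scale,
    tiller_yield_rho = tiller_yield_rho, reversion_rate = reversion_rate,
    n_epi_lines = as.integer(n_epi_lines), n_wt_lines = as.integer(n_wt_lines),
    plants_per_line_per_rep = as.integer(plants_per_line_per_rep),
    n_reps_by_env = as.integer(n_reps_by_env) |>
      stats::setNames(names(n_reps_by_env)),
    seed = as.integer(seed)
  ), class = "sim_params")
}

#' Default parameters emulating the single-plant (epi-F2 style) trial
#'
#' 100 epi families plus pooled wild-type checks, 3 replications, 15 measured
#' plants per row (45 per family), g/plant units. The wild-type per-plant
#' yield distribution is centred at 69 g with s.d. about 21 g so its 30th/70th
#' percentiles fall near 58 and 80 g, the cutoffs used downstream. The epi
#' mixture is skewed upward (9% up by ~11 g, 4% down by ~9 g), reflecting the
#' asymmetry seen in such populations.
#'
#' @param seed integer root seed.
#' @return a `sim_params` object.
#' @export
default_epiF2_params <- function(seed = 1L) {
  sim_params(
    wt_mean_by_env = c(Havelock = 69),
    line_var = 1, block_var = 16, resid_var = 441,
    epi_mixture = list(fraction_up = 0.09, fraction_down = 0.04,
                       fraction_null = 0.87, mean_up = 11, mean_down = 9),
    tiller_yield_rho = 0.52, reversion_rate = 0.0013,
    n_epi_lines = 100, n_wt_lines = 1, plants_per_line_per_rep = 15,
    n_reps_by_env = c(Havelock = 3), seed = seed
  )
}

#' Default parameters emulating the multi-location plot (epi-F3 style) trial
#'
#' 150 epi lines plus 19 wild-type check lines in a 13 x 13 lattice, 3
#' replications at the normal-input location and 2 at the low-nitrogen one,
#' kg/ha units with wild-type means 5999 and 2335 kg/ha.
#'
#' @param seed integer root seed.
#' @return a `sim_params` object.
#' @export
default_epiF3_params <- function(seed = 1L) {
  sim_params(
    wt_mean_by_env = c(Havelock = 5999, Mead = 2335),
    line_var = 90000, block_var = 40000, resid_var = 202500,
    epi_mixture = list(fraction_up = 0.09, fraction_down = 0.04,
                       fraction_null = 0.87, mean_up = 600, mean_down = 450),
    gxe_scale = 0.15, tiller_yield_rho = 0.52, reversion_rate = 0.0013,
    n_epi_lines = 150, n_wt_lines = 19, plants_per_line_per_rep = 1,
    n_reps_by_env = c(Havelock = 3, Mead = 2), seed = seed
  )
}

# variance of the 3-component epi-effect mixture
mixture_var <- function(mx) {
  m <- mx$fraction_up * mx$mean_up - mx$fraction_down * mx$mean_down
  mx$fraction_up * mx$mean_up^2 + mx$fraction_down * mx$mean_down^2 - m^2
}

mixture_mean <- function(mx) {
  mx$fraction_up * mx$mean_up - mx$fraction_down * mx$mean_down
}

# Draw one heritable epi effect per line from the up/null/down mixture.
draw_epi_effects <- function(n, mx) {
  u <- stats::runif(n)
  effect <- numeric(n)
  effect[u < mx$fraction_up] <- mx$mean_up
  effect[u >= mx$fraction_up & u < mx$fraction_up + mx$fraction_down] <- -mx$mean_down
  effect
}

# Attenuation of the latent-Gaussian -> Poisson copula: correlation between a
# standard normal Z and qpois(pnorm(Z), lambda), evaluated by quadrature. Used
# to inflate the latent correlation so the realised count-yield correlation
# hits the requested target.
poisson_copula_attenuation <- function(lambda) {
  if (lambda <= 0) return(0)
  z <- seq(-6, 6, length.out = 4001)
  w <- stats::dnorm(z); w <- w / sum(w)
  g <- stats::qpois(stats::pnorm(z), lambda)
  mg <- sum(w * g)
  vg <- sum(w * (g - mg)^2)
  if (vg <= 0) return(0)
  sum(w * z * (g - mg)) / sqrt(vg)
}

# incomplete-block labels: entries are chunked into blocks of `block_size`
# within each replication, after a seeded shuffle
assign_blocks <- function(entries, block_size, rep_id) {
  n <- length(entries)
  n_blocks <- ceiling(n / block_size)
  blk <- rep(seq_len(n_blocks), each = block_size)[seq_len(n)]
  sprintf("R%dB%02d", rep_id, blk)
}

#' Simulate a single-plant augmented incomplete-block trial
#'
#' Generates one record per plant for every (line, replication) cell. Epi
#' lines carry a heritable line-level effect drawn from the skewed up/null/down
#' mixture plus a Gaussian line deviation; wild-type checks are inserted in
#' every incomplete block and carry no epi effect. Tiller counts are coupled
#' to yield through a latent-Gaussian copula calibrated (by quadrature) so the
#' realised plant-level correlation matches `tiller_yield_rho`. Heights are
#' Gaussian and flowering dates Gamma, both inheriting a share of the line
#' effect. Deterministic given `params$seed`.
#'
#' @param params a [sim_params()] object (single environment).
#' @return a data.frame of plant records: `line_id`, `family_id`, `cohort`,
#'   `environment_id`, `replication`, `block`, `yield_g`, `height_cm`,
#'   `tiller_count`, `days_to_flowering`, `revertant`.
#' @export
simulate_epiF2_trial <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  env <- names(params$wt_mean_by_env)[1]
  m <- params$wt_mean_by_env[[1]]
  n_ep <- params$n_epi_lines
  n_rep <- params$n_reps_by_env[[env]] %||% params$n_reps_by_env[[1]]
  ppl <- params$plants_per_line_per_rep
  mx <- params$epi_mixture

  with_stream(params$seed, 1L, {
    epi_ids <- sprintf("EPI%03d", seq_len(n_ep))
    epi_eff <- draw_epi_effects(n_ep, mx) + stats::rnorm(n_ep, 0, sqrt(params$line_var))
    names(epi_eff) <- epi_ids
    # block layout: 10 epi entries + 1 WT check per incomplete block, per rep
    rows <- vector("list", n_rep)
    for (r in seq_len(n_rep)) {
      ord <- sample(epi_ids)
      blk_epi <- assign_blocks(ord, 10L, r)
      blocks <- unique(blk_epi)
      entries <- data.frame(
        line_id = c(ord, rep("WT", length(blocks))),
        block = c(blk_epi, blocks),
        stringsAsFactors = FALSE
      )
      entries$replication <- r
      rows[[r]] <- entries
    }
    layout <- do.call(rbind, rows)
    blocks_all <- unique(layout[c("replication", "block")])
    blk_eff <- stats::rnorm(nrow(blocks_all), 0, sqrt(params$block_var))
    names(blk_eff) <- paste0(blocks_all$replication, "/", blocks_all$block)

    n_plants <- nrow(layout) * ppl
    idx <- rep(seq_len(nrow(layout)), each = ppl)
    line <- layout$line_id[idx]
    is_wt <- line == "WT"
    eff <- ifelse(is_wt, 0, epi_eff[line])
    beff <- blk_eff[paste0(layout$replication[idx], "/", layout$block[idx])]

    z_y <- stats::rnorm(n_plants)
    yield <- pmax(0, m + eff + beff + sqrt(params$resid_var) * z_y)

    # standardized total yield deviation drives the tiller copula
    v_tot <- mixture_var(mx) + params$line_var + params$block_var + params$resid_var
    z_tot <- if (v_tot > 0) {
      (yield - m - ifelse(is_wt, 0, mixture_mean(mx))) / sqrt(v_tot)
    } else rep(0, n_plants)
    lambda_t <- 2
    k1 <- poisson_copula_attenuation(lambda_t)
    a <- if (k1 > 0) max(-0.999, min(0.999, params$tiller_yield_rho / k1)) else 0
    w <- stats::rnorm(n_plants)
    z_t <- a * z_tot + sqrt(1 - a^2) * w
    tiller <- stats::qpois(stats::pnorm(z_t), lambda_t)

    # height (cm): taller-skewed share of the line effect
    h_line <- ifelse(is_wt, 0, 1.5 * pmax(eff, 0) + 0.4 * pmin(eff, 0))
    height <- pmax(0, 120 + h_line + stats::rnorm(n_plants, 0, 8))

    # days to flowering: Gamma, slightly delayed in up-effect lines
    fl_mu <- 70 * exp(ifelse(is_wt, 0, 0.004 * eff))
    shape <- 400  # cv = 5%
    flowering <- pmax(1, round(stats::rgamma(n_plants, shape = shape,
                                             rate = shape / fl_mu)))

    revertant <- stats::runif(n_plants) < params$reversion_rate

    data.frame(
      line_id = line,
      family_id = ifelse(is_wt, "WT", line),
      cohort = ifelse(is_wt, "WT", "epiF2"),
      environment_id = env,
      replication = layout$replication[idx],
      block = layout$block[idx],
      yield_g = yield,
      height_cm = height,
      tiller_count = as.integer(tiller),
      days_to_flowering = as.integer(flowering),
      revertant = revertant,
      stringsAsFactors = FALSE
    )
  })
}

# default line counts per selection category: at least 10 lines each, 30 in
# the medium-individual cells, totalling 150
default_category_counts <- function() {
  c(LL.LI = 10, LL.MI = 30, LL.HI = 10,
    ML.LI = 10, ML.MI = 30, ML.HI = 10,
    HL.LI = 10, HL.MI = 30, HL.HI = 10)
}

#' Simulate a multi-location lattice plot trial
#'
#' Generates plot-level standardized yields for epi lines (each belonging to
#' one of the nine selection categories) and wild-type check lines across the
#' environments in `params$wt_mean_by_env`. Category effects shift a line's
#' expected yield proportionally to the environment wild-type mean; GxE enters
#' as a per-line multiplicative sensitivity to the lowest-mean (low-input)
#' environment with s.d. `gxe_scale`. Wild-type lines have neither. Raw plot
#' weight and moisture are back-computed so that [standardize_yield()]
#' round-trips to the stored `yield_kg_ha_std`. Deterministic given seed.
#'
#' @param params a [sim_params()] object with one entry per environment.
#' @param category_effects optional named list/vector: category label ->
#'   proportional yield effect (e.g. 0.2 for +20%), either a single number
#'   applied in every environment or a named vector by environment.
#' @param category_of_line optional named character vector mapping epi line ids
#'   to category labels; defaults to a layout with the study's category sizes.
#' @param plot_area_m2 harvested plot area (m^2).
#' @return a data.frame of plot records: `line_id`, `cohort`,
#'   `environment_id`, `replication`, `block`, `raw_grain_weight`,
#'   `moisture_g_per_kg`, `plot_area_m2`, `yield_kg_ha_std`, `category`.
#' @export
simulate_epiF3_multienv_trial <- function(params, category_effects = NULL,
                                          category_of_line = NULL,
                                          plot_area_m2 = 7.43) {
  stopifnot(inherits(params, "sim_params"))
  envs <- names(params$wt_mean_by_env)
  labels <- names(default_category_counts())
  if (!is.null(category_effects)) {
    if (!all(names(category_effects) %in% labels)) {
      stop_domain("unknown category label in `category_effects`")
    }
    for (ce in category_effects) {
      ns <- names(ce)
      if (!is.null(ns) && !all(ns %in% envs)) {
        stop_domain("unknown environment id in `category_effects`")
      }
    }
  }

  n_ep <- params$n_epi_lines
  epi_ids <- sprintf("EPI%03d", seq_len(n_ep))
  if (is.null(category_of_line)) {
    cnt <- default_category_counts()
    pool <- rep(names(cnt), times = cnt)
    pool <- rep_len(pool, n_ep)
    category_of_line <- stats::setNames(pool, epi_ids)
  } else {
    if (!all(epi_ids %in% names(category_of_line))) {
      stop_domain("`category_of_line` must name every epi line")
    }
  }
  wt_ids <- sprintf("WT%02d", seq_len(params$n_wt_lines))

  eff_of <- function(cat, env) {
    if (is.null(category_effects) || !cat %in% names(category_effects)) return(0)
    ce <- category_effects[[cat]]
    if (is.null(names(ce))) ce[[1]] else (ce[[env]] %||% 0)
  }

  low_env <- envs[which.min(params$wt_mean_by_env)]

  with_stream(params$seed, 2L, {
    dev_l <- stats::rnorm(n_ep, 0, sqrt(params$line_var))
    names(dev_l) <- epi_ids
    sens <- 1 + params$gxe_scale * stats::rnorm(n_ep)
    sens <- pmax(0.05, sens)
    names(sens) <- epi_ids

    all_ids <- c(epi_ids, wt_ids)
    block_size <- ceiling(sqrt(length(all_ids)))
    out <- list()
    for (env in envs) {
      m_e <- params$wt_mean_by_env[[env]]
      n_rep <- params$n_reps_by_env[[env]] %||% 1L
      for (r in seq_len(n_rep)) {
        ord <- sample(all_ids)
        blk <- assign_blocks(ord, block_size, r)
        b_eff <- stats::rnorm(length(unique(blk)), 0, sqrt(params$block_var))
        names(b_eff) <- unique(blk)
        is_wt <- startsWith(ord, "WT")
        cat_l <- ifelse(is_wt, NA_character_, category_of_line[ord])
        eff <- vapply(seq_along(ord), function(i) {
          if (is_wt[i]) 0 else eff_of(cat_l[i], env)
        }, numeric(1))
        s <- ifelse(is_wt | env != low_env, 1, sens[ord])
        mu <- m_e * s * (1 + eff) + ifelse(is_wt, 0, dev_l[ord])
        yld <- pmax(0, mu + b_eff[blk] + stats::rnorm(length(ord), 0, sqrt(params$resid_var)))
        moist <- round(pmin(300, pmax(50, stats::rnorm(length(ord), 140, 10))), 1)
        raw <- yld * plot_area_m2 / 10000 * (1000 - 140) / (1000 - moist)
        out[[length(out) + 1L]] <- data.frame(
          line_id = ord,
          cohort = ifelse(is_wt, "WT", "epiF3"),
          environment_id = env,
          replication = r,
          block = blk,
          raw_grain_weight = raw,
          moisture_g_per_kg = moist,
          plot_area_m2 = plot_area_m2,
          yield_kg_ha_std = yld,
          category = cat_l,
          stringsAsFactors = FALSE
        )
      }
    }
    do.call(rbind, out)
  })
}

#' Simulate cold-stress and standard-planting emergence series
#'
#' Each line gets two cumulative emergence series on the same day grid: a
#' standard planting reaching near-full emergence and an early (cold-stress)
#' planting whose logistic emergence curve is shifted right by the line's
#' stress delay (days). A delay of 0 reproduces the standard curve exactly in
#' noise-free mode; an infinite delay gives zero emergence. With `noise =
#' TRUE`, per-seed emergence times are drawn so counts are integer, cumulative
#' and stochastic. Deterministic given seed.
#'
#' @param params a [sim_params()] object (seed and line count are used).
#' @param stress_delay_by_line named numeric vector, cold-stress delay in days
#'   per line (may be `Inf`).
#' @param days strictly increasing positive observation days after planting;
#'   defaults to the 13-point grid days 13..46 used in field practice.
#' @param n_seeds seeds planted per line.
#' @param t50 day of 50% emergence under standard planting.
#' @param scale logistic time scale (days).
#' @param noise logical; draw per-seed emergence times instead of rounding the
#'   expected curve.
#' @return long data.frame: `line_id`, `planting` ("early"/"standard"),
#'   `day`, `count`.
#' @export
simulate_emergence <- function(params, stress_delay_by_line,
                               days = c(13, 14, 15, 16, 17, 18, 20, 22, 25, 27, 32, 39, 46),
                               n_seeds = 30, t50 = 14, scale = 1.5,
                               noise = TRUE) {
  stopifnot(inherits(params, "sim_params"))
  if (any(diff(days) <= 0) || any(days <= 0)) {
    stop_domain("`days` must be a strictly increasing positive sequence")
  }
  lines <- names(stress_delay_by_line)
  if (is.null(lines)) stop_domain("`stress_delay_by_line` must be named by line")

  with_stream(params$seed, 3L, {
    out <- list()
    for (ln in lines) {
      d <- stress_delay_by_line[[ln]]
      if (noise) {
        t_std <- t50 + stats::rlogis(n_seeds, 0, scale)
        t_cold <- t50 + d + stats::rlogis(n_seeds, 0, scale)
        cnt_std <- vapply(days, function(dd) sum(t_std <= dd), numeric(1))
        cnt_cold <- vapply(days, function(dd) sum(t_cold <= dd), numeric(1))
      } else {
        cnt_std <- round(n_seeds * stats::plogis((days - t50) / scale))
        cnt_cold <- if (is.infinite(d)) rep(0, length(days)) else {
          round(n_seeds * stats::plogis((days - t50 - d) / scale))
        }
      }
      out[[length(out) + 1L]] <- data.frame(
        line_id = ln,
        planting = rep(c("early", "standard"), each = length(days)),
        day = rep(days, 2),
        count = as.integer(c(cnt_cold, cnt_std)),
        stringsAsFactors = FALSE
      )
    }
    do.call(rbind, out)
  })
}

#' Simulate a revertant count
#'
#' One binomial draw: the number of plants among `n_plants` carrying the
#' revertant allele at per-plant probability `rate`.
#'
#' @param n_plants positive integer number of plants screened.
#' @param rate per-plant reversion probability in [0, 1].
#' @param seed integer seed.
#' @return integer count of revertants.
#' @export
simulate_reversion_counts <- function(n_plants, rate, seed = 1L) {
  if (n_plants < 1 || n_plants != round(n_plants)) {
    stop_domain("`n_plants` must be a positive integer")
  }
  assert_scalar_prob(rate, "rate")
  with_stream(seed, 4L, stats::rbinom(1, n_plants, rate))
}
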