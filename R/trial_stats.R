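# Per-trait trial models and contrasts.
#
# The analysis model is y_ij ~ genotype_i + block_j + e_ij with genotype fixed
# and block random, fitted by REML (lme4). Tiller counts use a Poisson model
# with log link, days to flowering a Gamma model with log link; both keep the
# same genotype + random-block structure. Wild-type checks are pooled into a
# single genotype level which serves as the contrast reference.

#' Specification of a per-trait model
#'
#' @param trait column name of the response.
#' @param family "gaussian-mixed" (identity link, REML), "poisson-log" or
#'   "gamma" (log link).
#' @param alpha significance level for directional calls, in (0, 1).
#' @return a `trait_model_spec` list.
#' @export
trait_model_spec <- function(trait,
                             family = c("gaussian-mixed", "poisson-log", "gamma"),
                             alpha = 0.05) {
  family <- match.arg(family)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop_domain("`alpha` must be in (0, 1)")
  }
  structure(list(trait = trait, family = family, alpha = alpha),
            class = "trait_model_spec")
}

# default model family per standard trait name
default_model_for_trait <- function(trait) {
  switch(trait,
         tiller_count = "poisson-log",
         days_to_flowering = "gamma",
         "gaussian-mixed")
}

#' Fit the per-trait trial model
#'
#' Fits genotype (fixed) + incomplete block (random) to plant- or plot-level
#' records. Genotypes are the epi line ids plus a pooled "WT" level built from
#' all `cohort == "WT"` rows; WT is the reference level so fixed-effect
#' coefficients are line-vs-WT differences on the link scale. With fewer than
#' two blocks the model degrades to fixed effects with a warning.
#'
#' @param records data.frame with `line_id`, `cohort`, `block` and the trait
#'   column.
#' @param spec a [trait_model_spec()].
#' @return a `trait_fit` object: list with `spec`, `genotypes`, `wt_level`,
#'   `coef` (named line-vs-WT differences), `se`, `intercept` (WT estimate,
#'   link scale), `block_var`, `resid_var`, `converged`, `messages`, `n_obs`,
#'   and the underlying `fit`.
#' @export
fit_trait_model <- function(records, spec) {
  stopifnot(inherits(spec, "trait_model_spec"),
            is.data.frame(records),
            all(c("line_id", "cohort", "block") %in% names(records)),
            spec$trait %in% names(records))
  d <- records
  d$genotype <- ifelse(d$cohort == "WT", "WT", d$line_id)
  if (!"WT" %in% d$genotype) stop_domain("no wild-type rows present")
  if (length(unique(d$genotype)) < 2) stop_domain("need >= 2 genotype levels")
  d$genotype <- stats::relevel(factor(d$genotype), ref = "WT")
  d$.block <- factor(paste(d$replication %||% "", d$block))
  use_random <- nlevels(d$.block) >= 2

  y <- spec$trait
  msgs <- character(0)
  converged <- TRUE

  if (!use_random) {
    warning("fewer than 2 blocks: degrading to fixed-effects model")
    msgs <- c(msgs, "fixed-effects fallback (single block)")
  }

  if (spec$family == "gaussian-mixed") {
    if (use_random) {
      fit <- lme4::lmer(stats::reformulate(c("genotype", "(1 | .block)"), response = y),
                        data = d, REML = TRUE,
                        control = lme4::lmerControl(calc.derivs = FALSE))
      vc <- as.data.frame(lme4::VarCorr(fit))
      block_var <- vc$vcov[vc$grp == ".block"]
      resid_var <- vc$vcov[vc$grp == "Residual"]
      fe <- lme4::fixef(fit)
      se <- sqrt(diag(as.matrix(stats::vcov(fit))))
    } else {
      fit <- stats::lm(stats::reformulate("genotype", response = y), data = d)
      block_var <- 0
      resid_var <- summary(fit)$sigma^2
      fe <- stats::coef(fit)
      se <- sqrt(diag(stats::vcov(fit)))
    }
  } else {
    fam <- if (spec$family == "poisson-log") stats::poisson("log") else stats::Gamma("log")
    if (use_random) {
      # nAGQ = 0 estimates the (large) fixed-effect vector inside PIRLS
      # rather than in the outer optimizer; with ~100 genotype levels the
      # default Laplace search is infeasibly slow and no more accurate here.
      fit <- tryCatch(
        lme4::glmer(stats::reformulate(c("genotype", "(1 | .block)"), response = y),
                    data = d, family = fam, nAGQ = 0L,
                    control = lme4::glmerControl(calc.derivs = FALSE)),
        warning = function(w) {
          msgs <<- c(msgs, conditionMessage(w))
          suppressWarnings(
            lme4::glmer(stats::reformulate(c("genotype", "(1 | .block)"), response = y),
                        data = d, family = fam, nAGQ = 0L,
                        control = lme4::glmerControl(calc.derivs = FALSE)))
        },
        error = function(e) {
          msgs <<- c(msgs, conditionMessage(e)); NULL
        })
      if (is.null(fit)) {
        converged <- FALSE
        fit <- stats::glm(stats::reformulate("genotype", response = y), data = d, family = fam)
        block_var <- NA_real_
        resid_var <- summary(fit)$dispersion
        fe <- stats::coef(fit)
        se <- sqrt(diag(stats::vcov(fit)))
      } else {
        vc <- as.data.frame(lme4::VarCorr(fit))
        block_var <- vc$vcov[vc$grp == ".block"][1]
        resid_var <- stats::sigma(fit)^2
        fe <- lme4::fixef(fit)
        se <- sqrt(diag(as.matrix(stats::vcov(fit))))
      }
    } else {
      fit <- stats::glm(stats::reformulate("genotype", response = y), data = d, family = fam)
      block_var <- 0
      resid_var <- summary(fit)$dispersion
      fe <- stats::coef(fit)
      se <- sqrt(diag(stats::vcov(fit)))
    }
  }

  coef_lines <- fe[grep("^genotype", names(fe))]
  names(coef_lines) <- sub("^genotype", "", names(coef_lines))
  se_lines <- se[grep("^genotype", names(se))]
  names(se_lines) <- sub("^genotype", "", names(se_lines))

  structure(list(
    spec = spec,
    genotypes = levels(d$genotype),
    wt_level = "WT",
    intercept = unname(fe[1]),
    coef = coef_lines,
    se = se_lines,
    block_var = block_var,
    resid_var = resid_var,
    converged = converged,
    messages = msgs,
    n_obs = nrow(d),
    fit = fit
  ), class = "trait_fit")
}

#' @export
print.trait_fit <- function(x, ...) {
  cat(sprintf("Trait model: %s (%s), %d genotypes, %d obs\n",
              x$spec$trait, x$spec$family, length(x$genotypes), x$n_obs))
  cat(sprintf("  block var %.4g, resid var %.4g, converged: %s\n",
              x$block_var, x$resid_var, x$converged))
  invisible(x)
}

# link-scale estimate -> response scale
inv_link <- function(fit, eta) {
  if (fit$spec$family == "gaussian-mixed") eta else exp(eta)
}

#' Line-vs-wild-type contrasts from a fitted trait model
#'
#' One contrast per epi line against the pooled wild-type level. Differences
#' and p-values (Wald, normal reference) are on the link scale; least-squares
#' means are reported on the response scale. The WT contrasted with itself is
#' included with difference 0 and p = 1 by convention.
#'
#' @param fitted a `trait_fit` from [fit_trait_model()].
#' @param alpha significance level (defaults to the spec's).
#' @param adjust "none" (default, matching raw pairwise reporting) or "BH" for
#'   Benjamini-Hochberg.
#' @return data.frame: `line_id`, `trait`, `ls_mean`, `wt_ls_mean`,
#'   `difference`, `p_value`, `direction` ("higher"/"lower"/"ns").
#' @export
contrast_lines_vs_wt <- function(fitted, alpha = NULL, adjust = c("none", "BH")) {
  stopifnot(inherits(fitted, "trait_fit"))
  adjust <- match.arg(adjust)
  alpha <- alpha %||% fitted$spec$alpha
  lines <- names(fitted$coef)
  z <- fitted$coef / fitted$se
  p <- 2 * stats::pnorm(-abs(z))
  if (adjust == "BH") p <- stats::p.adjust(p, method = "BH")
  res <- data.frame(
    line_id = c(fitted$wt_level, lines),
    trait = fitted$spec$trait,
    ls_mean = inv_link(fitted, fitted$intercept + c(0, unname(fitted$coef))),
    wt_ls_mean = inv_link(fitted, fitted$intercept),
    difference = c(0, unname(fitted$coef)),
    p_value = c(1, unname(p)),
    stringsAsFactors = FALSE
  )
  res$direction <- ifelse(res$p_value >= alpha, "ns",
                          ifelse(res$difference > 0, "higher", "lower"))
  res
}

#' Two-sided Fisher's exact test for a 2x2 count table
#'
#' Point-probability method: the p-value sums the probabilities of all tables
#' (with the observed margins) whose hypergeometric probability does not
#' exceed that of the observed table, with a small relative tolerance against
#' floating-point ties — the common two-sided convention.
#'
#' @param table a 2x2 matrix (or something coercible) of non-negative integer
#'   counts, e.g. `rbind(c(revertants_1, non_1), c(revertants_2, non_2))`.
#' @return the two-sided p-value.
#' @export
fisher_reversion_test <- function(table) {
  m <- as.matrix(table)
  if (!all(dim(m) == c(2, 2))) stop_domain("need a 2x2 table")
  if (any(m < 0) || any(m != round(m)) || any(!is.finite(m))) {
    stop_domain("counts must be non-negative integers")
  }
  a <- m[1, 1]
  r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); n <- sum(m)
  if (n == 0) return(1)
  lo <- max(0, r1 + c1 - n); hi <- min(r1, c1)
  x <- lo:hi
  px <- stats::dhyper(x, c1, n - c1, r1)
  p_obs <- stats::dhyper(a, c1, n - c1, r1)
  p <- sum(px[px <= p_obs * (1 + 1e-7)])
  min(1, p)
}

#' Reversion frequency as a percent
#'
#' @param n_revertants,n_total non-negative integers, `n_revertants <=
#'   n_total`, `n_total > 0`.
#' @param digits decimals to report (default 2, the usual printed precision),
#'   or NULL for full precision.
#' @return percent of plants carrying the revertant allele.
#' @export
reversion_frequency <- function(n_revertants, n_total, digits = 2) {
  if (any(n_total <= 0)) stop_domain("`n_total` must be > 0")
  if (any(n_revertants < 0) || any(n_revertants > n_total)) {
    stop_domain("`n_revertants` must be in [0, n_total]")
  }
  p <- 100 * n_revertants / n_total
  if (is.null(digits)) p else round_half_up(p, digits)
}

#' Standardize plot yield to kg/ha at 140 g/kg moisture
#'
#' Dry-matter-preserving rescale:
#' `raw_weight * (1000 - moisture) / (1000 - 140) * (10000 / area)`.
#'
#' @param raw_weight harvested grain weight per plot (kg).
#' @param moisture_g_per_kg grain moisture at harvest (g/kg, in [0, 1000)).
#' @param plot_area_m2 harvested area (m^2, > 0).
#' @return standardized yield (kg/ha at 140 g/kg moisture).
#' @export
standardize_yield <- function(raw_weight, moisture_g_per_kg, plot_area_m2) {
  if (any(moisture_g_per_kg < 0) || any(moisture_g_per_kg >= 1000)) {
    stop_domain("moisture must be in [0, 1000) g/kg")
  }
  if (any(plot_area_m2 <= 0)) stop_domain("plot area must be > 0")
  raw_weight * (1000 - moisture_g_per_kg) / (1000 - 140) * (10000 / plot_area_m2)
}
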