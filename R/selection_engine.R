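# Two-level percentile classification and selection-strategy evaluation.
#
# Families are classed Low/Medium/High against the 30th and 70th percentiles
# of wild-type per-plant grain yield; individual plants are classed against
# the same cutoffs, giving nine combined categories (LL.LI ... HL.HI). Three
# retroactive selection strategies — unselected, line-mean, line-mean plus
# individual — are then evaluated on the plot trial against wild-type checks.

CATEGORY_LEVELS <- c("LL.LI", "LL.MI", "LL.HI",
                     "ML.LI", "ML.MI", "ML.HI",
                     "HL.LI", "HL.MI", "HL.HI")
LINE_CLASS_LEVELS <- c("LL", "ML", "HL")

#' Percentile cutoffs from wild-type yields
#'
#' Computes the 30th and 70th percentiles of the wild-type per-plant yield
#' distribution. The percentile definition defaults to linear interpolation
#' between order statistics (`stats::quantile` type 7); the convention is
#' exposed because published cutoffs rarely state one.
#'
#' @param wt_yields numeric vector of wild-type per-plant yields (>= 2 finite
#'   values required; NAs dropped with a warning).
#' @param probs the two probabilities (default 0.30 and 0.70).
#' @param type quantile algorithm type passed to [stats::quantile()].
#' @return a `yield_cutoffs` object: list with `p30`, `p70`, `source_n`.
#' @export
compute_cutoffs <- function(wt_yields, probs = c(0.30, 0.70), type = 7) {
  if (anyNA(wt_yields)) {
    warning("dropping NA wild-type yields")
    wt_yields <- wt_yields[!is.na(wt_yields)]
  }
  if (length(wt_yields) < 2 || !all(is.finite(wt_yields))) {
    stop_domain("need at least 2 finite wild-type yields")
  }
  q <- unname(stats::quantile(wt_yields, probs = probs, type = type))
  yield_cutoffs(q[1], q[2], source_n = length(wt_yields))
}

#' Construct yield cutoffs directly
#'
#' Use this to reproduce published analyses where the cutoffs (e.g. 58 g and
#' 80 g) are given rather than recomputed.
#'
#' @param p30,p70 the lower and upper cutoff (trait units), `p30 <= p70`.
#' @param source_n number of wild-type plants behind the percentiles (NA if
#'   taken as given).
#' @return a `yield_cutoffs` object.
#' @export
yield_cutoffs <- function(p30, p70, source_n = NA_integer_) {
  if (!is.finite(p30) || !is.finite(p70)) stop_domain("cutoffs must be finite")
  if (p30 > p70) stop_domain("p30 must be <= p70")
  structure(list(p30 = p30, p70 = p70, source_n = source_n),
            class = "yield_cutoffs")
}

#' @export
print.yield_cutoffs <- function(x, ...) {
  cat(sprintf("Yield cutoffs: p30 = %g, p70 = %g (from %s WT plants)\n",
              x$p30, x$p70,
              ifelse(is.na(x$source_n), "given", x$source_n)))
  invisible(x)
}

#' Classify a yield value as Low / Medium / High
#'
#' Boundary semantics follow the published inequalities exactly: Low strictly
#' below `p30`, High strictly above `p70`, Medium inclusive of both cutoffs
#' (`p30 <= value <= p70`).
#'
#' @param value numeric vector of yields (finite).
#' @param cutoffs a `yield_cutoffs` object.
#' @return character vector of "L", "M" or "H".
#' @export
classify_value <- function(value, cutoffs) {
  stopifnot(inherits(cutoffs, "yield_cutoffs"))
  if (any(!is.finite(value))) stop_domain("yield values must be finite")
  ifelse(value < cutoffs$p30, "L", ifelse(value > cutoffs$p70, "H", "M"))
}

#' Render a combined category label
#'
#' @param line_class,individual_class "L", "M" or "H".
#' @return labels like "ML.HI" (medium line mean, high individual); with
#'   `individual_class = NA`, the line-only labels "LL"/"ML"/"HL".
#' @export
category_label <- function(line_class, individual_class = NA_character_) {
  stopifnot(all(line_class %in% c("L", "M", "H")))
  line_part <- paste0(line_class, "L")
  ifelse(is.na(individual_class), line_part,
         paste0(line_part, ".", individual_class, "I"))
}

#' Classify every plant of a population into the nine categories
#'
#' Each plant receives a line class from its family's mean yield and an
#' individual class from its own yield, both against the same wild-type
#' percentile cutoffs; the nine combined categories partition the population.
#' Wild-type plants (`cohort == "WT"`) are passed through unclassified.
#'
#' @param records data.frame of plant records with at least `line_id` and a
#'   yield column; rows with `cohort == "WT"` are ignored for classification.
#' @param cutoffs a `yield_cutoffs` object.
#' @param yield_col name of the yield column (default "yield_g").
#' @return the epi rows of `records` with added columns `line_class`,
#'   `individual_class` and `category`.
#' @export
classify_population <- function(records, cutoffs, yield_col = "yield_g") {
  stopifnot(is.data.frame(records), yield_col %in% names(records),
            "line_id" %in% names(records))
  epi <- if ("cohort" %in% names(records)) records[records$cohort != "WT", , drop = FALSE] else records
  if (nrow(epi) == 0) stop_domain("no epi plants to classify")
  ok <- is.finite(epi[[yield_col]])
  if (!all(ok)) {
    warning(sprintf("excluding %d plants with missing yield", sum(!ok)))
    epi <- epi[ok, , drop = FALSE]
  }
  line_means <- tapply(epi[[yield_col]], epi$line_id, mean)
  epi$line_class <- classify_value(unname(line_means[epi$line_id]), cutoffs)
  epi$individual_class <- classify_value(epi[[yield_col]], cutoffs)
  epi$category <- category_label(epi$line_class, epi$individual_class)
  epi
}

#' Line-level category map from classified plants
#'
#' Collapses a [classify_population()] result to one category per line, using
#' the line class plus the class of the line's best (selected) individual by
#' default, or a caller-supplied rule.
#'
#' @param classified output of [classify_population()].
#' @param rule "modal" (most frequent individual class in the line, ties to
#'   the higher class) or "line_only".
#' @return named character vector line_id -> category label.
#' @export
line_category_map <- function(classified, rule = c("modal", "line_only")) {
  rule <- match.arg(rule)
  sp <- split(classified, classified$line_id)
  vapply(sp, function(d) {
    lc <- d$line_class[1]
    if (rule == "line_only") return(category_label(lc))
    tab <- table(factor(d$individual_class, levels = c("H", "M", "L")))
    ic <- names(tab)[which.max(tab)]
    category_label(lc, ic)
  }, character(1))
}

#' Percent increase over a reference mean
#'
#' `100 * (group_mean - ref_mean) / ref_mean`, rounded half-up to one decimal
#' by default to match conventional reporting. Use `digits = NULL` for full
#' precision.
#'
#' @param group_mean,ref_mean yields on the same scale; `ref_mean > 0`.
#' @param digits decimals to report (default 1), or NULL for no rounding.
#' @return percent increase (may be negative).
#' @export
percent_increase <- function(group_mean, ref_mean, digits = 1) {
  if (any(ref_mean <= 0)) stop_domain("reference mean must be > 0")
  p <- 100 * (group_mean - ref_mean) / ref_mean
  if (is.null(digits)) p else round_half_up(p, digits)
}

significance_stars <- function(p) {
  ifelse(is.na(p), "", ifelse(p < 0.001, "***",
                       ifelse(p < 0.01, "**",
                       ifelse(p < 0.05, "*", ""))))
}

#' Evaluate the three selection strategies on a plot trial
#'
#' For one environment, compares epi-line groups against the pooled wild-type
#' checks under three retroactive strategies: (1) unselected — all epi lines
#' as one group; (2) line-mean selection — groups LL/ML/HL; (3) line-mean plus
#' individual selection — the nine combined categories. Group means are
#' mixed-model least-squares means (genotype-group fixed, incomplete block
#' random) by default, or raw arithmetic means with Welch t-tests in
#' `mode = "raw"`. Empty groups are reported with `estimable = FALSE`, never
#' dropped silently.
#'
#' @param f3_plots data.frame of plot records (needs `line_id`, `cohort`,
#'   `environment_id`, `block`, `yield_kg_ha_std`).
#' @param category_of_line named character vector line_id -> category label
#'   (e.g. from [line_category_map()] or the generator's assignment). Epi
#'   lines missing from the map are dropped with a warning.
#' @param environment_id which environment to evaluate.
#' @param mode "lsmeans" (default) or "raw".
#' @param yield_col yield column name.
#' @return data.frame of strategy results: `strategy`, `group`,
#'   `environment_id`, `n_lines`, `n_plots`, `group_mean_yield`,
#'   `wt_mean_yield`, `percent_increase`, `p_value`, `significance`,
#'   `estimable`.
#' @export
evaluate_strategies <- function(f3_plots, category_of_line, environment_id,
                                mode = c("lsmeans", "raw"),
                                yield_col = "yield_kg_ha_std") {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(f3_plots))
  d <- f3_plots[f3_plots$environment_id == environment_id, , drop = FALSE]
  if (nrow(d) == 0) stop_domain("no plots in environment ", environment_id)
  if (!any(d$cohort == "WT")) stop_domain("no wild-type plots in environment ", environment_id)

  is_epi <- d$cohort != "WT"
  unmapped <- setdiff(unique(d$line_id[is_epi]), names(category_of_line))
  if (length(unmapped) > 0) {
    warning(sprintf("dropping %d epi lines absent from the category map", length(unmapped)))
    d <- d[!(d$line_id %in% unmapped), , drop = FALSE]
    is_epi <- d$cohort != "WT"
  }
  d$category <- ifelse(is_epi, category_of_line[d$line_id], NA_character_)
  d$line_class3 <- ifelse(is_epi, substr(d$category, 1, 2), NA_character_)

  groupings <- list(
    unselected = ifelse(is_epi, "epi", "WT"),
    line_mean = ifelse(is_epi, d$line_class3, "WT"),
    line_and_individual = ifelse(is_epi, d$category, "WT")
  )
  expected_groups <- list(
    unselected = "epi",
    line_mean = LINE_CLASS_LEVELS,
    line_and_individual = CATEGORY_LEVELS
  )

  out <- list()
  for (strat in names(groupings)) {
    d$grp <- groupings[[strat]]
    res <- group_vs_wt_contrasts(d, expected_groups[[strat]], mode, yield_col)
    res$strategy <- strat
    res$environment_id <- environment_id
    out[[strat]] <- res
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[c("strategy", "group", "environment_id", "n_lines", "n_plots",
        "group_mean_yield", "wt_mean_yield", "percent_increase",
        "p_value", "significance", "estimable")]
}

# Fit one grouping scheme against WT and return per-group results.
group_vs_wt_contrasts <- function(d, groups, mode, yield_col) {
  present <- intersect(groups, unique(d$grp))
  wt_plots <- d[d$grp == "WT", , drop = FALSE]

  if (mode == "lsmeans" && length(unique(d$block)) >= 2 && length(present) >= 1) {
    d$grp_f <- stats::relevel(factor(d$grp), ref = "WT")
    fit <- lme4::lmer(stats::reformulate(c("grp_f", "(1 | block)"),
                                         response = yield_col),
                      data = d, REML = TRUE,
                      control = lme4::lmerControl(calc.derivs = FALSE))
    fe <- lme4::fixef(fit)
    se <- sqrt(diag(as.matrix(stats::vcov(fit))))
    wt_mean <- unname(fe[1])
    get_est <- function(g) {
      nm <- paste0("grp_f", g)
      if (!nm %in% names(fe)) return(c(NA, NA))
      c(unname(fe[nm]), unname(se[nm]))
    }
  } else {
    wt_mean <- mean(wt_plots[[yield_col]])
    get_est <- NULL
  }

  rows <- lapply(groups, function(g) {
    gp <- d[d$grp == g, , drop = FALSE]
    n_lines <- length(unique(gp$line_id))
    n_plots <- nrow(gp)
    if (n_plots == 0) {
      return(data.frame(group = g, n_lines = 0L, n_plots = 0L,
                        group_mean_yield = NA_real_, wt_mean_yield = wt_mean,
                        percent_increase = NA_real_, p_value = NA_real_,
                        significance = "", estimable = FALSE))
    }
    if (!is.null(get_est)) {
      est <- get_est(g)
      gmean <- wt_mean + est[1]
      p <- 2 * stats::pnorm(-abs(est[1] / est[2]))
    } else {
      gmean <- mean(gp[[yield_col]])
      p <- tryCatch(stats::t.test(gp[[yield_col]], wt_plots[[yield_col]])$p.value,
                    error = function(e) NA_real_)
    }
    data.frame(group = g, n_lines = n_lines, n_plots = n_plots,
               group_mean_yield = gmean, wt_mean_yield = wt_mean,
               percent_increase = percent_increase(gmean, wt_mean),
               p_value = p, significance = significance_stars(p),
               estimable = TRUE)
  })
  do.call(rbind, rows)
}
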