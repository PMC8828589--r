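# GxE resilience metrics: per-line yield differential between a favorable and
# a stress environment, and the stable / intermediate / dynamic classification.

#' Percent yield differential between environments
#'
#' `100 * (y_normal - y_low) / y_normal`: the percent yield lost moving from
#' the favorable to the stress environment. Negative when the stress-
#' environment yield is higher.
#'
#' @param y_normal yield under favorable conditions (> 0).
#' @param y_low yield under stress conditions.
#' @param digits decimals to report (default 1), or NULL for full precision.
#' @return percent differential.
#' @export
yield_differential <- function(y_normal, y_low, digits = 1) {
  if (any(y_normal <= 0)) stop_domain("`y_normal` must be > 0")
  p <- 100 * (y_normal - y_low) / y_normal
  if (is.null(digits)) p else round_half_up(p, digits)
}

#' Classify a line's resilience as stable / intermediate / dynamic
#'
#' Stable: differential strictly below `stable_max` (default 30%); dynamic:
#' strictly above `dynamic_min` (default 70%); intermediate otherwise.
#' Negative differentials (stress yield above normal) are stable.
#'
#' @param differential percent yield differential (vectorized).
#' @param stable_max,dynamic_min thresholds in percent,
#'   `stable_max <= dynamic_min`.
#' @return character vector of calls.
#' @export
classify_stability <- function(differential, stable_max = 30, dynamic_min = 70) {
  if (stable_max > dynamic_min) stop_domain("`stable_max` must be <= `dynamic_min`")
  ifelse(differential < stable_max, "stable",
         ifelse(differential > dynamic_min, "dynamic", "intermediate"))
}

#' Per-line yields by environment from a plot trial
#'
#' Collapses plot records to one yield per line per environment, by
#' least-squares means (per-environment model, line fixed, block random) or
#' raw means.
#'
#' @param plots plot records (needs `line_id`, `cohort`, `environment_id`,
#'   `block`, and the yield column).
#' @param mode "lsmeans" (default) or "raw".
#' @param yield_col yield column name.
#' @return data.frame: `line_id`, `cohort`, one column per environment.
#' @export
line_env_yields <- function(plots, mode = c("lsmeans", "raw"),
                            yield_col = "yield_kg_ha_std") {
  mode <- match.arg(mode)
  envs <- unique(plots$environment_id)
  per_env <- lapply(envs, function(e) {
    d <- plots[plots$environment_id == e, , drop = FALSE]
    if (mode == "lsmeans" && length(unique(d$block)) >= 2 &&
        length(unique(d$line_id)) >= 2) {
      d$line_f <- factor(d$line_id)
      fit <- lme4::lmer(stats::reformulate(c("0 + line_f", "(1 | block)"),
                                           response = yield_col),
                        data = d, REML = TRUE,
                        control = lme4::lmerControl(calc.derivs = FALSE))
      fe <- lme4::fixef(fit)
      names(fe) <- sub("^line_f", "", names(fe))
      data.frame(line_id = names(fe), yield = unname(fe),
                 environment_id = e, stringsAsFactors = FALSE)
    } else {
      mns <- tapply(d[[yield_col]], d$line_id, mean)
      data.frame(line_id = names(mns), yield = unname(mns),
                 environment_id = e, stringsAsFactors = FALSE)
    }
  })
  long <- do.call(rbind, per_env)
  wide <- stats::reshape(long, idvar = "line_id", timevar = "environment_id",
                         direction = "wide")
  names(wide) <- sub("^yield\\.", "", names(wide))
  cohort <- tapply(plots$cohort, plots$line_id, function(x) x[1])
  wide$cohort <- unname(cohort[wide$line_id])
  rownames(wide) <- NULL
  wide[, c("line_id", "cohort", envs)]
}

#' Stability calls for every line of a two-environment trial
#'
#' @param line_yields output of [line_env_yields()] (or any data.frame with
#'   `line_id` and the two environment columns).
#' @param env_normal,env_low column names of the favorable and stress
#'   environment.
#' @param stable_max,dynamic_min thresholds passed to [classify_stability()].
#' @return data.frame: `line_id`, `cohort`, `yield_normal`, `yield_low`,
#'   `differential`, `call`. Lines with non-positive normal yield are dropped
#'   with a warning.
#' @export
stability_calls <- function(line_yields, env_normal, env_low,
                            stable_max = 30, dynamic_min = 70) {
  stopifnot(all(c(env_normal, env_low) %in% names(line_yields)))
  yn <- line_yields[[env_normal]]
  yl <- line_yields[[env_low]]
  ok <- is.finite(yn) & is.finite(yl) & yn > 0
  if (!all(ok)) {
    warning(sprintf("dropping %d lines without a positive normal-environment yield",
                    sum(!ok)))
  }
  d <- line_yields[ok, , drop = FALSE]
  diffs <- yield_differential(d[[env_normal]], d[[env_low]])
  data.frame(line_id = d$line_id,
             cohort = d$cohort %||% NA_character_,
             yield_normal = d[[env_normal]],
             yield_low = d[[env_low]],
             differential = diffs,
             call = classify_stability(diffs, stable_max, dynamic_min),
             stringsAsFactors = FALSE)
}

#' Per-group yield profile across environments
#'
#' For each selection category: the mean of the per-line yields in each
#' environment and the differential of those means — the numbers behind a
#' group slope plot. Empty groups are reported with `estimable = FALSE`.
#'
#' @param line_yields output of [line_env_yields()].
#' @param grouping named character vector line_id -> group label; lines
#'   missing from it are dropped with a warning (wild-type lines may be mapped
#'   to "WT").
#' @param env_normal,env_low environment column names.
#' @return data.frame: `group`, `n_lines`, `mean_normal`, `mean_low`,
#'   `differential`, `estimable`.
#' @export
group_differential_profile <- function(line_yields, grouping,
                                       env_normal, env_low) {
  stopifnot(all(c(env_normal, env_low) %in% names(line_yields)))
  miss <- setdiff(line_yields$line_id, names(grouping))
  if (length(miss) > 0) {
    warning(sprintf("dropping %d ungrouped lines", length(miss)))
  }
  d <- line_yields[line_yields$line_id %in% names(grouping), , drop = FALSE]
  d$group <- unname(grouping[d$line_id])
  groups <- unique(c(grouping))
  rows <- lapply(sort(groups), function(g) {
    gd <- d[d$group == g, , drop = FALSE]
    if (nrow(gd) == 0) {
      return(data.frame(group = g, n_lines = 0L, mean_normal = NA_real_,
                        mean_low = NA_real_, differential = NA_real_,
                        estimable = FALSE))
    }
    mn <- mean(gd[[env_normal]]); ml <- mean(gd[[env_low]])
    data.frame(group = g, n_lines = nrow(gd), mean_normal = mn, mean_low = ml,
               differential = if (mn > 0) yield_differential(mn, ml) else NA_real_,
               estimable = mn > 0)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
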