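# Cold-stress emergence analysis: adjusted emergence ratios and the area
# under the plant emergence curve (AUPEC).
#
# Emergence is recorded as cumulative plant counts on an irregular day grid
# after planting. The early (cold-stress) planting is normalized by the same
# line's standard planting, which controls for seed quality, and the adjusted
# curve is integrated by the trapezoid rule.

#' Adjusted emergence: early planting normalized by standard planting
#'
#' Divides the early-planting cumulative counts by the standard planting. Two
#' conventions are supported: `"final"` (default) divides every early count by
#' the standard planting's final (maximum) count — a per-line seed-quality
#' denominator; `"daywise"` divides day by day on the shared grid. Values may
#' exceed 1 and are not clipped.
#'
#' @param early,standard data.frames with columns `day` and `count` for one
#'   line (cumulative counts, strictly increasing days).
#' @param mode "final" or "daywise".
#' @return data.frame with `day` and `adjusted` on the early grid.
#' @export
adjusted_emergence <- function(early, standard, mode = c("final", "daywise")) {
  mode <- match.arg(mode)
  for (s in list(early, standard)) {
    stopifnot(is.data.frame(s), all(c("day", "count") %in% names(s)))
    if (any(diff(s$day) <= 0)) stop_domain("days must be strictly increasing")
    if (any(s$count < 0)) stop_domain("counts must be non-negative")
  }
  if (mode == "final") {
    ref <- max(standard$count)
    if (ref <= 0) stop_domain("standard planting has zero final emergence")
    data.frame(day = early$day, adjusted = early$count / ref)
  } else {
    if (!identical(early$day, standard$day)) {
      stop_domain("daywise adjustment needs matching day grids")
    }
    if (any(standard$count <= 0)) {
      stop_domain("daywise adjustment undefined where the standard count is 0")
    }
    data.frame(day = early$day, adjusted = early$count / standard$count)
  }
}

#' Area under the plant emergence curve (AUPEC)
#'
#' Trapezoidal integral of adjusted emergence over days:
#' `sum((PE_n + PE_{n+1}) / 2 * (Y_{n+1} - Y_n))` with `PE_n` the (adjusted)
#' emergence and `Y_n` the day at observation `n`. Units: emergence x days.
#'
#' @param days strictly increasing numeric days (>= 2 points).
#' @param values emergence values aligned to `days`.
#' @return the area (scalar).
#' @export
aupec <- function(days, values) {
  if (is.data.frame(days)) { values <- days$adjusted %||% days$value; days <- days$day }
  n <- length(days)
  if (n < 2 || length(values) != n) stop_domain("need >= 2 aligned (day, value) points")
  if (any(diff(days) <= 0)) stop_domain("days must be strictly increasing")
  sum((values[-n] + values[-1]) / 2 * diff(days))
}

#' Emergence rate as the least-squares slope of adjusted emergence vs day
#'
#' The emergence-rate summary is the slope of the simple linear regression of
#' (adjusted) emergence on day over the recorded window — a documented
#' stand-in, as field practice varies.
#'
#' @param days strictly increasing numeric days (>= 2 points).
#' @param values emergence values aligned to `days`.
#' @return slope (per day).
#' @export
emergence_rate <- function(days, values) {
  if (is.data.frame(days)) { values <- days$adjusted %||% days$value; days <- days$day }
  if (length(days) < 2 || length(values) != length(days)) {
    stop_domain("need >= 2 aligned (day, value) points")
  }
  unname(stats::coef(stats::lm(values ~ days))[2])
}

#' Per-line AUPEC from a long emergence table
#'
#' Computes each line's adjusted emergence (early / standard) and its AUPEC.
#' Lines whose standard planting never emerges are excluded with a warning.
#' Multiple seasons (a `season` column) are averaged per line after per-season
#' AUPEC computation.
#'
#' @param emergence long data.frame: `line_id`, `planting`
#'   ("early"/"standard"), `day`, `count`, optional `season`.
#' @param mode adjustment mode, see [adjusted_emergence()].
#' @return data.frame: `line_id`, `aupec`, `emergence_rate`.
#' @export
aupec_by_line <- function(emergence, mode = c("final", "daywise")) {
  mode <- match.arg(mode)
  stopifnot(all(c("line_id", "planting", "day", "count") %in% names(emergence)))
  if (!"season" %in% names(emergence)) emergence$season <- 1L
  key <- interaction(emergence$line_id, emergence$season, drop = TRUE)
  res <- lapply(split(emergence, key), function(d) {
    early <- d[d$planting == "early", c("day", "count")]
    std <- d[d$planting == "standard", c("day", "count")]
    if (nrow(early) < 2 || nrow(std) < 1 || max(std$count) <= 0) {
      return(data.frame(line_id = d$line_id[1], aupec = NA_real_,
                        emergence_rate = NA_real_))
    }
    adj <- adjusted_emergence(early, std, mode = mode)
    data.frame(line_id = d$line_id[1],
               aupec = aupec(adj$day, adj$adjusted),
               emergence_rate = emergence_rate(adj$day, adj$adjusted))
  })
  long <- do.call(rbind, res)
  dropped <- unique(long$line_id[is.na(long$aupec)])
  if (length(dropped) > 0) {
    warning(sprintf("excluding %d lines with zero standard-planting emergence",
                    length(dropped)))
    long <- long[!is.na(long$aupec), , drop = FALSE]
  }
  agg <- stats::aggregate(cbind(aupec, emergence_rate) ~ line_id, long, mean)
  rownames(agg) <- NULL
  agg
}

#' Compare per-line AUPEC between selection groups and wild type
#'
#' Groups the per-line AUPEC values (wild-type lines as the reference level)
#' and tests each group against WT with the same linear-model contrast
#' machinery used for yields. With one AUPEC value per line this is a fixed-
#' effects linear model; empty groups are reported as not estimable.
#'
#' @param line_aupec data.frame with `line_id` and `aupec` (e.g. from
#'   [aupec_by_line()]).
#' @param grouping named character vector line_id -> group label for epi
#'   lines.
#' @param wt_lines character vector of wild-type line ids.
#' @param alpha significance level for the directional call.
#' @return data.frame: `group`, `n_lines`, `group_mean`, `wt_mean`,
#'   `difference`, `p_value`, `direction`, `estimable`.
#' @export
compare_emergence_groups <- function(line_aupec, grouping, wt_lines,
                                     alpha = 0.05) {
  stopifnot(all(c("line_id", "aupec") %in% names(line_aupec)))
  if (!any(line_aupec$line_id %in% wt_lines)) stop_domain("no wild-type lines present")
  d <- line_aupec
  d$group <- ifelse(d$line_id %in% wt_lines, "WT",
                    unname(grouping[d$line_id]))
  d <- d[!is.na(d$group), , drop = FALSE]
  d$group_f <- stats::relevel(factor(d$group), ref = "WT")
  fit <- stats::lm(aupec ~ group_f, data = d)
  fe <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  wt_mean <- unname(fe[1])
  groups <- sort(unique(stats::na.omit(unname(grouping))))
  rows <- lapply(groups, function(g) {
    nm <- paste0("group_f", g)
    n_lines <- sum(d$group == g)
    if (!nm %in% names(fe) || n_lines == 0) {
      return(data.frame(group = g, n_lines = n_lines, group_mean = NA_real_,
                        wt_mean = wt_mean, difference = NA_real_,
                        p_value = NA_real_, direction = NA_character_,
                        estimable = FALSE))
    }
    diff <- unname(fe[nm])
    p <- 2 * stats::pt(-abs(diff / se[nm]), df = stats::df.residual(fit))
    data.frame(group = g, n_lines = n_lines, group_mean = wt_mean + diff,
               wt_mean = wt_mean, difference = diff, p_value = p,
               direction = if (p >= alpha) "ns" else if (diff > 0) "higher" else "lower",
               estimable = TRUE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
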