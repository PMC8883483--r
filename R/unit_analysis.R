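# epoch step windows for a single trial's meta row
trial_window <- function(meta_i, which, dt = 0.02) {
  go <- meta_i$go; cue_on <- meta_i$cue_on; cue_off <- meta_i$cue_off
  one_s <- as.integer(round(1 / dt))
  switch(which,
    fixation = seq_len(cue_on - 1L),
    cue = cue_on:cue_off,
    delay = if (go > cue_off) (cue_off + 1L):go else integer(0),
    delay_last1 = if (go > cue_off)
      (max(cue_off + 1L, go - one_s + 1L)):go else integer(0),
    baseline = (max(1L, cue_on - one_s)):(cue_on - 1L),
    response = (go + 1L):meta_i$t_end,
    stop("unknown window '", which, "'"))
}

#' Per-trial mean rates of every unit over a task epoch
#'
#' @param record A `wm_record`.
#' @param window One of `"fixation"`, `"cue"`, `"delay"`, `"delay_last1"`
#'   (the final second of the delay), `"baseline"` (1 s pre-cue),
#'   `"response"`.
#' @return Matrix (units x trials) of window-mean rates.
#' @export
window_rates <- function(record, window = "delay") {
  meta <- record$meta
  out <- matrix(NA_real_, dim(record$rates)[1], nrow(meta))
  for (i in seq_len(nrow(meta))) {
    w <- trial_window(meta[i, ], window, record$dt)
    if (length(w)) {
      x <- record$rates[, i, w, drop = FALSE]
      out[, i] <- rowMeans(matrix(x, nrow = dim(x)[1]))
    }
  }
  out
}

#' Peristimulus-time histogram of one unit
#'
#' Trial-averaged activity of a unit, time-locked to cue onset (time 0 at
#' cue appearance).
#'
#' @param record A `wm_record`.
#' @param unit Unit index.
#' @param trials Optional integer vector of trial indices (default all).
#' @param normalize Express rates as (rate - baseline) / baseline using
#'   the 1 s pre-cue baseline (see [normalized_rate()]).
#' @return Tibble with `time` (s, relative to cue onset), `rate`, and the
#'   number of trials averaged (`n`).
#' @export
psth <- function(record, unit, trials = NULL, normalize = FALSE) {
  meta <- record$meta
  if (is.null(trials)) trials <- seq_len(nrow(meta))
  if (length(trials) == 0) stop("no trials match the PSTH condition")
  t_len <- min(meta$t_end[trials])
  cue_on <- unique(meta$cue_on[trials])
  if (length(cue_on) != 1)
    stop("PSTH trials must share cue-onset alignment")
  tr <- record$rates[unit, trials, seq_len(t_len), drop = FALSE]
  m <- apply(tr, 3, mean)
  if (normalize) {
    base <- mean(window_rates(record, "baseline")[unit, trials])
    m <- normalized_rate(m, base)
  }
  tibble::tibble(time = (seq_len(t_len) - cue_on) * record$dt, rate = m,
                 n = length(trials))
}

#' Baseline-normalized rate
#'
#' `(rate - baseline) / baseline`: 0 wherever the rate equals baseline,
#' dimensionless. Units whose baseline is below `eps` cannot be
#' normalized; they return `NA` with a warning rather than being silently
#' dropped.
#'
#' @param rate Rate trace (vector).
#' @param baseline Baseline rate (scalar; conventionally the mean over the
#'   1 s pre-cue period).
#' @param eps Divide-by-zero guard (default 1e-6).
#' @return Normalized trace, or `NA`s when the baseline is degenerate.
#' @export
normalized_rate <- function(rate, baseline, eps = 1e-6) {
  if (!is.finite(baseline) || baseline < eps) {
    warning("baseline below ", eps, ": unit excluded from normalization")
    return(rep(NA_real_, length(rate)))
  }
  (rate - baseline) / baseline
}

#' Select units with elevated delay-period activity
#'
#' Two-sample Welch t-test per unit on per-trial mean rates, delay versus
#' fixation epoch. A unit is a "delay unit" iff its delay mean exceeds its
#' fixation mean AND p < `alpha`. Degenerate zero-variance cases: exact
#' equality of the two epochs is never selected; constant but unequal
#' epochs are treated as p = 0.
#'
#' @param record A `wm_record` (at least 2 trials).
#' @param alpha Significance level (default 0.05).
#' @param trials Optional trial subset (e.g. correct trials only).
#' @return Tibble: `unit`, `delay_mean`, `fix_mean`, `t`, `p`, `selected`.
#' @export
select_delay_units <- function(record, alpha = 0.05, trials = NULL) {
  d <- window_rates(record, "delay")
  f <- window_rates(record, "fixation")
  if (!is.null(trials)) { d <- d[, trials, drop = FALSE]
                          f <- f[, trials, drop = FALSE] }
  keep <- colSums(is.na(d)) == 0          # zero-delay trials have no window
  d <- d[, keep, drop = FALSE]; f <- f[, keep, drop = FALSE]
  if (ncol(d) < 2) stop("need at least 2 trials with a delay epoch")
  res <- lapply(seq_len(nrow(d)), function(u) {
    x <- d[u, ]; y <- f[u, ]
    tt <- tryCatch(t.test(x, y), error = function(e) NULL)
    if (is.null(tt)) {                    # constant data in both groups
      eq <- isTRUE(all.equal(mean(x), mean(y)))
      tibble::tibble(unit = u, delay_mean = mean(x), fix_mean = mean(y),
                     t = if (eq) 0 else Inf, p = if (eq) 1 else 0,
                     selected = !eq && mean(x) > mean(y))
    } else {
      tibble::tibble(unit = u, delay_mean = mean(x), fix_mean = mean(y),
                     t = unname(tt$statistic), p = tt$p.value,
                     selected = mean(x) > mean(y) && tt$p.value < alpha)
    }
  })
  dplyr::bind_rows(res)
}

#' Delay-period tuning profile of each unit
#'
#' Mean delay-period rate of each unit at each cue location, the preferred
#' location (argmax), and the location offsets after rotating the curve so
#' the preferred location sits at offset 0. Offsets are wrapped to
#' (-180, 180], so an 8-location task yields offsets -135, ..., 180.
#'
#' @param record A `wm_record`.
#' @param behavior Optional behavior table; when given, only correct
#'   trials enter the tuning estimate.
#' @param units Unit indices (default all).
#' @param window Epoch window (default `"delay"`; `"delay_last1"` for the
#'   final second).
#' @return A `wm_tuning` tibble: `unit`, `location`, `rate`, `preferred`,
#'   `offset`.
#' @export
tuning_profile <- function(record, behavior = NULL, units = NULL,
                           window = "delay") {
  meta <- record$meta
  if (is.null(units)) units <- seq_len(dim(record$rates)[1])
  use <- if (!is.null(behavior)) which(behavior$correct)
         else seq_len(nrow(meta))
  r <- window_rates(record, window)
  locs <- sort(unique(meta$cue_angle))
  per_loc <- vapply(locs, function(L) {
    idx <- intersect(use, which(meta$cue_angle == L))
    if (length(idx) == 0) return(rep(NA_real_, length(units)))
    rowMeans(r[units, idx, drop = FALSE], na.rm = TRUE)
  }, numeric(length(units)))
  per_loc <- matrix(per_loc, nrow = length(units))
  pref <- locs[apply(per_loc, 1, which.max)]
  out <- tibble::tibble(
    unit = rep(units, times = length(locs)),
    location = rep(locs, each = length(units)),
    rate = as.vector(per_loc),
    preferred = rep(pref, times = length(locs)))
  out$offset <- angular_diff(out$location, out$preferred)
  class(out) <- c("wm_tuning", class(out))
  out
}

#' Sorted, normalized population heatmap
#'
#' One row per unit: the unit's trial-averaged activity for trials at its
#' preferred location, normalized by its peak delay-period rate (so every
#' row's delay maximum is 1), rows sorted by preferred location. A
#' bump-attractor-like population shows a single contiguous diagonal band.
#'
#' @param record A `wm_record`.
#' @param tuning A `wm_tuning` from [tuning_profile()] (determines the
#'   units and their preferred locations).
#' @param stimulus If `NULL` (default), each row shows the unit's response
#'   to its own preferred stimulus; a cue angle restricts every row to
#'   trials with that single stimulus, in which case the sorted matrix of
#'   a bump-coding population shows one contiguous band of active rows
#'   around the units tuned to it.
#' @return Matrix (units x time) with attributes `preferred` (sorted
#'   preferred locations) and `units` (original indices in row order).
#' @export
heatmap_matrix <- function(record, tuning, stimulus = NULL) {
  meta <- record$meta
  info <- dplyr::distinct(tuning, .data$unit, .data$preferred)
  info <- info[order(info$preferred, info$unit), ]
  t_len <- min(meta$t_end)
  avg <- function(u, cue) {
    idx <- which(meta$cue_angle == cue)
    tr <- record$rates[u, idx, seq_len(t_len), drop = FALSE]
    list(m = apply(tr, 3, mean),
         dw = trial_window(meta[idx[1], ], "delay", record$dt))
  }
  rows <- t(vapply(seq_len(nrow(info)), function(k) {
    u <- info$unit[k]
    # normalization is always by the unit's preferred delay firing rate
    pref <- avg(u, info$preferred[k])
    peak <- max(pref$m[pref$dw[pref$dw <= t_len]])
    m <- if (is.null(stimulus)) pref$m else avg(u, stimulus)$m
    if (peak > 1e-6) m / peak else m * 0
  }, numeric(t_len)))
  attr(rows, "preferred") <- info$preferred
  attr(rows, "units") <- info$unit
  rows
}

# signed saccade deviation for trials at one cue location, relative to one
# unit's preferred location: magnitude = |deviation from the per-location
# median endpoint|, sign + when the endpoint moved toward the preferred
# location (i.e. reduced the circular distance to it), - when away, ties NA
signed_saccade_dev <- function(dev, cue, preferred) {
  med <- median(dev)
  mag <- abs(angular_diff(dev, med))
  d_trial <- abs(angular_diff(wrap_angle(cue + dev), preferred))
  d_med <- abs(angular_diff(wrap_angle(cue + med), preferred))
  sgn <- sign(d_med - d_trial)      # + toward preferred, - away
  ifelse(sgn == 0 & mag > 0, NA_real_, sgn * mag)
}

#' Correlation between delay rates and saccade deviations
#'
#' For each delay unit and each cue location, computes the Pearson
#' correlation across correct trials between (a) the unit's rate deviation
#' — its mean rate over the final second of the delay minus the median
#' across all correct trials with the same cue — and (b) the signed
#' saccade deviation — the absolute deviation of the decoded endpoint from
#' the per-location median endpoint, signed positive when the endpoint
#' deviated toward the unit's preferred location and negative when away.
#' Curves are then rotated so each unit's preferred location sits at
#' offset 0 and averaged across units; drifting-bump dynamics predict an
#' "M" shape (positive correlation on the tuning flanks, none at the peak
#' and at the opposite location).
#'
#' @param record A `wm_record`.
#' @param behavior Behavior table from [score_trials()].
#' @param tuning A `wm_tuning` restricted to the units to analyze
#'   (conventionally the delay units).
#' @param window Rate window (default `"delay_last1"`).
#' @param min_trials Minimum correct trials per location (default 8).
#' @return A `wm_rbc` object: `by_cell` (unit x location r values with
#'   rotated offsets), `by_unit` (per-unit mean r), `curve` (mean r per
#'   offset), `mean_r`, one-sample t-test of the cell r values against 0
#'   (`t`, `df`, `p`), and the number of excluded cells.
#' @export
rate_behavior_correlation <- function(record, behavior, tuning,
                                      window = "delay_last1",
                                      min_trials = 8) {
  meta <- record$meta
  r <- window_rates(record, window)
  info <- dplyr::distinct(tuning, .data$unit, .data$preferred)
  locs <- sort(unique(meta$cue_angle))
  excluded <- 0L
  cells <- list()
  for (L in locs) {
    idx <- which(meta$cue_angle == L & behavior$correct &
                   !is.na(behavior$deviation))
    if (length(idx) < min_trials) { excluded <- excluded + nrow(info); next }
    # deviation from the required direction; in cue (memory) space this is
    # the deviation of the remembered location from the cue, for pro and
    # anti mappings alike
    dev <- behavior$deviation[idx]
    for (k in seq_len(nrow(info))) {
      u <- info$unit[k]
      rates <- r[u, idx]
      rate_dev <- rates - median(rates)
      sdev <- signed_saccade_dev(dev, L, info$preferred[k])
      ok <- !is.na(sdev)
      if (sum(ok) < min_trials || sd(rate_dev[ok]) == 0 ||
          sd(sdev[ok]) == 0) { excluded <- excluded + 1L; next }
      cells[[length(cells) + 1L]] <- tibble::tibble(
        unit = u, location = L, preferred = info$preferred[k],
        offset = angular_diff(L, info$preferred[k]),
        r = cor(rate_dev[ok], sdev[ok]), n = sum(ok))
    }
  }
  by_cell <- dplyr::bind_rows(cells)
  if (nrow(by_cell) == 0) stop("no unit-location cells had enough trials")
  by_unit <- dplyr::summarise(dplyr::group_by(by_cell, .data$unit),
                              mean_r = mean(.data$r), .groups = "drop")
  curve <- dplyr::summarise(dplyr::group_by(by_cell, .data$offset),
                            mean_r = mean(.data$r), n = dplyr::n(),
                            .groups = "drop")
  tt <- if (nrow(by_cell) > 1) t.test(by_cell$r) else NULL
  structure(list(by_cell = by_cell, by_unit = by_unit, curve = curve,
                 mean_r = mean(by_cell$r),
                 t = if (!is.null(tt)) unname(tt$statistic) else NA,
                 df = if (!is.null(tt)) unname(tt$parameter) else NA,
                 p = if (!is.null(tt)) tt$p.value else NA,
                 n_excluded = excluded),
            class = "wm_rbc")
}

#' @export
print.wm_rbc <- function(x, ...) {
  cat(sprintf(
    "<wm_rbc: mean r = %.4f over %d unit-location cells (t = %.2f, df = %.0f, p = %.3g)>\n",
    x$mean_r, nrow(x$by_cell), x$t, x$df, x$p))
  invisible(x)
}

#' @export
tidy.wm_rbc <- function(x, ...) x$by_cell

#' @export
glance.wm_rbc <- function(x, ...) {
  tibble::tibble(mean_r = x$mean_r, t = x$t, df = x$df, p = x$p,
                 n_cells = nrow(x$by_cell), n_excluded = x$n_excluded)
}

#' Fano factor of a measurement across trials
#'
#' Sample variance (n-1 denominator) divided by the mean. `NA` when the
#' mean is below `eps`.
#'
#' @param x Per-trial measurements (e.g. delay-window mean rates, or
#'   Poisson spike counts for a surrogate comparison).
#' @param eps Mean floor below which the ratio is undefined.
#' @return `var(x) / mean(x)`.
#' @export
fano <- function(x, eps = 1e-6) {
  m <- mean(x)
  if (!is.finite(m) || m < eps) return(NA_real_)
  var(x) / m
}

#' Fano factor of delay activity by unit and location
#'
#' For each unit and cue location, the Fano factor of the per-trial
#' delay-window mean rates across (up to) `n_trials` correct trials; the
#' per-location values are then rotated to put each unit's preferred
#' location at offset 0 and averaged into a population curve. Low values
#' (order 0.02 in trained networks) reflect the near-deterministic
#' trial-to-trial activity of rate units; a drifting bump makes the curve
#' M-shaped, with more variability on the tuning flanks than at the peak
#' or the opposite location.
#'
#' @param record A `wm_record`.
#' @param behavior Behavior table (correct trials are used).
#' @param tuning A `wm_tuning` restricted to the units to analyze.
#' @param window Rate window (default `"delay_last1"`; `"delay"` for the
#'   entire delay period).
#' @param n_trials Correct trials per location entering the estimate
#'   (default 16; locations with fewer than `min_trials` are skipped).
#' @param min_trials Minimum correct trials per location (default 2).
#' @return A `wm_fano` object: `by_cell` (`unit`, `location`, `offset`,
#'   `ff`, `mean_rate`, `n`), `curve` (mean FF per offset), `mean_ff`, and
#'   the number of undefined cells excluded.
#' @export
fano_factor <- function(record, behavior, tuning, window = "delay_last1",
                        n_trials = 16, min_trials = 2) {
  meta <- record$meta
  r <- window_rates(record, window)
  info <- dplyr::distinct(tuning, .data$unit, .data$preferred)
  locs <- sort(unique(meta$cue_angle))
  excluded <- 0L
  cells <- list()
  for (L in locs) {
    idx <- which(meta$cue_angle == L & behavior$correct)
    if (length(idx) < min_trials) { excluded <- excluded + nrow(info); next }
    idx <- idx[seq_len(min(length(idx), n_trials))]
    for (k in seq_len(nrow(info))) {
      u <- info$unit[k]
      ffv <- fano(r[u, idx])
      if (is.na(ffv)) { excluded <- excluded + 1L; next }
      cells[[length(cells) + 1L]] <- tibble::tibble(
        unit = u, location = L,
        offset = angular_diff(L, info$preferred[k]), ff = ffv,
        mean_rate = mean(r[u, idx]), n = length(idx))
    }
  }
  by_cell <- dplyr::bind_rows(cells)
  if (nrow(by_cell) == 0) stop("no unit-location cells had enough trials")
  curve <- dplyr::summarise(dplyr::group_by(by_cell, .data$offset),
                            mean_ff = mean(.data$ff), n = dplyr::n(),
                            .groups = "drop")
  structure(list(by_cell = by_cell, curve = curve,
                 mean_ff = mean(by_cell$ff), n_excluded = excluded),
            class = "wm_fano")
}

#' @export
print.wm_fano <- function(x, ...) {
  cat(sprintf("<wm_fano: mean Fano factor %.4g over %d unit-location cells>\n",
              x$mean_ff, nrow(x$by_cell)))
  invisible(x)
}

#' @export
tidy.wm_fano <- function(x, ...) x$by_cell

#' @export
glance.wm_fano <- function(x, ...) {
  tibble::tibble(mean_ff = x$mean_ff, n_cells = nrow(x$by_cell),
                 n_excluded = x$n_excluded)
}

#' One-way ANOVA of Fano factor by rotated location
#'
#' Tests for an effect of (rotated) stimulus location on the Fano factor,
#' with units as observations — significant location structure is the
#' statistical signature of the M-shaped variability curve.
#'
#' @param fano_obj A `wm_fano` (or its `by_cell` tibble).
#' @return Tibble with `F`, `df1`, `df2`, `p`.
#' @export
anova_fano_by_location <- function(fano_obj) {
  cells <- if (inherits(fano_obj, "wm_fano")) fano_obj$by_cell else fano_obj
  tab <- table(cells$offset)
  if (length(tab) < 2 || any(tab < 2))
    stop("need >= 2 locations with >= 2 observations each")
  fit <- aov(ff ~ factor(offset), data = cells)
  a <- anova(fit)
  tibble::tibble(F = a$`F value`[1], df1 = a$Df[1], df2 = a$Df[2],
                 p = a$`Pr(>F)`[1])
}

#' Correct-versus-error contrast of delay activity
#'
#' For each analyzed unit, takes trials whose cue was at the unit's
#' preferred location, and contrasts its mean rate (final second of the
#' delay) between correct and error trials. Per-unit condition means are
#' the observations (pool several networks by row-binding `obs` tables and
#' calling [pool_correct_error()]); the test is a two-tailed Welch t-test.
#'
#' @param record A `wm_record`.
#' @param behavior Behavior table.
#' @param tuning A `wm_tuning` for the units to analyze.
#' @param window Rate window (default `"delay_last1"`).
#' @return A `wm_cce` object: `obs` tibble (`unit`, `condition`, `rate`),
#'   group means, and — when both groups are nonempty — Welch `t`, `df`,
#'   `p`.
#' @export
compare_correct_error <- function(record, behavior, tuning,
                                  window = "delay_last1") {
  meta <- record$meta
  r <- window_rates(record, window)
  info <- dplyr::distinct(tuning, .data$unit, .data$preferred)
  obs <- list()
  for (k in seq_len(nrow(info))) {
    u <- info$unit[k]
    at_pref <- meta$cue_angle == info$preferred[k]
    for (cond in c("correct", "error")) {
      idx <- which(at_pref & (behavior$correct == (cond == "correct")))
      if (length(idx))
        obs[[length(obs) + 1L]] <- tibble::tibble(
          unit = u, condition = cond, rate = mean(r[u, idx]))
    }
  }
  pool_correct_error(dplyr::bind_rows(obs))
}

#' @rdname compare_correct_error
#' @param obs A (possibly row-bound, multi-network) observation tibble
#'   with columns `condition` and `rate`.
#' @export
pool_correct_error <- function(obs) {
  x <- obs$rate[obs$condition == "correct"]
  y <- obs$rate[obs$condition == "error"]
  res <- list(obs = obs,
              mean_correct = if (length(x)) mean(x) else NA_real_,
              mean_error = if (length(y)) mean(y) else NA_real_,
              n_correct = length(x), n_error = length(y),
              t = NA_real_, df = NA_real_, p = NA_real_)
  if (length(x) > 1 && length(y) > 1) {
    tt <- t.test(x, y)
    res$t <- unname(tt$statistic); res$df <- unname(tt$parameter)
    res$p <- tt$p.value
  }
  structure(res, class = "wm_cce")
}

#' @export
print.wm_cce <- function(x, ...) {
  cat(sprintf(
    "<wm_cce: correct %.4f (n=%d) vs error %.4f (n=%d); t = %.3g, df = %.1f, p = %.3g>\n",
    x$mean_correct, x$n_correct, x$mean_error, x$n_error, x$t, x$df, x$p))
  invisible(x)
}

#' @export
tidy.wm_cce <- function(x, ...) x$obs

#' @export
glance.wm_cce <- function(x, ...) {
  tibble::tibble(mean_correct = x$mean_correct, mean_error = x$mean_error,
                 n_correct = x$n_correct, n_error = x$n_error, t = x$t,
                 df = x$df, p = x$p)
}

#' Tuning-sorted weight matrices and diagonality statistic
#'
#' Reorders the recurrent dimension(s) of `W_in`, `W_rec`, `W_out` by each
#' recurrent unit's preferred location, and summarizes the recurrent
#' weight structure with a diagonality statistic: the mean recurrent
#' weight between unit pairs with similar tuning (circular preferred-
#' location difference <= 45 deg, diagonal excluded) minus the mean
#' between pairs with opposite tuning (difference >= 135 deg). Positive
#' values indicate the like-to-like connectivity of bump-attractor
#' models.
#'
#' @param params A `wm_rnn`.
#' @param preferred Preferred location (deg) of every recurrent unit.
#' @return List with the sorted matrices (`W_in`, `W_rec`, `W_out`), the
#'   sort `order`, and `diagonality`.
#' @export
weight_structure <- function(params, preferred) {
  stopifnot(length(preferred) == params$n_rec)
  ord <- order(preferred, seq_along(preferred))
  dmat <- abs(outer(preferred, preferred, angular_diff))
  off <- !diag(TRUE, params$n_rec)
  near <- dmat <= 45 & off
  far <- dmat >= 135 & off
  stat <- mean(params$W_rec[near]) - mean(params$W_rec[far])
  list(W_in = params$W_in[ord, , drop = FALSE],
       W_rec = params$W_rec[ord, ord, drop = FALSE],
       W_out = params$W_out[, ord, drop = FALSE],
       order = ord, preferred = preferred[ord], diagonality = stat)
}
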