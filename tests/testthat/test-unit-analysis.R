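test_that("PSTHs average trials time-locked to cue onset", {
  rec <- constant_record(fix_means = matrix(c(1, 3), 1),
                         delay_means = matrix(c(5, 7), 1))
  one <- psth(rec, 1, trials = 1)
  expect_equal(one$rate, rec$rates[1, 1, ])
  expect_equal(one$time[rec$meta$cue_on[1]], 0)   # cue onset at time 0
  both <- psth(rec, 1)
  expect_equal(both$rate, (rec$rates[1, 1, ] + rec$rates[1, 2, ]) / 2)
  expect_equal(both$n, rep(2L, nrow(both)))
  expect_error(psth(rec, 1, trials = integer(0)), "no trials")
})

test_that("a noisy constant-rate PSTH recovers the constant within 3 SE", {
  set.seed(11)
  n <- 100; T_ <- 175L; sd_noise <- 0.5
  fix <- matrix(2, 1, n); del <- matrix(2, 1, n)
  rec <- constant_record(fix, del)
  rec$rates <- rec$rates + array(rnorm(length(rec$rates), sd = sd_noise),
                                 dim(rec$rates))
  p <- psth(rec, 1)
  se <- sd_noise / sqrt(n)
  expect_true(all(abs(p$rate - 2) < 3.5 * se))
  expect_lt(mean(abs(p$rate - 2) > 2 * se), 0.1)
})

test_that("baseline normalization follows (rate - baseline) / baseline", {
  expect_equal(normalized_rate(4, 2), 1)
  expect_equal(normalized_rate(rep(3, 5), 3), rep(0, 5))
  expect_equal(normalized_rate(0.25, 0.5), -0.5)
  expect_warning(out <- normalized_rate(c(1, 2), 1e-9), "excluded")
  expect_true(all(is.na(out)))
})

test_that("delay units require elevated delay activity at p < 0.05", {
  # unit 1: delay {5,6,7,8} vs fixation {1,2,1,2} -> selected
  # unit 2: the reverse (elevated fixation) -> not selected
  # unit 3: identical epochs -> not selected
  fix <- rbind(c(1, 2, 1, 2), c(5, 6, 7, 8), c(3, 3, 3, 3))
  del <- rbind(c(5, 6, 7, 8), c(1, 2, 1, 2), c(3, 3, 3, 3))
  sel <- select_delay_units(constant_record(fix, del))
  expect_equal(sel$selected, c(TRUE, FALSE, FALSE))
  # the t statistic matches a directly computed Welch test
  ref <- t.test(c(5, 6, 7, 8), c(1, 2, 1, 2))
  expect_equal(sel$t[1], unname(ref$statistic))
  expect_lt(sel$p[1], 0.01)
  # unit 2's |t| is just as large, but the elevation points the wrong way
  expect_lt(sel$p[2], 0.01)
})

test_that("tuning profiles rotate each unit's preferred location to offset zero", {
  set.seed(12)
  locs <- canonical_locations()
  # three units tuned to 0, 90, 225 with von-Mises rates per location
  prefs <- c(0, 90, 225)
  n_rep <- 3
  cues <- rep(locs, each = n_rep)
  del <- t(vapply(prefs, function(p0)
    0.2 + exp(3.75 * (cos(pi / 180 * (cues - p0)) - 1)) +
      rnorm(length(cues), sd = 1e-3), numeric(length(cues))))
  fix <- matrix(0.2, 3, length(cues))
  rec <- constant_record(fix, del, cue_angles = cues)
  tun <- tuning_profile(rec)
  got <- dplyr::distinct(tun, unit, preferred)
  expect_equal(got$preferred, prefs)
  # rotated curve peaks at offset 0
  peak <- dplyr::slice_max(dplyr::group_by(tun, unit), rate, n = 1)
  expect_equal(peak$offset, rep(0, 3))
  # rotation bookkeeping: summing the curve over locations is invariant
  # under the preferred-at-center re-indexing
  for (u in 1:3)
    expect_equal(sum(tun$rate[tun$unit == u]),
                 sum(tapply(del[u, ], cues, mean)))
})

test_that("the sorted heatmap of a bump population is a contiguous diagonal band", {
  set.seed(13)
  locs <- canonical_locations()
  n_units <- 8
  prefs <- canonical_locations()
  cues <- rep(locs, each = 2)
  del <- t(vapply(prefs, function(p0)
    0.05 + exp(3.75 * (cos(pi / 180 * (cues - p0)) - 1)), numeric(length(cues))))
  rec <- constant_record(matrix(0.05, n_units, length(cues)), del,
                         cue_angles = cues)
  tun <- tuning_profile(rec)
  hm <- heatmap_matrix(rec, tun)
  expect_true(all(apply(hm, 1, max) <= 1 + 1e-12))
  # each row's delay activity is at (normalized) 1 somewhere
  dwin <- 76:150
  expect_equal(apply(hm[, dwin], 1, max), rep(1, nrow(hm)))
  # rows are sorted by preferred location
  expect_true(!is.unsorted(attr(hm, "preferred")))
  # a single fixed stimulus activates one contiguous block of sorted rows
  hm90 <- heatmap_matrix(rec, tun, stimulus = 90)
  act <- which(rowMeans(hm90[, dwin]) > 0.5)
  expect_true(all(diff(act) == 1))
  expect_true(3 %in% act)                        # the 90-degree-tuned row
  # permuting unit order leaves the sorted matrix unchanged
  perm <- sample(n_units)
  rec2 <- rec; rec2$rates <- rec$rates[perm, , , drop = FALSE]
  tun2 <- tuning_profile(rec2)
  hm2 <- heatmap_matrix(rec2, tun2)
  strip <- function(m) structure(m, preferred = NULL, units = NULL)
  expect_equal(strip(hm2), strip(hm))
  # single unit: a 1 x T matrix with max 1
  tun1 <- tuning_profile(rec, units = 1)
  hm1 <- heatmap_matrix(rec, tun1)
  expect_equal(nrow(hm1), 1L)
  expect_equal(max(hm1[1, dwin]), 1)
})

test_that("Fano factor follows the n-1 variance convention", {
  expect_equal(fano(rep(4, 10)), 0)
  expect_equal(fano(c(1, 2, 3)), 0.5)            # var 1, mean 2
  expect_true(is.na(fano(rep(0, 5))))
  set.seed(14)
  x <- rpois(200, lambda = 5)
  expect_equal(fano(x), 1, tolerance = 0.2)
})

test_that("perfectly repeatable trials have Fano factor exactly zero", {
  del <- rbind(rep(2, 16), rep(3, 16))           # 2 units, 16 identical trials
  rec <- constant_record(matrix(1, 2, 16), del, cue_angles = rep(0, 16))
  beh <- tibble::tibble(correct = rep(TRUE, 16))
  tun <- tibble::tibble(unit = 1:2, preferred = c(0, 0))
  ff <- fano_factor(rec, beh, tun)
  expect_equal(ff$by_cell$ff, c(0, 0))
})

test_that("rate-behavior correlation is +/-1 for exactly (anti)proportional deviations", {
  set.seed(15)
  n <- 16
  dev <- rnorm(n, 0, 12)                          # endpoint deviations, cue 0
  beh <- tibble::tibble(trial = 1:n, task_id = "odr", cue_angle = 0,
                        delay = 1.5, target_dir = 0, endpoint = wrap_angle(dev),
                        deviation = dev, fixation_hold = TRUE,
                        correct = TRUE)
  sdev <- wmrnn:::signed_saccade_dev(dev, 0, preferred = 45)
  # unit rates proportional to the signed deviation (plus a constant)
  del <- rbind(5 + 0.1 * sdev, 5 - 0.1 * sdev)
  rec <- constant_record(matrix(1, 2, n), del, cue_angles = rep(0, n))
  tun <- tibble::tibble(unit = 1:2, preferred = c(45, 45))
  rbc <- rate_behavior_correlation(rec, beh, tun, min_trials = 8)
  expect_equal(rbc$by_cell$r, c(1, -1), tolerance = 1e-10)
  expect_equal(rbc$by_cell$offset, c(-45, -45))
})

test_that("the drifting-bump surrogate yields M-shaped correlation and Fano curves", {
  set.seed(16)
  sur <- make_bump_surrogate(n_units = 32, n_per_loc = 20, drift_sd = 15)
  tun <- tuning_profile(sur$record, sur$behavior, window = "delay_last1")
  # ground-truth preferred locations are recovered on the 8-location grid
  got <- dplyr::distinct(tun, unit, preferred)
  true_pref <- sur$preferred
  nearest <- 45 * round(true_pref / 45) %% 360
  expect_gt(mean(abs(angular_diff(got$preferred, nearest)) <= 45), 0.95)

  rbc <- rate_behavior_correlation(sur$record, sur$behavior, tun,
                                   min_trials = 8)
  flank <- rbc$curve$mean_r[abs(rbc$curve$offset) %in% c(45, 90, 135)]
  center <- rbc$curve$mean_r[rbc$curve$offset == 0]
  opposite <- rbc$curve$mean_r[rbc$curve$offset == 180]
  expect_gt(mean(flank), 0)
  expect_gt(mean(flank), center)
  expect_gt(mean(flank), opposite)
  expect_gt(rbc$mean_r, 0)
  expect_lt(rbc$p, 0.05)

  ff <- fano_factor(sur$record, sur$behavior, tun)
  ff_flank <- ff$curve$mean_ff[abs(ff$curve$offset) %in% c(45, 90, 135)]
  expect_gt(mean(ff_flank), ff$curve$mean_ff[ff$curve$offset == 0])
  expect_gt(mean(ff_flank), ff$curve$mean_ff[ff$curve$offset == 180])
})

test_that("removing the drift ablates both M-shaped signatures", {
  set.seed(17)
  sur <- make_bump_surrogate(n_units = 32, n_per_loc = 20, drift_sd = 0)
  tun <- tuning_profile(sur$record, sur$behavior, window = "delay_last1")
  expect_true(all(sur$behavior$correct))          # no drift, no errors
  ff <- fano_factor(sur$record, sur$behavior, tun)
  # observation noise only: variability is tiny and unstructured
  expect_lt(ff$mean_ff, 0.01)
  rbc <- tryCatch(
    rate_behavior_correlation(sur$record, sur$behavior, tun,
                              min_trials = 8),
    error = function(e) NULL)
  if (!is.null(rbc)) expect_lt(abs(rbc$mean_r), 0.2)
})

test_that("correct trials carry more preferred-location delay activity in the contrast", {
  # identical groups: t = 0, p = 1
  obs_eq <- tibble::tibble(condition = rep(c("correct", "error"), each = 4),
                           rate = rep(c(2, 3, 2, 3), 2))
  cc <- pool_correct_error(obs_eq)
  expect_equal(cc$t, 0)
  expect_equal(cc$p, 1)
  # higher correct-trial rates: significant, and label swap negates t
  set.seed(18)
  obs <- tibble::tibble(
    condition = rep(c("correct", "error"), each = 6),
    rate = c(2 + rnorm(6, sd = 0.01), 1 + rnorm(6, sd = 0.01)))
  cc2 <- pool_correct_error(obs)
  expect_gt(cc2$mean_correct, cc2$mean_error)
  expect_lt(cc2$p, 0.05)
  swapped <- obs
  swapped$condition <- ifelse(obs$condition == "correct", "error", "correct")
  cc3 <- pool_correct_error(swapped)
  expect_equal(cc3$t, -cc2$t)
  # one group empty: means only, no test
  cc4 <- pool_correct_error(obs[obs$condition == "correct", ])
  expect_true(is.na(cc4$t))
  expect_equal(cc4$n_error, 0L)
})

test_that("compare_correct_error builds per-unit condition means at preferred locations", {
  cues <- rep(c(0, 90), each = 4)
  # unit prefers 0; correct trials (first two per location) have higher rates
  del <- matrix(0, 1, 8)
  del[1, ] <- c(4, 4, 2, 2, 1, 1, 1, 1)
  rec <- constant_record(matrix(0.5, 1, 8), del, cue_angles = cues)
  beh <- tibble::tibble(correct = c(TRUE, TRUE, FALSE, FALSE, rep(TRUE, 4)))
  tun <- tibble::tibble(unit = 1, preferred = 0)
  cc <- compare_correct_error(rec, beh, tun)
  expect_equal(cc$obs$rate[cc$obs$condition == "correct"], 4)
  expect_equal(cc$obs$rate[cc$obs$condition == "error"], 2)
})

test_that("ANOVA on Fano factor detects location structure and is calibrated", {
  set.seed(19)
  # equal-mean groups: p should be uniform over repeated draws
  ps <- replicate(400, {
    cells <- tibble::tibble(offset = rep(canonical_locations() - 135, each = 8),
                            ff = rnorm(64, mean = 1, sd = 0.1))
    anova_fano_by_location(cells)$p
  })
  ks <- stats::ks.test(ps, "punif")
  expect_gt(ks$p.value, 0.01)
  # a 5 SD shift in one group is detected
  cells <- tibble::tibble(offset = rep(canonical_locations() - 135, each = 8),
                          ff = rnorm(64, mean = 1, sd = 0.1))
  cells$ff[cells$offset == 0] <- cells$ff[cells$offset == 0] + 0.5
  expect_lt(anova_fano_by_location(cells)$p, 0.001)
  expect_error(anova_fano_by_location(cells[1:8, ]), ">= 2 locations")
})

test_that("trained-like weight structure shows positive diagonality; random does not", {
  set.seed(20)
  n <- 64
  prefs <- seq(0, 360 - 360 / n, by = 360 / n)
  d <- abs(outer(prefs, prefs, angular_diff))
  params <- list(W_in = matrix(0, n, 4), W_rec = exp(-(d / 60)^2),
                 W_out = matrix(0, 3, n), n_rec = n)
  class(params) <- "wm_rnn"
  ws <- weight_structure(params, prefs)
  expect_gt(ws$diagonality, 0)

  # random orthogonal weights with random preferences: near-zero statistic
  set.seed(21)
  q <- qr.Q(qr(matrix(rnorm(n * n), n)))
  params$W_rec <- q
  prefs_r <- sample(canonical_locations(), n, replace = TRUE)
  ws_r <- weight_structure(params, prefs_r)
  null_stats <- replicate(200, {
    pp <- sample(prefs_r)
    weight_structure(params, pp)$diagonality
  })
  expect_lt(abs(ws_r$diagonality),
            max(3 * sd(null_stats), 1e-12) + abs(mean(null_stats)))

  # statistic invariant to a permutation applied consistently to weights
  # and preferences
  perm <- sample(n)
  params2 <- params
  params2$W_rec <- params$W_rec[perm, perm]
  ws_p <- weight_structure(params2, prefs_r[perm])
  expect_equal(ws_p$diagonality, ws_r$diagonality)
})
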