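test_that("stimulus encoding peaks at the nearest ring unit and is shift-symmetric", {
  ring <- ring_code(8)
  expect_equal(ring$directions, seq(0, 315, by = 45))

  z <- encode_stimulus(90, ring)
  expect_equal(which.max(z), 3L)          # 90 deg unit
  expect_true(all(z >= 0))

  # encoding at theta + 45 equals the encoding at theta shifted one slot
  z0 <- encode_stimulus(10, ring)
  z1 <- encode_stimulus(55, ring)
  expect_equal(z1, z0[c(8, 1:7)], tolerance = 1e-12)

  # circular symmetry around the peak for an on-grid stimulus
  z90 <- encode_stimulus(90, ring)
  expect_equal(z90[c(2, 4)], rep(z90[2], 2))
  expect_equal(z90[c(1, 5)], rep(z90[1], 2))

  expect_error(encode_stimulus(360, ring), "0, 360")
  expect_error(encode_stimulus(-1, ring), "0, 360")
})

test_that("narrow tuning degenerates to a one-hot code", {
  onehot <- encode_stimulus(92, ring_code(8, kappa = Inf))
  expect_equal(onehot, c(0, 0, 1, 0, 0, 0, 0, 0))
  # finite but very concentrated tuning approaches the same limit
  sharp <- encode_stimulus(92, ring_code(8, kappa = 500))
  expect_equal(sharp / max(sharp), onehot, tolerance = 1e-6)
})

test_that("trial layout matches the task timing at dt = 20 ms", {
  spec <- task_spec("odr", 1)
  tr <- build_trial(spec, cue_angle = 180, sigma_in = 0)
  # 1.5 s delay is 75 steps; total (1 + 0.5 + 1.5 + 0.5) / 0.02 = 175
  expect_identical(tr$meta$go - tr$meta$cue_off, 75L)
  expect_identical(ncol(tr$inputs), 175L)
  expect_identical(tr$meta$cue_on, 51L)

  # fixation input on through the delay, off during response
  expect_equal(tr$inputs[1, 1:tr$meta$go], rep(1, tr$meta$go))
  expect_equal(tr$inputs[1, (tr$meta$go + 1):175], rep(0, 175 - tr$meta$go))
  # stimulus block active during the cue epoch only
  stim <- tr$inputs[2:9, ]
  active <- which(colSums(stim) > 0)
  expect_equal(active, 51:75)
  # fixation target high while fixating, zero after go
  expect_equal(tr$targets[1, 1:tr$meta$go], rep(1, tr$meta$go))
  expect_equal(tr$targets[1, 171:175], rep(0, 5))
  # mask: grace period zeroed, response upweighted, total positive
  expect_equal(tr$mask[1, 151:155], rep(0, 5))
  expect_equal(tr$mask[1, 156:175], rep(5, 20))
  expect_gt(sum(tr$mask), 0)

  expect_error(build_trial(spec, 90, delay = 1.513), "not a multiple")
})

test_that("distractor trials activate the stimulus block in two disjoint epochs", {
  spec <- task_spec("odrd", 1, delay = 1.5, distractor_onset = 0.5,
                    distractor_duration = 0.3)
  tr <- build_trial(spec, cue_angle = 0, distractor_angle = 180,
                    sigma_in = 0)
  stim <- tr$inputs[2:9, ]
  active <- which(colSums(stim) > 0.5)
  gaps <- which(diff(active) > 1)
  expect_length(gaps, 1)                         # exactly two runs
  expect_true(all(active <= tr$meta$go))         # both inside cue/delay
  # response target still points at the first stimulus (the cue)
  expect_equal(tr$meta$target_dir, 0)
  expect_error(build_trial(spec, 0), "distractor angle")
  expect_error(
    task_spec("bad", 1, delay = 1, distractor_onset = 0.8,
              distractor_duration = 0.3),
    "strictly inside")
})

test_that("anti-response tasks target the direction opposite the cue", {
  spec <- task_spec("anti_odr", 1, mapping = "anti")
  tr <- build_trial(spec, cue_angle = 90, sigma_in = 0)
  expect_equal(tr$meta$target_dir, 270)
  ring_target <- tr$targets[2:9, 175]
  expect_equal(which.max(ring_target), 7L)       # the 270 deg output
})

test_that("batch sampling covers tasks, delays and canonical locations", {
  expect_length(admissible_delays(), 31)
  expect_equal(diff(canonical_locations()), rep(45, 7))

  reg <- default_task_registry()
  expect_length(reg, 6)
  expect_error(sample_batch(reg, 3), "stratified")

  set.seed(5)
  b <- sample_batch(reg, 12, delay_mode = "fixed")
  expect_equal(sort(table(b$meta$task_id)), sort(rep(2L, 6)),
               ignore_attr = TRUE)
  expect_true(all(b$meta$cue_angle %in% canonical_locations()))

  # fixed 3 s delay occupies 150 steps
  reg3 <- default_task_registry("odr", delay = 3)
  b3 <- sample_batch(reg3, 4, delay_mode = "fixed")
  expect_equal(b3$meta$go - b3$meta$cue_off, rep(150L, 4))

  set.seed(6)
  bv <- sample_batch(default_task_registry("odr"), 64,
                     delay_mode = "variable")
  expect_true(all(bv$meta$delay %in% admissible_delays()))
  expect_gt(length(unique(bv$meta$delay)), 5)
  # padding carries no loss mask
  short <- which.min(bv$meta$t_end)
  if (bv$meta$t_end[short] < dim(bv$mask)[3])
    expect_equal(sum(bv$mask[, short, (bv$meta$t_end[short] + 1):dim(bv$mask)[3]]), 0)
})

test_that("cue encoding round-trips through the population vector on the 8-location grid", {
  ring <- ring_code(8)
  for (ang in canonical_locations()) {
    z <- encode_stimulus(ang, ring)
    expect_equal(population_vector(z, ring$directions), ang)
  }
})

test_that("input noise is zero-mean and averaging recovers the template", {
  spec <- task_spec("odr", 1)
  template <- build_trial(spec, 90, sigma_in = 0)$inputs
  set.seed(42)
  n <- 1000
  acc <- array(0, dim(template))
  for (i in seq_len(n))
    acc <- acc + build_trial(spec, 90, sigma_in = 0.01)$inputs
  avg <- acc / n
  se <- 0.01 / sqrt(n)
  expect_lt(max(abs(avg - template)), 5 * se)
  expect_lt(abs(mean(avg - template)), 3 * se / sqrt(length(template) / 2))
})
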