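test_that("nonlinearities match their closed forms and are numerically stable", {
  expect_equal(softplus(0), log(2))
  expect_equal(softplus(5), log(1 + exp(5)))
  expect_lt(softplus(-50), 1e-20)
  expect_equal(softplus(1000), 1000)             # no overflow
  expect_true(all(diff(softplus(seq(-20, 20, 0.5))) > 0))

  expect_equal(logistic(0), 0.5)
  expect_equal(logistic(2), 1 / (1 + exp(-2)))
  x <- seq(-30, 30, 0.7)
  expect_equal(logistic(x) + logistic(-x), rep(1, length(x)))
  expect_equal(logistic(-800), 0)                # stable, not NaN
})

test_that("initialization follows the orthogonal / scaled-normal / Glorot scheme", {
  set.seed(7)
  p <- init_params(n_in = 100, n_rec = 128, n_out = 9)
  expect_lt(max(abs(crossprod(p$W_rec) - diag(128))), 1e-6)
  expect_lt(abs(sd(p$W_in) - 1 / sqrt(100)) / (1 / sqrt(100)), 0.05)
  lim <- sqrt(6 / (128 + 9))
  expect_true(all(abs(p$W_out) <= lim))
  expect_gt(max(abs(p$W_out)), 0.9 * lim)        # actually fills the range
  expect_equal(p$b, numeric(128))
  expect_true(min(p$W_in) < 0 && min(p$W_rec) < 0 && min(p$W_out) < 0)
})

test_that("initialization refuses to run unseeded", {
  # simulate a fresh session by removing the RNG state
  set.seed(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  rm(".Random.seed", envir = globalenv())
  expect_error(init_params(4, 8, 2), "set.seed")
})

test_that("leak-only dynamics follow the closed-form geometric relaxation", {
  set.seed(1)
  p <- init_params(3, 5, 2, sigma_rec = 0)
  p$W_in[] <- 0; p$W_rec[] <- 0; p$W_out[] <- 0; p$b[] <- 0
  # alpha = 20/100 = 0.2; r_k = ln2 (1 - 0.8^k) from r0 = 0
  r <- numeric(5)
  for (k in 1:40) {
    r <- rnn_step(r, numeric(3), p)
    expect_equal(r, rep(log(2) * (1 - 0.8^k), 5), tolerance = 1e-12)
  }
  # and toward softplus(b) when b is nonzero
  p$b[] <- 1.3
  r <- numeric(5)
  for (k in 1:200) r <- rnn_step(r, numeric(3), p)
  expect_equal(r, rep(softplus(1.3), 5), tolerance = 1e-12)
})

test_that("activity stays nonnegative under arbitrary inputs and noise", {
  set.seed(2)
  p <- init_params(4, 12, 3)
  reg <- default_task_registry("odr")
  b <- sample_batch(reg, 4)
  p2 <- init_params(10, 12, 9)
  rec <- run_trials(p2, b, seed = 9)
  expect_true(all(rec$rates >= 0))
  # pure R step too, including strongly negative input drive
  r <- runif(12)
  for (k in 1:50) {
    r <- rnn_step(r, c(-30, 10, -5, 0), p)
    expect_true(all(r >= 0))
  }
})

test_that("noiseless relaxation reaches the fixed point r* = f(W r* + W_in u + b)", {
  set.seed(3)
  W <- matrix(rnorm(25, sd = 0.2), 5)              # contractive
  p <- init_params(2, 5, 2, sigma_rec = 0)
  p$W_rec <- W
  u <- c(0.3, -0.1)
  r <- numeric(5)
  for (k in 1:2000) r <- rnn_step(r, u, p)
  resid <- r - softplus(drop(W %*% r + p$W_in %*% u) + p$b)
  expect_lt(max(abs(resid)), 1e-8)
})

test_that("the compiled forward pass agrees with the R reference step", {
  set.seed(4)
  p <- init_params(10, 16, 9, sigma_rec = 0)
  b <- sample_batch(default_task_registry("odr"), 2)
  rec <- run_trials(p, b, seed = 1, sigma_rec = 0)
  r <- numeric(16)
  for (t in 1:20) {
    r <- rnn_step(r, b$inputs[, 1, t], p)
    expect_equal(rec$rates[, 1, t], r, tolerance = 1e-12)
    expect_equal(rec$outputs[, 1, t], readout(r, p), tolerance = 1e-12)
  }
})

test_that("readout is the logistic of W_out r, bounded in (0,1)", {
  set.seed(5)
  p <- init_params(3, 4, 3)
  p$W_out[] <- 0
  expect_equal(readout(runif(4), p), rep(0.5, 3))
  p$W_out <- matrix(rnorm(12), 3, 4)
  z <- readout(runif(4), p)
  expect_true(all(z > 0 & z < 1))
  p1 <- p; p1$W_out <- matrix(c(1, 0, 0, 0), 1, 4); p1$n_out <- 1L
  expect_equal(readout(c(2, 0, 0, 0), p1), logistic(2))
})

test_that("trial simulation is a pure function of (params, inputs, seed)", {
  set.seed(6)
  p <- init_params(10, 24, 9)
  b <- sample_batch(default_task_registry("odr"), 3)
  r1 <- run_trials(p, b, seed = 123)
  r2 <- run_trials(p, b, seed = 123)
  expect_identical(r1$rates, r2$rates)
  expect_identical(r1$outputs, r2$outputs)
  r3 <- run_trials(p, b, seed = 124)
  expect_false(identical(r1$rates, r3$rates))
  # record bookkeeping: one sample per 20 ms bin over the whole trial
  expect_equal(dim(r1$rates)[3], unique(b$meta$t_end))
})

test_that("per-step noise has sd sigma_rec * sqrt(2/alpha) in the pre-activation", {
  # with W = 0 and b large, softplus is locally ~identity, so the sd of
  # r after one step from r0 = 0 is ~ alpha * sigma_rec * sqrt(2/alpha)
  set.seed(8)
  n_trials <- 4000
  p <- init_params(1, 1, 1, sigma_rec = 0.05)
  p$W_in[] <- 0; p$W_rec[] <- 0; p$W_out[] <- 0; p$b[] <- 20
  U <- array(0, c(1, n_trials, 1))
  fw <- wmrnn:::rnn_forward_cpp(p$W_in, p$W_rec, p$W_out, p$b, U, 0.2,
                                0.05, 0, 77)
  r1 <- fw$rates[1, , 1]
  expect_equal(sd(r1) / 0.2, 0.05 * sqrt(2 / 0.2), tolerance = 0.05)
  # halving dt (alpha) doubles the per-step variance factor 2/alpha
  fw2 <- wmrnn:::rnn_forward_cpp(p$W_in, p$W_rec, p$W_out, p$b, U, 0.1,
                                 0.05, 0, 78)
  v1 <- var(fw$rates[1, , 1] / 0.2)
  v2 <- var(fw2$rates[1, , 1] / 0.1)
  expect_equal(v2 / v1, 2, tolerance = 0.15)
})

test_that("checkpoints round-trip bit-exactly and missing files error", {
  set.seed(9)
  p <- init_params(6, 10, 4)
  path <- file.path(tempdir(), "ckpt_test.rds")
  save_checkpoint(list(params = p, note = "x"), path)
  back <- load_checkpoint(path)
  expect_identical(back$params, p)
  unlink(path)
  expect_error(load_checkpoint(path), "not found")
})
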