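#' Softplus nonlinearity
#'
#' `f(x) = log(1 + exp(x))`, evaluated in the overflow-safe form
#' `x + log1p(exp(-x))` for positive `x`. This is the firing-rate
#' nonlinearity of the recurrent units; its range (0, Inf) keeps unit
#' activity positive.
#'
#' @param x Numeric vector.
#' @return `log(1 + exp(x))`, elementwise.
#' @export
softplus <- function(x) ifelse(x > 0, x + log1p(exp(-x)), log1p(exp(x)))

#' Logistic function
#'
#' `g(x) = 1 / (1 + exp(-x))`, the output nonlinearity; bounded in (0, 1).
#'
#' @param x Numeric vector.
#' @return `1 / (1 + exp(-x))`, elementwise.
#' @export
logistic <- function(x) {
  ifelse(x > 0, 1 / (1 + exp(-x)), exp(x) / (1 + exp(x)))
}

#' Initialize network parameters
#'
#' Builds a leaky firing-rate RNN with the standard initialization for
#' this model family: recurrent weights `W_rec` random orthogonal, input
#' weights `W_in` standard normal scaled by `1/sqrt(n_in)`, output weights
#' `W_out` Glorot/Xavier uniform on +/- sqrt(6 / (n_rec + n_out)), and the
#' trainable background input `b` at zero. Weights are unconstrained in
#' sign. The fixed constants are the membrane time constant `tau`
#' (default 100 ms), the timestep `dt` (default 20 ms) and the recurrent
#' noise strength `sigma_rec` (default 0.05); the Euler factor is
#' `alpha = dt / tau`.
#'
#' All randomness comes from R's RNG: seed with `set.seed()` before
#' calling (an unseeded fresh session is rejected so every run is
#' reproducible by construction).
#'
#' @param n_in,n_rec,n_out Layer sizes (recurrent default 256).
#' @param tau Time constant (ms).
#' @param dt Timestep (ms).
#' @param sigma_rec Recurrent noise strength.
#' @return A `wm_rnn` object: list of weights plus constants.
#' @export
init_params <- function(n_in, n_rec = 256, n_out, tau = 100, dt = 20,
                        sigma_rec = 0.05) {
  stopifnot(n_in >= 1, n_rec >= 1, n_out >= 1, tau > 0, dt > 0, dt <= tau)
  if (!exists(".Random.seed", envir = globalenv()))
    stop("RNG not initialized: call set.seed() first so the run is seeded")
  # orthogonal W_rec via QR of a Gaussian matrix, sign-fixed to the
  # Haar-uniform convention
  A <- matrix(rnorm(n_rec * n_rec), n_rec)
  qr_ <- qr(A)
  Q <- qr.Q(qr_)
  Q <- Q %*% diag(sign(diag(qr.R(qr_))), n_rec)
  W_in <- matrix(rnorm(n_rec * n_in) / sqrt(n_in), n_rec, n_in)
  lim <- sqrt(6 / (n_rec + n_out))
  W_out <- matrix(runif(n_out * n_rec, -lim, lim), n_out, n_rec)
  structure(
    list(W_in = W_in, W_rec = Q, W_out = W_out, b = numeric(n_rec),
         tau = tau, dt = dt, sigma_rec = sigma_rec,
         n_in = as.integer(n_in), n_rec = as.integer(n_rec),
         n_out = as.integer(n_out)),
    class = "wm_rnn")
}

#' @export
print.wm_rnn <- function(x, ...) {
  cat(sprintf(
    "<wm_rnn: %d in -> %d recurrent -> %d out; tau %g ms, dt %g ms, sigma_rec %g>\n",
    x$n_in, x$n_rec, x$n_out, x$tau, x$dt, x$sigma_rec))
  invisible(x)
}

alpha_of <- function(params) params$dt / params$tau

#' One Euler step of the leaky-rate dynamics (reference implementation)
#'
#' `r <- (1 - alpha) r + alpha f(W_rec r + W_in u + b + noise)` with
#' `alpha = dt/tau` and pre-activation noise
#' `sigma_rec * sqrt(2/alpha) * eps`, `eps` standard normal per unit.
#' This pure-R single step is the reference against which the compiled
#' forward pass is tested; simulation of whole trials goes through
#' [run_trials()].
#'
#' @param r Current activity vector (nonnegative).
#' @param u_t Input vector at this step.
#' @param params A `wm_rnn`.
#' @param noise Optional pre-drawn standard-normal vector (length `n_rec`);
#'   default draws from R's RNG. Ignored when `sigma_rec = 0`.
#' @return Updated activity vector.
#' @export
rnn_step <- function(r, u_t, params, noise = NULL) {
  if (any(!is.finite(r))) stop("non-finite network state")
  a <- alpha_of(params)
  pre <- drop(params$W_rec %*% r + params$W_in %*% u_t) + params$b
  if (params$sigma_rec > 0) {
    if (is.null(noise)) noise <- rnorm(params$n_rec)
    pre <- pre + params$sigma_rec * sqrt(2 / a) * noise
  }
  (1 - a) * r + a * softplus(pre)
}

#' Readout of output activations
#'
#' `z = g(W_out r)`: logistic readout of the recurrent state, each output
#' in (0, 1).
#'
#' @param r Recurrent activity vector.
#' @param params A `wm_rnn`.
#' @return Output activation vector (fixation output first, then the ring).
#' @export
readout <- function(r, params) drop(logistic(params$W_out %*% r))

#' Simulate a batch of trials
#'
#' Runs the full forward dynamics over a [sample_batch()] trial batch and
#' records unit rates and outputs at every 20 ms step — the "recording"
#' that all analyses consume. The pass is a pure function of
#' (params, inputs, seed): identical seeds give bitwise-identical records.
#'
#' @param params A `wm_rnn`.
#' @param batch A `trial_batch`.
#' @param seed Integer seed for the recurrent noise; if `NULL`, drawn from
#'   R's RNG stream.
#' @param r0 Initial state (default zeros).
#' @param sigma_rec Override the stored noise strength (e.g. 0 for a
#'   noiseless probe).
#' @return A `wm_record`: list with `rates` (n_rec x trials x time),
#'   `outputs` (n_out x trials x time), `meta` (trial metadata tibble),
#'   `dt` (s) and the noise `seed` used.
#' @export
run_trials <- function(params, batch, seed = NULL, r0 = NULL,
                       sigma_rec = params$sigma_rec) {
  stopifnot(inherits(params, "wm_rnn"), inherits(batch, "trial_batch"))
  if (dim(batch$inputs)[1] != params$n_in)
    stop("batch input channels do not match the network")
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1)
  if (is.null(r0)) r0 <- numeric(params$n_rec)
  fw <- rnn_forward_cpp(params$W_in, params$W_rec, params$W_out, params$b,
                        batch$inputs, alpha_of(params), sigma_rec, r0,
                        as.double(seed))
  structure(list(rates = fw$rates, outputs = fw$outputs, meta = batch$meta,
                 dt = 0.02, seed = seed),
            class = "wm_record")
}

#' @export
print.wm_record <- function(x, ...) {
  d <- dim(x$rates)
  cat(sprintf("<wm_record: %d units x %d trials x %d steps (dt %g s)>\n",
              d[1], d[2], d[3], x$dt))
  invisible(x)
}

#' Save / load a network (with optional training state)
#'
#' Serialization uses R's native format; the round-trip is bit-exact, so a
#' restored checkpoint resumes training identically given the same seed
#' stream.
#'
#' @param object List to save (e.g. `list(params =, opt =, record =)`), or
#'   a bare `wm_rnn`.
#' @param path File path.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   the saved object.
#' @export
save_checkpoint <- function(object, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  saveRDS(object, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  obj <- tryCatch(readRDS(path),
                  error = function(e) stop("corrupt checkpoint ", path,
                                           ": ", conditionMessage(e)))
  obj
}
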