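#' Masked mean-squared-error loss
#'
#' `L = sum(mask * (outputs - targets)^2) / sum(mask)`. Timesteps with a
#' zero mask (the post-go grace period, padding of short trials) never
#' contribute; the response epoch is up-weighted through the mask built by
#' [build_trial()]. Zero iff outputs equal targets wherever the mask is
#' positive.
#'
#' @param outputs,targets,mask Arrays of identical shape.
#' @return Scalar loss, `>= 0`.
#' @export
masked_loss <- function(outputs, targets, mask) {
  stopifnot(all(dim(outputs) == dim(targets)),
            all(dim(outputs) == dim(mask)))
  msum <- sum(mask)
  if (msum <= 0) stop("loss mask sums to zero")
  sum(mask * (outputs - targets)^2) / msum
}

#' Adam optimizer state
#'
#' Standard Adam with bias-corrected first and second moments
#' (beta1 = 0.9, beta2 = 0.999, eps = 1e-8) and optional global-norm
#' gradient clipping, applied to every trainable tensor
#' (`W_in`, `W_rec`, `W_out`, `b`).
#'
#' @param params A `wm_rnn`.
#' @param eta Learning rate (default 0.001).
#' @param beta1,beta2,eps Adam constants.
#' @param clip Global gradient-norm ceiling (`Inf` to disable; default 1).
#' @return An `adam_state` list.
#' @export
adam_init <- function(params, eta = 0.001, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, clip = 1) {
  stopifnot(eta > 0)
  zeros <- lapply(params[c("W_in", "W_rec", "W_out", "b")],
                  function(w) array(0, dim = dim(w) %||% length(w)))
  structure(list(m = zeros, v = zeros, t = 0L, eta = eta, beta1 = beta1,
                 beta2 = beta2, eps = eps, clip = clip, n_clipped = 0L,
                 n_skipped = 0L),
            class = "adam_state")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# one Adam update; grads is a list named like the trainable tensors
adam_update <- function(params, grads, state) {
  gn <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
  if (!is.finite(gn)) {                 # skip the update, keep a count
    state$n_skipped <- state$n_skipped + 1L
    return(list(params = params, state = state))
  }
  if (gn > state$clip) {
    grads <- lapply(grads, function(g) g * (state$clip / gn))
    state$n_clipped <- state$n_clipped + 1L
  }
  state$t <- state$t + 1L
  bc1 <- 1 - state$beta1^state$t
  bc2 <- 1 - state$beta2^state$t
  for (k in names(grads)) {
    state$m[[k]] <- state$beta1 * state$m[[k]] + (1 - state$beta1) * grads[[k]]
    state$v[[k]] <- state$beta2 * state$v[[k]] +
      (1 - state$beta2) * grads[[k]]^2
    upd <- state$eta * (state$m[[k]] / bc1) /
      (sqrt(state$v[[k]] / bc2) + state$eps)
    params[[k]] <- params[[k]] - array(upd, dim = dim(params[[k]]) %||%
                                         length(params[[k]]))
  }
  list(params = params, state = state)
}

#' One gradient step on a trial batch
#'
#' Computes the masked-MSE loss and its gradients by backpropagation
#' through the unrolled dynamics (all of `W_in`, `W_rec`, `W_out`, `b`
#' trainable) and applies one Adam update. Non-finite gradients skip the
#' update and are counted in the optimizer state.
#'
#' @param params A `wm_rnn`.
#' @param batch A `trial_batch`.
#' @param state An [adam_init()] state.
#' @param seed Noise seed for this forward/backward pass (default drawn
#'   from R's RNG).
#' @return List with updated `params`, `state`, and the batch `loss`.
#' @export
train_step <- function(params, batch, state, seed = NULL) {
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1)
  gr <- rnn_grad_cpp(params$W_in, params$W_rec, params$W_out, params$b,
                     batch$inputs, batch$targets, batch$mask,
                     alpha_of(params), params$sigma_rec,
                     numeric(params$n_rec), as.double(seed))
  grads <- list(W_in = gr$gW_in, W_rec = gr$gW_rec, W_out = gr$gW_out,
                b = drop(gr$gb))
  upd <- adam_update(params, grads, state)
  list(params = upd$params, state = upd$state, loss = gr$loss)
}

#' Classify a performance level into a training stage
#'
#' Stages partition [0, 100] with half-open bands: below 35 "early",
#' [35, 65) "mid-trained", [65, 95) "mature", and >= 95 "fully-trained".
#'
#' @param percent_correct Performance in percent, in [0, 100]; vectorized.
#' @return Factor with levels early, mid-trained, mature, fully-trained.
#' @export
classify_stage <- function(percent_correct) {
  if (any(!is.finite(percent_correct)) || any(percent_correct < 0) ||
      any(percent_correct > 100))
    stop("percent_correct must lie in [0, 100]")
  cut(percent_correct, breaks = c(-Inf, 35, 65, 95, Inf),
      labels = c("early", "mid-trained", "mature", "fully-trained"),
      right = FALSE)
}

#' Evaluate a network's task performance
#'
#' Generates fresh seeded trials (equal counts per task via stratified
#' round-robin, cue locations balanced within each task), simulates
#' them with the recurrent noise at its training value, scores each trial with the fixation-hold and 36-degree-window
#' criterion, and reports percent correct per task and overall. Scoring is
#' invariant to trial order.
#'
#' @param params A `wm_rnn`.
#' @param registry Task registry used in training.
#' @param n_per_task Fresh trials per task.
#' @param seed Seed for trial sampling and recurrent noise.
#' @param delay Optional delay (s) overriding every delayed task's delay —
#'   e.g. to probe generalization of a variable-delay network at an unseen
#'   duration.
#' @param ring Ring code matching the network's input layout.
#' @param ... Passed to [sample_batch()].
#' @return List: `per_task` tibble (task_id, n, n_correct,
#'   percent_correct), `overall` percent, `stage`, and the scored
#'   `behavior` table.
#' @export
evaluate_network <- function(params, registry, n_per_task = 100,
                             seed = NULL, delay = NULL,
                             ring = ring_code(8), ...) {
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(delay)) {
    registry <- lapply(registry, function(s) {
      if (s$delay > 0) s$delay <- delay
      if (!is.null(s$distractor_onset) &&
          s$distractor_onset + s$distractor_duration >= s$delay)
        stop("override delay too short for the distractor epoch")
      s
    })
  }
  batch <- sample_batch(registry, n_per_task * length(registry),
                        delay_mode = "fixed", ring = ring,
                        stratify = TRUE, balance_cues = TRUE, ...)
  rec <- run_trials(params, batch)
  beh <- score_trials(rec)
  per_task <- dplyr::summarise(
    dplyr::group_by(beh, .data$task_id),
    n = dplyr::n(), n_correct = sum(.data$correct),
    percent_correct = 100 * mean(.data$correct), .groups = "drop")
  overall <- 100 * mean(beh$correct)
  list(per_task = per_task, overall = overall,
       stage = as.character(classify_stage(overall)), behavior = beh)
}

#' Train a network on a task battery
#'
#' Supervised training with Adam on stratified minibatches. Performance is
#' evaluated on fresh seeded trials every `eval_every` updates; training
#' stops at the fully-trained criterion (>= `stop_at` percent correct,
#' default 95) or after `max_steps` updates. The first checkpoint observed
#' in each training stage is kept, so mid-trained and mature networks can
#' be analyzed alongside the final one.
#'
#' @param params A `wm_rnn` (from [init_params()]).
#' @param registry Task registry (list of [task_spec()]).
#' @param seed Master seed for the whole run (batches, noise, evaluation).
#' @param eta Learning rate.
#' @param batch_size Trials per minibatch (default 64).
#' @param max_steps Update budget (default 3000).
#' @param eval_every Updates between evaluations (default 50).
#' @param eval_trials Fresh trials per task per evaluation (default 24:
#'   three per cue location, balanced).
#' @param delay_mode `"fixed"` or `"variable"` delays during training.
#' @param stop_at Early-stop threshold on overall percent correct;
#'   `Inf` trains for the full budget.
#' @param ring Ring code shared by inputs and outputs.
#' @param clip Global gradient-norm ceiling.
#' @param keep_stage_checkpoints Keep the first checkpoint of each stage.
#' @param verbose Print evaluation lines.
#' @return A `wm_fit`: final `params`, `record` tibble (step, loss,
#'   percent correct overall and per task, stage), `checkpoints`,
#'   optimizer `state`, and the call configuration.
#' @export
train_network <- function(params, registry, seed = 1, eta = 0.001,
                          batch_size = 64, max_steps = 3000,
                          eval_every = 50, eval_trials = 24,
                          delay_mode = c("fixed", "variable"),
                          stop_at = 95, ring = ring_code(8), clip = 1,
                          keep_stage_checkpoints = TRUE, verbose = FALSE) {
  delay_mode <- match.arg(delay_mode)
  set.seed(seed)
  state <- adam_init(params, eta = eta, clip = clip)
  rows <- list()
  checkpoints <- list()
  trained <- FALSE
  step <- 0L
  loss_acc <- c()

  while (step < max_steps && !trained) {
    batch <- sample_batch(registry, batch_size, delay_mode = delay_mode,
                          ring = ring)
    st <- train_step(params, batch, state)
    params <- st$params; state <- st$state
    loss_acc <- c(loss_acc, st$loss)
    step <- step + 1L

    if (step %% eval_every == 0 || step == max_steps) {
      ev <- evaluate_network(params, registry, n_per_task = eval_trials,
                             seed = sample.int(.Machine$integer.max, 1),
                             ring = ring)
      stage <- ev$stage
      row <- tibble::tibble(step = step, loss = mean(loss_acc),
                            percent_correct = ev$overall, stage = stage)
      pc <- setNames(ev$per_task$percent_correct,
                     paste0("pc_", ev$per_task$task_id))
      rows[[length(rows) + 1L]] <- dplyr::bind_cols(row,
                                                    tibble::as_tibble_row(pc))
      loss_acc <- c()
      if (verbose)
        message(sprintf("step %5d  loss %.4f  correct %5.1f%%  [%s]",
                        step, row$loss, ev$overall, stage))
      if (keep_stage_checkpoints && !stage %in% names(checkpoints))
        checkpoints[[stage]] <- params
      if (ev$overall >= stop_at) trained <- TRUE
    }
  }
  record <- dplyr::bind_rows(rows)
  structure(list(params = params, record = record,
                 checkpoints = checkpoints, state = state,
                 config = list(seed = seed, eta = eta,
                               batch_size = batch_size,
                               max_steps = max_steps,
                               eval_every = eval_every,
                               eval_trials = eval_trials,
                               delay_mode = delay_mode, stop_at = stop_at,
                               tasks = vapply(registry, `[[`, "",
                                              "task_id")),
                 n_updates = step, trained = trained, ring = ring),
            class = "wm_fit")
}

#' @export
print.wm_fit <- function(x, ...) {
  last <- utils::tail(x$record, 1)
  cat(sprintf(
    "<wm_fit: %d updates on [%s]; final %.1f%% correct (%s)>\n",
    x$n_updates, paste(x$config$tasks, collapse = ", "),
    last$percent_correct, last$stage))
  invisible(x)
}

#' Tidy the training record of a fitted network
#'
#' @param x A `wm_fit`.
#' @param ... Unused.
#' @return The per-evaluation record tibble (step, loss, percent correct
#'   overall and per task, stage).
#' @export
tidy.wm_fit <- function(x, ...) x$record

#' One-row summary of a fitted network
#'
#' @param x A `wm_fit`.
#' @param ... Unused.
#' @return Tibble with final performance, stage, update count, whether the
#'   fully-trained criterion was reached, and clipped/skipped counts.
#' @export
glance.wm_fit <- function(x, ...) {
  last <- utils::tail(x$record, 1)
  tibble::tibble(n_updates = x$n_updates,
                 percent_correct = last$percent_correct,
                 stage = as.character(last$stage), trained = x$trained,
                 final_loss = last$loss, n_clipped = x$state$n_clipped,
                 n_skipped = x$state$n_skipped)
}
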