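#' Specify a delayed-response task
#'
#' A task is a sequence of epochs — fixation, cue, delay (optionally
#' containing a distractor), response — plus a response mapping: `"pro"`
#' tasks require a response toward the cue, `"anti"` tasks a response
#' opposite (180 deg from) the cue. Durations are in seconds and must be
#' integer multiples of the simulation timestep (20 ms); the canonical
#' epochs are 1 s fixation, 0.5 s cue, and a 1.5 or 3 s delay.
#'
#' @param task_id Short task name (e.g. `"odr"`).
#' @param rule_index Position of this task's unit in the one-hot rule
#'   block of the input; unique within a registry.
#' @param fixation,cue,response Epoch durations (s).
#' @param delay Delay duration (s); may be 0 for zero-delay control tasks.
#'   In variable-delay training this is the value used when a fixed delay
#'   is requested at evaluation time.
#' @param distractor_onset,distractor_duration Distractor timing (s,
#'   relative to delay onset), or `NULL` for tasks without a distractor.
#'   The distractor must fall strictly inside the delay.
#' @param mapping `"pro"` or `"anti"`.
#' @return A `task_spec` object.
#' @export
task_spec <- function(task_id, rule_index, fixation = 1, cue = 0.5,
                      delay = 1.5, response = 0.5,
                      distractor_onset = NULL, distractor_duration = NULL,
                      mapping = c("pro", "anti")) {
  mapping <- match.arg(mapping)
  stopifnot(fixation > 0, cue > 0, response > 0, delay >= 0)
  for (d in c(fixation, cue, delay, response, distractor_onset,
              distractor_duration))
    check_commensurate(d)
  if (xor(is.null(distractor_onset), is.null(distractor_duration)))
    stop("distractor onset and duration must be given together")
  if (!is.null(distractor_onset)) {
    if (distractor_onset <= 0 ||
        distractor_onset + distractor_duration >= delay)
      stop("distractor must fall strictly inside the delay")
  }
  structure(
    list(task_id = task_id, rule_index = as.integer(rule_index),
         fixation = fixation, cue = cue, delay = delay,
         response = response, distractor_onset = distractor_onset,
         distractor_duration = distractor_duration, mapping = mapping),
    class = "task_spec")
}

#' @export
print.task_spec <- function(x, ...) {
  cat(sprintf("<task_spec %s: %s, fix %gs / cue %gs / delay %gs / resp %gs%s>\n",
              x$task_id, x$mapping, x$fixation, x$cue, x$delay, x$response,
              if (!is.null(x$distractor_onset))
                sprintf(", distractor @%gs for %gs", x$distractor_onset,
                        x$distractor_duration) else ""))
  invisible(x)
}

#' Default task registry
#'
#' Six tasks: ODR (delayed pro-response), ODRD (ODR with a to-be-ignored
#' distractor mid-delay), their anti-response counterparts, and two
#' zero-delay pro/anti control tasks. Rule indices are assigned in that
#' order. The trained battery is configurable: pass any subset of task ids.
#'
#' @param tasks Character vector of task ids to include (default all six).
#' @param delay Default delay (s) for the delayed tasks.
#' @return List of [task_spec()] objects with consecutive rule indices.
#' @export
default_task_registry <- function(tasks = c("odr", "odrd", "anti_odr",
                                            "anti_odrd", "pro_ctrl",
                                            "anti_ctrl"),
                                  delay = 1.5) {
  all <- list(
    odr       = function(i) task_spec("odr", i, delay = delay),
    odrd      = function(i) task_spec("odrd", i, delay = delay,
                                      distractor_onset = round(delay / 3, 1),
                                      distractor_duration = 0.3),
    anti_odr  = function(i) task_spec("anti_odr", i, delay = delay,
                                      mapping = "anti"),
    anti_odrd = function(i) task_spec("anti_odrd", i, delay = delay,
                                      distractor_onset = round(delay / 3, 1),
                                      distractor_duration = 0.3,
                                      mapping = "anti"),
    pro_ctrl  = function(i) task_spec("pro_ctrl", i, delay = 0),
    anti_ctrl = function(i) task_spec("anti_ctrl", i, delay = 0,
                                      mapping = "anti"))
  tasks <- match.arg(tasks, names(all), several.ok = TRUE)
  out <- lapply(seq_along(tasks), function(i) all[[tasks[i]]](i))
  names(out) <- tasks
  out
}

#' Admissible delays for variable-delay training
#'
#' @return The 31 delay values 0, 0.1, ..., 3.0 s.
#' @export
admissible_delays <- function() seq(0, 3, by = 0.1)

#' The 8 canonical cue locations
#' @return Angles 0, 45, ..., 315 degrees.
#' @export
canonical_locations <- function() seq(0, 315, by = 45)

# durations must be integer multiples of dt
check_commensurate <- function(dur, dt = 0.02) {
  if (is.null(dur)) return(invisible(TRUE))
  steps <- dur / dt
  if (abs(steps - round(steps)) > 1e-9)
    stop(sprintf("duration %g s is not a multiple of dt = %g s", dur, dt))
  invisible(TRUE)
}

n_steps <- function(dur, dt = 0.02) as.integer(round(dur / dt))

#' Build a single trial
#'
#' Lays out the input, target and loss-mask time series for one trial.
#' Inputs are 1 fixation channel + `n_ring` stimulus channels + `n_rules`
#' rule channels; the fixation input is 1 from trial start through the end
#' of the delay and 0 during the response epoch, the stimulus block carries
#' the cue code during the cue epoch only (plus the distractor code during
#' the distractor epoch, for distractor tasks), and the rule block is a
#' one-hot vector held on for the whole trial. Gaussian noise of sd
#' `sigma_in` is added to every input channel and timestep. Targets: the
#' fixation output must be 1 while fixation is required and 0 afterwards;
#' the ring target is a bump of peak 1 centered on the required response
#' direction during the response epoch and a 0.05 baseline elsewhere. The
#' mask up-weights the response epoch by `response_weight` and zeroes the
#' first `grace` seconds after the go signal so the readout's finite rise
#' time is not penalized.
#'
#' @param spec A [task_spec()].
#' @param cue_angle Cue direction (deg, one of [0, 360)).
#' @param delay Delay to use (s); defaults to `spec$delay`.
#' @param distractor_angle Distractor direction (deg); required iff the
#'   task has a distractor epoch.
#' @param ring Input/output [ring_code()].
#' @param n_rules Width of the rule block.
#' @param sigma_in Input noise sd (default 0.01).
#' @param grace Post-go grace period (s, default 0.1).
#' @param response_weight Mask weight during the response epoch.
#' @param target_baseline Ring-target baseline outside the response epoch.
#' @param dt Timestep (s).
#' @return List with `inputs` (n_in x T), `targets` (n_out x T), `mask`
#'   (n_out x T) and a one-row `meta` tibble carrying the task id, cue and
#'   distractor angles, delay, the required response direction, and the
#'   step indices of epoch boundaries (`cue_on`, `cue_off`, `go`, `t_end`).
#' @export
build_trial <- function(spec, cue_angle, delay = spec$delay,
                        distractor_angle = NULL, ring = ring_code(8),
                        n_rules = 1L, sigma_in = 0.01, grace = 0.1,
                        response_weight = 5, target_baseline = 0.05,
                        dt = 0.02) {
  stopifnot(inherits(spec, "task_spec"))
  # the noiseless layout is deterministic given these arguments; cache it
  # so batch sampling only pays for the noise draw
  key <- paste(spec$task_id, spec$rule_index, spec$fixation, spec$cue,
               spec$response, spec$mapping, cue_angle, delay,
               distractor_angle %||% "-", ring$n_ring, ring$kappa,
               ring$amplitude, n_rules, grace, response_weight,
               target_baseline, dt, sep = "|")
  tmpl <- .trial_templates[[key]]
  if (!is.null(tmpl)) {
    if (sigma_in > 0)
      tmpl$inputs <- tmpl$inputs +
        matrix(rnorm(length(tmpl$inputs), sd = sigma_in),
               nrow(tmpl$inputs))
    return(tmpl)
  }
  for (d in c(delay, grace)) check_commensurate(d, dt)
  has_distractor <- !is.null(spec$distractor_onset)
  if (has_distractor && is.null(distractor_angle))
    stop("task ", spec$task_id, " needs a distractor angle")
  if (!has_distractor && !is.null(distractor_angle))
    stop("task ", spec$task_id, " has no distractor epoch")

  nf <- n_steps(spec$fixation, dt); nc <- n_steps(spec$cue, dt)
  nd <- n_steps(delay, dt); nr <- n_steps(spec$response, dt)
  ng <- n_steps(grace, dt)
  T_ <- nf + nc + nd + nr
  n_ring <- ring$n_ring
  n_in <- 1L + n_ring + n_rules
  n_out <- 1L + n_ring

  fix_idx <- 1L
  stim_idx <- 1L + seq_len(n_ring)
  rule_idx <- 1L + n_ring + spec$rule_index
  if (spec$rule_index > n_rules) stop("rule_index exceeds n_rules")

  cue_on <- nf + 1L; cue_off <- nf + nc        # cue occupies [cue_on, cue_off]
  go <- nf + nc + nd                           # last step of required fixation
  inputs <- matrix(0, n_in, T_)
  inputs[fix_idx, seq_len(go)] <- 1
  inputs[stim_idx, cue_on:cue_off] <- encode_stimulus(cue_angle, ring)
  if (has_distractor && nd > 0) {
    d_on <- go - nd + n_steps(spec$distractor_onset, dt) + 1L
    d_off <- d_on + n_steps(spec$distractor_duration, dt) - 1L
    inputs[stim_idx, d_on:d_off] <- inputs[stim_idx, d_on:d_off] +
      encode_stimulus(distractor_angle, ring)
  }
  inputs[rule_idx, ] <- 1

  target_dir <- if (spec$mapping == "anti") wrap_angle(cue_angle + 180)
                else cue_angle
  targets <- matrix(target_baseline, n_out, T_)
  targets[1L, seq_len(go)] <- 1
  targets[1L, (go + 1L):T_] <- 0
  bump <- encode_stimulus(target_dir, ring) / ring$amplitude
  targets[-1L, (go + 1L):T_] <- pmax(bump, target_baseline)

  mask <- matrix(1, n_out, T_)
  mask[, (go + 1L):T_] <- response_weight
  if (ng > 0) mask[, go + seq_len(min(ng, T_ - go))] <- 0

  meta <- tibble::new_tibble(list(
    task_id = spec$task_id, cue_angle = cue_angle,
    distractor_angle = if (has_distractor) distractor_angle else NA_real_,
    delay = delay, target_dir = target_dir,
    cue_on = cue_on, cue_off = cue_off, go = go, t_end = T_), nrow = 1L)
  out <- list(inputs = inputs, targets = targets, mask = mask, meta = meta)
  .trial_templates[[key]] <- out
  if (sigma_in > 0)
    out$inputs <- out$inputs + matrix(rnorm(n_in * T_, sd = sigma_in),
                                      n_in, T_)
  out
}

.trial_templates <- new.env(parent = emptyenv())

#' Sample a minibatch of trials
#'
#' Draws a batch of trials with tasks interleaved across the registry
#' (stratified round-robin by default, so every task appears in every
#' batch), cue angles uniform over the 8 canonical locations unless
#' `cue_angles` says otherwise, and — in variable-delay mode — each
#' delayed task's delay drawn uniformly from [admissible_delays()].
#' Trials of unequal length are right-padded with zero inputs and a zero
#' mask, so padding never contributes to the loss.
#'
#' @param registry List of [task_spec()]s (e.g. [default_task_registry()]).
#' @param batch_size Number of trials.
#' @param delay_mode `"fixed"` (each spec's own delay) or `"variable"`.
#' @param ring Input/output [ring_code()].
#' @param cue_angles Candidate cue directions (deg).
#' @param stratify Interleave tasks round-robin (requires
#'   `batch_size >= length(registry)`); otherwise tasks are drawn uniformly.
#' @param balance_cues Assign cue angles round-robin within each task so
#'   every location appears as evenly as the batch size allows — the
#'   stratified design used for evaluation, where a location-specific
#'   failure must not be missed by sampling accident. Default `FALSE`
#'   (training draws cues uniformly at random).
#' @param ... Passed to [build_trial()] (noise, mask weights, dt).
#' @return A `trial_batch`: list with arrays `inputs` (n_in x B x T),
#'   `targets` and `mask` (n_out x B x T), and a `meta` tibble (one row per
#'   trial).
#' @export
sample_batch <- function(registry, batch_size, delay_mode = c("fixed",
                         "variable"), ring = ring_code(8),
                         cue_angles = canonical_locations(),
                         stratify = TRUE, balance_cues = FALSE, ...) {
  delay_mode <- match.arg(delay_mode)
  stopifnot(length(registry) >= 1, batch_size >= 1)
  if (stratify && batch_size < length(registry))
    stop("batch_size must be >= number of tasks for stratified sampling")
  n_rules <- max(vapply(registry, function(s) s$rule_index, integer(1)))

  task_of <- if (stratify)
    rep_len(seq_along(registry), batch_size)
  else sample.int(length(registry), batch_size, replace = TRUE)
  cue_of <- rep(NA_real_, batch_size)
  if (balance_cues) {
    for (j in unique(task_of)) {
      idx <- which(task_of == j)
      cue_of[idx] <- rep_len(cue_angles, length(idx))
    }
  }

  draw1 <- function(x) x[sample.int(length(x), 1L)]  # safe for length-1 x
  trials <- lapply(seq_len(batch_size), function(i) {
    spec <- registry[[task_of[i]]]
    cue <- if (balance_cues) cue_of[i] else draw1(cue_angles)
    delay <- spec$delay
    if (delay_mode == "variable" && spec$delay > 0)
      delay <- draw1(admissible_delays())
    dist_ang <- NULL
    if (!is.null(spec$distractor_onset)) {
      if (delay_mode == "variable")     # keep the distractor inside the delay
        delay <- max(delay, spec$distractor_onset +
                       spec$distractor_duration + 0.1)
      dist_ang <- draw1(setdiff(cue_angles, cue))
    }
    build_trial(spec, cue, delay = delay, distractor_angle = dist_ang,
                ring = ring, n_rules = n_rules, ...)
  })
  pack_trials(trials)
}

# right-pad single trials into (n_in x B x T) arrays
pack_trials <- function(trials) {
  T_max <- max(vapply(trials, function(tr) ncol(tr$inputs), integer(1)))
  B <- length(trials)
  n_in <- nrow(trials[[1]]$inputs); n_out <- nrow(trials[[1]]$targets)
  inputs <- array(0, c(n_in, B, T_max))
  targets <- array(0, c(n_out, B, T_max))
  mask <- array(0, c(n_out, B, T_max))
  for (i in seq_len(B)) {
    T_i <- ncol(trials[[i]]$inputs)
    inputs[, i, seq_len(T_i)] <- trials[[i]]$inputs
    targets[, i, seq_len(T_i)] <- trials[[i]]$targets
    mask[, i, seq_len(T_i)] <- trials[[i]]$mask
  }
  meta <- dplyr::bind_rows(lapply(trials, `[[`, "meta"))
  meta$trial <- seq_len(B)
  structure(list(inputs = inputs, targets = targets, mask = mask,
                 meta = meta),
            class = "trial_batch")
}

#' @export
print.trial_batch <- function(x, ...) {
  d <- dim(x$inputs)
  cat(sprintf("<trial_batch: %d trials x %d steps, %d input channels; tasks: %s>\n",
              d[2], d[3], d[1],
              paste(unique(x$meta$task_id), collapse = ", ")))
  invisible(x)
}

#' Balanced batch of one task at every cue location
#'
#' Builds `n_per_loc` trials at each canonical cue location for a single
#' task at a fixed delay — the layout used for tuning, correlation and
#' Fano-factor analyses, which need matched trial counts per location.
#'
#' @param spec A [task_spec()].
#' @param n_per_loc Trials per cue location.
#' @param ring Input/output [ring_code()].
#' @param n_rules Width of the rule block (the trained registry's width).
#' @param cue_angles Cue locations (default the 8 canonical ones).
#' @param ... Passed to [build_trial()].
#' @return A `trial_batch`.
#' @export
location_batch <- function(spec, n_per_loc, ring = ring_code(8),
                           n_rules = 1L,
                           cue_angles = canonical_locations(), ...) {
  draw1 <- function(x) x[sample.int(length(x), 1L)]
  trials <- list()
  for (cue in cue_angles) {
    for (i in seq_len(n_per_loc)) {
      dist_ang <- if (!is.null(spec$distractor_onset))
        draw1(setdiff(cue_angles, cue)) else NULL
      trials[[length(trials) + 1L]] <-
        build_trial(spec, cue, distractor_angle = dist_ang, ring = ring,
                    n_rules = n_rules, ...)
    }
  }
  pack_trials(trials)
}
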