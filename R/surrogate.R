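#' Drifting-bump surrogate recording
#'
#' Generates a synthetic population recording with a known ground-truth
#' mechanism: on each trial a bump of activity appears at the cue location
#' and performs a Gaussian random walk for the rest of the trial; each
#' unit's rate is its von-Mises tuning curve evaluated at the current bump
#' position (plus small observation noise), and the behavioral endpoint is
#' the bump position at the end of the delay. Because the same drift
#' drives rates and behavior, the surrogate reproduces — by construction —
#' the diagnostic signatures of bump-attractor dynamics: a positive
#' rate-behavior correlation and elevated Fano factor on the tuning
#' flanks (the "M" shapes), both of which vanish when `drift_sd = 0`.
#' It serves as the independent ground-truth oracle for the analysis
#' functions, not as a model of the trained networks.
#'
#' @param n_units Number of units; preferred locations are spaced
#'   uniformly on [0, 360).
#' @param n_per_loc Trials per cue location.
#' @param locations Cue locations (default the 8 canonical ones).
#' @param drift_sd Bump drift, degrees per sqrt(second) (default 15; 0
#'   ablates the mechanism).
#' @param kappa Tuning concentration (as in [ring_code()]).
#' @param amplitude,baseline Tuning peak rate above baseline, and baseline
#'   rate.
#' @param obs_sd Observation noise sd added to every rate sample.
#' @param fixation,cue,delay,response Epoch durations (s).
#' @param dt Timestep (s).
#' @return List with `record` (a `wm_record`; `outputs` is `NULL` since
#'   behavior comes straight from the bump), `behavior` (a behavior
#'   tibble), and `preferred` (ground-truth preferred locations).
#' @export
make_bump_surrogate <- function(n_units = 64, n_per_loc = 16,
                                locations = canonical_locations(),
                                drift_sd = 15, kappa = 3.75,
                                amplitude = 1, baseline = 0.1,
                                obs_sd = 0.01, fixation = 1, cue = 0.5,
                                delay = 1.5, response = 0.5, dt = 0.02) {
  nf <- n_steps(fixation, dt); nc <- n_steps(cue, dt)
  nd <- n_steps(delay, dt); nr <- n_steps(response, dt)
  T_ <- nf + nc + nd + nr
  B <- n_per_loc * length(locations)
  pref <- seq(0, 360 - 360 / n_units, by = 360 / n_units)
  step_sd <- drift_sd * sqrt(dt)

  rates <- array(0, c(n_units, B, T_))
  meta <- tibble::tibble(
    task_id = "bump_surrogate",
    cue_angle = rep(locations, each = n_per_loc),
    distractor_angle = NA_real_,
    delay = delay, target_dir = rep(locations, each = n_per_loc),
    cue_on = nf + 1L, cue_off = nf + nc, go = nf + nc + nd, t_end = T_,
    trial = seq_len(B))
  endpoint <- numeric(B)

  tune <- function(pos) baseline +
    amplitude * exp(kappa * (cos(deg2rad(pos - pref)) - 1))

  for (i in seq_len(B)) {
    cue_loc <- meta$cue_angle[i]
    pos <- cue_loc + cumsum(rnorm(nc + nd + nr, sd = step_sd))
    tr <- matrix(baseline, n_units, T_)
    tr[, (nf + 1):T_] <- vapply(pos, tune, numeric(n_units))
    rates[, i, ] <- pmax(tr + matrix(rnorm(n_units * T_, sd = obs_sd),
                                     n_units, T_), 0)
    endpoint[i] <- wrap_angle(pos[nc + nd])   # bump position at the go cue
  }
  dev <- angular_diff(endpoint, meta$cue_angle)
  behavior <- tibble::tibble(
    trial = meta$trial, task_id = meta$task_id,
    cue_angle = meta$cue_angle, delay = delay,
    target_dir = meta$target_dir, endpoint = endpoint, deviation = dev,
    fixation_hold = TRUE, correct = abs(dev) <= 36)
  record <- structure(list(rates = rates, outputs = NULL, meta = meta,
                           dt = dt, seed = NA),
                      class = "wm_record")
  list(record = record, behavior = behavior, preferred = pref)
}
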