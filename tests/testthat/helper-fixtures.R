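# shared fixtures; heavyweight trained networks are built once per session
# and cached so several test files can reuse them

.fixture_cache <- new.env(parent = emptyenv())

cache_get <- function(key, build) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, build(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

odr_registry <- function(delay = 1.5) default_task_registry("odr", delay = delay)

# the study configuration: 128 recurrent units, ODR only, fixed 1.5 s
# delay, minibatch 64, learning rate 0.001, up to 3000 Adam updates
train_odr_net <- function(seed, max_steps = 3000) {
  cache_get(paste0("odr_net_", seed), function() {
    set.seed(seed)
    params <- init_params(n_in = 10, n_rec = 128, n_out = 9)
    train_network(params, odr_registry(), seed = seed,
                  max_steps = max_steps)
  })
}

# fully trained networks among the first seeds (>= 3 for ensemble analyses)
trained_ensemble <- function(n = 3, from_seeds = 1:10) {
  fits <- list()
  for (s in from_seeds) {
    fit <- train_odr_net(s)
    if (fit$trained) fits[[length(fits) + 1L]] <- fit
    if (length(fits) >= n) break
  }
  fits
}

# a balanced per-location ODR recording + behavior + delay-unit tuning for
# one trained network
analysis_set <- function(fit, seed, n_per_loc = 24) {
  key <- paste0("analysis_", fit$config$seed, "_", seed, "_", n_per_loc)
  cache_get(key, function() {
    set.seed(seed)
    batch <- location_batch(odr_registry()[[1]], n_per_loc)
    rec <- run_trials(fit$params, batch)
    beh <- score_trials(rec)
    sel <- select_delay_units(rec)
    units <- sel$unit[sel$selected]
    tun <- tuning_profile(rec, beh, units = units, window = "delay_last1")
    list(record = rec, behavior = beh, selection = sel, tuning = tun)
  })
}

# hand-built recording with prescribed per-trial epoch means: one row per
# unit, rates constant within fixation and within the delay
constant_record <- function(fix_means, delay_means,
                            cue_angles = rep(0, ncol(fix_means))) {
  n_units <- nrow(fix_means); B <- ncol(fix_means)
  nf <- 50L; nc <- 25L; nd <- 75L; nr <- 25L; T_ <- nf + nc + nd + nr
  rates <- array(0, c(n_units, B, T_))
  for (i in seq_len(B)) {
    rates[, i, 1:nf] <- fix_means[, i]
    rates[, i, (nf + 1):(nf + nc)] <- fix_means[, i]
    rates[, i, (nf + nc + 1):(nf + nc + nd)] <- delay_means[, i]
    rates[, i, (nf + nc + nd + 1):T_] <- delay_means[, i]
  }
  meta <- tibble::tibble(task_id = "odr", cue_angle = cue_angles,
                         distractor_angle = NA_real_, delay = 1.5,
                         target_dir = cue_angles, cue_on = nf + 1L,
                         cue_off = nf + nc, go = nf + nc + nd, t_end = T_,
                         trial = seq_len(B))
  structure(list(rates = rates, outputs = NULL, meta = meta, dt = 0.02,
                 seed = NA),
            class = "wm_record")
}
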