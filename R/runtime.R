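#' Default experiment configuration
#'
#' A single flat list merging task, network, training and analysis
#' settings. Any subset can be overridden via [load_config()] or the
#' `overrides` argument. The defaults describe a desk-scale run: one
#' 128-unit network trained on ODR with a fixed 1.5 s delay.
#'
#' @param overrides Named list of settings to override.
#' @return Config list.
#' @export
default_config <- function(overrides = list()) {
  cfg <- list(
    tasks = "odr", delay = 1.5, delay_mode = "fixed",
    n_ring = 8, kappa = 3.75,
    n_rec = 128, tau = 100, dt_ms = 20, sigma_rec = 0.05,
    eta = 0.001, batch_size = 64, max_steps = 3000, eval_every = 50,
    eval_trials = 24, stop_at = 95,
    n_networks = 1, seed = 1,
    analysis_trials_per_loc = 24, analysis_n_trials = 16,
    analysis_window = "delay_last1", alpha = 0.05,
    final_eval_trials = 500)
  stopifnot(is.list(overrides))
  modifyList(cfg, overrides)
}

#' Read an experiment configuration from YAML
#'
#' Unknown keys are rejected so typos in config files fail loudly.
#'
#' @param path YAML file.
#' @return Config list (defaults merged with the file's settings).
#' @export
load_config <- function(path) {
  user <- yaml::read_yaml(path)
  known <- names(default_config())
  bad <- setdiff(names(user), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  default_config(user)
}

# deterministic named substream seed below 2^31, derived from the master
# seed so adding analyses never perturbs training randomness
substream_seed <- function(master, name, k = 1L) {
  h <- sum(utf8ToInt(name) * (seq_along(utf8ToInt(name)) * 131)) + 7919 * k
  as.integer((as.numeric(master) * 48271 + h) %% 2147483647) + 1L
}

config_hash <- function(cfg) rlang::hash(cfg[order(names(cfg))])

#' Run a full experiment: train, evaluate, analyze, write artifacts
#'
#' Trains `n_networks` networks (seeds derived from the master seed via
#' named substreams), evaluates each at its final stage, scores behavior,
#' and runs the unit-level analyses (delay-unit selection, tuning,
#' rate-behavior correlation, Fano factor, correct-vs-error contrast,
#' weight structure) on a balanced per-location trial set. All tables are
#' written as CSV, checkpoints in R's native serialization, and a JSON
#' summary via [report()]. Re-running with the same config reproduces all
#' numeric outputs; every file name is accompanied by the config hash in
#' the summary.
#'
#' @param config Config list (see [default_config()]) or a YAML path.
#' @param out_dir Output directory (created if needed).
#' @param verbose Print progress.
#' @return The summary list from [report()], invisibly.
#' @export
run_experiment <- function(config = default_config(), out_dir,
                           verbose = FALSE) {
  if (is.character(config)) config <- load_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  marker <- file.path(out_dir, "INCOMPLETE")
  file.create(marker)
  ring <- ring_code(config$n_ring, kappa = config$kappa)
  registry <- default_task_registry(config$tasks, delay = config$delay)
  n_rules <- length(registry)

  records <- list(); rbc_cells <- list(); fano_cells <- list()
  cce_obs <- list(); behav <- list(); diag_stats <- numeric(0)

  for (net in seq_len(config$n_networks)) {
    seed_train <- substream_seed(config$seed, "train", net)
    set.seed(seed_train)
    params <- init_params(n_in = 1 + config$n_ring + n_rules,
                          n_rec = config$n_rec,
                          n_out = 1 + config$n_ring, tau = config$tau,
                          dt = config$dt_ms, sigma_rec = config$sigma_rec)
    fit <- train_network(params, registry, seed = seed_train,
                         eta = config$eta, batch_size = config$batch_size,
                         max_steps = config$max_steps,
                         eval_every = config$eval_every,
                         eval_trials = config$eval_trials,
                         delay_mode = config$delay_mode,
                         stop_at = config$stop_at, ring = ring,
                         verbose = verbose)
    save_checkpoint(fit, file.path(out_dir,
                                   sprintf("network_%02d.rds", net)))
    rec_tb <- fit$record; rec_tb$network <- net
    records[[net]] <- rec_tb

    # final evaluation on fresh trials
    ev <- evaluate_network(fit$params, registry,
                           n_per_task = config$final_eval_trials,
                           seed = substream_seed(config$seed, "eval", net),
                           ring = ring)
    b <- ev$behavior; b$network <- net
    behav[[net]] <- b

    # analysis recording: balanced per-location ODR trials
    an <- analyze_network(fit$params, registry, ring, config,
                          seed = substream_seed(config$seed, "analysis",
                                                net))
    if (!is.null(an$rbc)) {
      cells <- an$rbc$by_cell; cells$network <- net
      rbc_cells[[net]] <- cells
    }
    if (!is.null(an$fano)) {
      cells <- an$fano$by_cell; cells$network <- net
      fano_cells[[net]] <- cells
    }
    if (!is.null(an$cce)) {
      obs <- an$cce$obs; obs$network <- net
      cce_obs[[net]] <- obs
    }
    diag_stats <- c(diag_stats, an$weights$diagonality)
  }

  wr <- function(x, f) if (length(x))
    write.csv(dplyr::bind_rows(x), file.path(out_dir, f),
              row.names = FALSE)
  wr(records, "train_record.csv")
  wr(behav, "behavior.csv")
  wr(rbc_cells, "rbc_cells.csv")
  wr(fano_cells, "fano_cells.csv")
  wr(cce_obs, "cce_obs.csv")
  jsonlite::write_json(
    list(config = config, config_hash = config_hash(config),
         diagonality = diag_stats),
    file.path(out_dir, "config.json"), auto_unbox = TRUE, digits = NA)
  file.remove(marker)
  invisible(report(out_dir))
}

# run all unit-level analyses for one trained network
analyze_network <- function(params, registry, ring, config, seed) {
  set.seed(seed)
  spec <- registry[[which(vapply(registry, function(s) s$delay > 0,
                                 logical(1)))[1]]]
  batch <- location_batch(spec, config$analysis_trials_per_loc,
                          ring = ring, n_rules = length(registry))
  rec <- run_trials(params, batch)
  beh <- score_trials(rec)
  sel <- select_delay_units(rec, alpha = config$alpha)
  units <- sel$unit[sel$selected]
  out <- list(selection = sel, record = rec, behavior = beh, rbc = NULL,
              fano = NULL, cce = NULL, weights = NULL, tuning = NULL)
  if (length(units) == 0) return(out)
  tun <- tuning_profile(rec, beh, units = units,
                        window = config$analysis_window)
  out$tuning <- tun
  out$rbc <- tryCatch(
    rate_behavior_correlation(rec, beh, tun,
                              window = config$analysis_window),
    error = function(e) NULL)
  out$fano <- tryCatch(
    fano_factor(rec, beh, tun, window = config$analysis_window,
                n_trials = config$analysis_n_trials),
    error = function(e) NULL)
  out$cce <- tryCatch(compare_correct_error(rec, beh, tun,
                                            window = config$analysis_window),
                      error = function(e) NULL)
  tun_all <- tuning_profile(rec, beh, window = config$analysis_window)
  pref_all <- dplyr::distinct(tun_all, .data$unit, .data$preferred)
  out$weights <- weight_structure(params,
                                  pref_all$preferred[order(pref_all$unit)])
  out
}

#' Summarize an experiment directory as JSON
#'
#' Reads the tables written by [run_experiment()] and assembles a
#' schema-stable summary: training outcome per network, overall
#' performance and stage, pooled mean rate-behavior correlation, pooled
#' mean Fano factor, the pooled correct-vs-error contrast, and the weight
#' diagonality statistics. Missing tables are listed under `missing` and
#' flag the summary as incomplete.
#'
#' @param out_dir Directory written by [run_experiment()].
#' @param write Also write `summary.json` into the directory.
#' @return Summary list (with `complete` flag).
#' @export
report <- function(out_dir, write = TRUE) {
  need <- c("train_record.csv", "behavior.csv", "rbc_cells.csv",
            "fano_cells.csv", "cce_obs.csv", "config.json")
  missing <- need[!file.exists(file.path(out_dir, need))]
  if (file.exists(file.path(out_dir, "INCOMPLETE")))
    missing <- c(missing, "INCOMPLETE run")
  rd <- function(f) read.csv(file.path(out_dir, f))
  out <- list(complete = length(missing) == 0, missing = missing)
  if ("config.json" %in% setdiff(need, missing)) {
    cj <- jsonlite::read_json(file.path(out_dir, "config.json"))
    out$config_hash <- cj$config_hash
    out$diagonality <- unlist(cj$diagonality)
  }
  if (!"behavior.csv" %in% missing) {
    b <- rd("behavior.csv")
    out$percent_correct <- 100 * mean(b$correct)
    out$stage <- as.character(classify_stage(out$percent_correct))
  }
  if (!"train_record.csv" %in% missing) {
    tr <- rd("train_record.csv")
    out$n_updates <- vapply(split(tr$step, tr$network), max, numeric(1))
  }
  out$mean_r <- if (!"rbc_cells.csv" %in% missing) {
    cells <- rd("rbc_cells.csv")
    tt <- t.test(cells$r)
    out$rbc_p <- tt$p.value
    mean(cells$r)
  } else "unavailable"
  out$mean_fano <- if (!"fano_cells.csv" %in% missing)
    mean(rd("fano_cells.csv")$ff) else "unavailable"
  if (!"cce_obs.csv" %in% missing) {
    cce <- pool_correct_error(rd("cce_obs.csv"))
    out$correct_vs_error <- list(mean_correct = cce$mean_correct,
                                 mean_error = cce$mean_error, t = cce$t,
                                 df = cce$df, p = cce$p)
  } else out$correct_vs_error <- "unavailable"
  if (write)
    jsonlite::write_json(out, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
  out
}
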