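#' Score trials: decode endpoints and label correct/error
#'
#' For every trial in a recording, decodes the saccadic endpoint as the
#' population vector of the ring outputs averaged over the final
#' `window` seconds of the response epoch, checks fixation hold (the
#' fixation output must stay above 0.5 at every step while the fixation
#' input is on), and labels the trial correct iff fixation was held AND
#' the endpoint lies within `criterion` degrees (inclusive) of the
#' required response direction.
#'
#' @param record A `wm_record` from [run_trials()].
#' @param window Averaging window for the endpoint (s, default 0.2,
#'   taken at the end of the response epoch).
#' @param criterion Angular window for a correct response (deg,
#'   inclusive; default 36).
#' @param directions Preferred directions of the ring outputs (defaults to
#'   a uniform ring over the `n_out - 1` non-fixation outputs).
#' @return A behavior tibble, one row per trial: `trial`, `task_id`,
#'   `cue_angle`, `delay`, `target_dir`, `endpoint` (deg), `deviation`
#'   (signed, wrapped to (-180, 180], relative to the required direction),
#'   `fixation_hold`, `correct`.
#' @export
score_trials <- function(record, window = 0.2, criterion = 36,
                         directions = NULL) {
  stopifnot(inherits(record, "wm_record"))
  meta <- record$meta
  n_out <- dim(record$outputs)[1]
  if (is.null(directions))
    directions <- seq(0, 360 - 360 / (n_out - 1), by = 360 / (n_out - 1))
  w_steps <- max(1L, as.integer(round(window / record$dt)))

  score1 <- function(i) {
    go <- meta$go[i]; t_end <- meta$t_end[i]
    if (t_end <= go) stop("trial ", i, " has no response epoch")
    hold <- all(record$outputs[1, i, seq_len(go)] > 0.5)
    w <- max(go + 1L, t_end - w_steps + 1L):t_end
    zz <- record$outputs[-1, i, w, drop = FALSE]
    z <- rowMeans(matrix(zz, nrow = dim(zz)[1]))
    endpoint <- suppressWarnings(population_vector(z, directions))
    dev <- if (is.na(endpoint)) NA_real_
           else angular_diff(endpoint, meta$target_dir[i])
    correct <- isTRUE(hold && !is.na(dev) && abs(dev) <= criterion)
    tibble::tibble(endpoint = endpoint, deviation = dev,
                   fixation_hold = hold, correct = correct)
  }
  scored <- dplyr::bind_rows(lapply(seq_len(nrow(meta)), score1))
  dplyr::bind_cols(
    meta[, c("trial", "task_id", "cue_angle", "delay", "target_dir")],
    scored)
}

#' Histogram of saccadic-endpoint deviations
#'
#' Bins the signed deviations of decoded endpoints from the required
#' response direction, for correct trials, error trials, or all trials —
#' the endpoint distributions whose tightening tracks training progress.
#'
#' @param behavior A behavior tibble from [score_trials()].
#' @param split `"all"`, `"correct"` or `"error"`.
#' @param binwidth Bin width in degrees (default 9; bins span +/-180).
#' @param stage Optional stage label attached to the output.
#' @return Tibble with `bin_mid` (deg), `count`, `prop`, `split`, `stage`.
#'   Total count equals the number of trials in the split; an empty split
#'   warns and returns an all-zero histogram.
#' @export
endpoint_distribution <- function(behavior, split = c("all", "correct",
                                  "error"), binwidth = 9, stage = NA) {
  split <- match.arg(split)
  dev <- switch(split,
                all = behavior$deviation,
                correct = behavior$deviation[behavior$correct],
                error = behavior$deviation[!behavior$correct])
  dev <- dev[!is.na(dev)]
  if (length(dev) == 0)
    warning("no trials in split '", split, "'")
  # bins centered on 0, +/-binwidth, ...; the two half-covered end bins
  # together span the +/-180 boundary
  breaks <- seq(-180 - binwidth / 2, 180 + binwidth / 2, by = binwidth)
  cnt <- as.integer(table(cut(dev, breaks = breaks, right = TRUE,
                              include.lowest = TRUE)))
  tibble::tibble(bin_mid = breaks[-1] - binwidth / 2, count = cnt,
                 prop = if (length(dev)) cnt / length(dev) else 0,
                 split = split, stage = stage)
}

#' Plot endpoint-deviation distributions
#'
#' @param behavior A behavior tibble, or a list of them named by stage.
#' @param binwidth Bin width (deg).
#' @return A ggplot: deviation histograms for correct and error trials,
#'   faceted by stage when several tables are given.
#' @export
plot_endpoint_distribution <- function(behavior, binwidth = 9) {
  tables <- if (is.data.frame(behavior)) list(behavior = behavior)
            else behavior
  h <- purrr::imap(tables, function(tb, nm) {
    dplyr::bind_rows(endpoint_distribution(tb, "correct", binwidth, nm),
                     endpoint_distribution(tb, "error", binwidth, nm))
  })
  h <- dplyr::bind_rows(h)
  ggplot2::ggplot(h, ggplot2::aes(x = .data$bin_mid, y = .data$count,
                                  fill = .data$split)) +
    ggplot2::geom_col(position = "identity", alpha = 0.6) +
    ggplot2::facet_wrap(~stage) +
    ggplot2::geom_vline(xintercept = c(-36, 36), linetype = 2) +
    ggplot2::labs(x = "endpoint deviation from target (deg)",
                  y = "trials", fill = NULL)
}
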