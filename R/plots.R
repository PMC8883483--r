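#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the rotated rate-behavior correlation curve
#'
#' @param object A `wm_rbc`.
#' @param ... Unused.
#' @return A ggplot of mean Pearson r against rotated cue location; the
#'   drifting-bump signature is an "M" shape with positive flanks.
#' @export
autoplot.wm_rbc <- function(object, ...) {
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(x = .data$offset, y = .data$mean_r)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "cue location relative to preferred (deg)",
                  y = "mean Pearson r (rate vs saccade deviation)")
}

#' Plot the rotated Fano-factor curve
#'
#' @param object A `wm_fano`.
#' @param ... Unused.
#' @return A ggplot of mean Fano factor against rotated cue location.
#' @export
autoplot.wm_fano <- function(object, ...) {
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(x = .data$offset, y = .data$mean_ff)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "cue location relative to preferred (deg)",
                  y = "mean Fano factor")
}

#' Plot the rotated population tuning curve
#'
#' @param tuning A `wm_tuning` from [tuning_profile()].
#' @return A ggplot of the mean rotated tuning curve (preferred location
#'   at offset 0) with per-unit curves underlaid.
#' @export
plot_tuning <- function(tuning) {
  avg <- dplyr::summarise(dplyr::group_by(tuning, .data$offset),
                          rate = mean(.data$rate, na.rm = TRUE),
                          .groups = "drop")
  ggplot2::ggplot(tuning, ggplot2::aes(x = .data$offset, y = .data$rate)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$unit), alpha = 0.15) +
    ggplot2::geom_line(data = avg, linewidth = 1.2, colour = "firebrick") +
    ggplot2::labs(x = "cue location relative to preferred (deg)",
                  y = "delay-period rate")
}

#' Plot a sorted population heatmap
#'
#' @param mat A matrix from [heatmap_matrix()].
#' @param dt Timestep (s) for the time axis.
#' @param cue_on Cue-onset step (time 0).
#' @return A ggplot raster: units (sorted by preferred location) x time,
#'   rate normalized per row.
#' @export
plot_heatmap <- function(mat, dt = 0.02, cue_on = 51) {
  df <- tidyr::expand_grid(row = seq_len(nrow(mat)),
                           col = seq_len(ncol(mat)))
  df$value <- mat[cbind(df$row, df$col)]
  df$time <- (df$col - cue_on) * dt
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "normalized rate") +
    ggplot2::labs(x = "time from cue onset (s)",
                  y = "unit (sorted by preferred location)")
}
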