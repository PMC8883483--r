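#' Signed circular difference between two angles
#'
#' Computes `a - b` wrapped to the half-open interval (-180, 180], the
#' angular convention used throughout the package (degrees, 0 at the
#' positive x-axis, counterclockwise). A result of -20 for
#' `angular_diff(350, 10)` means 10 deg lies 20 deg counterclockwise of
#' 350 deg; the boundary case returns +180, never -180.
#'
#' @param a,b Angles in degrees (vectors recycle).
#' @return Signed difference in degrees, in (-180, 180].
#' @examples
#' angular_diff(350, 10)  # -20
#' angular_diff(180, 0)   # 180
#' @export
angular_diff <- function(a, b) {
  d <- (a - b) %% 360
  ifelse(d > 180, d - 360, d)
}

#' Wrap angles to [0, 360)
#' @param a Angles in degrees.
#' @return Angles reduced modulo 360.
#' @export
wrap_angle <- function(a) {
  out <- a %% 360
  # tiny negative inputs land exactly on 360 in floating point
  ifelse(out >= 360, 0, out)
}

deg2rad <- function(a) a * pi / 180
rad2deg <- function(a) a * 180 / pi
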