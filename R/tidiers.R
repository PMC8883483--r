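#' Turn a wmrnn result into a tidy tibble
#'
#' Broom-style generics: `tidy()` returns the per-observation table inside
#' a result object (per-evaluation training record, per-unit-per-location
#' statistics, ...), `glance()` a one-row summary.
#'
#' @param x A result object (`wm_fit`, `wm_rbc`, `wm_fano`, ...).
#' @param ... Passed to methods.
#' @return A tibble.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname tidy
#' @export
glance <- function(x, ...) UseMethod("glance")
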