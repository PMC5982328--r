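#' Partition a stance-phase series into gait sub-phases
#'
#' Gait sub-phases are conventionally given as percentages of the whole
#' gait cycle: loading response 0--10 %, mid stance 10--30 %, terminal
#' stance 30--50 %, pre-swing 50--60 %.  The force plate records the
#' stance only, which occupies ~60 % of the cycle, so on the stance the
#' four windows are the fractions \[0, 1/6), \[1/6, 1/2), \[1/2, 5/6),
#' \[5/6, 1\].  Boundaries are placed at `round(fraction * n)` with
#' half-away-from-zero rounding; windows are 0-based and half-open, and
#' tile `[0, n)` exactly.
#'
#' @param n Number of stance samples (>= 12, at least two per sub-phase).
#' @param sampling_rate_hz Optional rate, carried through for reporting.
#' @return A data frame with columns `phase` (`LR`, `MSt`, `TSt`,
#'   `PSw`), `start`, `end` (0-based, half-open sample indices).
#' @examples
#' segment_stance(960)  # LR [0,160) MSt [160,480) TSt [480,800) PSw [800,960)
#' @export
segment_stance <- function(n, sampling_rate_hz = NULL) {
  n <- as.integer(n)
  if (is.na(n) || n < 12L)
    stop("segment_stance: need at least 12 stance samples, got ", n)
  # round half away from zero (base round() rounds half to even)
  rhz <- function(x) floor(x + 0.5)
  b <- c(0L, rhz(n / 6), rhz(n / 2), rhz(5 * n / 6), n)
  data.frame(phase = c("LR", "MSt", "TSt", "PSw"),
             start = as.integer(b[1:4]), end = as.integer(b[2:5]))
}

#' Extract one sub-phase window from a GRF series
#'
#' @param series A `grf_series` (see [grf_component()]) or a plain
#'   numeric vector.
#' @param window One row of the [segment_stance()] table (or any list
#'   with `start` and `end` 0-based half-open indices).
#' @return The contiguous sub-series, same type as the input; length
#'   `end - start`.
#' @export
extract_phase <- function(series, window) {
  x <- if (inherits(series, "grf_series")) series$samples else series
  start <- window$start
  end <- window$end
  if (length(start) != 1L || length(end) != 1L || start < 0 || end > length(x) ||
      start >= end)
    stop("extract_phase: invalid window [", start, ", ", end, ") for series of length ",
         length(x))
  out <- x[(start + 1L):end]
  if (inherits(series, "grf_series")) {
    series$samples <- out
    series
  } else out
}

# Phase window lookup used internally by the distance code.
phase_window <- function(n, phase) {
  seg <- segment_stance(n)
  seg[seg$phase == phase, , drop = FALSE]
}
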