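#' Restrict a curve to the scan window
#'
#' Keeps the sub-signal between the first and the last beam-on sample,
#' inclusive, so that all irregularity statistics refer to breathing during
#' scan time only.  Amplitude values are untouched; only the time support
#' changes.
#'
#' @param signal a [breathing_signal()] with at least one true beam-on flag.
#' @return the windowed [breathing_signal()].
#' @export
window_to_beam_on <- function(signal) {
  b4_assert(!is.null(signal$beam_on), "missing_channel",
            "signal carries no beam_on channel")
  on_idx <- which(signal$beam_on)
  b4_assert(length(on_idx) > 0, "empty_window",
            "no beam-on samples: window is empty")
  keep <- seq(min(on_idx), max(on_idx))
  out <- breathing_signal(signal$times[keep], signal$amplitudes[keep],
                          signal$beam_on[keep], curve_id = signal$curve_id)
  attr(out, "window_s") <- c(signal$times[min(on_idx)], signal$times[max(on_idx)])
  out
}

#' Remove linear baseline drift
#'
#' Subtracts the ordinary-least-squares line of amplitude versus time, the
#' simplest reading of linear drift correction.  The corrected trace has a
#' zero-slope best-fit line.
#'
#' @param signal a [breathing_signal()] with at least two samples.
#' @return the drift-corrected [breathing_signal()]; the removed slope
#'   (a.u./s) is recorded in attribute `drift_slope`.
#' @export
remove_linear_drift <- function(signal) {
  t <- signal$times; a <- signal$amplitudes
  b4_assert(length(t) >= 2, "degenerate_fit", "need at least two samples")
  vt <- stats::var(t)
  b4_assert(vt > 0, "degenerate_fit", "constant time vector")
  slope <- stats::cov(t, a) / vt
  intercept <- mean(a) - slope * mean(t)
  out <- signal
  out$amplitudes <- a - (intercept + slope * t)
  attr(out, "window_s") <- attr(signal, "window_s")
  attr(out, "drift_slope") <- slope
  out
}

#' Normalize a breathing curve to unit range
#'
#' Affine rescale so that the minimum amplitude maps to 0 and the maximum
#' to 1.  On the unit-range scale the per-cycle peak-to-peak amplitude SD
#' is a dimensionless fraction of the total breathing excursion, comparable
#' across patients and cohorts.
#'
#' @param signal a [breathing_signal()] with non-constant amplitudes,
#'   normally already windowed and drift-corrected.
#' @return a `preprocessed_signal` (also a `breathing_signal`) whose
#'   `provenance` field records the window applied, the drift slope removed
#'   and the normalization `scale` (original range) and `offset` (original
#'   minimum).
#' @export
normalize_curve <- function(signal) {
  a <- signal$amplitudes
  rng <- range(a)
  b4_assert(diff(rng) > 0, "zero_range", "constant signal cannot be normalized")
  out <- signal
  out$amplitudes <- (a - rng[1]) / diff(rng)
  out$provenance <- list(
    window_s = attr(signal, "window_s"),
    drift_slope = attr(signal, "drift_slope") %||% 0,
    scale = diff(rng), offset = rng[1])
  class(out) <- c("preprocessed_signal", class(signal))
  out
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Full preprocessing pipeline
#'
#' Window to the beam-on period (skipped when the signal carries no beam-on
#' channel), remove linear drift, then normalize to unit range, in that
#' fixed order: the drift is estimated on scan-time data only, and the
#' normalization makes all downstream metrics invariant under positive
#' affine transforms of the raw amplitudes.
#'
#' @param signal a [breathing_signal()].
#' @return a `preprocessed_signal` with populated provenance.
#' @export
preprocess_signal <- function(signal) {
  if (!is.null(signal$beam_on) && any(signal$beam_on))
    signal <- window_to_beam_on(signal)
  normalize_curve(remove_linear_drift(signal))
}
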