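# Centered moving average with edge-shrinking window; window_s = 0 is the
# identity.  Linear, so all downstream metrics remain invariant under
# positive affine transforms of the amplitudes.
.smoothed_amplitudes <- function(signal, window_s) {
  a <- signal$amplitudes
  if (window_s <= 0) return(a)
  k <- floor(window_s * signal$sample_rate / 2)
  if (k < 1) return(a)
  n <- length(a)
  cs <- cumsum(c(0, a))
  lo <- pmax(seq_len(n) - k, 1L)
  hi <- pmin(seq_len(n) + k, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Detect end-inhalation peaks
#'
#' Finds strict local maxima of the amplitude trace, keeps those whose
#' topographic prominence reaches `min_prominence`, and thins the result so
#' that consecutive peaks are at least `min_separation_s` apart (on a
#' conflict the higher peak wins; on equal height the earlier one).  With
#' the inhale-positive amplitude convention these maxima are the
#' end-inspiration ("inhalation") points that delimit breathing cycles.
#'
#' The defaults (prominence 0.2 of the unit range, separation 1 s) reject
#' cardiac ripple and measurement noise while admitting breathing rates up
#' to about 60 breaths per minute.  Detection runs on a lightly smoothed
#' copy of the trace (centered moving average over `smooth_window_s`,
#' default 0.2 s, far below any breathing period) to suppress
#' sample-level measurement noise; `smooth_window_s = 0` disables it.
#'
#' @param signal a normalized [breathing_signal()] (see
#'   [preprocess_signal()]).
#' @param min_prominence minimum topographic prominence, as a fraction of
#'   the unit range; in `(0, 1)`.
#' @param min_separation_s minimum time between reported peaks, seconds.
#' @param smooth_window_s width of the noise-suppression moving average,
#'   seconds.
#' @return numeric vector of peak times (seconds), increasing.
#' @export
detect_inhalation_peaks <- function(signal, min_prominence = 0.2,
                                    min_separation_s = 1.0,
                                    smooth_window_s = 0.2) {
  b4_assert(min_prominence > 0 && min_prominence < 1, "malformed_input",
            "min_prominence must lie in (0, 1)")
  b4_assert(min_separation_s > 0, "malformed_input",
            "min_separation_s must be positive")
  a <- .smoothed_amplitudes(signal, smooth_window_s)
  n <- length(a)
  cand <- which(a[-c(1, 2)] < a[-c(1, n)] & a[-c(n - 1, n)] < a[-c(1, n)]) + 1L
  if (length(cand) > 0) {
    prom <- vapply(cand, function(i) .prominence(a, i), numeric(1))
    cand <- cand[prom >= min_prominence]
  }
  if (length(cand) < 2)
    b4_stop("insufficient_cycles",
            "fewer than two inhalation peaks found; curve is unanalyzable")
  # thin by separation: visit by height (desc), earlier first on ties
  ord <- cand[order(-a[cand], signal$times[cand])]
  kept <- numeric(0)
  for (i in ord) {
    ti <- signal$times[i]
    if (all(abs(kept - ti) >= min_separation_s)) kept <- c(kept, ti)
  }
  kept <- sort(kept)
  if (length(kept) < 2)
    b4_stop("insufficient_cycles",
            "fewer than two inhalation peaks found; curve is unanalyzable")
  kept
}

# Topographic prominence of a local maximum: height above the higher of
# the two key saddles, found by walking outward to the nearest sample that
# exceeds the peak (or to the trace edge).
.prominence <- function(a, i) {
  n <- length(a)
  left_min <- a[i]
  j <- i - 1L
  while (j >= 1L && a[j] <= a[i]) {
    if (a[j] < left_min) left_min <- a[j]
    j <- j - 1L
  }
  right_min <- a[i]
  j <- i + 1L
  while (j <= n && a[j] <= a[i]) {
    if (a[j] < right_min) right_min <- a[j]
    j <- j + 1L
  }
  a[i] - max(left_min, right_min)
}

#' Segment breathing cycles between successive peaks
#'
#' Cycles are the half-open peak-to-peak intervals.  For each cycle the
#' peak-to-peak amplitude is the cycle's own inhale-exhale excursion: the
#' amplitude at its starting end-inspiration peak minus the minimum
#' (end-expiration trough) of the samples inside the interval.  Measuring
#' the excursion from the cycle's own peak, rather than as max minus min
#' over the interval, keeps a neighbouring larger cycle from inflating the
#' estimate as the trace ascends towards the next peak at the interval
#' end.  The average breathing cycle length is estimated by
#' the median of the inter-peak durations: the median is robust against
#' the very pauses that the pause rule must later detect, which would
#' inflate an arithmetic mean.
#'
#' @param signal a [breathing_signal()] (normally preprocessed).
#' @param peaks increasing numeric vector of at least two peak times, as
#'   returned by [detect_inhalation_peaks()].
#' @param smooth_window_s width of the noise-suppression moving average
#'   applied before measuring peak-to-peak amplitudes, seconds (same
#'   default as in [detect_inhalation_peaks()]; 0 disables).
#' @return an object of class `cycle_segmentation` with fields
#'   `peak_times_s`, `cycle_intervals` (data frame of half-open intervals),
#'   `cycle_p2p_amplitudes`, `inter_peak_durations_s`, `mean_cycle_s`
#'   (median inter-peak duration) and `n_cycles`.
#' @export
segment_cycles <- function(signal, peaks, smooth_window_s = 0.2) {
  b4_assert(length(peaks) >= 2, "insufficient_cycles",
            "need at least two peaks to segment cycles")
  b4_assert(!is.unsorted(peaks, strictly = TRUE), "malformed_input",
            "peak times must be strictly increasing")
  k <- length(peaks) - 1L
  a <- .smoothed_amplitudes(signal, smooth_window_s)
  # times are sorted: locate each cycle's sample range once
  lo <- findInterval(peaks, signal$times, left.open = TRUE) + 1L
  p2p <- vapply(seq_len(k), function(i) {
    sel <- seq.int(lo[i], lo[i + 1] - 1L)
    a[lo[i]] - min(a[sel])
  }, numeric(1))
  gaps <- diff(peaks)
  structure(list(
    peak_times_s = peaks,
    cycle_intervals = data.frame(start_s = peaks[seq_len(k)],
                                 end_s = peaks[-1]),
    cycle_p2p_amplitudes = p2p,
    inter_peak_durations_s = gaps,
    mean_cycle_s = stats::median(gaps),
    n_cycles = k), class = "cycle_segmentation")
}

#' @export
print.cycle_segmentation <- function(x, ...) {
  cat(sprintf("<cycle_segmentation: %d cycles, median cycle %.2f s, p2p SD %.3f>\n",
              x$n_cycles, x$mean_cycle_s,
              if (x$n_cycles >= 2) stats::sd(x$cycle_p2p_amplitudes) else NA))
  invisible(x)
}

#' Assign breathing-phase bins to samples
#'
#' Time-fraction (phase-based) binning between successive end-inhalation
#' peaks, as used for retrospective 4D CT reconstruction with (usually ten)
#' pre-defined breathing phases: a sample at time `t` inside cycle
#' `[p_i, p_{i+1})` has phase fraction `f = (t - p_i) / (p_{i+1} - p_i)`
#' and bin `floor(f * n_phases)`.  Samples before the first or at/after the
#' last peak are unassigned (`NA`).
#'
#' @param signal a [breathing_signal()].
#' @param seg a [segment_cycles()] result.
#' @param n_phases number of phase bins (default 10).
#' @return an object of class `phase_assignment`: list with `bins`
#'   (integer vector, 0-based, `NA` outside cycles), `fraction` (phase
#'   fraction `f` in `[0, 1)`, `NA` outside), `cycle_index` (1-based cycle
#'   of each sample, `NA` outside) and `n_phases`.
#' @export
assign_phase <- function(signal, seg, n_phases = 10L) {
  b4_assert(n_phases >= 2, "malformed_input", "n_phases must be at least 2")
  peaks <- seg$peak_times_s
  t <- signal$times
  ci <- findInterval(t, peaks)
  ci[ci < 1L | ci > seg$n_cycles] <- NA_integer_
  f <- (t - peaks[ci]) / (peaks[ci + 1L] - peaks[ci])
  bins <- pmin(as.integer(floor(f * n_phases)), n_phases - 1L)
  structure(list(bins = bins, fraction = f, cycle_index = ci,
                 n_phases = as.integer(n_phases)),
            class = "phase_assignment")
}

#' Export a cycle segmentation to JSON
#'
#' @param seg a [segment_cycles()] result.
#' @param path optional file path; when `NULL` the JSON string is returned.
#' @return the JSON string, invisibly when written to file.
#' @export
segmentation_json <- function(seg, path = NULL) {
  js <- jsonlite::toJSON(list(
    peak_times_s = seg$peak_times_s,
    cycle_p2p_amplitudes = seg$cycle_p2p_amplitudes,
    inter_peak_durations_s = seg$inter_peak_durations_s,
    mean_cycle_s = seg$mean_cycle_s,
    n_cycles = seg$n_cycles), digits = NA, auto_unbox = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
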