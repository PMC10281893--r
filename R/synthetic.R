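#' Specification of a synthetic breathing signal
#'
#' Parameters of the quasi-periodic generator used for testing and
#' simulation studies.  Each breathing cycle is a raised cosine-power pulse
#' (`cos^(2 * shape_exponent)`), the standard surrogate for respiratory
#' motion: an even power gives one sharp end-inhalation peak per cycle and
#' a realistic dwell near the end-exhale baseline.  Cycle periods and
#' amplitudes are drawn from truncated normal distributions so the stated
#' means/SDs hold approximately while degenerate cycles are impossible.
#' Breathing pauses are end-exhale baseline holds inserted mid-cycle.
#'
#' @param duration_s total active breathing time in seconds (pauses are
#'   added on top); must cover at least one mean period.
#' @param sample_rate sampling rate in Hz (default 25, a typical surrogate
#'   camera rate; configurable because vendor exports differ).
#' @param period_mean_s,period_sd_s mean and SD of the cycle period in
#'   seconds; periods are truncated below at `0.5 * period_mean_s`.
#' @param amp_mean,amp_sd mean and SD of the per-cycle peak amplitude
#'   (arbitrary units); amplitudes are truncated below at zero.
#' @param shape_exponent positive integer; the cycle profile is
#'   `cos^(2 * shape_exponent)`.
#' @param pauses list of `c(after_cycle, duration_s)` pairs: a breathing
#'   pause of the given duration is inserted at the end-exhale point of the
#'   given cycle.
#' @param drift_slope linear baseline drift in amplitude units per second.
#' @param noise_sd SD of additive white Gaussian measurement noise.
#' @param seed integer seed; the same seed reproduces the signal exactly.
#' @return a list with class `synthetic_spec`.
#' @export
synthetic_spec <- function(duration_s = 120, sample_rate = 25,
                           period_mean_s = 4, period_sd_s = 0,
                           amp_mean = 1, amp_sd = 0,
                           shape_exponent = 2L, pauses = list(),
                           drift_slope = 0, noise_sd = 0, seed = 1L) {
  b4_assert(period_mean_s > 0 && amp_mean > 0, "degenerate_spec",
            "period_mean_s and amp_mean must be positive")
  b4_assert(period_sd_s >= 0 && amp_sd >= 0 && noise_sd >= 0,
            "degenerate_spec", "sd parameters must be non-negative")
  b4_assert(shape_exponent >= 1, "degenerate_spec",
            "shape_exponent must be a positive integer")
  for (p in pauses)
    b4_assert(length(p) == 2 && p[2] > 0, "degenerate_spec",
              "each pause is c(after_cycle, duration_s) with duration > 0")
  structure(list(duration_s = duration_s, sample_rate = sample_rate,
                 period_mean_s = period_mean_s, period_sd_s = period_sd_s,
                 amp_mean = amp_mean, amp_sd = amp_sd,
                 shape_exponent = as.integer(shape_exponent),
                 pauses = pauses, drift_slope = drift_slope,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Evaluate `code` under a private RNG stream, restoring the caller's
# stream afterwards (lazy evaluation: `code` runs after set.seed).
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

.rnorm_trunc <- function(mean, sd, lower) {
  if (sd == 0) return(max(mean, lower))
  repeat {
    x <- stats::rnorm(1, mean, sd)
    if (x >= lower) return(x)
  }
}

#' Generate a synthetic breathing signal with ground truth
#'
#' Draws cycle periods and amplitudes, concatenates cosine-power cycles
#' (one end-inhalation peak each), inserts the requested end-exhale pauses,
#' then adds linear drift and white noise.  Fully deterministic for a fixed
#' seed.  The returned ground truth records the true peak times, cycle
#' intervals and amplitudes, pause intervals, and summary statistics, so
#' downstream detectors can be scored against it.
#'
#' The last cycle is trimmed so that the total active breathing time
#' equals `duration_s` (when the remainder would be shorter than half a
#' mean period the partial cycle is dropped instead, leaving the active
#' time short by at most half a mean period).  A half-cycle ascent from
#' baseline precedes the first peak and a half-cycle descent follows the
#' last, so every true peak is an interior local maximum of the trace.
#'
#' @param spec a [synthetic_spec()].
#' @return a list with elements `signal` (a [breathing_signal()]) and
#'   `truth` (class `ground_truth`): `peak_times_s`, `cycle_intervals`
#'   (data frame, half-open peak-to-peak), `cycle_amplitudes`,
#'   `pause_intervals` (data frame), `periods_s` (drawn periods),
#'   `true_amp_sd` (sample SD of the cycle amplitudes) and
#'   `true_mean_period_s`.
#' @export
generate_signal <- function(spec) {
  b4_assert(inherits(spec, "synthetic_spec"), "degenerate_spec",
            "spec must be a synthetic_spec")
  b4_assert(spec$duration_s >= spec$period_mean_s, "degenerate_spec",
            "duration_s must cover at least one mean breathing period")
  with_seed(spec$seed, .generate_signal_impl(spec))
}

.generate_signal_impl <- function(spec) {
  min_period <- 0.5 * spec$period_mean_s
  tau <- numeric(0); amp <- numeric(0)
  while (sum(tau) < spec$duration_s) {
    tau <- c(tau, .rnorm_trunc(spec$period_mean_s, spec$period_sd_s, min_period))
    amp <- c(amp, .rnorm_trunc(spec$amp_mean, spec$amp_sd, 0))
  }
  n <- length(tau)
  excess <- sum(tau) - spec$duration_s
  if (tau[n] - excess >= min_period) {
    tau[n] <- tau[n] - excess
  } else if (n > 1) {
    # dropping the partial last cycle keeps every generated period inside
    # the truncated-normal support; extending a neighbour instead would
    # fabricate a long gap that mimics a breathing pause
    tau <- tau[-n]; amp <- amp[-n]; n <- n - 1
  }

  pause_after <- rep(0, n)
  for (p in spec$pauses) {
    j <- as.integer(p[1])
    b4_assert(j >= 1 && j <= n, "degenerate_spec",
              sprintf("pause after cycle %d, but only %d cycles generated", j, n))
    pause_after[j] <- pause_after[j] + p[2]
  }

  # Half-cycle lead-in and lead-out (ascent from baseline to the first
  # peak, descent to baseline after the last) so every true peak is an
  # interior local maximum of the trace.
  offset <- tau[1] / 2
  peaks <- offset + cumsum(c(0, tau + pause_after)) # n + 1 peak times
  half <- peaks[seq_len(n)] + tau / 2               # end-exhale points
  pause_start <- half[pause_after > 0]
  pause_dur <- pause_after[pause_after > 0]

  dt <- 1 / spec$sample_rate
  t_end <- peaks[n + 1] + tau[n] / 2
  times <- seq(0, by = dt, length.out = floor(t_end / dt + 1e-9) + 1)

  # Piecewise evaluation: each cycle i contributes up to three pieces
  # (descent, optional pause hold, ascent); findInterval maps samples to
  # pieces in one vectorized pass.
  starts <- as.vector(rbind(peaks[seq_len(n)], half, half + pause_after))
  piece_cycle <- rep(seq_len(n), each = 3)
  piece_kind <- rep(c(1L, 2L, 3L), n)              # 1 descent, 2 pause, 3 ascent
  idx <- findInterval(times, starts, rightmost.closed = FALSE)
  idx[idx < 1] <- 1L
  idx[idx > length(starts)] <- length(starts)
  ci <- piece_cycle[idx]; kind <- piece_kind[idx]
  # The descent half of cycle i has amplitude a_i; the ascent half blends
  # to a_{i+1} so the trace is continuous and each end-inhalation peak i
  # reaches exactly a_i.  The per-cycle excursion (peak minus following
  # trough) therefore equals a_i.
  asc <- c(amp[-1], amp[n])
  piece_amp <- ifelse(kind == 3, asc[ci], amp[ci])
  u <- ifelse(kind == 3, times - peaks[ci] - pause_after[ci], times - peaks[ci])
  base <- piece_amp * cos(pi * u / tau[ci])^(2 * spec$shape_exponent)
  base[kind == 2] <- 0
  values <- base + spec$drift_slope * times
  if (spec$noise_sd > 0)
    values <- values + stats::rnorm(length(times), 0, spec$noise_sd)

  truth <- structure(list(
    peak_times_s = peaks,
    cycle_intervals = data.frame(start_s = peaks[seq_len(n)],
                                 end_s = peaks[-1]),
    cycle_amplitudes = amp,
    pause_intervals = data.frame(start_s = pause_start,
                                 end_s = pause_start + pause_dur),
    periods_s = tau,
    true_amp_sd = if (n >= 2) stats::sd(amp) else 0,
    true_mean_period_s = mean(tau)), class = "ground_truth")

  list(signal = breathing_signal(times, values,
                                 curve_id = sprintf("synth-%d", spec$seed)),
       truth = truth)
}

#' Stamp beam-on intervals onto a signal as per-sample flags
#'
#' @param signal a [breathing_signal()].
#' @param intervals a [beam_on_intervals()] object; every interval must lie
#'   within the signal's time range (`[t_first, t_last + dt)`).
#' @return the signal with `beam_on` true exactly for samples whose time
#'   falls inside an interval.
#' @export
attach_beam_on <- function(signal, intervals) {
  b4_assert(inherits(signal, "breathing_signal"), "malformed_input",
            "signal must be a breathing_signal")
  n <- length(signal$times)
  dt <- sample_period(signal)
  if (nrow(intervals) == 0) {
    signal$beam_on <- rep(FALSE, n)
    return(signal)
  }
  eps <- 1e-9
  b4_assert(all(intervals$start_s >= signal$times[1] - eps) &&
              all(intervals$end_s <= signal$times[n] + dt + eps),
            "range_error", "beam-on interval outside the signal time range")
  bounds <- as.vector(rbind(intervals$start_s, intervals$end_s))
  idx <- findInterval(signal$times, bounds)
  signal$beam_on <- idx %% 2L == 1L
  signal
}
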