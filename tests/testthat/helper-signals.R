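# Small signal constructors used across the suite.

# Uniformly sampled signal from an amplitude function of time.
signal_from_fn <- function(fn, duration_s = 20, rate = 25, beam_on = NULL,
                           curve_id = "fn") {
  t <- seq(0, duration_s, by = 1 / rate)
  breathing_signal(t, fn(t), beam_on = beam_on, curve_id = curve_id)
}

# Plain sine breathing surrogate (period T, unit amplitude).
sine_signal <- function(n_periods = 5, T = 4, rate = 25) {
  signal_from_fn(function(t) sin(2 * pi * t / T),
                 duration_s = n_periods * T, rate = rate, curve_id = "sine")
}

# Hand-built cycle segmentation (for pause-rule unit tests).
fake_segmentation <- function(gaps, p2p = NULL) {
  peaks <- cumsum(c(0, gaps))
  k <- length(gaps)
  structure(list(
    peak_times_s = peaks,
    cycle_intervals = data.frame(start_s = peaks[seq_len(k)], end_s = peaks[-1]),
    cycle_p2p_amplitudes = p2p %||% rep(1, k),
    inter_peak_durations_s = gaps,
    mean_cycle_s = stats::median(gaps),
    n_cycles = k), class = "cycle_segmentation")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Minimal irregularity_metrics stub.
fake_metrics <- function(id, amp_sd, pause = 0) {
  structure(list(curve_id = id, amp_p2p_sd = amp_sd,
                 pauses = data.frame(start_s = numeric(0),
                                     duration_s = numeric(0)),
                 longest_pause_s = pause, mean_cycle_s = 4, n_cycles = 30),
            class = "irregularity_metrics")
}

# Full analysis chain on a generated curve.
analyze_generated <- function(gen, ...) {
  pp <- preprocess_signal(gen$signal)
  peaks <- detect_inhalation_peaks(pp, ...)
  seg <- segment_cycles(pp, peaks)
  list(pp = pp, peaks = peaks, seg = seg)
}
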