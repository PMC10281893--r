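#' Scan protocol configuration: conventional spiral 4D CT
#'
#' Defaults mirror a clinical low-pitch spiral 4D CT protocol
#' (0.5 s gantry rotation, pitch 0.09, 16 x 1.2 mm collimation).  At pitch
#' `p` each slice position is illuminated for `rotation_time_s / p`
#' seconds; with the defaults about 5.6 s, which is why slow breathers and
#' breathing pauses defeat the fixed-pitch protocol.
#'
#' @param rotation_time_s gantry rotation time, seconds.
#' @param pitch spiral pitch factor, in `(0, 2)`.
#' @param n_rows,row_width_mm detector collimation: number of rows and row
#'   width.
#' @param fov_length_mm longitudinal field-of-view length.
#' @param n_phases number of breathing-phase bins (default 10).
#' @return a list of class `scan_config` with `mode = "spiral"`.
#' @export
spiral_scan_config <- function(rotation_time_s = 0.5, pitch = 0.09,
                               n_rows = 16L, row_width_mm = 1.2,
                               fov_length_mm = 200, n_phases = 10L) {
  b4_assert(rotation_time_s > 0, "config_error", "rotation_time_s must be positive")
  b4_assert(pitch > 0 && pitch < 2, "config_error", "pitch must lie in (0, 2)")
  b4_assert(n_rows >= 1 && row_width_mm > 0 && fov_length_mm >= 0,
            "config_error", "invalid collimation or field of view")
  structure(list(mode = "spiral", rotation_time_s = rotation_time_s,
                 pitch = pitch, n_rows = as.integer(n_rows),
                 row_width_mm = row_width_mm, fov_length_mm = fov_length_mm,
                 n_phases = as.integer(n_phases)),
            class = "scan_config")
}

#' Scan protocol configuration: breathing-adapted sequence scanning
#'
#' Defaults mirror a breathing-adapted sequence ("intelligent" 4D CT style)
#' protocol: 64 x 0.6 mm collimation with a couch increment of
#' 0.9 x 64 x 0.6 mm.  At each couch position the beam stays on until one
#' complete representative breathing cycle has been recorded; the
#' representative-cycle rule used here accepts a completed cycle whose
#' duration and peak-to-peak amplitude lie within the stated tolerances of
#' a reference learned from the first `learning_cycles` cycles.  The rule
#' is an explicit, configurable stand-in for the scanner's proprietary
#' real-time gating logic; its defaults were chosen once as plausible
#' clinical values and are documented in the methods vignette.  The real
#' scanner adapts its rotation time to the breathing pattern; here the
#' rotation time is a fixed configurable margin.
#'
#' @param rotation_time_s gantry rotation time, seconds (added as margin
#'   after the accepted cycle).
#' @param n_rows,row_width_mm detector collimation.
#' @param couch_increment_mm couch step between positions; at most the
#'   collimation width.
#' @param fov_length_mm longitudinal field-of-view length.
#' @param n_phases number of breathing-phase bins.
#' @param amp_tolerance accepted relative deviation of a cycle's
#'   peak-to-peak amplitude from the reference.
#' @param period_tolerance accepted relative deviation of a cycle's
#'   duration from the reference.
#' @param learning_cycles number of initial cycles used to learn the
#'   reference statistics (medians).
#' @param couch_move_dead_time_s beam-off time needed to advance the couch.
#' @param max_dwell_s maximum beam-on time per position before the
#'   position is flagged incomplete.
#' @return a list of class `scan_config` with `mode = "sequence"`.
#' @export
sequence_scan_config <- function(rotation_time_s = 0.5, n_rows = 64L,
                                 row_width_mm = 0.6,
                                 couch_increment_mm = 0.9 * 64 * 0.6,
                                 fov_length_mm = 200, n_phases = 10L,
                                 amp_tolerance = 0.25,
                                 period_tolerance = 0.35,
                                 learning_cycles = 3L,
                                 couch_move_dead_time_s = 0.8,
                                 max_dwell_s = 30) {
  b4_assert(rotation_time_s > 0, "config_error", "rotation_time_s must be positive")
  b4_assert(couch_increment_mm > 0 &&
              couch_increment_mm <= n_rows * row_width_mm + 1e-9,
            "config_error",
            "couch_increment_mm must be positive and at most the collimation width")
  b4_assert(amp_tolerance >= 0 && period_tolerance >= 0, "config_error",
            "tolerances must be non-negative")
  b4_assert(learning_cycles >= 1 && max_dwell_s > 0 &&
              couch_move_dead_time_s >= 0, "config_error",
            "invalid sequence gating parameters")
  structure(list(mode = "sequence", rotation_time_s = rotation_time_s,
                 n_rows = as.integer(n_rows), row_width_mm = row_width_mm,
                 couch_increment_mm = couch_increment_mm,
                 fov_length_mm = fov_length_mm, n_phases = as.integer(n_phases),
                 amp_tolerance = amp_tolerance,
                 period_tolerance = period_tolerance,
                 learning_cycles = as.integer(learning_cycles),
                 couch_move_dead_time_s = couch_move_dead_time_s,
                 max_dwell_s = max_dwell_s),
            class = "scan_config")
}

#' Read / write scan configurations as YAML
#'
#' @param path YAML file path.
#' @return for `read_scan_config`, a `scan_config`.
#' @export
read_scan_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  b4_assert(!is.null(cfg$mode), "config_error", "scan config has no mode")
  mode <- cfg$mode
  cfg$mode <- NULL
  if (identical(mode, "spiral")) do.call(spiral_scan_config, cfg)
  else if (identical(mode, "sequence")) do.call(sequence_scan_config, cfg)
  else b4_stop("config_error", sprintf("unknown scan mode '%s'", mode))
}

#' @rdname read_scan_config
#' @param config a `scan_config`.
#' @export
write_scan_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# Pick, for every phase bin, the acquired sample representing that bin:
# the candidate whose phase fraction is closest to the bin center (so that
# adjacent couch positions reconstruct consistent motion states on regular
# breathing), with ties resolved by proximity to a target time.
.select_bins <- function(cand_idx, phases, times, target_time, n_phases) {
  sel <- rep(NA_integer_, n_phases)
  if (length(cand_idx) == 0) return(sel)
  b <- phases$bins[cand_idx]
  f <- phases$fraction[cand_idx]
  for (bin in 0:(n_phases - 1)) {
    in_bin <- which(b == bin)
    if (length(in_bin) == 0) next
    ix <- cand_idx[in_bin]
    d_phase <- abs(f[in_bin] - (bin + 0.5) / n_phases)
    d_time <- abs(times[ix] - target_time)
    sel[bin + 1L] <- ix[order(d_phase, d_time, times[ix])[1]]
  }
  sel
}

.empty_acquisition <- function(mode, config) {
  structure(list(mode = mode, couch_positions_mm = numeric(0),
                 beam_on = beam_on_intervals(),
                 coverage_time = matrix(numeric(0), 0, config$n_phases),
                 coverage_amp = matrix(numeric(0), 0, config$n_phases),
                 scan_duration_s = 0, beam_duty_cycle = 1,
                 incomplete_positions = integer(0), config = config),
            class = "acquisition_result")
}

#' Simulate a retrospectively gated spiral 4D CT acquisition
#'
#' The couch moves continuously at
#' `pitch * n_rows * row_width_mm / rotation_time_s`; each station (one
#' collimation width) is illuminated for `rotation_time_s / pitch` seconds,
#' and the beam is on for the whole scan.  For every
#' (couch station, phase bin) the simulator retrospectively selects the
#' acquired sample representing that bin within the station's illumination
#' window, or records the cell as missing when the window contains no
#' sample of that phase -- the situation that forces interpolation
#' artifacts in real reconstructions.
#'
#' The scan starts at the first detected inhalation peak and requires the
#' segmented signal to cover the whole scan duration.
#'
#' @param signal a preprocessed [breathing_signal()].
#' @param seg the matching [segment_cycles()] result.
#' @param phases the matching [assign_phase()] result; `n_phases` must
#'   agree with the config.
#' @param config a [spiral_scan_config()].
#' @return an `acquisition_result`: couch positions, beam-on intervals
#'   (a single interval for spiral), coverage matrices of selected sample
#'   times/amplitudes (`NA` = missing), scan duration, duty cycle and the
#'   (empty, for spiral) incomplete-position list.
#' @export
simulate_spiral <- function(signal, seg, phases, config) {
  b4_assert(identical(config$mode, "spiral"), "config_error",
            "config must have mode 'spiral'")
  b4_assert(phases$n_phases == config$n_phases, "config_error",
            "phase assignment and config disagree on n_phases")
  station_mm <- config$n_rows * config$row_width_mm
  v <- config$pitch * station_mm / config$rotation_time_s
  w <- config$rotation_time_s / config$pitch   # illumination window length
  n_pos <- ceiling(config$fov_length_mm / station_mm)
  if (n_pos == 0) return(.empty_acquisition("spiral", config))
  t0 <- seg$peak_times_s[1]
  t_last <- seg$peak_times_s[length(seg$peak_times_s)]
  b4_assert(t0 + n_pos * w <= t_last + 1e-9, "insufficient_signal",
            "breathing signal too short for the spiral scan duration")
  np <- config$n_phases
  cov_t <- matrix(NA_real_, n_pos, np)
  cov_a <- matrix(NA_real_, n_pos, np)
  for (j in seq_len(n_pos)) {
    win <- t0 + c(j - 1, j) * w
    cand <- which(signal$times >= win[1] & signal$times < win[2] &
                    !is.na(phases$bins))
    sel <- .select_bins(cand, phases, signal$times, mean(win), np)
    ok <- !is.na(sel)
    cov_t[j, ok] <- signal$times[sel[ok]]
    cov_a[j, ok] <- signal$amplitudes[sel[ok]]
  }
  structure(list(
    mode = "spiral",
    couch_positions_mm = (seq_len(n_pos) - 0.5) * station_mm,
    beam_on = beam_on_intervals(t0, t0 + n_pos * w),
    coverage_time = cov_t, coverage_amp = cov_a,
    scan_duration_s = n_pos * w, beam_duty_cycle = 1,
    incomplete_positions = integer(0), config = config),
    class = "acquisition_result")
}

#' Simulate a breathing-adapted sequence (i4DCT-style) acquisition
#'
#' Reference cycle statistics (median period and median peak-to-peak
#' amplitude) are learned from the first `learning_cycles` breathing
#' cycles.  Then, per couch position: the beam switches on at the next
#' detected cycle start (a peak is confirmable one sample after its
#' maximum, honouring the real-time constraint), stays on until a
#' completed cycle matches the reference within the configured period and
#' amplitude tolerances (plus one gantry rotation of margin), or until
#' `max_dwell_s` elapses (the position is then flagged incomplete), and
#' switches off; the couch advances during `couch_move_dead_time_s`.
#' Phase coverage is computed from the accepted cycle's samples (or, for
#' incomplete positions, from whatever was recorded).
#'
#' @inheritParams simulate_spiral
#' @param config a [sequence_scan_config()].
#' @return an `acquisition_result` with one beam-on interval per couch
#'   position.
#' @export
simulate_sequence_i4dct <- function(signal, seg, phases, config) {
  b4_assert(identical(config$mode, "sequence"), "config_error",
            "config must have mode 'sequence'")
  b4_assert(phases$n_phases == config$n_phases, "config_error",
            "phase assignment and config disagree on n_phases")
  L <- config$learning_cycles
  b4_assert(seg$n_cycles >= L + 1, "learning_error",
            sprintf("need %d learning cycles plus data to scan, have %d cycles",
                    L, seg$n_cycles))
  ref_period <- stats::median(seg$inter_peak_durations_s[seq_len(L)])
  ref_amp <- stats::median(seg$cycle_p2p_amplitudes[seq_len(L)])
  dt <- sample_period(signal)
  peaks <- seg$peak_times_s
  n_peaks <- length(peaks)
  t_end_signal <- signal$times[length(signal$times)]
  n_pos <- ceiling(config$fov_length_mm / config$couch_increment_mm)
  if (n_pos == 0) return(.empty_acquisition("sequence", config))
  np <- config$n_phases
  cov_t <- matrix(NA_real_, n_pos, np)
  cov_a <- matrix(NA_real_, n_pos, np)
  on_s <- numeric(n_pos); off_s <- numeric(n_pos)
  incomplete <- integer(0)
  t_cursor <- peaks[L + 1] + dt

  for (j in seq_len(n_pos)) {
    s <- which(peaks + dt >= t_cursor)[1]
    b4_assert(!is.na(s) && s < n_peaks, "insufficient_signal",
              "breathing signal ends before all couch positions are scanned")
    beam_start <- peaks[s] + dt
    accepted <- NA_integer_
    beam_off <- NA_real_
    for (k in s:(n_peaks - 1)) {
      confirm <- peaks[k + 1] + dt
      if (confirm - beam_start > config$max_dwell_s) break
      dur <- seg$inter_peak_durations_s[k]
      p2p <- seg$cycle_p2p_amplitudes[k]
      if (abs(dur - ref_period) <= config$period_tolerance * ref_period &&
          abs(p2p - ref_amp) <= config$amp_tolerance * ref_amp) {
        accepted <- k
        beam_off <- peaks[k + 1] + config$rotation_time_s
        break
      }
    }
    if (is.na(accepted)) {
      beam_off <- beam_start + config$max_dwell_s
      b4_assert(beam_off <= t_end_signal + 1e-9, "insufficient_signal",
                "breathing signal ends before all couch positions are scanned")
      incomplete <- c(incomplete, j)
      cand <- which(signal$times >= beam_start & signal$times < beam_off &
                      !is.na(phases$bins))
      target <- (beam_start + beam_off) / 2
    } else {
      b4_assert(beam_off <= t_end_signal + 1e-9, "insufficient_signal",
                "breathing signal ends before all couch positions are scanned")
      cand <- which(!is.na(phases$cycle_index) &
                      phases$cycle_index == accepted &
                      signal$times >= beam_start)
      target <- mean(peaks[accepted + c(0, 1)])
    }
    sel <- .select_bins(cand, phases, signal$times, target, np)
    ok <- !is.na(sel)
    cov_t[j, ok] <- signal$times[sel[ok]]
    cov_a[j, ok] <- signal$amplitudes[sel[ok]]
    on_s[j] <- beam_start; off_s[j] <- beam_off
    t_cursor <- beam_off + config$couch_move_dead_time_s
  }
  span <- off_s[n_pos] - on_s[1]
  structure(list(
    mode = "sequence",
    couch_positions_mm = (seq_len(n_pos) - 0.5) * config$couch_increment_mm,
    beam_on = beam_on_intervals(on_s, off_s),
    coverage_time = cov_t, coverage_amp = cov_a,
    scan_duration_s = span,
    beam_duty_cycle = sum(off_s - on_s) / span,
    incomplete_positions = incomplete, config = config,
    reference = list(period_s = ref_period, amp = ref_amp)),
    class = "acquisition_result")
}

#' @export
print.acquisition_result <- function(x, ...) {
  cat(sprintf(
    "<acquisition_result [%s]: %d positions, %.1f s scan, duty %.2f, %d missing cells>\n",
    x$mode, length(x$couch_positions_mm), x$scan_duration_s,
    x$beam_duty_cycle, sum(is.na(x$coverage_time))))
  invisible(x)
}

#' Artifact-proxy scores for an acquisition
#'
#' Two signal-level surrogates for the artifact mechanisms of 4D CT:
#' `interpolation_count`, the number of missing (couch position, phase)
#' cells, i.e. cells where no acquired sample of the required breathing
#' phase exists (interpolation artifacts); and `double_structure_score`,
#' the mean absolute amplitude difference between the samples selected at
#' adjacent couch positions for the same phase bin, divided by the median
#' cycle peak-to-peak amplitude (motion-state inconsistency at stitching
#' boundaries, the genesis of double-structure artifacts).
#'
#' @param result an `acquisition_result` with computed coverage.
#' @param signal the preprocessed [breathing_signal()] that was scanned.
#' @param seg the matching [segment_cycles()] result.
#' @return a list with `interpolation_count`, `double_structure_score`
#'   and `n_cells`.
#' @export
artifact_proxy <- function(result, signal, seg) {
  n_pos <- nrow(result$coverage_time)
  b4_assert(n_pos > 0, "empty_result", "acquisition has no coverage")
  interp <- sum(is.na(result$coverage_time))
  med_p2p <- stats::median(seg$cycle_p2p_amplitudes)
  ds <- NA_real_
  if (n_pos >= 2 && med_p2p > 0) {
    a <- result$coverage_amp
    d <- abs(a[-1, , drop = FALSE] - a[-n_pos, , drop = FALSE])
    if (any(!is.na(d))) ds <- mean(d, na.rm = TRUE) / med_p2p
  }
  list(interpolation_count = interp, double_structure_score = ds,
       n_cells = length(result$coverage_time))
}

#' Compare the two acquisition protocols on one breathing curve
#'
#' Runs the full chain -- preprocessing, peak detection, cycle
#' segmentation, phase binning, both acquisition simulations and the
#' artifact proxies -- and returns a per-protocol report.  For rendering,
#' beam-on intervals are also provided clipped to the first 90 s of the
#' preprocessed trace, the standard display window for side-by-side curve
#' comparisons.
#'
#' @param signal a raw [breathing_signal()].
#' @param spiral_cfg a [spiral_scan_config()].
#' @param seq_cfg a [sequence_scan_config()]; must agree on `n_phases`.
#' @param display_window_s length of the display window in seconds
#'   (default 90).
#' @return a list of class `protocol_comparison` with elements `curve_id`,
#'   `spiral` and `sequence` (each: scan duration, duty cycle, proxies,
#'   beam-on intervals, incomplete positions) and `display` (clipped
#'   beam-on intervals per protocol).
#' @export
compare_protocols <- function(signal, spiral_cfg = spiral_scan_config(),
                              seq_cfg = sequence_scan_config(),
                              display_window_s = 90) {
  b4_assert(inherits(signal, "breathing_signal"), "insufficient_signal",
            "signal must be a breathing_signal")
  b4_assert(spiral_cfg$n_phases == seq_cfg$n_phases, "config_error",
            "the two configs must agree on n_phases")
  pp <- preprocess_signal(signal)
  peaks <- detect_inhalation_peaks(pp)
  seg <- segment_cycles(pp, peaks)
  phases <- assign_phase(pp, seg, spiral_cfg$n_phases)
  res_sp <- simulate_spiral(pp, seg, phases, spiral_cfg)
  res_sq <- simulate_sequence_i4dct(pp, seg, phases, seq_cfg)
  report_one <- function(res) {
    px <- artifact_proxy(res, pp, seg)
    list(mode = res$mode, scan_duration_s = res$scan_duration_s,
         duty_cycle = res$beam_duty_cycle,
         interpolation_count = px$interpolation_count,
         double_structure_score = px$double_structure_score,
         n_positions = length(res$couch_positions_mm),
         n_incomplete = length(res$incomplete_positions),
         beam_on = res$beam_on)
  }
  clip <- function(iv, t_lim) {
    keep <- iv$start_s < t_lim
    beam_on_intervals(iv$start_s[keep], pmin(iv$end_s[keep], t_lim))
  }
  t_lim <- pp$times[1] + display_window_s
  structure(list(
    curve_id = signal$curve_id,
    spiral = report_one(res_sp),
    sequence = report_one(res_sq),
    display = list(window_s = c(pp$times[1], t_lim),
                   spiral_beam_on = clip(res_sp$beam_on, t_lim),
                   sequence_beam_on = clip(res_sq$beam_on, t_lim))),
    class = "protocol_comparison")
}
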