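# Shared fixture: fully regular breather, long enough for both protocols.
regular_chain <- function(duration_s = 150, period = 4, seed = 51,
                          n_phases = 10) {
  g <- generate_signal(synthetic_spec(duration_s = duration_s,
                                      period_mean_s = period, seed = seed))
  a <- analyze_generated(g, smooth_window_s = 0)
  a$phases <- assign_phase(a$pp, a$seg, n_phases)
  a$truth <- g$truth
  a
}

test_that("scan configurations validate their geometry and tolerances", {
  cfg <- spiral_scan_config()
  expect_equal(cfg$pitch, 0.09)
  expect_equal(cfg$rotation_time_s, 0.5)
  expect_error(spiral_scan_config(pitch = 2.5), class = "config_error")
  expect_error(sequence_scan_config(couch_increment_mm = 100),
               class = "config_error")

  f <- withr::local_tempfile(fileext = ".yaml")
  write_scan_config(sequence_scan_config(fov_length_mm = 150), f)
  back <- read_scan_config(f)
  expect_equal(back, sequence_scan_config(fov_length_mm = 150))
})

test_that("spiral scanning on a regular breather covers every phase bin", {
  a <- regular_chain()
  cfg <- spiral_scan_config(fov_length_mm = 192)
  res <- simulate_spiral(a$pp, a$seg, a$phases, cfg)

  # cycle period (4 s) is below the illumination window (0.5 / 0.09 s),
  # so no (position, phase) cell can be missing
  expect_equal(sum(is.na(res$coverage_time)), 0)
  expect_equal(nrow(res$coverage_time), 10)  # 192 mm / 19.2 mm stations
  expect_equal(nrow(res$beam_on), 1)
  expect_equal(res$beam_duty_cycle, 1)
  expect_equal(res$scan_duration_s, 10 * 0.5 / 0.09, tolerance = 1e-9)

  # every selected sample carries the phase bin of its cell
  ph_of <- function(tt) {
    i <- match(tt, a$pp$times)
    a$phases$bins[i]
  }
  for (b in 1:10)
    expect_true(all(ph_of(res$coverage_time[, b]) == b - 1))

  # degenerate field of view: no positions, empty result
  empty <- simulate_spiral(a$pp, a$seg, a$phases,
                           spiral_scan_config(fov_length_mm = 0))
  expect_equal(length(empty$couch_positions_mm), 0)
  expect_equal(nrow(empty$beam_on), 0)
})

test_that("spiral scanning needs a signal covering the scan duration", {
  a <- regular_chain(duration_s = 30)
  expect_error(simulate_spiral(a$pp, a$seg, a$phases,
                               spiral_scan_config(fov_length_mm = 192)),
               class = "insufficient_signal")
})

test_that("sequence scanning dwells one representative cycle per position", {
  a <- regular_chain()
  cfg <- sequence_scan_config(fov_length_mm = 100)
  res <- simulate_sequence_i4dct(a$pp, a$seg, a$phases, cfg)
  n_pos <- ceiling(100 / cfg$couch_increment_mm)
  expect_equal(nrow(res$beam_on), n_pos)
  expect_equal(length(res$incomplete_positions), 0)
  expect_equal(sum(is.na(res$coverage_time)), 0)

  # homogeneous cycles: each dwell is one period plus the rotation margin
  # (up to peak-confirmation latency of one sample)
  dwell <- res$beam_on$end_s - res$beam_on$start_s
  expect_lt(max(abs(dwell - (4 + cfg$rotation_time_s))), 3 / 25)

  # beam-on total bounded by positions x (reference period, max dwell)
  expect_gte(sum(dwell), n_pos * res$reference$period_s * 0.9)
  expect_lte(sum(dwell), n_pos * cfg$max_dwell_s)
  expect_lt(res$beam_duty_cycle, 1)
})

test_that("vacuous tolerances accept the first complete cycle everywhere", {
  g <- generate_signal(synthetic_spec(duration_s = 150, period_mean_s = 4,
                                      period_sd_s = 0.3, amp_sd = 0.3,
                                      seed = 52))
  a <- analyze_generated(g)
  a$phases <- assign_phase(a$pp, a$seg, 10)
  cfg <- sequence_scan_config(fov_length_mm = 100, amp_tolerance = Inf,
                              period_tolerance = Inf)
  res <- simulate_sequence_i4dct(a$pp, a$seg, a$phases, cfg)
  expect_equal(length(res$incomplete_positions), 0)
  # every dwell ends one rotation after the first cycle completed in it
  pk <- a$seg$peak_times_s
  for (j in seq_len(nrow(res$beam_on))) {
    first_peak_after <- pk[pk + 1 / 25 >= res$beam_on$start_s[j]][1]
    next_peak <- pk[pk > first_peak_after][1]
    expect_equal(res$beam_on$end_s[j], next_peak + cfg$rotation_time_s,
                 tolerance = 1e-9)
  }
})

test_that("sequence scanning requires enough learning cycles and signal", {
  a <- regular_chain()
  short_seg <- segment_cycles(a$pp, a$seg$peak_times_s[1:3])
  ph <- assign_phase(a$pp, short_seg, 10)
  expect_error(simulate_sequence_i4dct(a$pp, short_seg, ph,
                                       sequence_scan_config()),
               class = "learning_error")

  b <- regular_chain(duration_s = 40)
  expect_error(simulate_sequence_i4dct(b$pp, b$seg, b$phases,
                                       sequence_scan_config(fov_length_mm = 300)),
               class = "insufficient_signal")
})

test_that("a long breathing pause defeats spiral but not sequence scanning", {
  # pause (10 s) + cycle (4 s) exceeds twice the illumination window, so
  # at least one spiral station sees only a fraction of a cycle
  g <- generate_signal(synthetic_spec(duration_s = 150, period_mean_s = 4,
                                      pauses = list(c(8, 10)), seed = 53))
  a <- analyze_generated(g, smooth_window_s = 0)
  a$phases <- assign_phase(a$pp, a$seg, 10)

  sp <- simulate_spiral(a$pp, a$seg, a$phases,
                        spiral_scan_config(fov_length_mm = 192))
  expect_gt(sum(is.na(sp$coverage_time)), 0)

  sq <- simulate_sequence_i4dct(a$pp, a$seg, a$phases,
                                sequence_scan_config(fov_length_mm = 150))
  expect_equal(sum(is.na(sq$coverage_time)), 0)
  # the affected position's dwell stretches past the whole pause
  dwell <- sq$beam_on$end_s - sq$beam_on$start_s
  expect_gt(max(dwell), 10)
})

test_that("artifact proxies separate regular from alternating-amplitude breathing", {
  a <- regular_chain()
  spiral <- spiral_scan_config(fov_length_mm = 192)
  seq_cfg <- sequence_scan_config(fov_length_mm = 192)
  res_sp <- simulate_spiral(a$pp, a$seg, a$phases, spiral)
  res_sq <- simulate_sequence_i4dct(a$pp, a$seg, a$phases, seq_cfg)
  px_sp <- artifact_proxy(res_sp, a$pp, a$seg)
  px_sq <- artifact_proxy(res_sq, a$pp, a$seg)
  expect_equal(px_sp$interpolation_count, 0)
  expect_equal(px_sq$interpolation_count, 0)
  expect_lt(px_sp$double_structure_score, 0.05)
  expect_lt(px_sq$double_structure_score, 0.05)

  # strong cycle-to-cycle amplitude variability: retrospective stitching
  # mixes inconsistent motion states, the adapted protocol does not
  worse <- 0
  for (seed in 54:58) {
    g <- generate_signal(synthetic_spec(duration_s = 150, period_mean_s = 4,
                                        period_sd_s = 0.2, amp_sd = 0.35,
                                        seed = seed))
    b <- analyze_generated(g)
    b$phases <- assign_phase(b$pp, b$seg, 10)
    d_sp <- artifact_proxy(simulate_spiral(b$pp, b$seg, b$phases, spiral),
                           b$pp, b$seg)$double_structure_score
    d_sq <- artifact_proxy(
      simulate_sequence_i4dct(b$pp, b$seg, b$phases, seq_cfg),
      b$pp, b$seg)$double_structure_score
    worse <- worse + (d_sp > d_sq)
  }
  expect_gte(worse, 4)

  expect_error(artifact_proxy(
    simulate_spiral(a$pp, a$seg, a$phases,
                    spiral_scan_config(fov_length_mm = 0)), a$pp, a$seg),
    class = "empty_result")
})

test_that("the protocol comparison report is complete and clipped for display", {
  g <- generate_signal(synthetic_spec(duration_s = 150, period_mean_s = 4,
                                      period_sd_s = 0.3, amp_sd = 0.2,
                                      noise_sd = 0.02, seed = 59))
  cmp <- compare_protocols(g$signal, spiral_scan_config(fov_length_mm = 100),
                           sequence_scan_config(fov_length_mm = 100))
  expect_s3_class(cmp, "protocol_comparison")
  expect_equal(cmp$spiral$duty_cycle, 1)
  expect_lt(cmp$sequence$duty_cycle, 1)
  expect_equal(nrow(cmp$spiral$beam_on), 1)
  expect_equal(nrow(cmp$sequence$beam_on), cmp$sequence$n_positions)
  expect_lte(max(cmp$display$sequence_beam_on$end_s),
             cmp$display$window_s[2])

  tiny <- breathing_signal(seq(0, 5, 0.04), sin(seq(0, 5, 0.04)))
  expect_error(compare_protocols(tiny), class = "breath4dct_error")
})
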