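#' Configuration of a desk-scale comparison study
#'
#' Describes a fully synthetic re-enactment of the two-cohort study
#' design: generate two cohorts of breathing curves, compute irregularity
#' metrics, select the most irregular reference curves (by amplitude SD
#' and by longest pause), match the second cohort to them, simulate both
#' acquisition protocols on the matched pairs and summarize.
#'
#' Per-curve generator parameters are drawn from the configured ranges
#' with curve-specific child seeds (see [child_seed()]), so the study is
#' reproducible curve-by-curve under one master seed.  The default ranges
#' emulate adult breathing at rest: periods of 3-5.5 s (11-20 breaths per
#' minute), cycle-amplitude variability from near-regular up to strongly
#' irregular, occasional breathing pauses of 6-14 s, mild linear baseline
#' drift and camera-level measurement noise.
#'
#' @param n_per_cohort curves per cohort (at least `n_amp + n_pause`).
#' @param duration_s active breathing time per curve, seconds.
#' @param sample_rate surrogate sampling rate, Hz.
#' @param n_amp,n_pause selection counts, see [select_irregular_cohort()].
#' @param period_mean_range,period_sd_range,amp_sd_range,
#'   pause_duration_range,drift_slope_range length-2 numeric ranges from
#'   which per-curve generator parameters are drawn uniformly.
#' @param pause_prob probability that a curve contains one breathing pause.
#' @param noise_sd measurement noise SD (amplitude units).
#' @param spiral_cfg,seq_cfg scan configurations used for the per-pair
#'   protocol comparison.
#' @param master_seed integer master seed fixing all child seeds.
#' @return a list of class `study_config`.
#' @export
study_config <- function(n_per_cohort = 60L, duration_s = 210,
                         sample_rate = 25, n_amp = 15L, n_pause = 10L,
                         period_mean_range = c(3, 5.5),
                         period_sd_range = c(0.1, 0.5),
                         amp_sd_range = c(0.03, 0.35),
                         pause_prob = 0.3,
                         pause_duration_range = c(6, 14),
                         drift_slope_range = c(-0.002, 0.002),
                         noise_sd = 0.02,
                         spiral_cfg = spiral_scan_config(fov_length_mm = 192),
                         seq_cfg = sequence_scan_config(fov_length_mm = 192),
                         master_seed = 1L) {
  b4_assert(n_per_cohort >= n_amp + n_pause, "size_error",
            sprintf("cohort size %d cannot supply %d + %d selections",
                    n_per_cohort, n_amp, n_pause))
  structure(list(n_per_cohort = as.integer(n_per_cohort),
                 duration_s = duration_s, sample_rate = sample_rate,
                 n_amp = as.integer(n_amp), n_pause = as.integer(n_pause),
                 period_mean_range = period_mean_range,
                 period_sd_range = period_sd_range,
                 amp_sd_range = amp_sd_range, pause_prob = pause_prob,
                 pause_duration_range = pause_duration_range,
                 drift_slope_range = drift_slope_range, noise_sd = noise_sd,
                 spiral_cfg = spiral_cfg, seq_cfg = seq_cfg,
                 master_seed = as.integer(master_seed)),
            class = "study_config")
}

# Draw one curve's generator spec from the study ranges, using the curve's
# child seed for both the parameter draws and the waveform stream.
.draw_curve_spec <- function(config, cohort_salt, index) {
  seed_i <- child_seed(config$master_seed, index, salt = cohort_salt)
  with_seed(seed_i, {
    runi <- function(r) stats::runif(1, r[1], r[2])
    pauses <- list()
    if (stats::runif(1) < config$pause_prob)
      pauses <- list(c(sample(3:10, 1), runi(config$pause_duration_range)))
    synthetic_spec(
      duration_s = config$duration_s, sample_rate = config$sample_rate,
      period_mean_s = runi(config$period_mean_range),
      period_sd_s = runi(config$period_sd_range),
      amp_mean = 1, amp_sd = runi(config$amp_sd_range),
      pauses = pauses,
      drift_slope = runi(config$drift_slope_range),
      noise_sd = config$noise_sd,
      seed = child_seed(seed_i, 7L))
  })
}

.generate_cohort <- function(config, cohort_salt, prefix) {
  lapply(seq_len(config$n_per_cohort), function(i) {
    spec <- .draw_curve_spec(config, cohort_salt, i)
    gen <- generate_signal(spec)
    gen$signal$curve_id <- sprintf("%s-%03d", prefix, i)
    gen$spec <- spec
    gen
  })
}

.analyze_curve <- function(gen) {
  pp <- preprocess_signal(gen$signal)
  peaks <- detect_inhalation_peaks(pp)
  seg <- segment_cycles(pp, peaks)
  list(pp = pp, seg = seg,
       metrics = irregularity_metrics(seg, gen$signal$curve_id))
}

#' Run the desk-scale two-cohort comparison study
#'
#' Executes the full study pipeline (see [study_config()]) and writes all
#' results as JSON to `out_dir`: per-curve irregularity metrics for both
#' cohorts, the reference selection, the cross-cohort match, the
#' per-matched-pair protocol comparison (both simulators run on the
#' reference curve of each pair, so the protocol contrast is paired on an
#' identical breathing signal), the cohort summary with Mann-Whitney
#' results, and a run log.  All JSON output is deterministic given the
#' master seed; wall-clock timestamps appear in the log only.  On failure,
#' partially written outputs are removed.
#'
#' @param config a [study_config()].
#' @param out_dir output directory (created if missing).
#' @return invisibly, the study report (a list mirroring the JSON files).
#' @export
run_study <- function(config, out_dir) {
  b4_assert(inherits(config, "study_config"), "config_error",
            "config must be a study_config")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  files <- file.path(out_dir, c(
    "metrics_a.json", "metrics_b.json", "selection.json", "match.json",
    "protocol_comparison.json", "cohort_summary.json", "run_log.txt"))
  names(files) <- c("metrics_a", "metrics_b", "selection", "match",
                    "comparison", "summary", "log")
  written <- character(0)
  on_fail <- function(e) {
    unlink(written)
    stop(e)
  }
  tryCatch({
    t_start <- Sys.time()
    cohort_a <- .generate_cohort(config, 1L, "A")
    cohort_b <- .generate_cohort(config, 2L, "B")
    ana_a <- lapply(cohort_a, .analyze_curve)
    ana_b <- lapply(cohort_b, .analyze_curve)
    metrics_a <- lapply(ana_a, `[[`, "metrics")
    metrics_b <- lapply(ana_b, `[[`, "metrics")

    selection <- select_irregular_cohort(metrics_a, config$n_amp, config$n_pause)
    mt <- match_cohorts(selection, metrics_b)

    sel_ids <- c(selection$amp_selected, selection$pause_selected)
    id_a <- vapply(metrics_a, `[[`, character(1), "curve_id")
    id_b <- vapply(metrics_b, `[[`, character(1), "curve_id")
    summary <- cohort_summary(metrics_a[match(sel_ids, id_a)],
                              metrics_b[match(mt$pairs$matched_id, id_b)])

    pair_reports <- lapply(seq_len(nrow(mt$pairs)), function(i) {
      ref_id <- mt$pairs$reference_id[i]
      gen <- cohort_a[[match(ref_id, id_a)]]
      cmp <- tryCatch(
        compare_protocols(gen$signal, config$spiral_cfg, config$seq_cfg),
        breath4dct_error = function(e) NULL)
      keep <- c("scan_duration_s", "duty_cycle", "interpolation_count",
                "double_structure_score", "n_incomplete")
      list(reference_id = ref_id, matched_id = mt$pairs$matched_id[i],
           criterion = mt$pairs$criterion[i],
           status = if (is.null(cmp)) "skipped: signal too short" else "ok",
           spiral = if (is.null(cmp)) NULL else cmp$spiral[keep],
           sequence = if (is.null(cmp)) NULL else cmp$sequence[keep])
    })

    wj <- function(x, f) {
      jsonlite::write_json(x, f, digits = NA, auto_unbox = TRUE, pretty = TRUE)
      written <<- c(written, f)
    }
    metrics_json <- function(ml) lapply(ml, function(m)
      list(curve_id = m$curve_id, amp_p2p_sd = m$amp_p2p_sd,
           longest_pause_s = m$longest_pause_s, mean_cycle_s = m$mean_cycle_s,
           n_cycles = m$n_cycles, pauses = m$pauses))
    schema <- list(schema_version = "1.0")
    wj(c(schema, list(metrics = metrics_json(metrics_a))), files["metrics_a"])
    wj(c(schema, list(metrics = metrics_json(metrics_b))), files["metrics_b"])
    wj(c(schema, list(amp_selected = selection$amp_selected,
                      pause_selected = selection$pause_selected)),
       files["selection"])
    wj(c(schema, list(pairs = mt$pairs)), files["match"])
    wj(c(schema, list(pairs = pair_reports)), files["comparison"])
    wj(c(schema, list(
      median_longest_pause_s = as.list(summary$median_longest_pause_s),
      median_amp_p2p_sd = as.list(summary$median_amp_p2p_sd),
      mw_pause_p = summary$mw_pause$p_value,
      mw_amp_p = summary$mw_amp$p_value)), files["summary"])

    cfg_hash <- sum(utf8ToInt(paste(deparse(unclass(config)), collapse = "")))
    writeLines(c(
      sprintf("breath4dct run_study, master seed %d", config$master_seed),
      sprintf("config hash: %d", cfg_hash),
      sprintf("started: %s", format(t_start)),
      sprintf("finished: %s", format(Sys.time())),
      sprintf("cohorts: %d + %d curves; %d matched pairs",
              length(cohort_a), length(cohort_b), nrow(mt$pairs))),
      files["log"])
    written <- c(written, files["log"])

    invisible(list(selection = selection, match = mt, summary = summary,
                   pair_reports = pair_reports,
                   metrics_a = metrics_a, metrics_b = metrics_b,
                   files = files))
  }, error = on_fail)
}
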