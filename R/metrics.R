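#' Amplitude variability of a breathing curve
#'
#' Sample standard deviation (n-1 denominator) of the per-cycle
#' peak-to-peak amplitudes.  Computed after windowing, drift correction and
#' unit-range normalization, the statistic is dimensionless: a fraction of
#' the total breathing excursion.
#'
#' @param seg a [segment_cycles()] result obtained from a fully
#'   preprocessed signal.
#' @return the amplitude SD (single number, >= 0).
#' @export
amp_variability <- function(seg) {
  b4_assert(seg$n_cycles >= 2, "insufficient_cycles",
            "amplitude variability needs at least two cycles")
  stats::sd(seg$cycle_p2p_amplitudes)
}

#' Detect breathing pauses
#'
#' A pause is an inter-peak duration (time between two successive
#' inhalation points) that is at least `factor` times the patient's average
#' breathing cycle, with the average estimated by the median inter-peak
#' duration (pause-robust; an arithmetic mean would be inflated by the very
#' gaps being tested).  The pause is attributed to the earlier peak and its
#' duration is the full inter-peak gap.
#'
#' @param seg a [segment_cycles()] result.
#' @param factor pause threshold as a multiple of the average cycle
#'   (default 1.5).
#' @return a data frame with columns `start_s` and `duration_s`, zero rows
#'   when no gap qualifies.
#' @export
detect_pauses <- function(seg, factor = 1.5) {
  b4_assert(seg$n_cycles >= 2, "insufficient_cycles",
            "pause detection needs at least two cycles")
  gaps <- seg$inter_peak_durations_s
  hit <- gaps >= factor * seg$mean_cycle_s
  data.frame(start_s = seg$peak_times_s[which(hit)],
             duration_s = gaps[hit])
}

#' Irregularity metrics for one breathing curve
#'
#' Bundles the two irregularity statistics used for cohort selection:
#' the amplitude-variability SD and the breathing pauses (with the longest
#' pause as scalar summary), plus the cycle-length estimate.
#'
#' @param seg a [segment_cycles()] result from a preprocessed signal.
#' @param curve_id curve identifier.
#' @param pause_factor pause threshold multiple, see [detect_pauses()].
#' @return an object of class `irregularity_metrics`: list with `curve_id`,
#'   `amp_p2p_sd`, `pauses` (data frame), `longest_pause_s` (0 when there
#'   is no pause), `mean_cycle_s`, `n_cycles`.
#' @export
irregularity_metrics <- function(seg, curve_id = "curve", pause_factor = 1.5) {
  pauses <- detect_pauses(seg, pause_factor)
  structure(list(
    curve_id = as.character(curve_id),
    amp_p2p_sd = amp_variability(seg),
    pauses = pauses,
    longest_pause_s = if (nrow(pauses)) max(pauses$duration_s) else 0,
    mean_cycle_s = seg$mean_cycle_s,
    n_cycles = seg$n_cycles), class = "irregularity_metrics")
}

.metrics_table <- function(metrics_list) {
  b4_assert(length(metrics_list) > 0, "size_error", "empty metrics list")
  data.frame(
    curve_id = vapply(metrics_list, `[[`, character(1), "curve_id"),
    amp_p2p_sd = vapply(metrics_list, `[[`, numeric(1), "amp_p2p_sd"),
    longest_pause_s = vapply(metrics_list, `[[`, numeric(1), "longest_pause_s"),
    stringsAsFactors = FALSE)
}

#' Select the most irregular curves of a cohort
#'
#' Reproduces the two-criterion selection used to build an
#' irregular-breather reference cohort: first the `n_amp` curves with the
#' largest amplitude-variability SD, then, among the remaining curves, the
#' `n_pause` curves with the longest breathing pause.  The two lists are
#' disjoint; the amplitude criterion takes precedence.  Ties are broken by
#' curve id (lexicographic), making the selection deterministic.
#'
#' @param all_metrics list of [irregularity_metrics()] objects.
#' @param n_amp number of curves selected by amplitude SD (default 15).
#' @param n_pause number of curves selected by longest pause (default 10).
#' @return an object of class `cohort_selection`: list with `amp_selected`
#'   and `pause_selected` (character vectors of curve ids, ranked
#'   descending by their criterion) and the metrics table.
#' @export
select_irregular_cohort <- function(all_metrics, n_amp = 15L, n_pause = 10L) {
  tab <- .metrics_table(all_metrics)
  b4_assert(nrow(tab) >= n_amp + n_pause, "size_error",
            sprintf("cohort of %d curves cannot supply %d + %d selections",
                    nrow(tab), n_amp, n_pause))
  ord_amp <- tab[order(-tab$amp_p2p_sd, tab$curve_id), ]
  amp_sel <- ord_amp$curve_id[seq_len(n_amp)]
  rest <- tab[!tab$curve_id %in% amp_sel, ]
  ord_pause <- rest[order(-rest$longest_pause_s, rest$curve_id), ]
  pause_sel <- ord_pause$curve_id[seq_len(n_pause)]
  structure(list(amp_selected = amp_sel, pause_selected = pause_sel,
                 metrics = tab), class = "cohort_selection")
}

#' Match a second cohort to a selected reference cohort
#'
#' Greedy nearest-neighbour matching without replacement: reference curves
#' are processed in descending order of their selection statistic;
#' amplitude-selected references are matched to the pool curve with the
#' closest amplitude SD, pause-selected references to the pool curve with
#' the closest longest-pause duration.  Each pool curve is used at most
#' once; ties go to the lexicographically smaller pool id.
#'
#' @param selection a [select_irregular_cohort()] result for the reference
#'   cohort.
#' @param pool_metrics list of [irregularity_metrics()] for the candidate
#'   cohort; must contain at least as many curves as the selection.
#' @return an object of class `cohort_match`: data frame `pairs` with
#'   columns `reference_id`, `matched_id`, `criterion` (`"amp"` or
#'   `"pause"`) and `metric_distance`.
#' @export
match_cohorts <- function(selection, pool_metrics) {
  pool <- .metrics_table(pool_metrics)
  n_need <- length(selection$amp_selected) + length(selection$pause_selected)
  b4_assert(nrow(pool) >= n_need, "size_error",
            sprintf("pool of %d curves cannot match %d references",
                    nrow(pool), n_need))
  ref <- selection$metrics
  rownames(ref) <- ref$curve_id
  tasks <- rbind(
    data.frame(reference_id = selection$amp_selected, criterion = "amp",
               value = ref[selection$amp_selected, "amp_p2p_sd"],
               stringsAsFactors = FALSE),
    data.frame(reference_id = selection$pause_selected, criterion = "pause",
               value = ref[selection$pause_selected, "longest_pause_s"],
               stringsAsFactors = FALSE))
  available <- rep(TRUE, nrow(pool))
  out <- vector("list", nrow(tasks))
  for (i in seq_len(nrow(tasks))) {
    pv <- if (tasks$criterion[i] == "amp") pool$amp_p2p_sd else pool$longest_pause_s
    d <- abs(pv - tasks$value[i])
    d[!available] <- Inf
    j <- order(d, pool$curve_id)[1]
    available[j] <- FALSE
    out[[i]] <- data.frame(reference_id = tasks$reference_id[i],
                           matched_id = pool$curve_id[j],
                           criterion = tasks$criterion[i],
                           metric_distance = d[j], stringsAsFactors = FALSE)
  }
  structure(list(pairs = do.call(rbind, out)), class = "cohort_match")
}

#' Compare irregularity statistics between two cohorts
#'
#' Per-cohort medians of the longest-pause duration and the amplitude SD,
#' with two-sided Mann-Whitney U tests for the cohort differences.
#'
#' @param metrics_a,metrics_b lists of [irregularity_metrics()].
#' @return a list with `median_longest_pause_s`, `median_amp_p2p_sd`
#'   (named length-2 vectors, cohorts `a` and `b`) and `mw_pause` /
#'   `mw_amp` ([mann_whitney_u()] results).
#' @export
cohort_summary <- function(metrics_a, metrics_b) {
  ta <- .metrics_table(metrics_a); tb <- .metrics_table(metrics_b)
  list(
    median_longest_pause_s = c(a = stats::median(ta$longest_pause_s),
                               b = stats::median(tb$longest_pause_s)),
    median_amp_p2p_sd = c(a = stats::median(ta$amp_p2p_sd),
                          b = stats::median(tb$amp_p2p_sd)),
    mw_pause = mann_whitney_u(ta$longest_pause_s, tb$longest_pause_s),
    mw_amp = mann_whitney_u(ta$amp_p2p_sd, tb$amp_p2p_sd))
}
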