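#' Construct a breathing signal
#'
#' A `breathing_signal` is a uniformly sampled respiratory amplitude trace,
#' as exported by camera-based surrogate systems (Varian RPM/RGSC style),
#' optionally carrying a per-sample beam-on flag that marks when the scanner
#' acquired projection data.  Larger amplitude means more inhaled, so
#' end-inspiration is a local maximum.
#'
#' @param times numeric vector of sample times in seconds, strictly
#'   increasing and uniformly spaced (relative tolerance `1e-6`).
#' @param amplitudes numeric vector of breathing amplitudes (arbitrary
#'   units), same length as `times`, all finite.
#' @param beam_on optional logical vector, same length as `times`.
#' @param curve_id character identifier for the curve.
#' @return an object of class `breathing_signal` with fields `times`,
#'   `amplitudes`, `beam_on`, `sample_rate` (Hz, inferred from the median
#'   spacing) and `curve_id`.
#' @export
breathing_signal <- function(times, amplitudes, beam_on = NULL,
                             curve_id = "curve") {
  times <- as.numeric(times)
  amplitudes <- as.numeric(amplitudes)
  b4_assert(length(times) >= 2, "malformed_input",
            "a breathing signal needs at least two samples")
  b4_assert(length(times) == length(amplitudes), "malformed_input",
            "times and amplitudes must have equal length")
  b4_assert(all(is.finite(times)) && all(is.finite(amplitudes)),
            "malformed_input", "times and amplitudes must be finite")
  dts <- diff(times)
  b4_assert(all(dts > 0), "malformed_input", "times must be strictly increasing")
  dt <- stats::median(dts)
  b4_assert(max(rel_diff(dts, dt)) <= 1e-6, "malformed_input",
            "sampling must be uniform (relative tolerance 1e-6)")
  if (!is.null(beam_on)) {
    beam_on <- as.logical(beam_on)
    b4_assert(length(beam_on) == length(times) && !anyNA(beam_on),
              "malformed_input", "beam_on must be logical, one flag per sample")
  }
  structure(
    list(times = times, amplitudes = amplitudes, beam_on = beam_on,
         sample_rate = 1 / dt, curve_id = as.character(curve_id)),
    class = "breathing_signal")
}

#' @export
print.breathing_signal <- function(x, ...) {
  cat(sprintf("<breathing_signal '%s': %d samples @ %.3g Hz, %.1f s%s>\n",
              x$curve_id, length(x$times), x$sample_rate,
              x$times[length(x$times)] - x$times[1],
              if (is.null(x$beam_on)) "" else
                sprintf(", %d beam-on samples", sum(x$beam_on))))
  invisible(x)
}

sample_period <- function(signal) 1 / signal$sample_rate

#' Column-mapping dialect for breathing-curve files
#'
#' Vendor export formats differ in delimiter and column layout; a dialect
#' maps them onto the neutral layout used here.  The default dialect is
#' comma-separated with header `time_s,amplitude,beam_on` (beam_on optional).
#'
#' @param sep field delimiter.
#' @param header logical; does the file carry a header line?
#' @param time_col,amp_col,beam_col column names (when `header = TRUE`) or
#'   1-based column indices (when `header = FALSE`).  `beam_col = NULL`
#'   means the file has no beam-on channel.
#' @return a list with class `curve_dialect`.
#' @export
curve_dialect <- function(sep = ",", header = TRUE, time_col = "time_s",
                          amp_col = "amplitude", beam_col = "beam_on") {
  structure(list(sep = sep, header = header, time_col = time_col,
                 amp_col = amp_col, beam_col = beam_col),
            class = "curve_dialect")
}

.dialect_column <- function(df, col, what, required = TRUE) {
  if (is.null(col)) return(NULL)
  if (is.character(col)) {
    if (!col %in% names(df)) {
      if (required)
        b4_stop("format_error", sprintf("missing required column '%s' (%s)",
                                        col, what))
      return(NULL)
    }
    return(df[[col]])
  }
  if (col > ncol(df)) {
    if (required)
      b4_stop("format_error", sprintf("file has no column %d (%s)", col, what))
    return(NULL)
  }
  df[[col]]
}

#' Read a breathing curve from a delimited text file
#'
#' @param path path to a delimited text file with at least a time and an
#'   amplitude column.
#' @param dialect a [curve_dialect()] describing the file layout.
#' @return a validated [breathing_signal()]; the sample rate is inferred
#'   from the median time spacing.
#' @export
read_breathing_curve <- function(path, dialect = curve_dialect()) {
  b4_assert(file.exists(path), "io_error", sprintf("file not found: %s", path))
  df <- utils::read.table(path, sep = dialect$sep, header = dialect$header,
                          stringsAsFactors = FALSE)
  times <- .dialect_column(df, dialect$time_col, "time")
  amps <- .dialect_column(df, dialect$amp_col, "amplitude")
  beam <- .dialect_column(df, dialect$beam_col, "beam_on", required = FALSE)
  if (!is.null(beam)) beam <- beam != 0
  breathing_signal(times, amps, beam,
                   curve_id = sub("\\.[^.]*$", "", basename(path)))
}

#' Write a breathing curve to the default text dialect
#'
#' Writes `time_s,amplitude[,beam_on]` with six decimal places, readable by
#' [read_breathing_curve()] with the default dialect.  Writing, reading and
#' writing again is byte-stable.
#'
#' @param signal a [breathing_signal()].
#' @param path output file path.
#' @export
write_breathing_curve <- function(signal, path) {
  b4_assert(inherits(signal, "breathing_signal"), "malformed_input",
            "signal must be a breathing_signal")
  has_beam <- !is.null(signal$beam_on)
  header <- if (has_beam) "time_s,amplitude,beam_on" else "time_s,amplitude"
  lines <- if (has_beam) {
    sprintf("%.6f,%.6f,%d", signal$times, signal$amplitudes,
            as.integer(signal$beam_on))
  } else {
    sprintf("%.6f,%.6f", signal$times, signal$amplitudes)
  }
  ok <- tryCatch({
    writeLines(c(header, lines), path)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  b4_assert(ok, "io_error", sprintf("cannot write to %s", path))
  invisible(path)
}

#' Beam-on intervals
#'
#' Half-open `[start_s, end_s)` intervals during which projection data are
#' acquired; sorted and non-overlapping.
#'
#' @param starts,ends numeric vectors of interval starts / ends in seconds.
#' @return an object of class `beam_on_intervals` (a two-column data frame).
#' @export
beam_on_intervals <- function(starts = numeric(0), ends = numeric(0)) {
  starts <- as.numeric(starts); ends <- as.numeric(ends)
  b4_assert(length(starts) == length(ends), "malformed_input",
            "starts and ends must have equal length")
  b4_assert(all(starts < ends), "malformed_input",
            "each interval needs start < end")
  if (length(starts) > 1) {
    b4_assert(!is.unsorted(starts, strictly = TRUE), "malformed_input",
              "intervals must be sorted")
    b4_assert(all(utils::head(ends, -1) <= starts[-1]), "malformed_input",
              "intervals must not overlap")
  }
  structure(data.frame(start_s = starts, end_s = ends),
            class = c("beam_on_intervals", "data.frame"))
}

#' Extract beam-on intervals from per-sample flags
#'
#' Maximal runs of true flags become half-open time intervals.  A run's end
#' is the time of the sample after its last true sample, or the last sample
#' time plus one sample period when the run touches the end of the trace,
#' so total beam-on duration equals the number of true flags times the
#' sample period.
#'
#' @param signal a [breathing_signal()] with `beam_on` present.
#' @return a [beam_on_intervals()] object.
#' @export
beam_on_intervals_from_flags <- function(signal) {
  b4_assert(!is.null(signal$beam_on), "missing_channel",
            "signal carries no beam_on channel")
  r <- rle(signal$beam_on)
  if (!any(r$values)) return(beam_on_intervals())
  last <- cumsum(r$lengths)
  first <- last - r$lengths + 1
  keep <- r$values
  dt <- sample_period(signal)
  n <- length(signal$times)
  end_idx <- last[keep] + 1
  ends <- ifelse(end_idx > n, signal$times[n] + dt, signal$times[pmin(end_idx, n)])
  beam_on_intervals(signal$times[first[keep]], ends)
}

#' Serialize beam-on intervals to JSON
#'
#' @param intervals a [beam_on_intervals()] object.
#' @return a JSON string of the form `[[start, end], ...]`.
#' @export
beam_on_intervals_json <- function(intervals) {
  m <- unname(as.matrix(intervals))
  jsonlite::toJSON(m, digits = NA)
}
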