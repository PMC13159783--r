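#' Construct a validated RR series
#'
#' Container for one recording session: strictly increasing beat times in
#' seconds and positive beat intervals (RR) in milliseconds.
#'
#' @param patient_id Identifier.
#' @param pma_weeks Post-menstrual age at recording, in weeks.
#' @param beat_times Numeric vector, seconds, strictly increasing.
#' @param rr_ms Numeric vector, milliseconds, same length, all > 0.
#' @param ga_weeks Optional gestational age at birth, weeks.
#' @return Object of class `rr_series`.
#' @export
rr_series <- function(patient_id, pma_weeks, beat_times, rr_ms,
                      ga_weeks = NA_real_) {
  if (length(beat_times) != length(rr_ms)) {
    stop("beat_times and rr_ms must have equal length", call. = FALSE)
  }
  if (length(rr_ms) && any(rr_ms <= 0)) {
    stop("rr_ms values must be positive", call. = FALSE)
  }
  if (length(beat_times) > 1L && any(diff(beat_times) <= 0)) {
    bad <- which(diff(beat_times) <= 0)[1L] + 1L
    stop(sprintf("beat_times must be strictly increasing (violated at beat %d)",
                 bad), call. = FALSE)
  }
  structure(
    list(patient_id = patient_id, pma_weeks = pma_weeks,
         ga_weeks = ga_weeks,
         beat_times = as.numeric(beat_times), rr_ms = as.numeric(rr_ms)),
    class = "rr_series"
  )
}

#' @export
print.rr_series <- function(x, ...) {
  cat(sprintf("<rr_series> patient %s, PMA %.1f wk: %d beats over %.1f min\n",
              x$patient_id, x$pma_weeks, length(x$rr_ms),
              if (length(x$beat_times)) diff(range(x$beat_times)) / 60 else 0))
  invisible(x)
}

#' @export
length.rr_series <- function(x) length(x$rr_ms)

#' Read a beat file
#'
#' Parses a two-column (time in seconds, RR in ms) whitespace-separated
#' beat file; lines starting with `#` are ignored. Non-monotone beat times
#' produce a parse error naming the offending line.
#'
#' @param path File path.
#' @param patient_id,pma_weeks Metadata attached to the series (default id
#'   is the file name without extension).
#' @return An `rr_series` object.
#' @export
read_rr <- function(path, patient_id = NULL, pma_weeks = NA_real_) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  if (!any(keep)) stop(sprintf("no beat data in %s", path), call. = FALSE)
  line_no <- which(keep)
  fields <- strsplit(trimws(lines[keep]), "\\s+")
  bad_ncol <- which(lengths(fields) < 2L)
  if (length(bad_ncol)) {
    stop(sprintf("line %d of %s: expected two numeric columns",
                 line_no[bad_ncol[1L]], path), call. = FALSE)
  }
  t_s <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 1L)))
  rr <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  bad_num <- which(!is.finite(t_s) | !is.finite(rr))
  if (length(bad_num)) {
    stop(sprintf("line %d of %s: non-numeric value",
                 line_no[bad_num[1L]], path), call. = FALSE)
  }
  non_mono <- which(diff(t_s) <= 0)
  if (length(non_mono)) {
    stop(sprintf("line %d of %s: beat time not increasing",
                 line_no[non_mono[1L] + 1L], path), call. = FALSE)
  }
  if (is.null(patient_id)) {
    patient_id <- sub("\\.[^.]*$", "", basename(path))
  }
  rr_series(patient_id, pma_weeks, t_s, rr)
}

#' Flag artifact beats by running-median deviation
#'
#' A beat is flagged when its RR deviates from the centered 11-beat running
#' median by more than `deviation_threshold` (as a fraction of the local
#' median). Flagged beats are marked, not deleted, so segment quality can
#' be computed; the cleaned series (flagged beats removed) is also
#' returned. A single pass is used; re-running on the cleaned series flags
#' nothing for isolated artifacts.
#'
#' @param series An `rr_series`.
#' @param deviation_threshold Fractional deviation above which a beat is
#'   flagged (default 0.20).
#' @return List with `series` (cleaned `rr_series`), `flags` (logical, per
#'   original beat), `n_flagged`.
#' @export
clean_rr <- function(series, deviation_threshold = 0.20) {
  stopifnot(inherits(series, "rr_series"))
  n <- length(series$rr_ms)
  k <- 11L
  if (n < k) {
    warning("series shorter than the running-median window; returned unchanged")
    return(list(series = series, flags = rep(FALSE, n), n_flagged = 0L))
  }
  med <- stats::runmed(series$rr_ms, k = k, endrule = "median")
  flags <- abs(series$rr_ms - med) > deviation_threshold * med
  cleaned <- rr_series(series$patient_id, series$pma_weeks,
                       series$beat_times[!flags], series$rr_ms[!flags],
                       series$ga_weeks)
  list(series = cleaned, flags = flags, n_flagged = sum(flags))
}

#' Segment a recording into fixed-length good-quality windows
#'
#' Tiles the recording with contiguous non-overlapping half-open windows
#' `[start, start + window_s)` beginning at the first beat. Beats are
#' assigned to windows by beat time. Each complete window's quality is the
#' fraction of its beats not flagged by [clean_rr()]; windows with quality
#' below `min_quality`, or with fewer than `min_beats` beats, or truncated
#' by the end of the recording, are dropped.
#'
#' @param series An `rr_series`.
#' @param window_s Window length in seconds (default 1800 = 30 min).
#' @param min_quality Minimum fraction of clean beats (default 0.80).
#' @param min_beats Minimum beats per retained window (default 1000).
#' @param deviation_threshold Passed to [clean_rr()].
#' @return List of `rr_segment` objects (possibly empty). Each segment
#'   carries the clean beats only, plus `quality` and window bounds.
#' @export
segment_series <- function(series, window_s = 1800, min_quality = 0.80,
                           min_beats = 1000L, deviation_threshold = 0.20) {
  stopifnot(inherits(series, "rr_series"))
  check_scalar(window_s, "window_s", 0, strict_lower = TRUE)
  if (length(series$rr_ms) == 0L) return(list())
  cl <- suppressWarnings(clean_rr(series, deviation_threshold))
  t0 <- series$beat_times[1L]
  t_end <- series$beat_times[length(series$beat_times)]
  n_windows <- floor((t_end - t0) / window_s)
  segments <- list()
  for (w in seq_len(n_windows)) {
    start <- t0 + (w - 1L) * window_s
    end <- start + window_s
    in_win <- series$beat_times >= start & series$beat_times < end
    n_beats <- sum(in_win)
    if (n_beats == 0L) next
    quality <- sum(in_win & !cl$flags) / n_beats
    if (quality < min_quality || n_beats < min_beats) next
    keep <- in_win & !cl$flags
    segments[[length(segments) + 1L]] <- structure(
      list(patient_id = series$patient_id, pma_weeks = series$pma_weeks,
           ga_weeks = series$ga_weeks,
           start_s = start, end_s = end,
           beat_times = series$beat_times[keep],
           rr_ms = series$rr_ms[keep],
           quality = quality),
      class = "rr_segment"
    )
  }
  segments
}

#' @export
print.rr_segment <- function(x, ...) {
  cat(sprintf(
    "<rr_segment> patient %s [%.0f, %.0f) s: %d clean beats, quality %.3f\n",
    x$patient_id, x$start_s, x$end_s, length(x$rr_ms), x$quality))
  invisible(x)
}
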