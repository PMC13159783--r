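#' Configuration for a synthetic neonatal RR series
#'
#' Describes one simulated recording session. The defaults encode a simple
#' maturation law: baseline heart rate slows and beat-to-beat variability
#' grows as post-menstrual age (PMA) increases, mirroring the development of
#' the central autonomic network over the preterm period. RR values are a
#' baseline plus low-frequency (LF) and high-frequency (HF, respiratory)
#' sinusoidal modulation plus white Gaussian noise; a configurable fraction
#' of beats is replaced by ectopic-like artifacts (RR doubled or halved).
#'
#' @param ga_weeks Gestational age at birth in weeks (24-30).
#' @param pma_weeks Post-menstrual age at the recording, in weeks.
#' @param duration_s Recording length in seconds (> 0).
#' @param mean_rr_ms Baseline beat interval in ms. Default shortens with
#'   lower PMA (faster heart rate in the least mature infants).
#' @param sdnn_scale_ms Standard deviation of the white-noise component in
#'   ms. Default grows with PMA (overall variability matures upward).
#' @param hf_amp_ms,hf_freq_hz Respiratory modulation amplitude (ms) and
#'   frequency (Hz; neonatal breathing is around 1 Hz).
#' @param lf_amp_ms,lf_freq_hz Low-frequency modulation amplitude (ms) and
#'   frequency (Hz).
#' @param ectopic_rate Fraction of beats replaced by artifacts, in [0, 1).
#' @param seed Integer seed; identical config + seed gives identical series.
#' @return An object of class `rr_gen_config`.
#' @export
rr_gen_config <- function(ga_weeks = 27,
                          pma_weeks = 34,
                          duration_s = 3600,
                          mean_rr_ms = 400 - 3 * (pma_weeks - 32),
                          sdnn_scale_ms = 5 + 0.8 * (pma_weeks - 28),
                          hf_amp_ms = 2 + 0.3 * (pma_weeks - 28),
                          hf_freq_hz = 1.0,
                          lf_amp_ms = 5 + 0.5 * (pma_weeks - 28),
                          lf_freq_hz = 0.1,
                          ectopic_rate = 0.02,
                          seed = 1L) {
  check_scalar(ga_weeks, "ga_weeks", 22, 42)
  check_scalar(pma_weeks, "pma_weeks", 22, 45)
  check_scalar(duration_s, "duration_s", 0, strict_lower = TRUE)
  check_scalar(mean_rr_ms, "mean_rr_ms", 0, strict_lower = TRUE)
  check_scalar(sdnn_scale_ms, "sdnn_scale_ms", 0)
  check_scalar(hf_amp_ms, "hf_amp_ms", 0)
  check_scalar(hf_freq_hz, "hf_freq_hz", 0)
  check_scalar(lf_amp_ms, "lf_amp_ms", 0)
  check_scalar(lf_freq_hz, "lf_freq_hz", 0)
  check_scalar(ectopic_rate, "ectopic_rate", 0, 1, strict_upper = TRUE)
  structure(
    list(ga_weeks = ga_weeks, pma_weeks = pma_weeks, duration_s = duration_s,
         mean_rr_ms = mean_rr_ms, sdnn_scale_ms = sdnn_scale_ms,
         hf_amp_ms = hf_amp_ms, hf_freq_hz = hf_freq_hz,
         lf_amp_ms = lf_amp_ms, lf_freq_hz = lf_freq_hz,
         ectopic_rate = ectopic_rate, seed = as.integer(seed)),
    class = "rr_gen_config"
  )
}

#' Simulate a beat-interval series for one recording
#'
#' Beats are generated sequentially: the RR interval at beat time t is
#' `mean_rr_ms + lf_amp * sin(2*pi*lf_freq*t) + hf_amp * sin(2*pi*hf_freq*t)
#' + N(0, sdnn_scale_ms)`, the next beat time follows after RR seconds, and
#' a fraction `ectopic_rate` of beats is replaced by 2x or 0.5x its value
#' (ectopic-like artifacts the cleaning stage is meant to catch).
#'
#' @param config An [rr_gen_config()] object.
#' @param patient_id Identifier attached to the series.
#' @return An `rr_series` object (see [rr_series()]).
#' @export
generate_rr_series <- function(config, patient_id = "synthetic") {
  if (!inherits(config, "rr_gen_config")) {
    stop("'config' must be an rr_gen_config object", call. = FALSE)
  }
  n_max <- ceiling(config$duration_s * 1000 / config$mean_rr_ms * 1.5) + 10
  rr <- with_seed(config$seed, {
    noise <- rnorm(n_max, 0, config$sdnn_scale_ms)
    ect <- runif(n_max) < config$ectopic_rate
    updown <- runif(n_max) < 0.5
    t <- numeric(n_max)
    rr <- numeric(n_max)
    cur <- 0
    i <- 0L
    while (cur < config$duration_s && i < n_max) {
      i <- i + 1L
      t[i] <- cur
      val <- config$mean_rr_ms +
        config$lf_amp_ms * sin(2 * pi * config$lf_freq_hz * cur) +
        config$hf_amp_ms * sin(2 * pi * config$hf_freq_hz * cur) +
        noise[i]
      val <- max(val, 0.1 * config$mean_rr_ms)
      if (ect[i]) val <- if (updown[i]) 2 * val else 0.5 * val
      rr[i] <- val
      cur <- cur + val / 1000
    }
    list(t = t[seq_len(i)], rr = rr[seq_len(i)])
  })
  rr_series(patient_id = patient_id, pma_weeks = config$pma_weeks,
            beat_times = rr$t, rr_ms = rr$rr, ga_weeks = config$ga_weeks)
}

#' Write a beat file
#'
#' Two tab-separated numeric columns (beat time in seconds, RR in ms) after
#' a `#`-prefixed header; the format [read_rr()] reads back.
#'
#' @param series An `rr_series` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_rr <- function(series, path) {
  stopifnot(inherits(series, "rr_series"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# patient_id=%s pma_weeks=%g time_s\trr_ms",
                     series$patient_id, series$pma_weeks), con)
  writeLines(sprintf("%.6f\t%.6f", series$beat_times, series$rr_ms), con)
  invisible(path)
}
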