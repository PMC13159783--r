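#' Canonical HRV feature registry
#'
#' Names of every feature the extractor can compute, spanning the four
#' families used for maturation-age estimation: time domain, frequency
#' domain (Lomb-Scargle band powers), Poincare geometry, and non-linear
#' measures (sample entropy, detrended fluctuation analysis, natural
#' visibility graph).
#'
#' @return Character vector of feature names.
#' @export
hrv_feature_registry <- function() {
  c("mean_nn", "sdnn", "rmssd", "sdsd", "pnn20", "pnn50",
    "lf_power", "hf_power", "lf_hf_ratio", "total_power",
    "sd1", "sd2", "sd1_sd2_ratio",
    "sampen", "dfa_alpha1", "dfa_alpha2",
    "vg_mean_degree", "vg_degree_sd", "vg_assortativity")
}

# Attach/merge a missing-value reason log onto a named numeric vector.
add_reason <- function(x, name, reason) {
  r <- attr(x, "reasons")
  if (is.null(r)) r <- character()
  r[name] <- reason
  attr(x, "reasons") <- r
  x
}

#' Time-domain HRV features
#'
#' All dispersion statistics use the population convention (divide by n),
#' which makes the Poincare identities exact.
#'
#' @param rr_ms Beat intervals in ms (>= 2 beats).
#' @return Named vector: `mean_nn`, `sdnn`, `rmssd`, `sdsd`, `pnn20`,
#'   `pnn50`.
#' @export
time_domain <- function(rr_ms) {
  if (length(rr_ms) < 2L) stop("time_domain needs at least 2 beats",
                               call. = FALSE)
  d <- diff(rr_ms)
  c(mean_nn = mean(rr_ms),
    sdnn = sd_pop(rr_ms),
    rmssd = sqrt(mean(d^2)),
    sdsd = sd_pop(d),
    pnn20 = mean(abs(d) > 20),
    pnn50 = mean(abs(d) > 50))
}

# Lomb periodogram of an unevenly sampled series, returned as a one-sided
# power spectral density (ms^2/Hz) scaled so that, for even sampling, the
# integral over frequency approximates the series variance.
lomb_psd <- function(t, y, freqs) {
  y <- y - mean(y)
  n <- length(y)
  dt_mean <- mean(diff(t))
  p <- numeric(length(freqs))
  chunk <- 256L
  for (k in seq(1L, length(freqs), by = chunk)) {
    idx <- k:min(k + chunk - 1L, length(freqs))
    w <- 2 * pi * freqs[idx]
    # tau makes the sinusoid basis orthogonal at each frequency
    arg2 <- outer(2 * w, t)
    tau <- atan2(rowSums(sin(arg2)), rowSums(cos(arg2))) / (2 * w)
    arg <- outer(w, t) - w * tau
    ca <- cos(arg); sa <- sin(arg)
    cy <- as.vector(ca %*% y); sy <- as.vector(sa %*% y)
    cc <- rowSums(ca^2); ss <- rowSums(sa^2)
    p[idx] <- 0.5 * (ifelse(cc > 0, cy^2 / cc, 0) +
                       ifelse(ss > 0, sy^2 / ss, 0))
  }
  2 * dt_mean * p / 1
}

#' Frequency-domain HRV features from the Lomb periodogram
#'
#' Computes band powers of the unevenly sampled RR series by trapezoidal
#' integration of the Lomb periodogram (no resampling). Default bands are
#' neonatal: LF 0.04-0.2 Hz, HF 0.2-2.0 Hz (neonatal respiration is far
#' faster than adult, so the adult HF band would miss it).
#'
#' @param beat_times Beat times in seconds.
#' @param rr_ms Beat intervals in ms (>= 64 beats).
#' @param bands Named list of `c(low, high)` Hz pairs; must be disjoint.
#'   Must contain `lf` and `hf` for the ratio.
#' @param oversample Frequency oversampling factor for the grid.
#' @param max_freqs Cap on the number of grid frequencies.
#' @return Named vector `lf_power`, `hf_power`, `lf_hf_ratio`,
#'   `total_power` (ms^2). A zero HF power yields a missing ratio with a
#'   reason in `attr(, "reasons")`, never an infinity.
#' @export
frequency_domain <- function(beat_times, rr_ms,
                             bands = list(lf = c(0.04, 0.2),
                                          hf = c(0.2, 2.0)),
                             oversample = 4, max_freqs = 3000L) {
  n <- length(rr_ms)
  if (n < 64L) stop("frequency_domain needs at least 64 beats", call. = FALSE)
  if (length(beat_times) != n) stop("length mismatch", call. = FALSE)
  lims <- do.call(rbind, bands)
  if (any(lims[, 2] <= lims[, 1])) {
    stop("each band must be (low, high) with low < high", call. = FALSE)
  }
  ord <- order(lims[, 1])
  if (any(lims[ord, 1][-1] < lims[ord, 2][-nrow(lims)])) {
    stop("bands must be disjoint", call. = FALSE)
  }
  f_lo <- min(lims[, 1]); f_hi <- max(lims[, 2])
  span <- diff(range(beat_times))
  df <- max(1 / (oversample * span), (f_hi - f_lo) / max_freqs)
  freqs <- seq(f_lo, f_hi, by = df)
  psd <- lomb_psd(beat_times, rr_ms, freqs)
  band_power <- function(lo, hi) {
    sel <- freqs >= lo & freqs <= hi
    if (sum(sel) < 2L) return(0)
    f <- freqs[sel]; p <- psd[sel]
    sum(diff(f) * (head(p, -1) + tail(p, -1)) / 2)
  }
  powers <- vapply(bands, function(b) band_power(b[1], b[2]), numeric(1))
  out <- c(lf_power = unname(powers["lf"]),
           hf_power = unname(powers["hf"]),
           lf_hf_ratio = NA_real_,
           total_power = band_power(f_lo, f_hi))
  if (is.finite(powers["hf"]) && powers["hf"] > 1e-12) {
    out["lf_hf_ratio"] <- powers[["lf"]] / powers[["hf"]]
  } else {
    out <- add_reason(out, "lf_hf_ratio", "hf_power is zero")
  }
  out
}

#' Poincare plot descriptors
#'
#' `sd1^2 = mean(diff^2)/2` (short-term axis, uncentered second moment of
#' the successive differences) and `sd2^2 = 2*sdnn^2 - sd1^2` (long-term
#' axis, floored at zero), with the population convention for `sdnn`, so
#' `sd1 = rmssd/sqrt(2)` and `sd1^2 + sd2^2 = 2*sdnn^2` hold exactly.
#'
#' @param rr_ms Beat intervals in ms (>= 3 beats).
#' @return Named vector `sd1`, `sd2`, `sd1_sd2_ratio` (ratio missing with a
#'   reason when `sd2` is zero).
#' @export
poincare <- function(rr_ms) {
  if (length(rr_ms) < 3L) stop("poincare needs at least 3 beats",
                               call. = FALSE)
  sd1sq <- 0.5 * mean(diff(rr_ms)^2)
  sd2sq <- max(0, 2 * var_pop(rr_ms) - sd1sq)
  out <- c(sd1 = sqrt(sd1sq), sd2 = sqrt(sd2sq), sd1_sd2_ratio = NA_real_)
  if (sd2sq > 0) {
    out["sd1_sd2_ratio"] <- sqrt(sd1sq) / sqrt(sd2sq)
  } else {
    out <- add_reason(out, "sd1_sd2_ratio", "degenerate variance (sd2 = 0)")
  }
  out
}

#' Sample entropy
#'
#' `sampen = -ln(A/B)` where `B` counts template pairs of length `m` and
#' `A` of length `m + 1` within Chebyshev distance `r * sd` of each other,
#' self-matches excluded (templates taken at the first `n - m` positions
#' for both lengths). When the series sd is zero the tolerance falls back
#' to the absolute value of `r`.
#'
#' @param rr_ms Beat intervals (length > m + 1).
#' @param m Embedding dimension (default 2).
#' @param r Tolerance as a fraction of the population sd (default 0.2).
#' @return Length-1 named vector `sampen`; `NA` with a reason attribute
#'   when no templates match at either length.
#' @export
sample_entropy <- function(rr_ms, m = 2L, r = 0.2) {
  n <- length(rr_ms)
  if (n <= m + 1L) stop("sample_entropy needs length > m + 1", call. = FALSE)
  if (r <= 0) stop("'r' must be positive", call. = FALSE)
  s <- sd_pop(rr_ms)
  tol <- if (s > 0) r * s else r
  nt <- n - m
  A <- 0; B <- 0
  x <- as.numeric(rr_ms)
  for (i in seq_len(nt - 1L)) {
    js <- (i + 1L):nt
    dmax <- abs(x[i] - x[js])
    if (m > 1L) {
      for (k in seq_len(m - 1L)) {
        dmax <- pmax(dmax, abs(x[i + k] - x[js + k]))
      }
    }
    B <- B + sum(dmax <= tol)
    dmax1 <- pmax(dmax, abs(x[i + m] - x[js + m]))
    A <- A + sum(dmax1 <= tol)
  }
  out <- c(sampen = NA_real_)
  if (B == 0) return(add_reason(out, "sampen", "no template matches (B = 0)"))
  if (A == 0) return(add_reason(out, "sampen", "no extended matches (A = 0)"))
  out["sampen"] <- -log(A / B)
  out
}

# Fluctuation function for one box size: split the integrated profile into
# floor(N/s) boxes from the start and again from the end, detrend each box
# linearly, return the root-mean-square residual. The s^2/(s^2 - 4) factor
# is the finite-size correction for first-order detrending: the exact
# white-noise expectation of the raw fluctuation is proportional to
# (s^2 - 4)/s rather than s, which inflates the exponent at the short
# scales used for alpha1; the corrected statistic scales as s^(1/2) in
# expectation for uncorrelated data.
dfa_fluctuation <- function(profile, s) {
  N <- length(profile)
  nb <- N %/% s
  X <- cbind(1, seq_len(s))
  P <- diag(s) - X %*% solve(crossprod(X), t(X))
  fwd <- matrix(profile[seq_len(nb * s)], nrow = s)
  bwd <- matrix(profile[(N - nb * s + 1L):N], nrow = s)
  res <- cbind(P %*% fwd, P %*% bwd)
  sqrt(mean(res^2) * s^2 / (s^2 - 4))
}

#' Detrended fluctuation analysis exponents
#'
#' First-order DFA of the RR series: integrate the mean-centered series,
#' detrend linearly in non-overlapping boxes (taken from both ends of the
#' record), and regress `log F(s)` on `log s`. `dfa_alpha1` uses short
#' scales (4-11 beats), `dfa_alpha2` long scales (12-64 beats). An exponent
#' near 0.5 indicates uncorrelated intervals, near 1.5 integrated noise.
#'
#' @param rr_ms Beat intervals (length >= 100).
#' @param scales1,scales2 Integer box sizes for the two regimes.
#' @return Named vector `dfa_alpha1`, `dfa_alpha2`; an exponent whose scale
#'   range cannot be populated (fewer than 4 boxes at some scale, or fewer
#'   than 2 usable scales) is `NA` with a reason.
#' @export
dfa <- function(rr_ms, scales1 = 4:11,
                scales2 = unique(round(exp(seq(log(12), log(64),
                                               length.out = 10))))) {
  n <- length(rr_ms)
  if (n < 100L) stop("dfa needs at least 100 beats", call. = FALSE)
  profile <- cumsum(rr_ms - mean(rr_ms))
  fit_alpha <- function(scales) {
    usable <- scales[n %/% scales >= 4L]
    if (length(usable) < 2L) return(NA_real_)
    Fs <- vapply(usable, function(s) dfa_fluctuation(profile, s), numeric(1))
    if (any(Fs <= 0)) return(NA_real_)
    unname(coef(lm(log(Fs) ~ log(usable)))[2L])
  }
  out <- c(dfa_alpha1 = fit_alpha(scales1), dfa_alpha2 = fit_alpha(scales2))
  if (is.na(out["dfa_alpha1"])) {
    out <- add_reason(out, "dfa_alpha1", "insufficient length for scale range")
  }
  if (is.na(out["dfa_alpha2"])) {
    out <- add_reason(out, "dfa_alpha2", "insufficient length for scale range")
  }
  out
}

# Natural visibility adjacency by the running-maximum-slope scan: b is
# visible from a (a < b) iff the slope from a to b strictly exceeds the
# slope from a to every intermediate point.
visibility_edges <- function(t, y) {
  n <- length(y)
  from <- vector("list", n - 1L)
  to <- vector("list", n - 1L)
  for (a in seq_len(n - 1L)) {
    js <- (a + 1L):n
    slopes <- (y[js] - y[a]) / (t[js] - t[a])
    prev_max <- c(-Inf, cummax(slopes)[-length(slopes)])
    vis <- slopes > prev_max
    from[[a]] <- rep.int(a, sum(vis))
    to[[a]] <- js[vis]
  }
  cbind(unlist(from), unlist(to))
}

#' Natural visibility graph metrics
#'
#' Maps the RR sequence (values against beat times) to its natural
#' visibility graph: two beats are connected when the straight line between
#' their (time, RR) points passes strictly above every intermediate beat.
#' Longer series are subsampled deterministically to at most `cap` beats.
#'
#' @param rr_ms Beat intervals (>= 10 beats for defined metrics).
#' @param beat_times Optional beat times (seconds); beat index is used when
#'   omitted.
#' @param cap Maximum number of nodes (default 1024).
#' @return Named vector `vg_mean_degree`, `vg_degree_sd` (population sd),
#'   `vg_assortativity` (degree assortativity; `NA` with reason when
#'   degenerate, e.g. a regular graph). Series shorter than 10 beats give
#'   all-`NA` metrics with a reason.
#' @export
visibility_graph <- function(rr_ms, beat_times = NULL, cap = 1024L) {
  out <- c(vg_mean_degree = NA_real_, vg_degree_sd = NA_real_,
           vg_assortativity = NA_real_)
  n <- length(rr_ms)
  if (n < 10L) {
    for (nm in names(out)) out <- add_reason(out, nm, "fewer than 10 beats")
    return(out)
  }
  if (is.null(beat_times)) beat_times <- seq_len(n)
  if (n > cap) {
    idx <- unique(round(seq(1, n, length.out = cap)))
    rr_ms <- rr_ms[idx]
    beat_times <- beat_times[idx]
    n <- length(idx)
  }
  edges <- visibility_edges(as.numeric(beat_times), as.numeric(rr_ms))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  deg <- igraph::degree(g)
  out["vg_mean_degree"] <- mean(deg)
  out["vg_degree_sd"] <- sd_pop(deg)
  assort <- suppressWarnings(igraph::assortativity_degree(g))
  if (is.finite(assort)) {
    out["vg_assortativity"] <- assort
  } else {
    out <- add_reason(out, "vg_assortativity",
                      "assortativity undefined (degree-regular graph)")
  }
  out
}

#' Extract an HRV feature vector from one segment
#'
#' Computes the requested features (default: the whole registry) on the
#' clean beats of a segment. Features whose value is undefined are returned
#' as `NA` with a cause recorded in `attr(, "reasons")`; unknown feature
#' names are an error listing the registry.
#'
#' @param segment An `rr_segment` (from [segment_series()]) or an
#'   `rr_series`.
#' @param feature_names Features to compute, from [hrv_feature_registry()].
#' @param sampen_m,sampen_r Sample-entropy parameters.
#' @param bands Spectral bands, as in [frequency_domain()].
#' @param vg_cap Visibility-graph node cap.
#' @return Object of class `hrv_features`: named numeric vector with
#'   metadata attributes (`patient_id`, `pma_weeks`, `start_s`, `quality`,
#'   `reasons`).
#' @export
extract_features <- function(segment,
                             feature_names = hrv_feature_registry(),
                             sampen_m = 2L, sampen_r = 0.2,
                             bands = list(lf = c(0.04, 0.2),
                                          hf = c(0.2, 2.0)),
                             vg_cap = 1024L) {
  unknown <- setdiff(feature_names, hrv_feature_registry())
  if (length(unknown)) {
    stop(sprintf("unknown feature name(s) %s; registry: %s",
                 paste(sQuote(unknown), collapse = ", "),
                 paste(hrv_feature_registry(), collapse = ", ")),
         call. = FALSE)
  }
  rr <- segment$rr_ms
  t <- segment$beat_times
  values <- setNames(rep(NA_real_, length(feature_names)), feature_names)
  reasons <- character()
  pull <- function(res, wanted) {
    got <- intersect(names(res), wanted)
    values[got] <<- res[got]
    r <- attr(res, "reasons")
    if (!is.null(r)) reasons[intersect(names(r), wanted)] <<-
        r[intersect(names(r), wanted)]
  }
  guard <- function(wanted, fun) {
    wanted <- intersect(feature_names, wanted)
    if (!length(wanted)) return(invisible())
    res <- tryCatch(fun(), error = function(e) {
      out <- setNames(rep(NA_real_, length(wanted)), wanted)
      for (nm in wanted) out <- add_reason(out, nm, conditionMessage(e))
      out
    })
    pull(res, wanted)
  }
  guard(c("mean_nn", "sdnn", "rmssd", "sdsd", "pnn20", "pnn50"),
        function() time_domain(rr))
  guard(c("lf_power", "hf_power", "lf_hf_ratio", "total_power"),
        function() frequency_domain(t, rr, bands = bands))
  guard(c("sd1", "sd2", "sd1_sd2_ratio"), function() poincare(rr))
  guard("sampen", function() sample_entropy(rr, m = sampen_m, r = sampen_r))
  guard(c("dfa_alpha1", "dfa_alpha2"), function() dfa(rr))
  guard(c("vg_mean_degree", "vg_degree_sd", "vg_assortativity"),
        function() visibility_graph(rr, beat_times = t, cap = vg_cap))
  structure(values,
            patient_id = segment$patient_id,
            pma_weeks = segment$pma_weeks,
            ga_weeks = if (!is.null(segment$ga_weeks)) segment$ga_weeks
                       else NA_real_,
            start_s = if (!is.null(segment$start_s)) segment$start_s
                      else NA_real_,
            quality = if (!is.null(segment$quality)) segment$quality
                      else NA_real_,
            reasons = reasons,
            class = "hrv_features")
}

#' @export
print.hrv_features <- function(x, digits = 3, ...) {
  cat(sprintf("<hrv_features> patient %s, PMA %s wk\n",
              attr(x, "patient_id"), format(attr(x, "pma_weeks"))))
  print(round(setNames(as.numeric(x), names(x)), digits))
  r <- attr(x, "reasons")
  if (length(r)) {
    cat("missing:", paste0(names(r), " (", r, ")", collapse = "; "), "\n")
  }
  invisible(x)
}

#' Build a feature table from many segments
#'
#' One row per segment: `patient_id`, `pma_weeks`, `ga_weeks`,
#' `segment_start_s`, `quality`, then one column per feature. Missing
#' values stay `NA`; their causes are collected in
#' `attr(, "missing_reasons")`.
#'
#' @param segments List of `rr_segment` objects.
#' @inheritParams extract_features
#' @return data.frame of class `hrv_feature_table`.
#' @export
features_table <- function(segments,
                           feature_names = hrv_feature_registry(), ...) {
  rows <- lapply(segments, extract_features, feature_names = feature_names,
                 ...)
  df <- data.frame(
    patient_id = vapply(rows, attr, "", "patient_id"),
    pma_weeks = vapply(rows, attr, 0, "pma_weeks"),
    ga_weeks = vapply(rows, attr, 0, "ga_weeks"),
    segment_start_s = vapply(rows, attr, 0, "start_s"),
    quality = vapply(rows, attr, 0, "quality"),
    stringsAsFactors = FALSE
  )
  for (nm in feature_names) {
    df[[nm]] <- vapply(rows, function(r) unname(r[nm]), numeric(1))
  }
  logs <- lapply(rows, attr, "reasons")
  names(logs) <- df$patient_id
  attr(df, "missing_reasons") <- logs
  class(df) <- c("hrv_feature_table", "data.frame")
  df
}

#' Write a feature table to CSV (plus a sidecar missing-reason log)
#'
#' @param table An `hrv_feature_table`.
#' @param path Output CSV path; the reason log goes to `<path>.reasons.txt`
#'   when any value is missing.
#' @return `path`, invisibly.
#' @export
write_features <- function(table, path) {
  write.csv(as.data.frame(table), path, row.names = FALSE, na = "")
  logs <- attr(table, "missing_reasons")
  lines <- unlist(lapply(seq_along(logs), function(i) {
    r <- logs[[i]]
    if (!length(r)) return(character())
    sprintf("row %d (%s): %s = %s", i, names(logs)[i], names(r), r)
  }))
  if (length(lines)) writeLines(lines, paste0(path, ".reasons.txt"))
  invisible(path)
}
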