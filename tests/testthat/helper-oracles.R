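# Independent brute-force oracles. These deliberately share no code with
# the package implementations they check.

# Time-domain statistics by direct arithmetic.
oracle_time_domain <- function(rr) {
  n <- length(rr)
  m <- sum(rr) / n
  d <- rr[-1] - rr[-n]
  c(mean_nn = m,
    sdnn = sqrt(sum((rr - m)^2) / n),
    rmssd = sqrt(sum(d^2) / (n - 1)),
    sdsd = sqrt(sum((d - sum(d) / (n - 1))^2) / (n - 1)),
    pnn20 = sum(abs(d) > 20) / (n - 1),
    pnn50 = sum(abs(d) > 50) / (n - 1))
}

# Sample entropy by naive template counting (triple loop).
oracle_sampen <- function(x, m = 2L, r = 0.2) {
  n <- length(x)
  s <- sqrt(mean((x - mean(x))^2))
  tol <- if (s > 0) r * s else r
  count_matches <- function(len) {
    cnt <- 0L
    for (i in 1:(n - m - 1L)) {
      for (j in (i + 1L):(n - m)) {
        ok <- TRUE
        for (k in 0:(len - 1L)) {
          if (abs(x[i + k] - x[j + k]) > tol) { ok <- FALSE; break }
        }
        if (ok) cnt <- cnt + 1L
      }
    }
    cnt
  }
  B <- count_matches(m)
  A <- count_matches(m + 1L)
  if (B == 0L || A == 0L) return(NA_real_)
  -log(A / B)
}

# Natural visibility adjacency by checking every intermediate point
# against the straight line between a and b (strict inequality).
oracle_vg_adjacency <- function(t, y) {
  n <- length(y)
  adj <- matrix(FALSE, n, n)
  for (a in 1:(n - 1L)) {
    for (b in (a + 1L):n) {
      visible <- TRUE
      if (b > a + 1L) {
        for (cc in (a + 1L):(b - 1L)) {
          line <- y[b] + (y[a] - y[b]) * (t[b] - t[cc]) / (t[b] - t[a])
          if (y[cc] >= line) { visible <- FALSE; break }
        }
      }
      adj[a, b] <- adj[b, a] <- visible
    }
  }
  adj
}

# Exact two-sided rank-sum p-value by enumerating all group assignments.
oracle_rank_perm_p <- function(g1, g2) {
  all_v <- c(g1, g2)
  n1 <- length(g1)
  idx <- utils::combn(length(all_v), n1)
  obs <- sum(rank(all_v)[seq_len(n1)])
  stats <- apply(idx, 2, function(i) sum(rank(all_v)[i]))
  center <- n1 * (length(all_v) + 1) / 2
  mean(abs(stats - center) >= abs(obs - center) - 1e-9)
}

# Adjacency matrix of the package's visibility construction, for
# comparison with the oracle.
package_vg_adjacency <- function(t, y) {
  n <- length(y)
  edges <- neomat:::visibility_edges(t, y)
  adj <- matrix(FALSE, n, n)
  adj[edges] <- TRUE
  adj | t(adj)
}

# Synthetic feature table: `n_informative` features affine in PMA with
# noise, `n_noise` pure-noise features; grouped by patient.
make_feature_table <- function(n_patients = 40, segs_per_patient = 3,
                               n_informative = 3, n_noise = 17,
                               info_noise_sd = 0.1, seed = 1) {
  set.seed(seed)
  rows <- n_patients * segs_per_patient
  pid <- rep(sprintf("P%03d", seq_len(n_patients)), each = segs_per_patient)
  pma <- rep(runif(n_patients, 30, 38), each = segs_per_patient) +
    rnorm(rows, 0, 0.2)
  ga <- rep(runif(n_patients, 24, 30), each = segs_per_patient)
  tab <- data.frame(patient_id = pid, pma_weeks = pma, ga_weeks = ga,
                    stringsAsFactors = FALSE)
  for (i in seq_len(n_informative)) {
    tab[[sprintf("info_%d", i)]] <- pma + rnorm(rows, 0, info_noise_sd)
  }
  for (i in seq_len(n_noise)) {
    tab[[sprintf("noise_%02d", i)]] <- rnorm(rows)
  }
  tab
}

# Small ASQ data.frame builder: `responses` is a named list mapping domain
# to a character vector of 6 tokens.
make_asq_record <- function(responses = list(), age_months = 24) {
  rec <- data.frame(patient_id = "A1", asq_age_months = age_months,
                    stringsAsFactors = FALSE)
  for (dom in asq_domains()) {
    toks <- if (dom %in% names(responses)) responses[[dom]] else
      rep("yes", 6)
    for (i in 1:6) rec[[paste0(dom, "_", i)]] <- toks[i]
  }
  rec
}

# Items that sum to a given domain score (multiples of 5, 0..60).
items_for_score <- function(score) {
  n10 <- score %/% 10
  n5 <- (score - 10 * n10) %/% 5
  c(rep("yes", n10), rep("sometimes", n5), rep("not_yet", 6 - n10 - n5))
}
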