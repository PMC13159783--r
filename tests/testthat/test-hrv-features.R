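test_that("time-domain features match the arithmetic oracle", {
  rr <- c(400, 410, 405, 420, 400)
  expect_equal(time_domain(rr)[c("mean_nn", "rmssd", "pnn20", "pnn50")],
               oracle_time_domain(rr)[c("mean_nn", "rmssd", "pnn20",
                                        "pnn50")])
  # population-sd convention differs from the oracle's sample-sd only for
  # sdnn/sdsd; check those against direct population formulas
  expect_equal(unname(time_domain(rr)["sdnn"]),
               sqrt(mean((rr - mean(rr))^2)))

  set.seed(21)
  for (i in 1:5) {
    r <- rnorm(50, 400, 20)
    got <- time_domain(r)
    expect_equal(unname(got["rmssd"]), sqrt(mean(diff(r)^2)))
    expect_equal(unname(got["pnn20"]), mean(abs(diff(r)) > 20))
  }

  const <- time_domain(rep(400, 10))
  expect_equal(unname(const[c("sdnn", "rmssd", "pnn50")]), c(0, 0, 0))
  alt <- time_domain(rep(c(400, 420), 10))
  expect_equal(unname(alt["rmssd"]), 20)
  expect_error(time_domain(400), "at least 2")
})

test_that("Poincare identities hold exactly", {
  set.seed(4)
  for (i in 1:5) {
    rr <- rnorm(1000, 400, 25)
    p <- poincare(rr)
    td <- time_domain(rr)
    expect_equal(unname(p["sd1"]), unname(td["rmssd"]) / sqrt(2),
                 tolerance = 1e-9)
    expect_equal(unname(p["sd1"]^2 + p["sd2"]^2),
                 unname(2 * td["sdnn"]^2), tolerance = 1e-6)
  }
  pc <- poincare(rep(400, 10))
  expect_equal(unname(pc[c("sd1", "sd2")]), c(0, 0))
  expect_true(is.na(pc["sd1_sd2_ratio"]))
  expect_match(attr(pc, "reasons")[["sd1_sd2_ratio"]], "degenerate")
})

test_that("spectral band powers concentrate at the modulation frequency", {
  t <- cumsum(rep(0.4, 1500))
  lf_mod <- 400 + 10 * sin(2 * pi * 0.1 * t)
  fd <- frequency_domain(t, lf_mod)
  expect_gt(fd[["lf_power"]] / fd[["total_power"]], 0.9)

  hf_mod <- 400 + 10 * sin(2 * pi * 0.5 * t)
  fdh <- frequency_domain(t, hf_mod)
  expect_gt(fdh[["hf_power"]], fdh[["lf_power"]])

  const <- frequency_domain(t, rep(400, length(t)))
  expect_lt(const[["lf_power"]], 1e-6)
  expect_lt(const[["hf_power"]], 1e-6)
  expect_true(is.na(const[["lf_hf_ratio"]]))
  expect_match(attr(const, "reasons")[["lf_hf_ratio"]], "zero")

  expect_error(frequency_domain(t[1:50], lf_mod[1:50]), "64")
  expect_error(frequency_domain(t, lf_mod,
                                bands = list(lf = c(0.04, 0.3),
                                             hf = c(0.2, 2))),
               "disjoint")
})

test_that("sample entropy equals the brute-force oracle exactly", {
  set.seed(31)
  for (i in 1:5) {
    x <- rnorm(60, 400, 15)
    expect_equal(unname(sample_entropy(x)["sampen"]), oracle_sampen(x))
  }
  x100 <- rnorm(100, 400, 15)
  expect_equal(unname(sample_entropy(x100)["sampen"]), oracle_sampen(x100))

  expect_equal(unname(sample_entropy(rep(7, 40))["sampen"]), 0)
  ramp <- seq(1, 40)  # gaps of 1, tolerance covers them
  expect_equal(unname(sample_entropy(ramp, r = 5)["sampen"]), 0)
  expect_error(sample_entropy(c(1, 2, 3), m = 2), "length")
})

test_that("DFA exponents sit at their theoretical values", {
  set.seed(12)
  wn <- rnorm(10000)
  a <- dfa(wn)
  expect_gt(a[["dfa_alpha1"]], 0.4); expect_lt(a[["dfa_alpha1"]], 0.6)

  iw <- cumsum(rnorm(10000))
  ai <- dfa(iw)
  expect_gt(ai[["dfa_alpha1"]], 1.3); expect_lt(ai[["dfa_alpha1"]], 1.7)

  # doubling the data leaves the exponents essentially unchanged
  x <- rnorm(2000)
  expect_equal(dfa(rep(x, 2))[["dfa_alpha1"]], dfa(x)[["dfa_alpha1"]],
               tolerance = 0.05)
  expect_error(dfa(rnorm(50)), "100")
  # a scale range needing >= 4 boxes per scale cannot be populated here
  short <- dfa(rnorm(150), scales2 = c(80, 100, 120))
  expect_true(is.na(short[["dfa_alpha2"]]))
  expect_match(attr(short, "reasons")[["dfa_alpha2"]], "insufficient")
})

test_that("visibility graph matches the all-pairs oracle", {
  # strictly convex series: complete graph
  conv <- visibility_graph((1:40)^2)
  expect_equal(unname(conv["vg_mean_degree"]), 39)
  # constant series: path graph under strict inequality
  const <- visibility_graph(rep(5, 40))
  expect_equal(unname(const["vg_mean_degree"]), 2 * 39 / 40)

  set.seed(17)
  for (i in 1:3) {
    y <- rnorm(50)
    t <- sort(runif(50, 0, 10))
    expect_identical(package_vg_adjacency(t, y), oracle_vg_adjacency(t, y))
  }
  short <- visibility_graph(rnorm(5))
  expect_true(all(is.na(short)))
  expect_match(attr(short, "reasons")[["vg_mean_degree"]], "10")
})

test_that("dimensionless features are invariant to consistent rescaling", {
  set.seed(23)
  rr <- 400 + cumsum(rnorm(600, 0, 4))
  rr <- pmax(rr, 200)
  t <- cumsum(rr) / 1000
  k <- 1000
  seg1 <- list(patient_id = "p", pma_weeks = 34, beat_times = t, rr_ms = rr)
  seg2 <- list(patient_id = "p", pma_weeks = 34, beat_times = t * k,
               rr_ms = rr * k)
  dimless <- c("sampen", "dfa_alpha1", "sd1_sd2_ratio", "vg_mean_degree",
               "vg_degree_sd", "vg_assortativity")
  f1 <- extract_features(seg1, dimless)
  f2 <- extract_features(seg2, dimless)
  expect_equal(as.numeric(f1), as.numeric(f2), tolerance = 1e-8)
})

test_that("extract_features honours the registry contract", {
  rr <- 400 + 10 * sin(2 * pi * 0.1 * cumsum(rep(0.4, 1200)))
  seg <- list(patient_id = "p", pma_weeks = 34,
              beat_times = cumsum(rr) / 1000, rr_ms = rr)
  f <- extract_features(seg, c("sdnn", "sampen"))
  expect_named(f, c("sdnn", "sampen"))
  expect_error(extract_features(seg, c("sdnn", "foo")), "registry")
  expect_identical(as.numeric(extract_features(seg, c("sdnn", "sampen"))),
                   as.numeric(f))
})

test_that("all features are finite on clean synthetic segments", {
  for (i in 1:8) {
    cfg <- rr_gen_config(pma_weeks = 30 + i, duration_s = 620,
                         ectopic_rate = 0, seed = 900 + i)
    s <- generate_rr_series(cfg)
    f <- extract_features(s)
    # degree assortativity may be legitimately undefined; everything else
    # must be a finite number on clean data
    finite_required <- setdiff(hrv_feature_registry(), "vg_assortativity")
    expect_true(all(is.finite(f[finite_required])),
                info = paste("seed", 900 + i))
  }
})
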