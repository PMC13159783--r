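test_that("delta is the signed PMA - FMA difference", {
  expect_equal(compute_delta(34, 31.7), 2.3)
  expect_equal(compute_delta(33, 33), 0)
  expect_equal(compute_delta(33, 34), -1)
  expect_equal(compute_delta(34, 31.7), -compute_delta(31.7, 34))
  expect_error(compute_delta(NA, 34), "finite")
  expect_error(compute_delta(34, Inf), "finite")
})

test_that("IQR fences remove only genuine outliers", {
  res <- remove_outliers(c(1, 2, 3, 4, 100))
  expect_equal(res$removed, 100)
  expect_equal(res$retained, c(1, 2, 3, 4))
  expect_equal(res$fences, c(2 - 1.5 * 2, 4 + 1.5 * 2))

  none <- remove_outliers(c(1, 2, 3, 4, 5))
  expect_length(none$removed, 0)

  equal <- remove_outliers(rep(3.3, 6))
  expect_length(equal$removed, 0)

  expect_warning(short <- remove_outliers(c(1, 2, 100)), "fewer than 4")
  expect_equal(short$retained, c(1, 2, 100))

  # single pass with frozen fences: re-applying removes nothing more
  again <- remove_outliers(res$retained)
  expect_length(again$removed, 0)
})

test_that("per-patient outlier removal uses each patient's own fences", {
  obs <- data.frame(
    patient_id = rep(c("a", "b"), each = 5),
    pma_weeks = rep(32:36, 2),
    fma_weeks = c(30, 31, 32, 33, 60, 31, 32, 33, 34, 35))
  out <- remove_outliers_by_patient(obs)
  expect_equal(attr(out, "n_removed"), 1L)
  expect_false(60 %in% out$fma_weeks)
  expect_equal(sum(out$patient_id == "b"), 5L)
})

simulate_delta_obs <- function(n_pat = 60, visits = 32:36, slope = 0.3,
                               ri_sd = 0.8, resid_sd = 0.3,
                               bpd_effect = 0, seed = 1) {
  set.seed(seed)
  bpd <- rbinom(n_pat, 1, 0.34)
  ri <- rnorm(n_pat, 0, ri_sd)
  rows <- expand.grid(patient_id = sprintf("p%03d", 1:n_pat),
                      pma_weeks = visits, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  i <- match(rows$patient_id, sprintf("p%03d", 1:n_pat))
  rows$bpd <- bpd[i]
  rows$iugr <- 0L
  rows$neuro_lesions <- 0L
  rows$pda <- 0L
  rows$delta_weeks <- 2 + ri[i] + slope * (rows$pma_weeks - 34) +
    bpd_effect * rows$bpd + rnorm(nrow(rows), 0, resid_sd)
  rows
}

test_that("the mixed model recovers a noiseless common line exactly", {
  obs <- simulate_delta_obs(n_pat = 20, ri_sd = 0, resid_sd = 0, seed = 2)
  fit <- suppressWarnings(fit_mixed_model(obs))
  est <- setNames(fit$effects$estimate, fit$effects$term)
  expect_equal(unname(est["(Intercept)"]), 2, tolerance = 1e-6)
  expect_equal(unname(est["pma_c"]), 0.3, tolerance = 1e-6)
})

test_that("fixed-effect estimates and CIs behave over replicates", {
  hits <- 0L
  bpd_est <- numeric(40)
  for (r in 1:40) {
    obs <- simulate_delta_obs(n_pat = 80, bpd_effect = 0.8, seed = 100 + r)
    fit <- fit_mixed_model(obs, covariates = "bpd")
    eff <- fit$effects[fit$effects$term == "pma_c", ]
    if (eff$ci_low <= 0.3 && 0.3 <= eff$ci_high) hits <- hits + 1L
    bpd_est[r] <- fit$effects$estimate[fit$effects$term == "bpd"]
  }
  expect_gte(hits / 40, 0.9)
  expect_lt(abs(mean(bpd_est) - 0.8), 0.1)
})

test_that("interpolation at 34 weeks returns patient-specific BLUPs", {
  # noiseless patient on the line 2 + 0.5 * (pma - 34)
  obs <- simulate_delta_obs(n_pat = 30, ri_sd = 0.6, resid_sd = 0.2,
                            seed = 5)
  special <- obs$patient_id == "p001"
  obs$delta_weeks[special] <- 2 + 0.5 * (obs$pma_weeks[special] - 34)
  fit <- fit_mixed_model(obs)
  d34 <- interpolate_at_34(fit, "p001")
  expect_equal(d34$delta34_weeks, 2, tolerance = 0.15)

  all34 <- interpolate_at_34(fit)
  expect_equal(nrow(all34), 30)
  expect_error(interpolate_at_34(fit, "nobody"), "not in the fitted")
})

test_that("duplicate patients interpolate identically", {
  obs <- simulate_delta_obs(n_pat = 15, seed = 7)
  twin <- obs[obs$patient_id == "p002", ]
  twin$patient_id <- "p999"
  fit <- fit_mixed_model(rbind(obs, twin))
  d <- interpolate_at_34(fit, c("p002", "p999"))
  expect_equal(d$delta34_weeks[1], d$delta34_weeks[2], tolerance = 1e-8)
})

test_that("conditional predictions shrink toward the population line", {
  set.seed(9)
  # one deviant patient observed with decreasing data support
  base <- simulate_delta_obs(n_pat = 40, ri_sd = 0.5, resid_sd = 0.4,
                             seed = 9)
  gaps <- c(5, 3, 2)
  dev <- sapply(gaps, function(k) {
    extra <- data.frame(patient_id = "dev", pma_weeks = (32:36)[1:k],
                        bpd = 0L, iugr = 0L, neuro_lesions = 0L, pda = 0L,
                        delta_weeks = 4 + 0.3 * ((32:36)[1:k] - 34))
    fit <- fit_mixed_model(rbind(base, extra))
    interpolate_at_34(fit, "dev")$delta34_weeks
  })
  pop_mean <- mean(base$delta_weeks[base$pma_weeks == 34])
  # fewer observations -> prediction pulled further from 4 toward the mean
  expect_true(all(diff(abs(dev - pop_mean)) <= 1e-8))
})

test_that("the full trajectory stage recovers latent delays", {
  co <- generate_cohort(cohort_gen_config(n_infants = 300, seed = 13))
  obs <- generate_trajectories(co, 32:36, noise_sd = 0.3, seed = 14)
  obs <- merge(obs, co[c("patient_id", "iugr", "bpd", "neuro_lesions",
                         "pda")], by = "patient_id")
  res <- delta_trajectory(obs)
  d <- merge(res$delta34, co[c("patient_id", "delta34_true")],
             by = "patient_id")
  expect_gte(cor(d$delta34_weeks, d$delta34_true), 0.9)
})
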