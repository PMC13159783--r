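test_that("RR generator honours degenerate and deterministic contracts", {
  cfg0 <- rr_gen_config(mean_rr_ms = 400, duration_s = 120, sdnn_scale_ms = 0,
                        hf_amp_ms = 0, lf_amp_ms = 0, ectopic_rate = 0,
                        seed = 1)
  s0 <- generate_rr_series(cfg0)
  expect_true(all(s0$rr_ms == 400))
  expect_true(all(diff(s0$beat_times) > 0))

  cfg <- rr_gen_config(duration_s = 600, seed = 42)
  expect_identical(generate_rr_series(cfg), generate_rr_series(cfg))
  expect_false(identical(generate_rr_series(cfg),
                         generate_rr_series(rr_gen_config(duration_s = 600,
                                                          seed = 43))))
})

test_that("RR sample mean converges to the configured baseline", {
  cfg <- rr_gen_config(mean_rr_ms = 400, duration_s = 1800,
                       sdnn_scale_ms = 8, hf_amp_ms = 0, lf_amp_ms = 0,
                       ectopic_rate = 0, seed = 7)
  s <- generate_rr_series(cfg)
  expect_gt(length(s), 4000)
  expect_lt(abs(mean(s$rr_ms) - 400), 1)
})

test_that("invalid generator configs fail naming the field", {
  expect_error(rr_gen_config(duration_s = 0), "duration_s")
  expect_error(rr_gen_config(mean_rr_ms = -5), "mean_rr_ms")
  expect_error(rr_gen_config(ectopic_rate = 1), "ectopic_rate")
  expect_error(rr_gen_config(hf_amp_ms = -1), "hf_amp_ms")
  expect_error(cohort_gen_config(n_infants = 0), "n_infants")
  expect_error(cohort_gen_config(ga_distribution = c(0.5, 0.4, 0.2)),
               "ga_distribution")
})

test_that("cohort prevalences converge to configured values", {
  co <- generate_cohort(cohort_gen_config(n_infants = 10000, seed = 5))
  expect_lt(abs(mean(co$sex == "male") - 0.515), 0.02)
  expect_lt(abs(mean(co$pda) - 0.652), 0.02)
  expect_lt(abs(mean(co$bpd) - 0.34), 0.02)
  expect_lt(abs(mean(co$ga_stratum == "lt26") - 0.235), 0.02)
})

test_that("follow-up flag behaves at the boundary rates", {
  co <- generate_cohort(cohort_gen_config(n_infants = 200, followup_rate = 1,
                                          seed = 2))
  expect_true(all(co$followup))
  expect_true(all(!is.na(co$asq_personal_social_abnormal)))
  co0 <- generate_cohort(cohort_gen_config(n_infants = 200,
                                           followup_rate = 0, seed = 2))
  expect_true(all(is.na(co0$asq_personal_social_abnormal)))
})

test_that("zero ASQ slopes decouple outcomes from the delay", {
  null_effects <- default_asq_effects()
  null_effects$personal_social <- list(intercept = qlogis(0.2), slope = 0)
  n_sig <- 0L
  for (rep in 1:60) {
    co <- generate_cohort(cohort_gen_config(
      n_infants = 300, asq_effects = null_effects, followup_rate = 1,
      seed = 5000 + rep))
    hi <- co$delta34_true > median(co$delta34_true)
    tab <- table(hi, co$asq_personal_social_abnormal)
    if (all(dim(tab) == c(2, 2)) &&
        categorical_assoc(tab)$p_value < 0.05) {
      n_sig <- n_sig + 1L
    }
  }
  expect_lt(n_sig / 60, 0.15)
})

test_that("ASQ outcomes follow the configured logistic law at scale", {
  co <- generate_cohort(cohort_gen_config(n_infants = 30000,
                                          followup_rate = 1, seed = 9))
  eff <- default_asq_effects()$personal_social
  slope_cond <- eff$slope *
    sqrt(1 + 0.346 * (eff$covariates[["tobacco"]]^2 * 0.106 * 0.894 +
                        eff$covariates[["neuro_lesions"]]^2 * 0.28 * 0.72))
  fit <- glm(asq_personal_social_abnormal ~ delta34_true + tobacco +
               neuro_lesions, family = binomial(), data = co)
  est <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  expect_lt(abs(est[["delta34_true"]] - slope_cond),
            3 * se[["delta34_true"]])
  expect_lt(abs(est[["tobacco"]] - log(9.57)), 3 * se[["tobacco"]])
  expect_lt(abs(est[["neuro_lesions"]] - log(7.72)),
            3 * se[["neuro_lesions"]])
})

test_that("trajectory generator reproduces the latent delay at 34 weeks", {
  rec <- list(patient_id = "X", delta34_true = 2.3)
  tr <- generate_trajectory(rec, c(32, 34, 36), noise_sd = 0, seed = 1)
  expect_equal(tr$delta_weeks[tr$pma_weeks == 34], 2.3)
  expect_true(all(diff(tr$delta_weeks) > 0))  # delay grows with age

  rec0 <- list(patient_id = "Y", delta34_true = 0)
  tr0 <- generate_trajectory(rec0, 32:36, slope = 0, noise_sd = 0, seed = 1)
  expect_true(all(tr0$delta_weeks == 0))

  expect_error(generate_trajectory(rec, numeric(0)), "at least one")
  expect_error(generate_trajectory(rec, c(27, 34)), "pma_grid")
})

test_that("trajectory observation noise has the configured spread", {
  co <- generate_cohort(cohort_gen_config(n_infants = 1000, seed = 3))
  obs <- generate_trajectories(co, 34, slope = 0.3, noise_sd = 0.5,
                               seed = 11)
  resid <- obs$delta_weeks - co$delta34_true[match(obs$patient_id,
                                                   co$patient_id)]
  expect_lt(abs(sd(resid) - 0.5), 0.05)
})

test_that("beat files round-trip through write_rr and read_rr", {
  s <- generate_rr_series(rr_gen_config(duration_s = 120, seed = 3), "P1")
  f <- tempfile(fileext = ".rr")
  write_rr(s, f)
  back <- read_rr(f, patient_id = "P1", pma_weeks = s$pma_weeks)
  expect_equal(back$rr_ms, s$rr_ms, tolerance = 1e-5)
  expect_equal(back$beat_times, s$beat_times, tolerance = 1e-5)
  unlink(f)
})
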