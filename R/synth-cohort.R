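#' Configuration for a synthetic very-preterm cohort
#'
#' Encodes the cohort structure the downstream analyses assume: gestational
#' age (GA) strata for infants born before 30 weeks, perinatal covariate
#' prevalences, a latent maturation-delay model (the true delta at 34 weeks
#' post-menstrual age for each infant), and per-domain logistic models for
#' abnormal ASQ-3 outcomes at 2 years.
#'
#' The delay model draws the latent 34-week delay from a log-normal
#' distribution per GA stratum (medians 3.0, 2.3 and 1.3 weeks for the
#' `<26`, `26-<28` and `>=28`-week strata; log-scale spreads matched to the
#' corresponding interquartile ranges), then adds mean-centered additive
#' shifts for bronchopulmonary dysplasia (BPD) and patent ductus arteriosus
#' (PDA) so that infants with those complications are more delayed without
#' moving the stratum medians. ASQ-3 abnormality flags are Bernoulli draws
#' from `plogis(intercept + slope * delta34 + covariate terms)`; the default
#' personal-social slope corresponds to an odds ratio of 2.05 per week of
#' delay, with additional tobacco and neurological-lesion log-odds.
#'
#' @param n_infants Number of infants (>= 1).
#' @param ga_distribution Probabilities over the three GA strata
#'   (`lt26`, `ga26_28`, `ge28`); must sum to 1.
#' @param covariate_prevalences Named probabilities for binary covariates
#'   (`male`, `iugr`, `bpd`, `pda`, `neuro_lesions`, `tobacco`).
#' @param delay_model List with `medians` (per-stratum median delay at 34
#'   weeks), `log_sigmas` (log-normal sd per stratum), `bpd_effect` and
#'   `pda_effect` (additive weeks, applied centered at the prevalence).
#' @param asq_effects Named list per ASQ domain, each with `intercept`
#'   (log-odds), `slope` (log-odds per week of delta34) and optional
#'   `covariates` (named log-odds for binary covariates).
#' @param followup_rate Probability that the 2-year ASQ is available.
#' @param seed Integer seed.
#' @return An object of class `cohort_gen_config`.
#' @export
cohort_gen_config <- function(n_infants = 132,
                              ga_distribution = c(lt26 = 0.235,
                                                  ga26_28 = 0.394,
                                                  ge28 = 0.371),
                              covariate_prevalences = c(male = 0.515,
                                                        iugr = 0.25,
                                                        bpd = 0.34,
                                                        pda = 0.652,
                                                        neuro_lesions = 0.28,
                                                        tobacco = 0.106),
                              delay_model = list(
                                medians = c(lt26 = 3.0, ga26_28 = 2.3,
                                            ge28 = 1.3),
                                log_sigmas = c(lt26 = 0.391, ga26_28 = 0.620,
                                               ge28 = 0.814),
                                bpd_effect = 0.8,
                                pda_effect = 0.8),
                              asq_effects = default_asq_effects(),
                              followup_rate = 0.66,
                              seed = 1L) {
  if (!is.numeric(n_infants) || length(n_infants) != 1L || n_infants < 1) {
    stop_invalid("n_infants", "must be >= 1")
  }
  if (length(ga_distribution) != 3L || any(ga_distribution < 0) ||
      any(ga_distribution > 1) ||
      abs(sum(ga_distribution) - 1) > 1e-8) {
    stop_invalid("ga_distribution", "must be 3 probabilities summing to 1")
  }
  if (any(covariate_prevalences < 0) || any(covariate_prevalences > 1)) {
    stop_invalid("covariate_prevalences", "probabilities must lie in [0, 1]")
  }
  check_scalar(followup_rate, "followup_rate", 0, 1)
  stopifnot(length(delay_model$medians) == 3L,
            length(delay_model$log_sigmas) == 3L)
  structure(
    list(n_infants = as.integer(n_infants),
         ga_distribution = ga_distribution,
         covariate_prevalences = covariate_prevalences,
         delay_model = delay_model,
         asq_effects = asq_effects,
         followup_rate = followup_rate,
         seed = as.integer(seed)),
    class = "cohort_gen_config"
  )
}

#' Default per-domain ASQ-3 outcome models
#'
#' Intercepts reproduce the observed abnormality rates of each domain in a
#' cohort with median delay near 2.3 weeks; the personal-social domain
#' carries the delay effect (odds ratio 2.05 per week) plus tobacco and
#' neurological-lesion effects, the other domains are delay-independent.
#'
#' @return Named list of per-domain effect specifications.
#' @export
default_asq_effects <- function() {
  list(
    communication = list(intercept = qlogis(0.23), slope = 0),
    gross_motor = list(intercept = qlogis(0.058), slope = 0),
    fine_motor = list(intercept = qlogis(0.005), slope = 0),
    problem_solving = list(intercept = qlogis(0.046), slope = 0),
    personal_social = list(
      intercept = -7.072,
      slope = log(2.05),
      covariates = c(tobacco = log(9.57), neuro_lesions = log(7.72)))
  )
}

#' Generate a synthetic preterm cohort
#'
#' One row per infant with GA, binary perinatal covariates, the latent true
#' maturation delay at 34 weeks PMA (`delta34_true`), a follow-up indicator
#' and per-domain ASQ abnormality flags (NA when follow-up is missing).
#'
#' @param config A [cohort_gen_config()] object.
#' @return A data.frame of class `infant_cohort`.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_gen_config")) {
    stop("'config' must be a cohort_gen_config object", call. = FALSE)
  }
  n <- config$n_infants
  with_seed(config$seed, {
    strata <- sample(names(config$ga_distribution), n, replace = TRUE,
                     prob = config$ga_distribution)
    ga_lo <- c(lt26 = 24, ga26_28 = 26, ge28 = 28)[strata]
    ga_weeks <- ga_lo + runif(n) * 2

    cov <- lapply(config$covariate_prevalences, function(p) {
      as.integer(runif(n) < p)
    })
    dm <- config$delay_model
    med <- dm$medians[strata]
    sig <- dm$log_sigmas[strata]
    delta34 <- exp(rnorm(n, log(med), sig)) +
      dm$bpd_effect * (cov$bpd - config$covariate_prevalences[["bpd"]]) +
      dm$pda_effect * (cov$pda - config$covariate_prevalences[["pda"]])

    followup <- runif(n) < config$followup_rate
    out <- data.frame(
      patient_id = sprintf("P%04d", seq_len(n)),
      ga_weeks = ga_weeks,
      ga_stratum = factor(strata, levels = c("lt26", "ga26_28", "ge28")),
      stringsAsFactors = FALSE
    )
    out$sex <- ifelse(cov$male == 1L, "male", "female")
    for (nm in setdiff(names(cov), "male")) out[[nm]] <- cov[[nm]]
    out$delta34_true <- as.numeric(delta34)
    out$followup <- followup
    for (dom in names(config$asq_effects)) {
      eff <- config$asq_effects[[dom]]
      # The configured slope is the marginal (univariate) log-odds per week,
      # the scale on which cohort studies report it. When conditional
      # covariate effects are also configured, marginalizing over them
      # attenuates a logistic slope (non-collapsibility); the conditional
      # slope used for generation is therefore inflated by the standard
      # logit approximation sqrt(1 + 0.346 * var(omitted linear predictor))
      # so that the univariate analysis recovers the configured value.
      sigma2_u <- 0
      for (cv in names(eff$covariates)) {
        pcv <- config$covariate_prevalences[[cv]]
        sigma2_u <- sigma2_u + eff$covariates[[cv]]^2 * pcv * (1 - pcv)
      }
      slope_cond <- eff$slope * sqrt(1 + 0.346 * sigma2_u)
      eta <- eff$intercept + slope_cond * out$delta34_true
      for (cv in names(eff$covariates)) {
        eta <- eta + eff$covariates[[cv]] * out[[cv]]
      }
      flag <- runif(n) < plogis(eta)
      flag[!followup] <- NA
      out[[paste0("asq_", dom, "_abnormal")]] <- flag
    }
    class(out) <- c("infant_cohort", "data.frame")
    attr(out, "config") <- config
    out
  })
}

#' Generate maturation-delay observations for one infant
#'
#' Emits (patient, PMA, FMA, delta) tuples over a PMA grid. The latent
#' delay grows linearly with postnatal age and equals the infant's
#' `delta34_true` at 34 weeks; functional maturation age is
#' `FMA = PMA - delay(PMA)` plus Gaussian observation noise.
#'
#' @param record One-row data.frame (or list) with at least `patient_id`
#'   and `delta34_true`.
#' @param pma_grid PMA values in weeks, all within \code{[28, 40]}.
#' @param slope Growth of the delay per week of PMA (weeks/week).
#' @param noise_sd Observation noise sd on FMA, in weeks.
#' @param seed Integer seed.
#' @return data.frame with `patient_id`, `pma_weeks`, `fma_weeks`,
#'   `delta_weeks`.
#' @export
generate_trajectory <- function(record, pma_grid, slope = 0.3,
                                noise_sd = 0.3, seed = 1L) {
  if (length(pma_grid) == 0L) {
    stop("'pma_grid' must contain at least one PMA value", call. = FALSE)
  }
  if (any(pma_grid < 28 | pma_grid > 40)) {
    stop_invalid("pma_grid", "values must lie within [28, 40] weeks")
  }
  delay <- record$delta34_true + slope * (pma_grid - 34)
  noise <- with_seed(seed, rnorm(length(pma_grid), 0, noise_sd))
  fma <- pma_grid - delay + noise
  data.frame(patient_id = rep(record$patient_id, length(pma_grid)),
             pma_weeks = as.numeric(pma_grid),
             fma_weeks = as.numeric(fma),
             delta_weeks = as.numeric(pma_grid - fma),
             stringsAsFactors = FALSE)
}

#' Generate trajectories for a whole cohort
#'
#' Applies [generate_trajectory()] to every infant with per-infant seeds
#' derived deterministically from `seed`.
#'
#' @param cohort An `infant_cohort` data.frame.
#' @inheritParams generate_trajectory
#' @return Long data.frame of delta observations for all infants.
#' @export
generate_trajectories <- function(cohort, pma_grid, slope = 0.3,
                                  noise_sd = 0.3, seed = 1L) {
  rows <- lapply(seq_len(nrow(cohort)), function(i) {
    generate_trajectory(cohort[i, ], pma_grid, slope = slope,
                        noise_sd = noise_sd, seed = derive_seed(seed, i))
  })
  do.call(rbind, rows)
}

#' Attach item-level ASQ-3 responses consistent with the abnormality flags
#'
#' For each domain with a non-missing abnormality flag, draws a domain score
#' (multiple of 5 in 0-60, below the domain threshold when abnormal, at or
#' above it otherwise) and decomposes it into six item responses
#' (`yes` = 10, `sometimes` = 5, `not_yet` = 0), shuffled across item
#' positions. A completion age in months is drawn uniformly in [21, 26].
#'
#' @param cohort An `infant_cohort` data.frame with `asq_*_abnormal` flags.
#' @param seed Integer seed.
#' @return `cohort` with added `asq_age_months` and `<domain>_<i>` item
#'   columns (NA for infants without follow-up).
#' @export
generate_asq_items <- function(cohort, seed = 1L) {
  domains <- asq_domains()
  thresholds <- asq_thresholds()
  with_seed(seed, {
    n <- nrow(cohort)
    cohort$asq_age_months <- ifelse(cohort$followup,
                                    round(runif(n, 21, 26), 1), NA_real_)
    for (dom in domains) {
      flag <- cohort[[paste0("asq_", dom, "_abnormal")]]
      items <- matrix(NA_character_, nrow = n, ncol = 6)
      for (i in seq_len(n)) {
        if (is.na(flag[i])) next
        thr <- thresholds[[dom]]
        score <- if (flag[i]) {
          5 * sample.int(thr / 5, 1L) - 5          # in {0, ..., thr - 5}
        } else {
          thr + 5 * (sample.int((60 - thr) / 5 + 1L, 1L) - 1L)
        }
        n10 <- score %/% 10
        n5 <- (score - 10 * n10) %/% 5
        resp <- c(rep("yes", n10), rep("sometimes", n5),
                  rep("not_yet", 6 - n10 - n5))
        items[i, ] <- sample(resp)
      }
      colnames(items) <- paste0(dom, "_", 1:6)
      cohort <- cbind(cohort, as.data.frame(items, stringsAsFactors = FALSE))
    }
    class(cohort) <- c("infant_cohort", "data.frame")
    cohort
  })
}

#' Write a cohort table to CSV
#'
#' @param cohort An `infant_cohort` data.frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  write.csv(as.data.frame(cohort), path, row.names = FALSE, na = "")
  invisible(path)
}
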