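#' Maturation delay from PMA and estimated FMA
#'
#' `delta = PMA - FMA` in weeks; positive values mean the autonomic network
#' lags chronological (post-menstrual) age.
#'
#' @param pma_weeks,fma_weeks Finite numeric vectors (recycled).
#' @return `pma_weeks - fma_weeks`.
#' @export
compute_delta <- function(pma_weeks, fma_weeks) {
  if (any(!is.finite(pma_weeks)) || any(!is.finite(fma_weeks))) {
    stop("compute_delta requires finite inputs", call. = FALSE)
  }
  pma_weeks - fma_weeks
}

#' Remove outliers by interquartile fences
#'
#' Single pass: quartiles are computed once from the original values
#' (linear-interpolation convention, R type 7) and values outside
#' `[Q1 - 1.5*IQR, Q3 + 1.5*IQR]` are removed. Fewer than 4 values pass
#' through unchanged with a warning (fences are not meaningful).
#'
#' @param values Numeric vector.
#' @return List with `retained`, `removed` (values), `keep` (logical mask
#'   over the input), `fences` (`c(low, high)` or `NULL`).
#' @export
remove_outliers <- function(values) {
  if (length(values) < 4L) {
    warning("fewer than 4 values; outlier fences not applied")
    return(list(retained = values, removed = numeric(0),
                keep = rep(TRUE, length(values)), fences = NULL))
  }
  q <- quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  fences <- c(q[1] - 1.5 * iqr, q[2] + 1.5 * iqr)
  keep <- values >= fences[1] & values <= fences[2]
  list(retained = values[keep], removed = values[!keep], keep = keep,
       fences = fences)
}

#' Per-patient FMA outlier removal on a long observation table
#'
#' Applies [remove_outliers()] to each patient's FMA values; observations
#' outside that patient's fences are dropped.
#'
#' @param observations data.frame with `patient_id` and `fma_weeks`.
#' @return Filtered data.frame with an attribute `n_removed`.
#' @export
remove_outliers_by_patient <- function(observations) {
  keep <- unlist(lapply(split(seq_len(nrow(observations)),
                              observations$patient_id), function(idx) {
    res <- suppressWarnings(remove_outliers(observations$fma_weeks[idx]))
    idx[res$keep]
  }), use.names = FALSE)
  out <- observations[sort(keep), , drop = FALSE]
  attr(out, "n_removed") <- nrow(observations) - nrow(out)
  out
}

#' Fit the covariate-adjusted linear mixed-effects delta trajectory
#'
#' Models all delta observations in the 32-36 week PMA window as
#' `delta ~ (PMA - 34) + IUGR + BPD + neurological lesions + PDA` with a
#' random intercept per patient (REML). Gestational age is deliberately not
#' a covariate: it already enters the FMA estimate. A singular random-effect
#' fit falls back to a fixed-effects-only model with a warning.
#'
#' @param observations data.frame with `patient_id`, `pma_weeks`,
#'   `delta_weeks` and the covariate columns.
#' @param covariates Covariate column names (binary 0/1). Columns absent
#'   from `observations` are dropped with a warning.
#' @param window PMA window (weeks) retained for modelling.
#' @param random_slope Also give each patient a random PMA slope.
#' @return Object of class `delta_model`: the fit, the modelling frame,
#'   fixed-effect estimates with standard errors and 95% Wald confidence
#'   intervals, variance components, and a `singular` flag.
#' @export
fit_mixed_model <- function(observations,
                            covariates = c("iugr", "bpd", "neuro_lesions",
                                           "pda"),
                            window = c(32, 36), random_slope = FALSE) {
  missing_cov <- setdiff(covariates, names(observations))
  if (length(missing_cov)) {
    warning(sprintf("covariate(s) not in data, dropped: %s",
                    paste(missing_cov, collapse = ", ")))
    covariates <- setdiff(covariates, missing_cov)
  }
  dat <- observations[observations$pma_weeks >= window[1] &
                        observations$pma_weeks <= window[2], , drop = FALSE]
  if (!nrow(dat)) stop("no observations inside the PMA window", call. = FALSE)
  dat$pma_c <- dat$pma_weeks - 34
  n_pat <- length(unique(dat$patient_id))
  if (n_pat < 10L) {
    warning(sprintf("only %d patients; variance components may be unstable",
                    n_pat))
  }
  fixed <- paste(c("pma_c", covariates), collapse = " + ")
  re_term <- if (random_slope) "(1 + pma_c | patient_id)" else
    "(1 | patient_id)"
  form <- as.formula(sprintf("delta_weeks ~ %s + %s", fixed, re_term))
  fit <- tryCatch(
    suppressMessages(lme4::lmer(form, data = dat, REML = TRUE)),
    error = function(e) NULL)
  singular <- is.null(fit) || lme4::isSingular(fit, tol = 1e-5)
  if (is.null(fit)) {
    warning("mixed-model fit failed; falling back to fixed effects only")
    fit <- lm(as.formula(sprintf("delta_weeks ~ %s", fixed)), data = dat)
  } else if (singular) {
    warning("random-effect variance is singular; estimates kept, flagged")
  }
  if (inherits(fit, "merMod")) {
    est <- lme4::fixef(fit)
    se <- sqrt(diag(as.matrix(vcov(fit))))
    vc <- as.data.frame(lme4::VarCorr(fit))
    var_comp <- setNames(vc$vcov, paste(vc$grp, vc$var1, sep = "."))
  } else {
    est <- coef(fit)
    se <- sqrt(diag(vcov(fit)))
    var_comp <- c(Residual = summary(fit)$sigma^2)
  }
  effects <- data.frame(
    term = names(est), estimate = unname(est), se = unname(se),
    ci_low = unname(est - qnorm(0.975) * se),
    ci_high = unname(est + qnorm(0.975) * se),
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(
    list(fit = fit, data = dat, covariates = covariates, window = window,
         effects = effects, var_comp = var_comp, singular = singular),
    class = "delta_model"
  )
}

#' @export
print.delta_model <- function(x, ...) {
  cat(sprintf("<delta_model> %d obs, %d patients, PMA %g-%g wk%s\n",
              nrow(x$data), length(unique(x$data$patient_id)),
              x$window[1], x$window[2],
              if (x$singular) " [singular]" else ""))
  print(x$effects, digits = 3)
  invisible(x)
}

#' Interpolate each patient's maturation delay at 34 weeks PMA
#'
#' Conditional (patient-specific) prediction at PMA = 34: fixed effects
#' evaluated at the patient's own covariates plus the patient's estimated
#' random effect (best linear unbiased prediction). Set
#' `conditional = FALSE` for the marginal population prediction.
#'
#' @param model A `delta_model` from [fit_mixed_model()].
#' @param patient_id Patients to interpolate (default: all in the fit).
#' @param conditional Include the patient's BLUP (default TRUE).
#' @return data.frame with `patient_id`, `delta34_weeks` and the covariate
#'   values used.
#' @export
interpolate_at_34 <- function(model, patient_id = NULL, conditional = TRUE) {
  stopifnot(inherits(model, "delta_model"))
  dat <- model$data
  if (is.null(patient_id)) patient_id <- unique(dat$patient_id)
  unknown <- setdiff(patient_id, dat$patient_id)
  if (length(unknown)) {
    stop(sprintf("patient(s) not in the fitted data: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  first_row <- dat[match(patient_id, dat$patient_id), , drop = FALSE]
  newdata <- first_row[c("patient_id", model$covariates)]
  newdata$pma_c <- 0
  if (inherits(model$fit, "merMod")) {
    pred <- predict(model$fit, newdata = newdata,
                    re.form = if (conditional) NULL else NA)
  } else {
    pred <- predict(model$fit, newdata = newdata)
  }
  out <- data.frame(patient_id = patient_id,
                    delta34_weeks = as.numeric(pred),
                    stringsAsFactors = FALSE)
  cbind(out, first_row[model$covariates])
}

#' Run the full trajectory stage
#'
#' Convenience wrapper: per-patient FMA outlier removal, delta computation,
#' window filtering, mixed-model fit and 34-week interpolation.
#'
#' @param observations data.frame with `patient_id`, `pma_weeks`,
#'   `fma_weeks` and covariate columns.
#' @inheritParams fit_mixed_model
#' @param conditional Passed to [interpolate_at_34()].
#' @return List with `model` (`delta_model`) and `delta34` (data.frame).
#' @export
delta_trajectory <- function(observations,
                             covariates = c("iugr", "bpd", "neuro_lesions",
                                            "pda"),
                             window = c(32, 36), conditional = TRUE) {
  obs <- remove_outliers_by_patient(observations)
  obs$delta_weeks <- compute_delta(obs$pma_weeks, obs$fma_weeks)
  model <- fit_mixed_model(obs, covariates = covariates, window = window)
  list(model = model,
       delta34 = interpolate_at_34(model, conditional = conditional))
}
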