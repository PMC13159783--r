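#' ASQ-3 domains and abnormality thresholds
#'
#' Five parent-reported domains, six items each, 0-60 points per domain.
#' A domain is abnormal below its threshold (more than two standard
#' deviations below the age norm): 35 for communication, 25 for the others.
#'
#' @return Character vector of domain names (`asq_domains`) or named
#'   numeric thresholds (`asq_thresholds`).
#' @export
asq_domains <- function() {
  c("communication", "gross_motor", "fine_motor", "problem_solving",
    "personal_social")
}

#' @rdname asq_domains
#' @export
asq_thresholds <- function() {
  c(communication = 35, gross_motor = 25, fine_motor = 25,
    problem_solving = 25, personal_social = 25)
}

asq_item_points <- function(responses) {
  pts <- c(yes = 10, sometimes = 5, not_yet = 0)
  responses <- as.character(responses)
  responses[is.na(responses) | responses == "" | responses == "missing"] <-
    NA_character_
  bad <- !is.na(responses) & !responses %in% names(pts)
  if (any(bad)) {
    stop(sprintf("invalid ASQ response token(s): %s",
                 paste(unique(responses[bad]), collapse = ", ")),
         call. = FALSE)
  }
  unname(pts[responses])
}

#' Score ASQ-3 questionnaires
#'
#' Item points are yes = 10, sometimes = 5, not yet = 0. A domain score is
#' the sum over its six items; with one or two missing items the adjusted
#' score is the mean of the answered items times six; with more than two
#' missing the domain is undefined. A domain is abnormal when its score is
#' below the domain threshold. The total score is the sum of the five
#' domains (undefined when any domain is undefined) and abnormal when
#' <= 220. Records completed outside 21-26 months of corrected age are
#' flagged non-analyzable.
#'
#' @param asq data.frame with `<domain>_1` ... `<domain>_6` response
#'   columns (tokens `yes`, `sometimes`, `not_yet`, `missing`/empty/NA) and
#'   optionally `asq_age_months`.
#' @param items_per_domain Items per domain (default 6).
#' @return `asq` with added `<domain>_score`, `<domain>_abnormal`,
#'   `asq_total_score`, `asq_total_abnormal` and `asq_analyzable` columns.
#' @export
score_asq <- function(asq, items_per_domain = 6L) {
  domains <- asq_domains()
  thresholds <- asq_thresholds()
  max_score <- 10 * items_per_domain
  for (dom in domains) {
    cols <- paste0(dom, "_", seq_len(items_per_domain))
    miss_cols <- setdiff(cols, names(asq))
    if (length(miss_cols)) {
      stop(sprintf("ASQ item column(s) missing: %s",
                   paste(miss_cols, collapse = ", ")), call. = FALSE)
    }
    pts <- vapply(cols, function(cn) asq_item_points(asq[[cn]]),
                  numeric(nrow(asq)))
    if (nrow(asq) == 1L) pts <- matrix(pts, nrow = 1L)
    n_answered <- rowSums(!is.na(pts))
    raw <- rowSums(pts, na.rm = TRUE)
    score <- ifelse(
      n_answered == items_per_domain, raw,
      ifelse(n_answered >= items_per_domain - 2L & n_answered > 0L,
             raw / n_answered * items_per_domain, NA_real_))
    score[n_answered == 0L] <- NA_real_
    score <- pmin(score, max_score)
    asq[[paste0(dom, "_score")]] <- score
    asq[[paste0(dom, "_abnormal")]] <- score < thresholds[[dom]]
  }
  score_cols <- paste0(domains, "_score")
  totals <- rowSums(as.matrix(asq[score_cols]))
  asq$asq_total_score <- totals
  asq$asq_total_abnormal <- totals <= 220
  if (!is.null(asq$asq_age_months)) {
    asq$asq_analyzable <- !is.na(asq$asq_age_months) &
      asq$asq_age_months >= 21 & asq$asq_age_months <= 26
  } else {
    asq$asq_analyzable <- NA
  }
  asq
}

#' Compare the 34-week delay across levels of a clinical factor
#'
#' Reports N (%), median and quartiles of `delta34` per category, with a
#' two-sided rank test: Mann-Whitney-Wilcoxon for two groups,
#' Kruskal-Wallis for more (Student's t-test / one-way ANOVA behind
#' `parametric = TRUE`). Empty categories are dropped with a warning.
#'
#' @param cohort data.frame with the factor column and a delay column.
#' @param variable Name of the factor column.
#' @param delta_col Name of the delay column (default `"delta34_weeks"`).
#' @param parametric Use t-test/ANOVA instead of rank tests.
#' @return data.frame: one row per category with `variable`, `category`,
#'   `n`, `percent`, `median`, `q1`, `q3`, `test`, `p_value` (test and p
#'   repeated across the variable's rows).
#' @export
compare_delta_by_factor <- function(cohort, variable,
                                    delta_col = "delta34_weeks",
                                    parametric = FALSE) {
  if (!variable %in% names(cohort)) {
    stop(sprintf("variable '%s' not in cohort", variable), call. = FALSE)
  }
  ok <- !is.na(cohort[[variable]]) & !is.na(cohort[[delta_col]])
  x <- factor(cohort[[variable]][ok])
  empty <- levels(x)[table(x) == 0]
  if (length(empty)) {
    warning(sprintf("dropping empty categor%s: %s",
                    if (length(empty) > 1) "ies" else "y",
                    paste(empty, collapse = ", ")))
    x <- droplevels(x)
  }
  y <- cohort[[delta_col]][ok]
  if (nlevels(x) < 2L) {
    stop(sprintf("variable '%s' needs >= 2 non-empty categories", variable),
         call. = FALSE)
  }
  if (parametric) {
    if (nlevels(x) == 2L) {
      test <- "Student t"
      p <- t.test(y ~ x)$p.value
    } else {
      test <- "ANOVA"
      p <- summary(aov(y ~ x))[[1]][["Pr(>F)"]][1]
    }
  } else {
    if (nlevels(x) == 2L) {
      test <- "Mann-Whitney-Wilcoxon"
      p <- suppressWarnings(wilcox.test(y ~ x)$p.value)
    } else {
      test <- "Kruskal-Wallis"
      p <- kruskal.test(y ~ x)$p.value
    }
  }
  stats_by <- lapply(levels(x), function(lv) {
    v <- y[x == lv]
    q <- quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    data.frame(variable = variable, category = lv, n = length(v),
               percent = round(100 * length(v) / length(y), 1),
               median = q[2], q1 = q[1], q3 = q[3],
               test = test, p_value = p, stringsAsFactors = FALSE)
  })
  do.call(rbind, stats_by)
}

#' Association test for a two-way contingency table
#'
#' Fisher's exact test when any expected cell count is below 5, otherwise
#' the chi-square test (without continuity correction); the choice is
#' recorded in the result.
#'
#' @param counts Matrix of non-negative integer counts.
#' @return List with `test` (`"fisher"` or `"chi-square"`), `p_value`,
#'   `expected` (matrix of expected counts).
#' @export
categorical_assoc <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("degenerate table: a row or column margin is zero", call. = FALSE)
  }
  expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  if (any(expected < 5)) {
    list(test = "fisher", p_value = fisher.test(counts)$p.value,
         expected = expected)
  } else {
    list(test = "chi-square",
         p_value = chisq.test(counts, correct = FALSE)$p.value,
         expected = expected)
  }
}

#' Univariate logistic regression odds ratio
#'
#' Maximum-likelihood logistic fit of a binary outcome on one predictor,
#' reported as the odds ratio per unit of the predictor (per week for the
#' 34-week delay) with Wald 95% confidence interval and p-value. Complete
#' or quasi-complete separation is detected and flagged (`separation =
#' TRUE`, infinite OR sentinel) rather than returning a silently diverged
#' estimate.
#'
#' @param cohort data.frame.
#' @param outcome Name of the binary (logical or 0/1) outcome column; both
#'   classes must be present.
#' @param predictor Name of the predictor column.
#' @return List with `or`, `ci_low`, `ci_high`, `p_value`, `n`, `n_events`,
#'   `separation`.
#' @export
logistic_or <- function(cohort, outcome, predictor) {
  ok <- !is.na(cohort[[outcome]]) & !is.na(cohort[[predictor]])
  y <- as.integer(as.logical(cohort[[outcome]][ok]))
  x <- cohort[[predictor]][ok]
  if (length(unique(y)) < 2L) {
    stop(sprintf("outcome '%s' must have both classes present", outcome),
         call. = FALSE)
  }
  fit <- suppressWarnings(glm(y ~ x, family = binomial()))
  beta <- coef(fit)[["x"]]
  se <- sqrt(diag(vcov(fit)))[["x"]]
  fitted_p <- fitted(fit)
  separation <- !fit$converged || abs(beta) > 15 ||
    all(fitted_p > 1 - 1e-8 | fitted_p < 1e-8)
  if (separation) {
    return(list(or = if (beta > 0) Inf else 0, ci_low = NA_real_,
                ci_high = NA_real_, p_value = NA_real_,
                n = length(y), n_events = sum(y), separation = TRUE,
                note = "complete or quasi-complete separation detected"))
  }
  z <- beta / se
  list(or = exp(beta),
       ci_low = exp(beta - qnorm(0.975) * se),
       ci_high = exp(beta + qnorm(0.975) * se),
       p_value = 2 * stats::pnorm(-abs(z)),
       n = length(y), n_events = sum(y), separation = FALSE)
}

#' Descriptive association table for a scored cohort
#'
#' Builds the standard population-characteristics table: for every listed
#' variable present in the cohort, N (%) per category with the median
#' (Q1; Q3) of the 34-week delay and the rank-test p-value, via
#' [compare_delta_by_factor()]. Variables absent from the cohort are
#' omitted with a warning.
#'
#' @param cohort data.frame with covariates and a delay column.
#' @param variables Variables to tabulate (default: the perinatal factors
#'   the synthetic cohort carries).
#' @param delta_col Delay column name.
#' @return data.frame of comparison rows.
#' @export
build_table1 <- function(cohort,
                         variables = c("ga_stratum", "sex", "iugr", "bpd",
                                       "pda", "neuro_lesions", "tobacco"),
                         delta_col = "delta34_weeks") {
  present <- variables %in% names(cohort)
  if (any(!present)) {
    warning(sprintf("variable(s) not in cohort, omitted: %s",
                    paste(variables[!present], collapse = ", ")))
  }
  rows <- lapply(variables[present], function(v) {
    ok <- !is.na(cohort[[v]]) & !is.na(cohort[[delta_col]])
    if (length(unique(cohort[[v]][ok])) < 2L) {
      warning(sprintf("variable '%s' has a single category, omitted", v))
      return(NULL)
    }
    compare_delta_by_factor(cohort, v, delta_col = delta_col)
  })
  do.call(rbind, rows)
}

#' Cohort inclusion flow summary
#'
#' Applies the study exclusions to the eligible pool and summarises
#' follow-up: infants without usable ECG and infants used to train the
#' maturation model are removed; the included count, inclusion percentage
#' and ASQ follow-up percentage (respondents among included) are reported.
#'
#' @param n_eligible Eligible records (born before 30 weeks GA).
#' @param n_no_ecg Excluded for missing ECG recordings.
#' @param n_model_training Excluded as model-training infants.
#' @param n_asq_respondents Included infants with a 2-year ASQ.
#' @return List with `n_included`, `included_percent`,
#'   `followup_percent` (both rounded to the nearest integer).
#' @export
cohort_flow <- function(n_eligible, n_no_ecg, n_model_training,
                        n_asq_respondents = NA_integer_) {
  n_included <- n_eligible - n_no_ecg - n_model_training
  if (n_included < 0) stop("exclusions exceed the eligible pool",
                           call. = FALSE)
  followup <- if (is.na(n_asq_respondents)) NA_real_ else
    round(100 * n_asq_respondents / n_included)
  list(n_included = n_included,
       included_percent = round(100 * n_included / n_eligible),
       followup_percent = followup)
}
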