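#' Genetic-algorithm configuration for HRV feature selection
#'
#' The GA searches fixed-size feature subsets; fitness is the grouped
#' cross-validated mean absolute error (weeks) of the maturation-age
#' ensemble trained on the candidate subset (patients never split across
#' folds). Selection is by tournament, crossover samples a child subset
#' from the union of two parents, mutation swaps one member for a random
#' non-member; the best individual is carried over unchanged.
#'
#' @param subset_size Number of features to select (default 15).
#' @param population_size Individuals per generation (>= 2).
#' @param n_generations Number of generations.
#' @param crossover_rate,mutation_rate Rates in [0, 1].
#' @param fitness_folds Grouped folds for the fitness CV (default 5).
#' @param fitness_trees Forest size used inside the fitness evaluation
#'   (smaller than the final model's for tractability).
#' @param ga_included Include gestational age as a predictor in fitness
#'   models.
#' @param seed Integer seed.
#' @return Object of class `ga_config`.
#' @export
ga_config <- function(subset_size = 15L, population_size = 24L,
                      n_generations = 20L, crossover_rate = 0.8,
                      mutation_rate = 0.1, fitness_folds = 5L,
                      fitness_trees = 100L, ga_included = TRUE, seed = 1L) {
  check_scalar(crossover_rate, "crossover_rate", 0, 1)
  check_scalar(mutation_rate, "mutation_rate", 0, 1)
  if (population_size < 2L) stop_invalid("population_size", "must be >= 2")
  if (subset_size < 1L) stop_invalid("subset_size", "must be >= 1")
  structure(
    list(subset_size = as.integer(subset_size),
         population_size = as.integer(population_size),
         n_generations = as.integer(n_generations),
         crossover_rate = crossover_rate, mutation_rate = mutation_rate,
         fitness_folds = as.integer(fitness_folds),
         fitness_trees = as.integer(fitness_trees),
         ga_included = isTRUE(ga_included),
         seed = as.integer(seed)),
    class = "ga_config"
  )
}

# Columns of a feature table that are metadata, not candidate features.
feature_meta_cols <- function() {
  c("patient_id", "pma_weeks", "ga_weeks", "segment_start_s", "quality")
}

feature_candidates <- function(table) {
  setdiff(names(table), feature_meta_cols())
}

# Deterministic grouped fold assignment: patients shuffled once under the
# seed, dealt round-robin into folds.
grouped_folds <- function(patient_ids, k, seed) {
  patients <- unique(patient_ids)
  k <- min(k, length(patients))
  shuffled <- with_seed(seed, sample(patients))
  fold_of <- setNames(rep_len(seq_len(k), length(shuffled)), shuffled)
  unname(fold_of[as.character(patient_ids)])
}

# Grouped k-fold CV MAE for a candidate feature subset.
cv_mae <- function(table, feature_names, folds, ga_included, num_trees,
                   seed) {
  errs <- numeric(0)
  for (f in sort(unique(folds))) {
    train <- table[folds != f, , drop = FALSE]
    test <- table[folds == f, , drop = FALSE]
    fit <- fit_ensemble(train, feature_names, ga_included = ga_included,
                        num_trees = num_trees, seed = seed)
    pred <- predict_fma(fit, test)
    errs <- c(errs, abs(pred - test$pma_weeks))
  }
  mean(errs)
}

#' Select HRV features with a genetic algorithm
#'
#' @param table A feature table (one row per segment; `patient_id`,
#'   `pma_weeks`, `ga_weeks` plus feature columns).
#' @param config A [ga_config()] object.
#' @return List with `features` (selected names), `fitness` (their CV MAE
#'   in weeks), and `trace` (best-so-far MAE per generation,
#'   non-increasing). Deterministic under the config seed.
#' @export
ga_select <- function(table, config = ga_config()) {
  candidates <- feature_candidates(table)
  p <- length(candidates)
  k <- config$subset_size
  if (k > p) {
    stop(sprintf("subset_size (%d) exceeds available features (%d)", k, p),
         call. = FALSE)
  }
  folds <- grouped_folds(table$patient_id, config$fitness_folds,
                         derive_seed(config$seed, 1L))
  cache <- new.env(parent = emptyenv())
  fitness <- function(idx) {
    key <- paste(idx, collapse = ",")
    if (!is.null(cache[[key]])) return(cache[[key]])
    val <- cv_mae(table, candidates[idx], folds, config$ga_included,
                  config$fitness_trees, derive_seed(config$seed, 2L))
    cache[[key]] <- val
    val
  }
  with_seed(config$seed, {
    pop <- lapply(seq_len(config$population_size),
                  function(i) sort(sample.int(p, k)))
    scores <- vapply(pop, fitness, numeric(1))
    trace <- numeric(config$n_generations)
    for (gen in seq_len(config$n_generations)) {
      best <- which.min(scores)
      newpop <- list(pop[[best]])
      while (length(newpop) < config$population_size) {
        tourn <- function() {
          ij <- sample.int(length(pop), 2L)
          pop[[ij[which.min(scores[ij])]]]
        }
        p1 <- tourn(); p2 <- tourn()
        child <- if (runif(1) < config$crossover_rate) {
          sort(sample(union(p1, p2), k))
        } else {
          p1
        }
        if (runif(1) < config$mutation_rate) {
          out_of <- setdiff(seq_len(p), child)
          if (length(out_of)) {
            child <- sort(c(child[-sample.int(k, 1L)],
                            out_of[sample.int(length(out_of), 1L)]))
          }
        }
        newpop[[length(newpop) + 1L]] <- child
      }
      pop <- newpop
      scores <- vapply(pop, fitness, numeric(1))
      trace[gen] <- min(scores, if (gen > 1) trace[gen - 1] else Inf)
    }
    best <- which.min(scores)
    list(features = candidates[pop[[best]]], fitness = scores[best],
         trace = trace)
  })
}

# Build the generalized-logistic component: PMA modelled as a bounded
# sigmoid of a linear score of standardized features, asymptotes fitted
# within [22, 45] weeks. Falls back to fixed asymptotes when the nonlinear
# refinement cannot improve on the initialization.
fit_sigmoid <- function(X, y) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, function(c) {
    s <- stats::sd(c)
    if (!is.finite(s) || s == 0) 1 else s
  })
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  L0 <- 22; U0 <- 45
  z <- qlogis(pmin(pmax((y - L0) / (U0 - L0), 1e-6), 1 - 1e-6))
  init_fit <- lm(z ~ Xs)
  beta <- coef(init_fit)
  beta[!is.finite(beta)] <- 0
  result <- list(L = L0, U = U0, beta = beta, center = ctr, scale = scl,
                 refined = FALSE)
  p <- ncol(Xs)
  if (stats::sd(y) > 1e-8) {
    dat <- as.data.frame(Xs)
    names(dat) <- paste0("x", seq_len(p))
    dat$y <- y
    lin <- paste(c("b0", paste0("b", seq_len(p), "*x", seq_len(p))),
                 collapse = " + ")
    form <- as.formula(sprintf("y ~ L + (U - L) / (1 + exp(-(%s)))", lin))
    start <- c(list(L = L0, U = U0),
               setNames(as.list(unname(beta)), paste0("b", 0:p)))
    lower <- c(22, max(y) + 1e-3, rep(-Inf, p + 1))
    upper <- c(min(min(y) - 1e-3, 44.9), 45, rep(Inf, p + 1))
    if (lower[2] < upper[2] && lower[1] < upper[1]) {
      # maxiter warnings are expected on near-degenerate subsets; the
      # best-so-far parameters are still returned and used
      fit <- tryCatch(
        suppressWarnings(
          minpack.lm::nlsLM(form, data = dat, start = start,
                            lower = lower, upper = upper,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 100))),
        error = function(e) NULL)
      if (!is.null(fit)) {
        cf <- coef(fit)
        result$L <- cf[["L"]]; result$U <- cf[["U"]]
        result$beta <- cf[paste0("b", 0:p)]
        result$refined <- TRUE
      }
    }
  }
  result
}

predict_sigmoid <- function(sig, X) {
  Xs <- sweep(sweep(X, 2, sig$center), 2, sig$scale, "/")
  eta <- sig$beta[1] + as.vector(Xs %*% sig$beta[-1])
  sig$L + (sig$U - sig$L) * plogis(eta)
}

#' Fit the maturation-age ensemble
#'
#' Combines two regressors of post-menstrual age on HRV features (plus
#' gestational age when `ga_included`): a generalized-logistic (bounded
#' sigmoid) component for the saturating, near-linear part of maturation,
#' and a random-forest component for non-linear structure. The ensemble
#' prediction is the weighted mean of the two (default equal weights).
#' Rows are put into a canonical order before fitting, so the fit is
#' invariant to row permutations of the input.
#'
#' @param table Feature table with `patient_id`, `pma_weeks`, `ga_weeks`
#'   and feature columns; >= 10 rows, all modelling values finite.
#' @param feature_names Features to use as predictors.
#' @param ga_included Append gestational age as a predictor.
#' @param weights Ensemble weights `c(sigmoid, forest)`, summing to 1.
#' @param num_trees Random-forest size.
#' @param seed Integer seed (forest bootstrap).
#' @return Object of class `maturation_model`.
#' @export
fit_ensemble <- function(table, feature_names, ga_included = TRUE,
                         weights = c(0.5, 0.5), num_trees = 500L,
                         seed = 1L) {
  if (nrow(table) < 10L) {
    stop("fit_ensemble needs at least 10 training rows", call. = FALSE)
  }
  missing_cols <- setdiff(c(feature_names, "pma_weeks",
                            if (ga_included) "ga_weeks"), names(table))
  if (length(missing_cols)) {
    stop(sprintf("table lacks column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  predictors <- c(feature_names, if (ga_included) "ga_weeks")
  bad <- predictors[vapply(predictors,
                           function(cn) any(!is.finite(table[[cn]])),
                           logical(1))]
  if (any(!is.finite(table$pma_weeks))) bad <- c("pma_weeks", bad)
  if (length(bad)) {
    stop(sprintf("non-finite values in column(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  if (abs(sum(weights) - 1) > 1e-8 || any(weights < 0)) {
    stop_invalid("weights", "must be non-negative and sum to 1")
  }
  ord <- do.call(order, c(unname(table[c("patient_id", "pma_weeks",
                                         predictors)]), list()))
  table <- table[ord, , drop = FALSE]
  X <- as.matrix(table[predictors])
  y <- table$pma_weeks
  sig <- fit_sigmoid(X, y)
  dat <- as.data.frame(X)
  dat$.pma <- y
  forest <- ranger::ranger(
    dependent.variable.name = ".pma", data = dat,
    num.trees = num_trees, seed = seed, num.threads = 1
  )
  structure(
    list(features = feature_names, ga_included = ga_included,
         predictors = predictors, sigmoid = sig, forest = forest,
         weights = weights,
         meta = list(seed = seed, n_rows = nrow(table),
                     n_patients = length(unique(table$patient_id)),
                     version = "1")),
    class = "maturation_model"
  )
}

#' @export
print.maturation_model <- function(x, ...) {
  cat(sprintf(paste0("<maturation_model> %d feature(s)%s, sigmoid ",
                     "bounds [%.1f, %.1f] wk, %d trees, weights (%.2f, %.2f)\n"),
              length(x$features),
              if (x$ga_included) " + gestational age" else "",
              x$sigmoid$L, x$sigmoid$U, x$forest$num.trees,
              x$weights[1], x$weights[2]))
  invisible(x)
}

#' Predict functional maturation age
#'
#' @param model A `maturation_model`.
#' @param newdata Named numeric vector (one segment) or data.frame with
#'   the model's predictor columns.
#' @return Numeric vector of FMA estimates, clamped to [22, 45] weeks.
#' @export
predict_fma <- function(model, newdata) {
  stopifnot(inherits(model, "maturation_model"))
  if (is.numeric(newdata) && !is.null(names(newdata))) {
    newdata <- as.data.frame(as.list(newdata))
  }
  missing_cols <- setdiff(model$predictors, names(newdata))
  if (length(missing_cols)) {
    stop(sprintf("newdata lacks required feature(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  X <- as.matrix(newdata[model$predictors])
  if (any(!is.finite(X))) {
    stop("non-finite predictor values in newdata", call. = FALSE)
  }
  p_sig <- predict_sigmoid(model$sigmoid, X)
  p_rf <- predict(model$forest, data = as.data.frame(X),
                  num.threads = 1)$predictions
  pred <- model$weights[1] * p_sig + model$weights[2] * p_rf
  pmin(pmax(pred, 22), 45)
}

#' Grouped leave-one-out cross-validation of the ensemble
#'
#' One fold per patient: every segment of the held-out patient is predicted
#' by a model trained on all other patients, so no patient contributes to
#' both training and test. Patients whose rows all contain missing
#' modelling values are excluded (and listed); remaining rows with missing
#' values are dropped listwise.
#'
#' @inheritParams fit_ensemble
#' @param feature_names Features to use; default all candidates in `table`.
#' @return List with `predictions` (data.frame: `patient_id`, `pma_weeks`,
#'   `fma_pred`, `delta`), `mae_weeks` (mean |FMA - PMA| over held-out
#'   segments), `per_patient_week` (median FMA per patient and PMA week),
#'   and `excluded` (patient ids dropped for all-missing features).
#' @export
loocv <- function(table, feature_names = NULL, ga_included = TRUE,
                  weights = c(0.5, 0.5), num_trees = 500L, seed = 1L) {
  if (is.null(feature_names)) feature_names <- feature_candidates(table)
  predictors <- c(feature_names, if (ga_included) "ga_weeks")
  ok <- complete.cases(table[c(predictors, "pma_weeks")])
  dropped_rows <- table[!ok, , drop = FALSE]
  excluded <- setdiff(unique(table$patient_id),
                      unique(table$patient_id[ok]))
  if (length(excluded)) {
    message(sprintf("excluding %d patient(s) with no complete rows: %s",
                    length(excluded), paste(excluded, collapse = ", ")))
  }
  table <- table[ok, , drop = FALSE]
  patients <- unique(table$patient_id)
  if (length(patients) < 3L) {
    stop("grouped LOOCV needs at least 3 patients", call. = FALSE)
  }
  preds <- vector("list", length(patients))
  for (i in seq_along(patients)) {
    pid <- patients[i]
    train <- table[table$patient_id != pid, , drop = FALSE]
    test <- table[table$patient_id == pid, , drop = FALSE]
    fit <- fit_ensemble(train, feature_names, ga_included = ga_included,
                        weights = weights, num_trees = num_trees,
                        seed = seed)
    preds[[i]] <- data.frame(patient_id = test$patient_id,
                             pma_weeks = test$pma_weeks,
                             fma_pred = predict_fma(fit, test),
                             stringsAsFactors = FALSE)
  }
  predictions <- do.call(rbind, preds)
  predictions$delta <- predictions$pma_weeks - predictions$fma_pred
  agg <- stats::aggregate(fma_pred ~ patient_id + pma_weeks,
                          data = predictions, FUN = median)
  names(agg)[names(agg) == "fma_pred"] <- "fma_weeks"
  list(predictions = predictions,
       mae_weeks = mean(abs(predictions$delta)),
       per_patient_week = agg[order(agg$patient_id, agg$pma_weeks), ],
       excluded = excluded)
}

#' Save / load a fitted maturation model
#'
#' Serializes the model (version-tagged) so a fit can be reloaded and
#' produce identical predictions.
#'
#' @param model A `maturation_model`.
#' @param path File path.
#' @return `path` invisibly (`save_model`); the model (`load_model`).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "maturation_model"))
  saveRDS(model, path, version = 3)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "maturation_model")) {
    stop("file does not contain a maturation_model", call. = FALSE)
  }
  model
}
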