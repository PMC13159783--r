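#' Default end-to-end run configuration
#'
#' Stage toggles, output paths and per-stage seeds for [run_pipeline()].
#' The demo scale (a small cohort, short recordings) keeps a full run fast
#' while exercising every stage; all knobs are overridable.
#'
#' @param out_dir Output directory (stage outputs are files, so each stage
#'   is independently inspectable and resumable).
#' @param n_infants Cohort size.
#' @param rr_duration_s Simulated recording length per session (seconds).
#' @param rr_pma_weeks PMA weeks at which RR sessions are simulated for the
#'   feature/model stages.
#' @param pma_grid PMA grid for the trajectory stage.
#' @param window_s,min_quality,min_beats Segmentation parameters.
#' @param subset_size,population_size,n_generations GA parameters.
#' @param num_trees Final ensemble forest size.
#' @param stages Character vector of stages to run, in order, among
#'   `"generate"`, `"ingest"`, `"features"`, `"train"`, `"trajectory"`,
#'   `"cohort"`.
#' @param seed Master seed; per-stage seeds are derived from it.
#' @return List of class `run_config`.
#' @export
run_config <- function(out_dir = tempfile("neomat_run_"),
                       n_infants = 30L,
                       rr_duration_s = 2100,
                       rr_pma_weeks = c(32, 34, 36),
                       pma_grid = seq(32, 36, by = 1),
                       window_s = 1800, min_quality = 0.8, min_beats = 1000L,
                       subset_size = 5L, population_size = 12L,
                       n_generations = 6L, num_trees = 200L,
                       stages = c("generate", "ingest", "features", "train",
                                  "trajectory", "cohort"),
                       seed = 1L) {
  stages <- match.arg(stages, several.ok = TRUE)
  structure(
    list(out_dir = out_dir, n_infants = as.integer(n_infants),
         rr_duration_s = rr_duration_s, rr_pma_weeks = rr_pma_weeks,
         pma_grid = pma_grid, window_s = window_s,
         min_quality = min_quality, min_beats = as.integer(min_beats),
         subset_size = as.integer(subset_size),
         population_size = as.integer(population_size),
         n_generations = as.integer(n_generations),
         num_trees = as.integer(num_trees),
         stages = stages, seed = as.integer(seed)),
    class = "run_config"
  )
}

stage_path <- function(config, ...) file.path(config$out_dir, ...)

manifest_entry <- function(files) {
  files <- files[file.exists(files)]
  list(files = as.list(setNames(unname(tools::md5sum(files)),
                                basename(files))))
}

#' Run the maturation pipeline end to end
#'
#' Executes the enabled stages in order — synthetic cohort and RR
#' generation, beat-file ingestion and segmentation, HRV feature
#' extraction, GA selection + ensemble training with grouped LOOCV, delta
#' trajectory modelling with 34-week interpolation, and the cohort
#' association report — writing every stage's outputs to files and a JSON
#' manifest with per-file checksums. Re-running with the same config
#' reproduces the checksums.
#'
#' @param config A [run_config()].
#' @return The manifest (list), invisibly written to
#'   `<out_dir>/manifest.json`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = config$seed, stages = list(),
                   started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  yaml::write_yaml(unclass(config)[setdiff(names(config), "out_dir")],
                   stage_path(config, "run_config.yaml"))

  # Pre-flight: every enabled stage must find its inputs, either on disk
  # already or produced by an earlier enabled stage; otherwise nothing runs.
  needs <- list(generate = character(), ingest = "beats",
                features = c("segments.rds", "cohort.csv"),
                train = "features.csv",
                trajectory = c("fma.csv", "cohort.csv"),
                cohort = c("cohort.csv", "delta34.csv"))
  provides <- list(generate = c("beats", "cohort.csv"),
                   ingest = "segments.rds", features = "features.csv",
                   train = c("model.rds", "fma.csv", "train_summary.json"),
                   trajectory = c("delta34.csv", "trajectory_summary.json"),
                   cohort = "table1.csv")
  available <- character()
  for (st in config$stages) {
    req <- needs[[st]]
    missing <- req[!(req %in% available) &
                     !file.exists(stage_path(config, req))]
    if (length(missing)) {
      manifest$stages[[st]] <- list(
        status = "failed",
        error = sprintf("missing input(s): %s",
                        paste(missing, collapse = ", ")))
      jsonlite::write_json(manifest, stage_path(config, "manifest.json"),
                           auto_unbox = TRUE, pretty = TRUE)
      stop(sprintf("pre-flight failed for stage '%s': missing %s",
                   st, paste(missing, collapse = ", ")), call. = FALSE)
    }
    available <- c(available, provides[[st]])
  }

  run_stage <- function(name, fun) {
    if (!name %in% config$stages) return()
    res <- tryCatch(fun(), error = function(e) e)
    if (inherits(res, "error")) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(res))
      manifest_path <- stage_path(config, "manifest.json")
      jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                           pretty = TRUE)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(res)),
           call. = FALSE)
    }
    manifest$stages[[name]] <<- c(list(status = "complete"),
                                  manifest_entry(res))
  }

  run_stage("generate", function() {
    cohort <- generate_cohort(cohort_gen_config(
      n_infants = config$n_infants, seed = derive_seed(config$seed, 10L)))
    cohort <- generate_asq_items(cohort, seed = derive_seed(config$seed, 11L))
    write_cohort(cohort, stage_path(config, "cohort.csv"))
    beat_dir <- stage_path(config, "beats")
    dir.create(beat_dir, showWarnings = FALSE)
    files <- character()
    for (i in seq_len(nrow(cohort))) {
      for (pma in config$rr_pma_weeks) {
        cfg <- rr_gen_config(ga_weeks = cohort$ga_weeks[i], pma_weeks = pma,
                             duration_s = config$rr_duration_s,
                             seed = derive_seed(config$seed, 100L * i + pma))
        f <- file.path(beat_dir, sprintf("%s_pma%02d.rr",
                                         cohort$patient_id[i], pma))
        write_rr(generate_rr_series(cfg, cohort$patient_id[i]), f)
        files <- c(files, f)
      }
    }
    c(stage_path(config, "cohort.csv"), files)
  })

  run_stage("ingest", function() {
    files <- list.files(stage_path(config, "beats"), full.names = TRUE,
                        pattern = "\\.rr$")
    segs <- list()
    for (f in files) {
      pma <- as.numeric(sub(".*_pma(\\d+)\\.rr$", "\\1", f))
      pid <- sub("_pma\\d+\\.rr$", "", basename(f))
      series <- read_rr(f, patient_id = pid, pma_weeks = pma)
      segs <- c(segs, segment_series(series, window_s = config$window_s,
                                     min_quality = config$min_quality,
                                     min_beats = config$min_beats))
    }
    saveRDS(segs, stage_path(config, "segments.rds"))
    stage_path(config, "segments.rds")
  })

  run_stage("features", function() {
    segs <- readRDS(stage_path(config, "segments.rds"))
    cohort <- utils::read.csv(stage_path(config, "cohort.csv"))
    tab <- features_table(segs)
    tab$ga_weeks <- cohort$ga_weeks[match(tab$patient_id,
                                          cohort$patient_id)]
    write_features(tab, stage_path(config, "features.csv"))
    stage_path(config, "features.csv")
  })

  run_stage("train", function() {
    tab <- utils::read.csv(stage_path(config, "features.csv"))
    tab <- tab[complete.cases(tab), , drop = FALSE]
    sel <- ga_select(tab, ga_config(
      subset_size = config$subset_size,
      population_size = config$population_size,
      n_generations = config$n_generations,
      fitness_trees = 50L, seed = derive_seed(config$seed, 20L)))
    cv <- loocv(tab, feature_names = sel$features,
                num_trees = config$num_trees,
                seed = derive_seed(config$seed, 21L))
    model <- fit_ensemble(tab, sel$features, num_trees = config$num_trees,
                          seed = derive_seed(config$seed, 21L))
    save_model(model, stage_path(config, "model.rds"))
    write.csv(cv$per_patient_week, stage_path(config, "fma.csv"),
              row.names = FALSE)
    jsonlite::write_json(
      list(selected_features = sel$features, ga_fitness = sel$fitness,
           loocv_mae_weeks = cv$mae_weeks),
      stage_path(config, "train_summary.json"), auto_unbox = TRUE,
      pretty = TRUE, digits = NA)
    stage_path(config, c("model.rds", "fma.csv", "train_summary.json"))
  })

  run_stage("trajectory", function() {
    fma <- utils::read.csv(stage_path(config, "fma.csv"))
    cohort <- utils::read.csv(stage_path(config, "cohort.csv"))
    obs <- merge(fma, cohort[c("patient_id", "iugr", "bpd", "neuro_lesions",
                               "pda")], by = "patient_id")
    res <- delta_trajectory(obs)
    write.csv(res$delta34, stage_path(config, "delta34.csv"),
              row.names = FALSE)
    jsonlite::write_json(
      list(effects = res$model$effects, var_comp = as.list(res$model$var_comp),
           singular = res$model$singular),
      stage_path(config, "trajectory_summary.json"), auto_unbox = TRUE,
      pretty = TRUE, digits = NA)
    stage_path(config, c("delta34.csv", "trajectory_summary.json"))
  })

  run_stage("cohort", function() {
    cohort <- utils::read.csv(stage_path(config, "cohort.csv"))
    delta34 <- utils::read.csv(stage_path(config, "delta34.csv"))
    cohort <- merge(cohort, delta34[c("patient_id", "delta34_weeks")],
                    by = "patient_id")
    tab1 <- build_table1(cohort)
    write.csv(tab1, stage_path(config, "table1.csv"), row.names = FALSE)
    has_items <- all(paste0("communication_", 1:6) %in% names(cohort))
    if (has_items) {
      with_asq <- cohort[!is.na(cohort$communication_1) &
                           cohort$communication_1 != "", , drop = FALSE]
      if (nrow(with_asq)) {
        scored <- score_asq(with_asq)
        write.csv(
          scored[c("patient_id", paste0(asq_domains(), "_score"),
                   paste0(asq_domains(), "_abnormal"),
                   "asq_total_score", "asq_total_abnormal")],
          stage_path(config, "asq_scores.csv"), row.names = FALSE)
      }
    }
    stage_path(config, c("table1.csv", "asq_scores.csv"))
  })

  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  manifest_path <- stage_path(config, "manifest.json")
  jsonlite::write_json(manifest[setdiff(names(manifest),
                                        c("started", "finished"))],
                       manifest_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Write a human-readable report from a completed run
#'
#' Markdown report with the population table, the trajectory model
#' estimates, the LOOCV error and (when available) the ASQ outcome
#' summary; incomplete runs produce a partial report with a notice.
#' Regeneration from the same run directory is idempotent.
#'
#' @param out_dir A [run_pipeline()] output directory containing
#'   `manifest.json`.
#' @param path Report path (default `<out_dir>/report.md`).
#' @return `path`, invisibly.
#' @export
write_report <- function(out_dir, path = file.path(out_dir, "report.md")) {
  manifest_path <- file.path(out_dir, "manifest.json")
  if (!file.exists(manifest_path)) {
    stop("no manifest.json in out_dir; run the pipeline first", call. = FALSE)
  }
  manifest <- jsonlite::read_json(manifest_path)
  lines <- c("# Maturation-delay pipeline report", "")
  statuses <- vapply(manifest$stages, function(s) s$status, "")
  if (any(statuses != "complete")) {
    lines <- c(lines, "**Partial run**: stage(s) incomplete or failed:",
               paste0("- ", names(statuses)[statuses != "complete"]), "")
  }
  add_csv <- function(lines, title, file) {
    f <- file.path(out_dir, file)
    if (!file.exists(f)) return(lines)
    df <- utils::read.csv(f)
    c(lines, paste("##", title), "",
      paste(names(df), collapse = " | "),
      paste(rep("---", ncol(df)), collapse = " | "),
      apply(df, 1, function(r) paste(r, collapse = " | ")), "")
  }
  train_file <- file.path(out_dir, "train_summary.json")
  if (file.exists(train_file)) {
    ts <- jsonlite::read_json(train_file)
    lines <- c(lines, "## Model",
               sprintf("- selected features: %s",
                       paste(unlist(ts$selected_features), collapse = ", ")),
               sprintf("- grouped LOOCV MAE: %.2f weeks",
                       ts$loocv_mae_weeks), "")
  }
  traj_file <- file.path(out_dir, "trajectory_summary.json")
  if (file.exists(traj_file)) {
    tj <- jsonlite::read_json(traj_file)
    eff <- do.call(rbind, lapply(tj$effects, as.data.frame))
    lines <- c(lines, "## Delta trajectory model (32-36 weeks PMA)", "",
               paste(names(eff), collapse = " | "),
               paste(rep("---", ncol(eff)), collapse = " | "),
               apply(format(eff, digits = 3), 1,
                     function(r) paste(r, collapse = " | ")), "")
  }
  lines <- add_csv(lines, "Population characteristics vs 34-week delay",
                   "table1.csv")
  if (file.exists(file.path(out_dir, "asq_scores.csv"))) {
    lines <- add_csv(lines, "ASQ-3 domain scores", "asq_scores.csv")
  } else {
    lines <- c(lines, "## ASQ-3 outcomes",
               "Not available for this run (no ASQ stage output).", "")
  }
  writeLines(lines, path)
  invisible(path)
}
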