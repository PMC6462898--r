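#' End-to-end analysis pipeline
#'
#' Chains the four stages -- simulate (or load) a cohort, screen it,
#' extract the beat features, and run the three correlation analyses --
#' under a single serializable configuration whose hash is stamped into
#' every output file, so a rerun with the same configuration reproduces
#' identical artifacts.
#'
#' @name pipeline
NULL

#' Default pipeline run configuration
#'
#' Cohort-level heterogeneity mimics a multi-subject study: each subject
#' draws its own baseline SBP and mean PAT around the population values,
#' while sharing the coupling slope and noise levels of `synthetic`.
#'
#' @param n_subjects number of clean simulated subjects.
#' @param n_corrupt_per_mode corrupted copies added per non-good category.
#' @param seed master seed; per-subject seeds are derived from it.
#' @param out_dir output directory for artifacts.
#' @param bp_target blood-pressure column for the pooled analyses.
#' @param bin_feature feature binned in the subject-mode report.
#' @param synthetic named list of overrides for [synthetic_config()].
#' @param cohort list with `sbp_mean_sd` and `pat_rs_mean_sd`, the
#'   between-subject SDs of baseline SBP (mmHg) and mean PAT (s).
#' @return List of class `run_config`.
#' @export
default_run_config <- function(n_subjects = 20, n_corrupt_per_mode = 0,
                               seed = 1L, out_dir = tempfile("patcor_run"),
                               bp_target = "sbp",
                               bin_feature = "pat_rsstar",
                               synthetic = list(),
                               cohort = list(sbp_mean_sd = 12,
                                             pat_rs_mean_sd = 0.03)) {
  cfg <- list(n_subjects = as.integer(n_subjects),
              n_corrupt_per_mode = as.integer(n_corrupt_per_mode),
              seed = as.integer(seed), out_dir = out_dir,
              bp_target = bp_target, bin_feature = bin_feature,
              synthetic = synthetic, cohort = cohort)
  stopifnot(cfg$n_subjects >= 1L, cfg$n_corrupt_per_mode >= 0L)
  class(cfg) <- "run_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file with any subset of the [default_run_config()]
#'   fields.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(default_run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  do.call(default_run_config, vals)
}

# Hash of the scientific parameters only: output location does not alter
# results, so two runs differing only in out_dir stamp identical hashes.
config_hash <- function(config) {
  x <- unclass(config)
  x$out_dir <- NULL
  rlang::hash(x)
}

#' Simulate a heterogeneous cohort
#'
#' @param config a `run_config`.
#' @return List with `records` (clean plus corrupted
#'   [waveform_record()]s), `truths` (ground-truth tables for the clean
#'   records, keyed by subject id), and `true_labels` (named character
#'   vector of the intended quality category per record).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "run_config"))
  n <- config$n_subjects
  withr::with_seed(config$seed, {
    sbp_means <- rnorm(n, 120, config$cohort$sbp_mean_sd)
    pat_means <- rnorm(n, 0.35, config$cohort$pat_rs_mean_sd)
  })
  records <- list(); truths <- list(); labels <- character(0)
  for (i in seq_len(n)) {
    args <- utils::modifyList(
      list(sbp_mean = round(sbp_means[i], 1),
           pat_rs_mean = round(pat_means[i], 4),
           seed = config$seed + 97L * i),
      config$synthetic)
    args$sbp_mean <- max(args$sbp_mean, 90)
    args$pat_rs_mean <- min(max(args$pat_rs_mean, 0.2), 0.45)
    gen <- generate_record(do.call(synthetic_config, args))
    records[[gen$record$subject_id]] <- gen$record
    truths[[gen$record$subject_id]] <- gen$truth
    labels[gen$record$subject_id] <- "good"
  }
  if (config$n_corrupt_per_mode > 0) {
    modes <- setdiff(QUALITY_CATEGORIES, "good")
    k <- 0L
    for (m in modes) {
      for (j in seq_len(config$n_corrupt_per_mode)) {
        k <- k + 1L
        base_cfg <- synthetic_config(seed = config$seed + 7919L * k)
        base <- generate_record(base_cfg)$record
        bad <- corrupt_record(base, m, seed = config$seed + k)
        bad$subject_id <- sprintf("corrupt_%s_%02d", m, j)
        records[[bad$subject_id]] <- bad
        labels[bad$subject_id] <- m
      }
    }
  }
  list(records = records, truths = truths, true_labels = labels)
}

write_stamped_csv <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#config_hash=", hash), con)
  write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the full pipeline
#'
#' Stages: simulate -> screen -> extract -> correlate (all three modes),
#' writing the screening ledger, the pooled feature table, and the rendered
#' correlation reports under `config$out_dir`. Any stage failure aborts
#' with the stage name in the error.
#'
#' @param config a `run_config`.
#' @return List with `ledger`, `features`, `reports` (subject, collective,
#'   excellent), `files`, and `config_hash`, invisibly.
#' @export
run_pipeline <- function(config = default_run_config()) {
  stopifnot(inherits(config, "run_config"))
  hash <- config_hash(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  sim <- stage("simulate", simulate_cohort(config))
  screened <- stage("screen", screen_cohort(sim$records))
  ledger_file <- file.path(config$out_dir, "screening_ledger.csv")
  write_ledger(screened$ledger, ledger_file)

  features <- stage("extract", build_feature_table(screened$good))
  feat_file <- file.path(config$out_dir, "beat_features.csv")
  feat_out <- features
  num <- vapply(feat_out, is.numeric, logical(1))
  feat_out[num] <- lapply(feat_out[num], function(v) {
    formatC(v, digits = 9, format = "g")
  })
  write_stamped_csv(feat_out, feat_file, hash)

  reports <- list()
  files <- c(ledger_file, feat_file)
  if (nrow(features) > 0) {
    reports$subject <- stage("correlate",
      analyze_subject_by_subject(features, config$bp_target,
                                 bin_feature = config$bin_feature))
    files <- c(files, render_reports(reports$subject, config$out_dir))
    reports$collective <- lapply(c(sbp = "sbp", map = "map", dbp = "dbp"),
                                 function(bp) {
                                   stage("correlate",
                                         analyze_collective(features, bp))
                                 })
    reports$excellent <- lapply(c(sbp = "sbp", map = "map", dbp = "dbp"),
                                function(bp) {
                                  stage("correlate",
                                        analyze_one_excellent_beat(features,
                                                                   bp))
                                })
    coll <- do.call(rbind, lapply(reports$collective, function(x) {
      cbind(bp = toupper(x$bp_target), x$rows)
    }))
    exc <- do.call(rbind, lapply(reports$excellent, function(x) {
      cbind(bp = toupper(x$bp_target), x$rows)
    }))
    pooled <- rbind(coll, exc)
    pooled[PAT_FEATURES] <- lapply(pooled[PAT_FEATURES], round, digits = 2)
    pooled_file <- file.path(config$out_dir, "pooled_r.csv")
    write_stamped_csv(pooled, pooled_file, hash)
    files <- c(files, pooled_file)
  }
  invisible(list(ledger = screened$ledger, features = features,
                 reports = reports, files = files, config_hash = hash,
                 truths = sim$truths, true_labels = sim$true_labels))
}
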