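#' Pearson correlation analyses
#'
#' The association between per-beat blood pressure and the eight arterial
#' wave propagation features is quantified with the sample Pearson
#' coefficient, run in three modes: subject by subject (one coefficient per
#' subject and feature, summarized as mean +/- SD and binned by strength),
#' on the pooled beats of all subjects, and on one best-quality beat per
#' subject. Strength bins on |r|: very strong [0.8, 1.0], strong
#' [0.6, 0.8), moderate [0.4, 0.6), weak [0.2, 0.4), very weak [0, 0.2).
#'
#' @name correlation
NULL

STRENGTH_LEVELS <- c("very weak", "weak", "moderate", "strong",
                     "very strong")

#' Sample Pearson correlation coefficient
#'
#' Computed from centered sums, `sum(dx dy) / sqrt(sum(dx^2) sum(dy^2))`;
#' symmetric in its arguments. Zero variance in either input is an error
#' (an undefined coefficient is never silently reported as 0).
#'
#' @param x,y equal-length numeric vectors, length >= 2, all finite.
#' @return The correlation coefficient in [-1, 1].
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2L) stop("need at least 2 observations")
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("inputs must be finite")
  }
  dx <- x - mean(x)
  dy <- y - mean(y)
  vx <- sum(dx * dx); vy <- sum(dy * dy)
  if (vx == 0 || vy == 0) {
    stop("correlation undefined: zero variance in ",
         if (vx == 0) "x" else "y")
  }
  r <- sum(dx * dy) / sqrt(vx * vy)
  min(1, max(-1, r))
}

#' Bin a correlation coefficient by strength
#'
#' @param r coefficient(s) in [-1, 1]; binning is on |r| with half-open
#'   intervals so every value lands in exactly one bin.
#' @return Factor with levels very weak < weak < moderate < strong <
#'   very strong.
#' @export
strength_bin <- function(r) {
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE)) {
    stop("|r| > 1 is not a correlation coefficient")
  }
  cut(pmin(abs(r), 1), breaks = c(0, 0.2, 0.4, 0.6, 0.8, 1 + 1e-9),
      labels = STRENGTH_LEVELS, right = FALSE, include.lowest = TRUE)
}

new_correlation_report <- function(mode, rows, summary = NULL,
                                   strength_bins = NULL,
                                   bin_feature = NULL, bp_target = "sbp",
                                   skipped = character(0)) {
  structure(list(mode = mode, rows = rows, summary = summary,
                 strength_bins = strength_bins, bin_feature = bin_feature,
                 bp_target = bp_target, skipped = skipped),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  cat("<correlation_report> mode=", x$mode, ", bp=", toupper(x$bp_target),
      ", ", nrow(x$rows), " row(s)\n", sep = "")
  print(x$rows, digits = 2)
  if (!is.null(x$strength_bins)) {
    cat("strength bins (", x$bin_feature, "):\n", sep = "")
    print(x$strength_bins)
  }
  invisible(x)
}

feature_correlations <- function(ft, bp_target) {
  vapply(PAT_FEATURES, function(f) pearson(ft[[bp_target]], ft[[f]]),
         numeric(1))
}

#' Subject-by-subject correlation analysis
#'
#' One Pearson coefficient per subject between the blood-pressure column
#' and each propagation feature, an unweighted mean +/- SD summary row, and
#' strength-bin counts computed on `bin_feature` (by default the ECG-to-ABP
#' interval `pat_rsstar`, the feature with the strongest overall
#' association).
#'
#' @param ft feature table from [build_feature_table()].
#' @param bp_target `"sbp"`, `"map"`, or `"dbp"`.
#' @param bin_feature feature whose per-subject coefficients are binned.
#' @return A `correlation_report` with per-subject rows (`subject_id`,
#'   `n_beats`, one column per feature), `summary` (mean and SD per
#'   feature), and `strength_bins` counts summing to the number of
#'   subjects.
#' @export
analyze_subject_by_subject <- function(ft, bp_target = c("sbp", "map", "dbp"),
                                       bin_feature = "pat_rsstar") {
  bp_target <- match.arg(bp_target)
  stopifnot(bin_feature %in% PAT_FEATURES)
  skipped <- character(0)
  rows <- list()
  for (id in unique(ft$subject_id)) {
    sub <- ft[ft$subject_id == id, , drop = FALSE]
    r <- tryCatch(feature_correlations(sub, bp_target), error = function(e) {
      NULL
    })
    if (nrow(sub) < 2L || is.null(r)) {
      skipped <- c(skipped, id)
      next
    }
    rows[[id]] <- data.frame(subject_id = id, n_beats = nrow(sub),
                             as.list(r), stringsAsFactors = FALSE)
  }
  rows <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(rows)) {
    rows <- data.frame(subject_id = character(0), n_beats = integer(0))
    rows[PAT_FEATURES] <- numeric(0)
  }
  rmat <- as.matrix(rows[PAT_FEATURES])
  summary <- data.frame(
    feature = PAT_FEATURES,
    mean_r = if (nrow(rmat) > 0) colMeans(rmat) else NA_real_,
    sd_r = if (nrow(rmat) > 1) apply(rmat, 2, stats::sd)
           else if (nrow(rmat) == 1) 0 else NA_real_
  )
  bins <- table(strength_bin(rows[[bin_feature]]))
  new_correlation_report("subject_by_subject", rows, summary = summary,
                         strength_bins = bins, bin_feature = bin_feature,
                         bp_target = bp_target, skipped = skipped)
}

#' Pooled ("collective beats") correlation analysis
#'
#' One coefficient per feature over all beats of all subjects pooled, with
#' no per-subject centering: between-subject differences in baseline PAT
#' and blood pressure therefore contribute to (and can dominate) the
#' pooled coefficient.
#'
#' @inheritParams analyze_subject_by_subject
#' @return A `correlation_report` with a single pooled row.
#' @export
analyze_collective <- function(ft, bp_target = c("sbp", "map", "dbp")) {
  bp_target <- match.arg(bp_target)
  if (nrow(ft) < 2L) stop("pooled table needs at least 2 beats")
  r <- feature_correlations(ft, bp_target)
  rows <- data.frame(scope = "collective", n_beats = nrow(ft), as.list(r),
                     stringsAsFactors = FALSE)
  new_correlation_report("collective", rows, bp_target = bp_target)
}

#' One-best-beat-per-subject correlation analysis
#'
#' Selects, for each subject, the beat with the highest per-beat quality
#' score (mean beat-template correlation across channels; ties broken by
#' the earliest beat) and correlates across the selected beats, one per
#' subject.
#'
#' @inheritParams analyze_subject_by_subject
#' @param records optional list of [waveform_record()]s keyed by subject;
#'   only needed when `ft` lacks the `sqi` column written by
#'   [extract_features()].
#' @return A `correlation_report` with one pooled row over `n_subjects`
#'   selected beats; the selection is in attribute `selected` of the
#'   report.
#' @export
analyze_one_excellent_beat <- function(ft, bp_target = c("sbp", "map", "dbp"),
                                       records = NULL) {
  bp_target <- match.arg(bp_target)
  if (!"sqi" %in% names(ft)) {
    if (is.null(records)) {
      stop("feature table has no sqi column; supply the source records")
    }
    stop("recompute features with extract_features() to obtain sqi scores")
  }
  picks <- lapply(split(ft, ft$subject_id), function(sub) {
    sqi <- ifelse(is.na(sub$sqi), -Inf, sub$sqi)
    sub[which.max(sqi), , drop = FALSE]   # which.max: earliest on ties
  })
  sel <- do.call(rbind, c(picks, list(make.row.names = FALSE)))
  if (nrow(sel) < 2L) stop("need at least 2 subjects for correlation")
  r <- feature_correlations(sel, bp_target)
  rows <- data.frame(scope = "one_excellent_beat", n_beats = nrow(sel),
                     as.list(r), stringsAsFactors = FALSE)
  rep <- new_correlation_report("one_excellent_beat", rows,
                                bp_target = bp_target)
  attr(rep, "selected") <- sel
  rep
}

#' Render a correlation report to delimited tables
#'
#' Writes the per-subject (or pooled) coefficient table with r rounded to
#' two decimals; subject-mode reports also get a `Mean ± STD` summary
#' row and a strength-bin count table.
#'
#' @param report a `correlation_report`.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return Character vector of the files written, invisibly.
#' @export
render_reports <- function(report, dir, prefix = report$mode) {
  stopifnot(inherits(report, "correlation_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  rows <- report$rows
  for (f in intersect(PAT_FEATURES, names(rows))) {
    rows[[f]] <- round(rows[[f]], 2)
  }
  if (!is.null(report$summary) && nrow(rows) > 0) {
    lab <- stats::setNames(
      as.list(sprintf("%.2f ± %.2f", report$summary$mean_r,
                      report$summary$sd_r)),
      report$summary$feature)
    summary_row <- data.frame(subject_id = "Mean ± STD",
                              n_beats = sprintf("%.0f ± %.0f",
                                                mean(rows$n_beats),
                                                stats::sd(rows$n_beats)),
                              lab, stringsAsFactors = FALSE)
    rows <- rbind(data.frame(lapply(rows, as.character),
                             stringsAsFactors = FALSE), summary_row)
  }
  main <- file.path(dir, paste0(prefix, "_r.csv"))
  write.csv(rows, main, row.names = FALSE, quote = FALSE)
  files <- main
  if (!is.null(report$strength_bins)) {
    bins <- data.frame(strength = names(report$strength_bins),
                       count = as.integer(report$strength_bins))
    bf <- file.path(dir, paste0(prefix, "_strength_bins.csv"))
    write.csv(bins, bf, row.names = FALSE, quote = FALSE)
    files <- c(files, bf)
  }
  invisible(files)
}
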