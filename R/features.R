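#' Arterial wave propagation features
#'
#' Per beat, seven propagation intervals plus the R-R interval are measured:
#' five pulse arrival times from the ECG R peak to PPG-family landmarks
#' (PAT_RO, PAT_Ra, PAT_Rw-1, PAT_Rb, PAT_RS), one from R to the ABP
#' systolic peak (PAT_RS*), the pulse transit time from the ABP peak to the
#' PPG peak (PTT_S*S), and RRI. Reference blood pressure is read from the
#' unfiltered ABP: SBP at S*, DBP at D*, and MAP as the time average of ABP
#' over the cardiac cycle (the standard monitor convention; the alternative
#' DBP + PP/3 estimate is available via `map_rule`).
#'
#' @name features
NULL

#' Compute the propagation features for one beat
#'
#' @param beat one-row data frame (or list) with the complete fiducial set:
#'   `r_time`, `o_time`, `a_time`, `w_time`, `b_time`, `s_time`,
#'   `sstar_time`, `dstar_time`, `beat_index`.
#' @param next_r_time time of the following R peak in seconds
#'   (> `beat$r_time`).
#' @param abp unfiltered ABP samples in mmHg.
#' @param fs sampling rate in Hz.
#' @param map_rule `"waveform_mean"` (default) averages ABP over
#'   `[r_time, next_r_time)`; `"dbp_pp3"` uses DBP + (SBP - DBP)/3.
#' @param subject_id optional subject identifier carried into the row.
#' @return One-row data frame of `BeatFeatures`: the eight intervals in
#'   seconds, `sbp`, `dbp`, `map` in mmHg, `subject_id`, `beat_index`.
#' @export
compute_beat_features <- function(beat, next_r_time, abp, fs,
                                  map_rule = c("waveform_mean", "dbp_pp3"),
                                  subject_id = NA_character_) {
  map_rule <- match.arg(map_rule)
  r <- beat$r_time
  if (!(next_r_time > r)) stop("next_r_time must exceed r_time")
  ord_ok <- r < beat$o_time && beat$o_time <= beat$a_time &&
    beat$a_time <= beat$w_time && beat$w_time <= beat$b_time &&
    beat$b_time <= beat$s_time && beat$sstar_time > r &&
    beat$sstar_time <= beat$s_time && beat$dstar_time > beat$sstar_time
  if (!ord_ok) {
    stop("beat ", beat$beat_index,
         " rejected: fiducial ordering violated (require r < O <= a <= w",
         " <= b <= S and r < S* <= S < D*)")
  }
  at <- function(t) abp[as.integer(round(t * fs)) + 1L]
  sbp <- at(beat$sstar_time)
  dbp <- at(beat$dstar_time)
  i0 <- as.integer(round(r * fs)) + 1L
  i1 <- min(length(abp), as.integer(round(next_r_time * fs)))
  map <- switch(map_rule,
                waveform_mean = mean(abp[i0:i1]),
                dbp_pp3 = dbp + (sbp - dbp) / 3)
  data.frame(
    subject_id = subject_id,
    beat_index = beat$beat_index,
    pat_ro = beat$o_time - r,
    pat_ra = beat$a_time - r,
    pat_rw1 = beat$w_time - r,
    pat_rb = beat$b_time - r,
    pat_rs = beat$s_time - r,
    pat_rsstar = beat$sstar_time - r,
    ptt_sstars = beat$s_time - beat$sstar_time,
    rri = next_r_time - r,
    sbp = sbp, dbp = dbp, map = map,
    stringsAsFactors = FALSE
  )
}

#' Run the full per-record feature extraction
#'
#' Filters the ECG and PPG channels, computes the PPG derivatives, detects
#' all fiducials, pairs them into complete beats, and measures the
#' propagation features. A per-beat signal quality score (mean beat-template
#' correlation across the three channels) is attached in column `sqi` for
#' downstream best-beat selection.
#'
#' @param record a `waveform_record` with all three channels present.
#' @param map_rule passed to [compute_beat_features()].
#' @param window_frac passed to [detect_ppg_fiducials()].
#' @return Data frame of beat features (possibly zero rows), one row per
#'   surviving beat.
#' @export
extract_features <- function(record, map_rule = "waveform_mean",
                             window_frac = 0.9) {
  stopifnot(inherits(record, "waveform_record"))
  if (is.null(record$ecg) || is.null(record$ppg) || is.null(record$abp)) {
    stop("record ", record$subject_id, ": all three channels are required")
  }
  fs <- record$fs
  ecg_f <- filter_ecg(record$ecg, fs)
  ppg_f <- filter_ppg(record$ppg, fs)
  der <- derive_vpg_apg(ppg_f, fs)
  r_times <- detect_r_peaks(ecg_f, fs)
  empty <- empty_feature_table()
  if (length(r_times) < 2L) return(empty)
  abp_fid <- detect_abp_fiducials(record$abp, fs, r_times)
  ppg_fid <- detect_ppg_fiducials(der, r_times, window_frac = window_frac)
  beats <- pair_beats(r_times, abp_fid, ppg_fid)
  if (nrow(beats) == 0L) return(empty)
  # vectorized equivalent of compute_beat_features() over all paired beats
  # (ordering is already enforced by pair_beats)
  abp <- record$abp
  at <- function(t) abp[as.integer(round(t * fs)) + 1L]
  sbp <- at(beats$sstar_time)
  dbp <- at(beats$dstar_time)
  i0 <- as.integer(round(beats$r_time * fs)) + 1L
  i1 <- pmin(length(abp), as.integer(round(beats$next_r_time * fs)))
  cs <- cumsum(abp)
  map <- switch(match.arg(map_rule, c("waveform_mean", "dbp_pp3")),
                waveform_mean = (cs[i1] - cs[i0 - 1L]) / (i1 - i0 + 1L),
                dbp_pp3 = dbp + (sbp - dbp) / 3)
  ft <- data.frame(
    subject_id = record$subject_id,
    beat_index = beats$beat_index,
    pat_ro = beats$o_time - beats$r_time,
    pat_ra = beats$a_time - beats$r_time,
    pat_rw1 = beats$w_time - beats$r_time,
    pat_rb = beats$b_time - beats$r_time,
    pat_rs = beats$s_time - beats$r_time,
    pat_rsstar = beats$sstar_time - beats$r_time,
    ptt_sstars = beats$s_time - beats$sstar_time,
    rri = beats$next_r_time - beats$r_time,
    sbp = sbp, dbp = dbp, map = map,
    stringsAsFactors = FALSE)
  sqi <- beat_quality_scores(record, r_times)
  ft$sqi <- sqi$sqi[match(ft$beat_index, sqi$beat_index)]
  ft
}

empty_feature_table <- function() {
  data.frame(subject_id = character(0), beat_index = integer(0),
             pat_ro = numeric(0), pat_ra = numeric(0), pat_rw1 = numeric(0),
             pat_rb = numeric(0), pat_rs = numeric(0),
             pat_rsstar = numeric(0), ptt_sstars = numeric(0),
             rri = numeric(0), sbp = numeric(0), dbp = numeric(0),
             map = numeric(0), sqi = numeric(0), stringsAsFactors = FALSE)
}

#' Build the pooled feature table for a cohort
#'
#' @param records list of screened `waveform_record` objects.
#' @param ... passed to [extract_features()].
#' @return Data frame with one row per surviving beat across all subjects;
#'   the per-subject beat counts are available in attribute `beat_counts`.
#' @export
build_feature_table <- function(records, ...) {
  tabs <- lapply(records, extract_features, ...)
  ft <- if (length(tabs) > 0) {
    do.call(rbind, c(tabs, list(make.row.names = FALSE)))
  } else NULL
  if (is.null(ft) || nrow(ft) == 0L) ft <- empty_feature_table()
  counts <- table(factor(ft$subject_id,
                         levels = vapply(records, function(r) r$subject_id,
                                         character(1))))
  attr(ft, "beat_counts") <- counts
  ft
}
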