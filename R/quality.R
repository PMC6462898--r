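#' Automated signal-quality screening
#'
#' Reproducible proxies for visual screening of ICU waveform records into
#' seven categories: a channel that is absent or a flat line over the whole
#' record is "missing"; a present channel whose beats cannot be detected at
#' a plausible heart rate, whose beat morphology does not correlate with
#' the record's own median beat template, or (for ABP) whose values leave
#' the physiologically plausible range, is "abnormal". Missing takes
#' precedence over abnormal, and channels are checked in the order ABP,
#' ECG, PPG.
#'
#' @name quality
NULL

#' Default screening thresholds
#'
#' All constants are exposed here so screening runs are reproducible:
#' `flat_tol` (flatline SD threshold relative to the channel's mean level),
#' `sqi_min` (minimum mean beat-template correlation), `detect_min`
#' (minimum fraction of inter-beat intervals inside the heart-rate band),
#' `hr_band` (plausible heart rate, bpm), `abp_range` (plausible ABP, mmHg)
#' and `abp_outlier_max` (maximum tolerated fraction of ABP samples outside
#' that range).
#'
#' @return Named list of thresholds.
#' @export
quality_thresholds <- function() {
  list(flat_tol = 1e-6, sqi_min = 0.8, detect_min = 0.8,
       hr_band = c(30, 200), abp_range = c(20, 300), abp_outlier_max = 0.10)
}

is_flatline <- function(x, tol) {
  rg <- diff(range(x))
  rg == 0 || stats::sd(x) < tol * max(abs(mean(x)), 1)
}

# Peak detection tuned per channel: ECG uses QRS-scale windows on the
# band-passed signal; ABP/PPG use pulse-scale windows.
channel_peaks <- function(x, fs, channel) {
  f <- tryCatch({
    if (channel == "ecg") filter_ecg(x, fs) else filter_ppg(x, fs)
  }, error = function(e) NULL)
  if (is.null(f)) return(integer(0))
  if (channel == "ecg") {
    detect_peaks_ma(f, fs, w1 = 0.097, w2 = 0.611)
  } else {
    detect_peaks_ma(f, fs, w1 = 0.111, w2 = 0.667)
  }
}

# Mean correlation of each beat segment with the record's median beat
# template. Segments span -0.3 to +0.5 of the median inter-peak interval.
template_sqi <- function(x, fs, peaks) {
  if (length(peaks) < 3L) return(0)
  rr <- stats::median(diff(peaks))
  pre <- as.integer(round(0.3 * rr)); post <- as.integer(round(0.5 * rr))
  if (pre + post < 4L) return(0)
  keep <- peaks[peaks - pre >= 1L & peaks + post <= length(x)]
  if (length(keep) < 3L) return(0)
  segs <- vapply(keep, function(p) x[(p - pre):(p + post)],
                 numeric(pre + post + 1L))
  template <- apply(segs, 1L, stats::median)
  if (stats::sd(template) == 0) return(0)
  cors <- apply(segs, 2L, function(s) {
    if (stats::sd(s) == 0) return(0)
    stats::cor(s, template)
  })
  mean(cors)
}

#' Screen a record for missing channels
#'
#' @param record a [waveform_record()].
#' @param thresholds see [quality_thresholds()].
#' @return `"missing_abp"`, `"missing_ecg"`, `"missing_ppg"` (first match
#'   in that order), or `NULL` if all channels are present and varying.
#' @export
screen_missing <- function(record, thresholds = quality_thresholds()) {
  stopifnot(inherits(record, "waveform_record"))
  for (ch in c("abp", "ecg", "ppg")) {
    x <- record[[ch]]
    if (is.null(x) || is_flatline(x, thresholds$flat_tol)) {
      return(paste0("missing_", ch))
    }
  }
  NULL
}

#' Screen a record for abnormal channels
#'
#' For each channel in the order ABP, ECG, PPG: beats are detected with the
#' channel's own peak detector, and the channel fails if fewer than
#' `detect_min` of the inter-beat intervals fall in the plausible
#' heart-rate band, or if the mean beat-template correlation falls below
#' `sqi_min`. The ABP channel additionally fails if more than
#' `abp_outlier_max` of its samples lie outside `abp_range`.
#'
#' @inheritParams screen_missing
#' @return An `abnormal_*` label, or `NULL` if every channel passes.
#' @export
screen_abnormal <- function(record, thresholds = quality_thresholds()) {
  stopifnot(inherits(record, "waveform_record"))
  fs <- record$fs
  for (ch in c("abp", "ecg", "ppg")) {
    x <- record[[ch]]
    if (is.null(x)) next
    if (ch == "abp") {
      out_frac <- mean(x < thresholds$abp_range[1] |
                         x > thresholds$abp_range[2])
      if (out_frac > thresholds$abp_outlier_max) return("abnormal_abp")
    }
    peaks <- channel_peaks(x, fs, ch)
    if (length(peaks) < 3L) return(paste0("abnormal_", ch))
    ibi <- diff(peaks) / fs
    in_band <- ibi >= 60 / thresholds$hr_band[2] &
      ibi <= 60 / thresholds$hr_band[1]
    if (mean(in_band) < thresholds$detect_min) {
      return(paste0("abnormal_", ch))
    }
    if (template_sqi(x, fs, peaks) < thresholds$sqi_min) {
      return(paste0("abnormal_", ch))
    }
  }
  NULL
}

#' Classify one record into a quality category
#'
#' @inheritParams screen_missing
#' @return List of class `quality_label` with `category` (one of the seven
#'   categories) and `metrics` (named per-channel quality scores).
#' @export
screen_record <- function(record, thresholds = quality_thresholds()) {
  cat_missing <- screen_missing(record, thresholds)
  category <- if (!is.null(cat_missing)) {
    cat_missing
  } else {
    cat_abn <- screen_abnormal(record, thresholds)
    if (is.null(cat_abn)) "good" else cat_abn
  }
  metrics <- list()
  for (ch in c("abp", "ecg", "ppg")) {
    x <- record[[ch]]
    if (is.null(x)) next
    peaks <- channel_peaks(x, record$fs, ch)
    metrics[[paste0(ch, "_sqi")]] <- template_sqi(x, record$fs, peaks)
    metrics[[paste0(ch, "_n_peaks")]] <- length(peaks)
  }
  structure(list(category = category, metrics = metrics),
            class = "quality_label")
}

#' Screen a cohort of records
#'
#' @param records list of [waveform_record()] objects.
#' @param thresholds see [quality_thresholds()].
#' @return List with `ledger` (a [screening_ledger()] partitioning every
#'   input record into exactly one category) and `good` (the records that
#'   passed, in input order).
#' @export
screen_cohort <- function(records, thresholds = quality_thresholds()) {
  cats <- vapply(records, function(r) {
    screen_record(r, thresholds)$category
  }, character(1))
  ids <- vapply(records, function(r) r$subject_id, character(1))
  ledger <- screening_ledger(split(ids, factor(cats,
                                               levels = QUALITY_CATEGORIES)))
  list(ledger = ledger, good = records[cats == "good"])
}

#' Per-beat signal quality scores
#'
#' For best-beat selection: each beat (one R-to-R segment, common across
#' channels) is correlated with the channel's median beat template; the
#' beat score is the mean correlation over the three channels.
#'
#' @param record a [waveform_record()] with all three channels.
#' @param r_times R-peak times in seconds (>= 3 beats for a usable
#'   template).
#' @return Data frame with `beat_index` and `sqi` in [-1, 1] (0 when no
#'   template can be formed).
#' @export
beat_quality_scores <- function(record, r_times) {
  stopifnot(inherits(record, "waveform_record"))
  fs <- record$fs
  nb <- length(r_times) - 1L
  if (nb < 1L) {
    return(data.frame(beat_index = integer(0), sqi = numeric(0)))
  }
  rr_med <- stats::median(diff(r_times))
  seg_len <- as.integer(round(0.9 * rr_med * fs))
  starts <- as.integer(round(r_times[seq_len(nb)] * fs)) + 1L
  scores <- matrix(0, nrow = nb, ncol = 3L)
  chans <- c("ecg", "ppg", "abp")
  for (k in seq_along(chans)) {
    x <- record[[chans[k]]]
    if (is.null(x)) next
    ok <- starts + seg_len - 1L <= length(x)
    if (sum(ok) < 3L) next
    segs <- vapply(starts[ok], function(s0) x[s0:(s0 + seg_len - 1L)],
                   numeric(seg_len))
    template <- apply(segs, 1L, stats::median)
    if (stats::sd(template) == 0) next
    cors <- apply(segs, 2L, function(s) {
      if (stats::sd(s) == 0) return(0)
      stats::cor(s, template)
    })
    scores[ok, k] <- cors
  }
  data.frame(beat_index = seq_len(nb), sqi = rowMeans(scores))
}
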