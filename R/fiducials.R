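#' Fiducial point detection
#'
#' Per-beat landmark detection on the three channels: the ECG R peak anchors
#' each beat; the ABP systolic peak S* and diastolic trough D* are located
#' in each R-to-R window; and the PPG-family points -- pulse foot O and
#' systolic peak S on the PPG, maximum-slope point w on the VPG, and the a
#' and b waves on the APG -- are located in a window covering the first 90%
#' of each cardiac cycle. All times are reported at sample resolution, with
#' ties in window extrema broken by the earliest sample.
#'
#' @name fiducials
NULL

# Centered running mean with edge windows truncated symmetrically.
run_mean <- function(x, w) {
  n <- length(x)
  w <- min(as.integer(w), n)
  cs <- cumsum(c(0, x))
  half <- w %/% 2L
  lo <- pmax(1L, seq_len(n) - half)
  hi <- pmin(n, seq_len(n) + half)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Two-event moving-average peak detector (the TERMA scheme): the squared,
# positively rectified signal is smoothed at an event-scale window w1 and a
# cycle-scale window w2; runs where the event average exceeds the cycle
# average plus an offset mark candidate peaks. A refractory period keeps
# only the larger of two competing detections.
detect_peaks_ma <- function(x, fs, w1, w2, beta = 0.08, refractory = 0.25,
                            min_block = w1) {
  n <- length(x)
  if (n < 5L) return(integer(0))
  s <- pmax(x - stats::median(x), 0)^2
  if (max(s) <= 0) return(integer(0))
  W1 <- max(1L, as.integer(round(w1 * fs)))
  W2 <- max(W1 + 1L, as.integer(round(w2 * fs)))
  ma_peak <- run_mean(s, W1)
  ma_beat <- run_mean(s, W2)
  thr <- ma_beat + beta * mean(s)
  above <- ma_peak > thr
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= max(1L, as.integer(round(min_block * fs)))
  peaks <- integer(0)
  for (k in which(keep)) {
    blk <- starts[k]:ends[k]
    peaks <- c(peaks, blk[which.max(x[blk])])
  }
  if (length(peaks) == 0L) return(integer(0))
  # snap to the local maximum of x within +/-2 samples
  for (j in seq_along(peaks)) {
    lo <- max(1L, peaks[j] - 2L); hi <- min(n, peaks[j] + 2L)
    peaks[j] <- (lo:hi)[which.max(x[lo:hi])]
  }
  # refractory: keep the larger of detections closer than the refractory gap
  ref <- as.integer(round(refractory * fs))
  out <- peaks[1L]
  for (p in peaks[-1L]) {
    last <- out[length(out)]
    if (p - last < ref) {
      if (x[p] > x[last]) out[length(out)] <- p
    } else {
      out <- c(out, p)
    }
  }
  unique(out)
}

#' Detect ECG R peaks
#'
#' Two-event moving-average thresholding on the squared, rectified filtered
#' ECG with a 250 ms refractory period. Every returned time is a local
#' maximum of the input. A flat or too-short signal yields an empty result
#' rather than an error.
#'
#' @param ecg filtered ECG samples.
#' @param fs sampling rate in Hz.
#' @param refractory minimum R-to-R separation in seconds (default 0.25).
#' @return Numeric vector of strictly increasing R-peak times in seconds
#'   from record start (sample `i` maps to time `(i - 1) / fs`).
#' @export
detect_r_peaks <- function(ecg, fs, refractory = 0.25) {
  stopifnot(fs > 0)
  idx <- detect_peaks_ma(ecg, fs, w1 = 0.097, w2 = 0.611,
                         refractory = refractory)
  (idx - 1) / fs
}

#' Detect ABP systolic peak and diastolic trough per beat
#'
#' Within each R-to-R window, S* is the global ABP maximum and D* the
#' minimum between S* and the next R. Beats whose window has no interior
#' peak (maximum at a window edge, as on a monotone segment) are dropped;
#' the final partial beat (no following R) is excluded.
#'
#' @param abp ABP samples (mmHg, unfiltered).
#' @param fs sampling rate in Hz.
#' @param r_times R-peak times in seconds (non-empty).
#' @return Data frame with columns `beat_index`, `sstar_time`, `dstar_time`.
#' @export
detect_abp_fiducials <- function(abp, fs, r_times) {
  stopifnot(length(r_times) > 0, fs > 0)
  nb <- max(0L, length(r_times) - 1L)
  ss <- ds <- rep(NA_integer_, nb)
  for (i in seq_len(nb)) {
    lo <- as.integer(round(r_times[i] * fs)) + 2L    # strictly after R
    hi <- as.integer(round(r_times[i + 1L] * fs))    # strictly before next R
    if (hi - lo < 3L || hi > length(abp)) next
    win <- abp[lo:hi]
    si <- which.max(win)
    if (si == 1L || si == length(win)) next          # no interior peak
    di <- si + which.min(win[(si + 1L):length(win)])
    ss[i] <- lo + si - 1L
    ds[i] <- lo + di - 1L
  }
  ok <- which(!is.na(ss))
  data.frame(beat_index = ok, sstar_time = (ss[ok] - 1L) / fs,
             dstar_time = (ds[ok] - 1L) / fs)
}

#' Detect PPG, VPG, and APG fiducials per beat
#'
#' Within each window `(r_i, r_i + window_frac * RRI)`: S is the PPG
#' maximum; w the VPG maximum before S; a the APG maximum before w; b the
#' APG minimum between a and S; and O the PPG minimum between R and a (the
#' pulse foot). Beats violating the ordering `O <= a <= w <= b <= S` or with
#' degenerate windows are dropped.
#'
#' @param derived a [derive_vpg_apg()] result.
#' @param r_times R-peak times in seconds (non-empty).
#' @param window_frac fraction of the R-to-R interval searched (default 0.9,
#'   excluding the next beat's upstroke).
#' @return Data frame with columns `beat_index`, `o_time`, `a_time`,
#'   `w_time`, `b_time`, `s_time`.
#' @export
detect_ppg_fiducials <- function(derived, r_times, window_frac = 0.9) {
  stopifnot(inherits(derived, "derived_ppg"), length(r_times) > 0)
  fs <- derived$fs
  ppg <- derived$ppg; vpg <- derived$vpg; apg <- derived$apg
  nb <- max(0L, length(r_times) - 1L)
  o <- a <- w <- b <- s <- rep(NA_integer_, nb)
  for (i in seq_len(nb)) {
    rri <- r_times[i + 1L] - r_times[i]
    lo <- as.integer(round(r_times[i] * fs)) + 2L
    hi <- as.integer(round((r_times[i] + window_frac * rri) * fs))
    if (hi - lo < 5L || hi > length(ppg)) next
    win <- lo:hi
    si <- win[which.max(ppg[win])]
    if (si <= lo || si >= hi || si - lo < 3L) next
    wi <- (lo:(si - 1L))[which.max(vpg[lo:(si - 1L)])]
    if (wi - lo < 2L) next
    ai <- (lo:(wi - 1L))[which.max(apg[lo:(wi - 1L)])]
    bi <- (ai:si)[which.min(apg[ai:si])]
    if (ai - lo < 1L) next
    oi <- (lo:(ai - 1L))[which.min(ppg[lo:(ai - 1L)])]
    if (!(oi <= ai && ai <= wi && wi <= bi && bi <= si)) next
    o[i] <- oi; a[i] <- ai; w[i] <- wi; b[i] <- bi; s[i] <- si
  }
  ok <- which(!is.na(s))
  data.frame(beat_index = ok,
             o_time = (o[ok] - 1L) / fs, a_time = (a[ok] - 1L) / fs,
             w_time = (w[ok] - 1L) / fs, b_time = (b[ok] - 1L) / fs,
             s_time = (s[ok] - 1L) / fs)
}

#' Pair per-channel fiducials into complete beats
#'
#' Inner-joins the ABP and PPG fiducial tables on beat index and keeps only
#' beats with the complete landmark set satisfying the cross-channel
#' ordering `r < o` and `r < sstar <= s < dstar-window`; `beat_index` is
#' preserved for traceability back to the R-peak sequence.
#'
#' @param r_times R-peak times in seconds.
#' @param abp_fiducials result of [detect_abp_fiducials()].
#' @param ppg_fiducials result of [detect_ppg_fiducials()].
#' @return Data frame with one row per surviving beat: `beat_index`,
#'   `r_time`, `o_time`, `a_time`, `w_time`, `b_time`, `s_time`,
#'   `sstar_time`, `dstar_time`, `next_r_time`.
#' @export
pair_beats <- function(r_times, abp_fiducials, ppg_fiducials) {
  m <- merge(ppg_fiducials, abp_fiducials, by = "beat_index")
  if (nrow(m) == 0L) {
    return(cbind(m[0, ], data.frame(r_time = numeric(0),
                                    next_r_time = numeric(0))))
  }
  m$r_time <- r_times[m$beat_index]
  m$next_r_time <- r_times[m$beat_index + 1L]
  ok <- m$r_time < m$o_time &
    m$o_time <= m$a_time & m$a_time <= m$w_time &
    m$w_time <= m$b_time & m$b_time <= m$s_time &
    m$sstar_time > m$r_time & m$sstar_time <= m$s_time &
    m$dstar_time > m$sstar_time & m$s_time < m$next_r_time
  m <- m[ok, , drop = FALSE]
  m <- m[order(m$beat_index),
         c("beat_index", "r_time", "o_time", "a_time", "w_time", "b_time",
           "s_time", "sstar_time", "dstar_time", "next_r_time")]
  rownames(m) <- NULL
  m
}
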