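#' Synthetic ECG/PPG/ABP record generation
#'
#' Generates synchronized three-channel records with per-beat ground truth
#' and a programmable linear coupling between pulse arrival time and
#' systolic pressure. Beat-to-beat SBP follows a bounded first-order
#' autoregressive walk; for each beat i the R-to-PPG-systolic-peak interval
#' is programmed as
#' `PAT_RS(i) = pat_rs_mean + coupling_slope * (SBP(i) - sbp_mean) + noise`,
#' and the ABP systolic peak is placed at `pat_rsstar_fraction * PAT_RS(i)`
#' after R. Pulse shapes are two-bump kernels (a dominant systolic wave plus
#' a smaller, later diastolic wave) so the pulse foot O, maximum-slope point
#' w, APG a and b waves, and systolic peak S all exist and are separable.
#'
#' @name synthetic
NULL

# Fixed morphology/process constants (documented, not user-tunable):
# AR(1) persistence of the beat-to-beat SBP walk; kernel widths and
# relative amplitudes of the rendered pulses; ECG P/T wave geometry.
SYN_AR1_PHI <- 0.9
SYN_SBP_FLOOR_MARGIN <- 30    # SBP floor = dbp_offset + this (mmHg)
SYN_SBP_CEILING <- 250        # physiologic ceiling (mmHg)
SYN_PP_NOISE_FRAC <- 0.03     # pulse-pressure jitter, fraction of dbp_offset
SYN_PPG_SYS_SD <- 0.09        # s, systolic bump width
SYN_PPG_DIA_SD <- 0.16        # s (wide: keeps the pulse foot a sharp V)
SYN_PPG_DIA_DELAY <- 0.20     # s after the systolic peak
SYN_PPG_DIA_AMP <- 0.40       # relative to systolic amplitude 1
SYN_ABP_SYS_SD <- 0.08        # s
SYN_ABP_DIA_SD <- 0.12        # s
SYN_ABP_DIA_DELAY <- 0.25     # s
SYN_ABP_DIA_AMP <- 0.25

#' Synthetic record configuration
#'
#' Defaults emulate the study conditions of the source recordings: 125 Hz
#' sampling, roughly two minutes of signal (150 beats at 75 bpm), SBP
#' varying around 120 mmHg with 8 mmHg beat-to-beat spread, a 40 mmHg mean
#' pulse pressure, a negative PAT-SBP coupling of -2 ms/mmHg around a
#' 350 ms mean PAT, and the ABP systolic peak at 60% of the R-to-PPG-peak
#' interval.
#'
#' @param n_beats number of beats (>= 1).
#' @param fs sampling rate in Hz (> 0).
#' @param hr_mean,hr_sd heart rate mean and beat-to-beat SD, beats/min.
#' @param sbp_mean,sbp_sd stationary mean and SD of the SBP walk, mmHg.
#' @param dbp_offset mean pulse pressure SBP - DBP, mmHg.
#' @param coupling_slope change in PAT_RS per mmHg of SBP, s/mmHg
#'   (negative for physiological behavior).
#' @param pat_rs_mean mean R-to-PPG-systolic-peak interval, s.
#' @param pat_rsstar_fraction fraction of PAT_RS at which the ABP systolic
#'   peak occurs, in (0, 1).
#' @param pat_noise_sd per-beat PAT jitter SD, s.
#' @param amplitude_noise_sd additive white noise SD relative to unit pulse
#'   amplitude (the ABP channel scales it by `dbp_offset`).
#' @param seed integer RNG seed (< 2^31 - 1).
#' @return Validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_beats = 150, fs = 125, hr_mean = 75,
                             hr_sd = 3, sbp_mean = 120, sbp_sd = 8,
                             dbp_offset = 40, coupling_slope = -0.002,
                             pat_rs_mean = 0.35, pat_rsstar_fraction = 0.6,
                             pat_noise_sd = 0.01, amplitude_noise_sd = 0.02,
                             seed = 1L) {
  cfg <- list(n_beats = as.integer(n_beats), fs = fs, hr_mean = hr_mean,
              hr_sd = hr_sd, sbp_mean = sbp_mean, sbp_sd = sbp_sd,
              dbp_offset = dbp_offset, coupling_slope = coupling_slope,
              pat_rs_mean = pat_rs_mean,
              pat_rsstar_fraction = pat_rsstar_fraction,
              pat_noise_sd = pat_noise_sd,
              amplitude_noise_sd = amplitude_noise_sd,
              seed = as.integer(seed))
  if (cfg$n_beats < 1L) stop("n_beats must be >= 1")
  if (cfg$fs <= 0) stop("fs must be positive")
  if (cfg$hr_mean <= 0) stop("hr_mean must be positive")
  if (cfg$hr_sd < 0 || cfg$sbp_sd < 0 || cfg$pat_noise_sd < 0 ||
      cfg$amplitude_noise_sd < 0) stop("noise SDs must be non-negative")
  if (cfg$pat_rsstar_fraction <= 0 || cfg$pat_rsstar_fraction >= 1) {
    stop("pat_rsstar_fraction must lie strictly in (0, 1)")
  }
  if (cfg$pat_rs_mean <= 0) stop("pat_rs_mean must be positive")
  if (cfg$dbp_offset <= 0) stop("dbp_offset must be positive")
  if (abs(cfg$seed) >= 2^31 - 1) stop("seed out of 32-bit integer range")
  class(cfg) <- "synthetic_config"
  cfg
}

#' Generate the per-beat blood-pressure series
#'
#' Bounded AR(1) walk: `sbp_i = m + phi (sbp_{i-1} - m) + e_i` with
#' persistence 0.9 and innovation SD chosen so the stationary SD equals
#' `sbp_sd`; values are clipped to `[dbp_offset + 30, 250]` mmHg. DBP is
#' SBP minus a jittered pulse pressure; the MAP column here is the
#' DBP + PP/3 estimate (the rendered-waveform ground truth replaces it with
#' the cycle-average rule used by the feature extractor).
#'
#' @param config a [synthetic_config()].
#' @return Data frame with `n_beats` rows: `sbp`, `dbp`, `map` (mmHg);
#'   deterministic given `config$seed`.
#' @export
generate_bp_series <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_beats
  phi <- SYN_AR1_PHI
  withr::with_seed(config$seed, {
    e <- rnorm(n, 0, config$sbp_sd * sqrt(1 - phi^2))
    sbp <- numeric(n)
    sbp[1] <- config$sbp_mean + rnorm(1, 0, config$sbp_sd)
    for (i in seq_len(n)[-1]) {
      sbp[i] <- config$sbp_mean + phi * (sbp[i - 1] - config$sbp_mean) + e[i]
    }
    lo <- config$dbp_offset + SYN_SBP_FLOOR_MARGIN
    sbp <- pmin(pmax(sbp, lo), SYN_SBP_CEILING)
    pp <- config$dbp_offset +
      rnorm(n, 0, SYN_PP_NOISE_FRAC * config$dbp_offset)
    pp <- pmax(pp, 10)
  })
  dbp <- sbp - pp
  data.frame(sbp = sbp, dbp = dbp, map = dbp + pp / 3)
}

# Gaussian bump train: adds amps[j] * exp(-(t - centers[j])^2 / (2 sd^2))
# for every beat j, truncated at +/- 5 sd. Vectorized across beats by
# looping over kernel offsets; beat centers are at least one refractory
# interval apart, so positions never collide within one offset row.
add_bumps <- function(y, centers, sd_s, amps, fs) {
  n <- length(y)
  half <- as.integer(ceiling(5 * sd_s * fs))
  base <- as.integer(round(centers * fs))        # 0-based center sample
  for (off in (-half):half) {
    pos <- base + off + 1L
    ok <- pos >= 1L & pos <= n
    if (!any(ok)) next
    t_off <- (pos[ok] - 1L) / fs - centers[ok]
    y[pos[ok]] <- y[pos[ok]] + amps[ok] * exp(-t_off^2 / (2 * sd_s^2))
  }
  y
}

# The diastolic bump's tail shifts the summed kernel's maximum slightly off
# the systolic bump center. This computes that constant offset once so the
# systolic center can be pre-shifted and the rendered peak lands exactly on
# the programmed time.
kernel_peak_shift <- function(sd_s, sd_d, delay, amp_d) {
  f <- function(t) {
    exp(-t^2 / (2 * sd_s^2)) +
      amp_d * exp(-(t - delay)^2 / (2 * sd_d^2))
  }
  opt <- stats::optimize(f, c(-0.1, 0.1), maximum = TRUE)
  list(shift = opt$maximum, gain = opt$objective)
}

# Windowed extremum on the clean rendered signal; returns the sample index
# (earliest on ties, which.max/min semantics).
win_extreme <- function(x, lo, hi, max = TRUE) {
  lo <- max(1L, lo); hi <- min(length(x), hi)
  if (hi <= lo) return(NA_integer_)
  w <- x[lo:hi]
  lo - 1L + if (max) which.max(w) else which.min(w)
}

#' Generate one synthetic record with ground truth
#'
#' Renders the three channels on a common sample grid and derives the
#' ground-truth fiducial times from the clean (noise-free) rendering by the
#' same windowed-extremum definitions the detectors use, so ground truth
#' and waveform agree to within one sample. White amplitude noise is added
#' afterwards.
#'
#' @param config a [synthetic_config()].
#' @return List with elements `record` (a [waveform_record()]) and `truth`,
#'   a data frame with one row per beat: fiducial times (`r_time`,
#'   `o_time`, `a_time`, `w_time`, `b_time`, `s_time`, `sstar_time`,
#'   `dstar_time`, s), `sbp`, `dbp`, `map` (mmHg), and the programmed
#'   `pat_rs` before rendering.
#' @export
generate_record <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  fs <- config$fs
  n <- config$n_beats
  bp <- generate_bp_series(config)

  withr::with_seed(config$seed + 1L, {
    hr <- pmin(pmax(rnorm(n, config$hr_mean, config$hr_sd), 30), 200)
    rr <- 60 / hr
    pat_noise <- rnorm(n, 0, config$pat_noise_sd)
  })
  r_cont <- 0.8 + c(0, cumsum(rr[-n]))
  pat_rs <- config$pat_rs_mean +
    config$coupling_slope * (bp$sbp - config$sbp_mean) + pat_noise
  if (any(pat_rs <= 0.05) || any(pat_rs >= 0.9 * rr)) {
    stop("config rejected: programmed PAT values must stay positive and ",
         "below the beat period (got range [",
         signif(min(pat_rs), 3), ", ", signif(max(pat_rs), 3), "] s)")
  }

  end_time <- r_cont[n] + rr[n]
  nsamp <- as.integer(floor(end_time * fs))
  tg <- (seq_len(nsamp) - 1) / fs

  s_center <- r_cont + pat_rs                          # PPG systolic peak
  tstar <- r_cont + config$pat_rsstar_fraction * pat_rs # ABP systolic peak

  k_ppg <- kernel_peak_shift(SYN_PPG_SYS_SD, SYN_PPG_DIA_SD,
                             SYN_PPG_DIA_DELAY, SYN_PPG_DIA_AMP)
  k_abp <- kernel_peak_shift(SYN_ABP_SYS_SD, SYN_ABP_DIA_SD,
                             SYN_ABP_DIA_DELAY, SYN_ABP_DIA_AMP)
  d_ppg <- k_ppg$shift
  d_abp <- k_abp$shift
  ecg <- numeric(nsamp); ppg <- numeric(nsamp)
  ones <- rep(1, n)
  ecg <- add_bumps(ecg, r_cont, 0.020, ones, fs)                  # R spikes
  ecg <- add_bumps(ecg, r_cont - 0.18, 0.030, 0.12 * ones, fs)    # P waves
  ecg <- add_bumps(ecg, r_cont + 0.30 * rr, 0.050, 0.25 * ones, fs) # T
  # Phantom lead-in pulse (PPG/ABP only, no ECG R spike): gives the first
  # counted beat a preceding diastolic tail so its pulse foot is as sharp
  # as every later beat's.
  ppg_c <- c(s_center[1] - rr[1], s_center) - d_ppg
  ppg <- add_bumps(ppg, ppg_c, SYN_PPG_SYS_SD, rep(1, n + 1L), fs)
  ppg <- add_bumps(ppg, ppg_c + SYN_PPG_DIA_DELAY, SYN_PPG_DIA_SD,
                   rep(SYN_PPG_DIA_AMP, n + 1L), fs)
  # ABP: slowly varying diastolic baseline (linear interpolation through a
  # knot shortly before each next beat) plus per-beat pressure pulses,
  # scaled so the rendered peak (baseline + kernel) hits sbp exactly.
  knot_t <- c(r_cont[1] - 0.05, r_cont[-1] - 0.05, end_time)
  knot_v <- c(bp$dbp[1], bp$dbp[-n], bp$dbp[n])
  abp <- approx(knot_t, knot_v, xout = tg, rule = 2)$y
  base_at_peak <- approx(knot_t, knot_v, xout = tstar, rule = 2)$y
  amps <- c(bp$sbp[1] - bp$dbp[1],                  # phantom lead-in pulse
            bp$sbp - base_at_peak) / k_abp$gain
  abp_c <- c(tstar[1] - rr[1], tstar) - d_abp
  abp <- add_bumps(abp, abp_c, SYN_ABP_SYS_SD, amps, fs)
  abp <- add_bumps(abp, abp_c + SYN_ABP_DIA_DELAY, SYN_ABP_DIA_SD,
                   SYN_ABP_DIA_AMP * amps, fs)

  # Ground truth from the clean rendering, windowed as the detectors window.
  idx_of <- function(t) as.integer(round(t * fs)) + 1L
  r_idx <- vapply(seq_len(n), function(i) {
    win_extreme(ecg, idx_of(r_cont[i] - 0.04), idx_of(r_cont[i] + 0.04))
  }, integer(1))
  next_edge <- c(r_idx[-1], nsamp + 1L)
  vpg <- diff(ppg) * fs; vpg <- c(vpg, vpg[length(vpg)])
  apg <- diff(vpg) * fs; apg <- c(apg, apg[length(apg)])
  cs_abp <- cumsum(abp)
  oi <- ai <- wi <- bi <- si <- ssi <- dsi <- integer(n)
  map_gt <- numeric(n)
  for (i in seq_len(n)) {
    lo <- r_idx[i] + 1L
    hi_ppg <- idx_of(r_cont[i] + 0.9 * rr[i])
    si[i] <- win_extreme(ppg, lo, hi_ppg)
    wi[i] <- win_extreme(vpg, lo, si[i] - 1L)
    ai[i] <- win_extreme(apg, lo, wi[i] - 1L)
    bi[i] <- win_extreme(apg, ai[i], si[i], max = FALSE)
    oi[i] <- win_extreme(ppg, lo, ai[i] - 1L, max = FALSE)
    hi_abp <- next_edge[i] - 1L
    ssi[i] <- win_extreme(abp, lo, hi_abp)
    dsi[i] <- win_extreme(abp, ssi[i] + 1L, hi_abp, max = FALSE)
    i1 <- min(nsamp, next_edge[i] - 1L)
    map_gt[i] <- (cs_abp[i1] - cs_abp[r_idx[i] - 1L]) / (i1 - r_idx[i] + 1L)
  }
  truth <- data.frame(
    beat_index = seq_len(n),
    r_time = (r_idx - 1L) / fs,
    o_time = (oi - 1L) / fs, a_time = (ai - 1L) / fs,
    w_time = (wi - 1L) / fs, b_time = (bi - 1L) / fs,
    s_time = (si - 1L) / fs,
    sstar_time = (ssi - 1L) / fs, dstar_time = (dsi - 1L) / fs,
    sbp = abp[ssi], dbp = abp[dsi], map = map_gt, pat_rs = pat_rs)

  withr::with_seed(config$seed + 2L, {
    ecg <- ecg + rnorm(nsamp, 0, config$amplitude_noise_sd)
    ppg <- ppg + rnorm(nsamp, 0, config$amplitude_noise_sd)
    abp <- abp + rnorm(nsamp, 0, config$amplitude_noise_sd * config$dbp_offset)
  })

  rec <- waveform_record(subject_id = sprintf("sim%08d", config$seed),
                         fs = fs, ecg = ecg, ppg = ppg, abp = abp)
  list(record = rec, truth = truth)
}

#' Corrupt a record into one of the six excluded categories
#'
#' `missing_*` modes replace the named channel with a constant (a flat line
#' over the whole record); `abnormal_*` modes destroy the channel's
#' morphology with heavy broadband noise (for ABP, wide enough to also
#' leave the physiologically plausible 20--300 mmHg range), leaving the
#' other channels intact. Deterministic given `seed`.
#'
#' @param record a [waveform_record()].
#' @param mode one of `missing_abp`, `missing_ecg`, `missing_ppg`,
#'   `abnormal_abp`, `abnormal_ecg`, `abnormal_ppg` (`good` is rejected).
#' @param seed integer RNG seed.
#' @return The corrupted `waveform_record`.
#' @export
corrupt_record <- function(record, mode, seed = 1L) {
  stopifnot(inherits(record, "waveform_record"))
  modes <- setdiff(QUALITY_CATEGORIES, "good")
  if (identical(mode, "good")) stop("mode 'good' is not a corruption mode")
  mode <- match.arg(mode, modes)
  ch <- sub("^(missing|abnormal)_", "", mode)
  x <- record[[ch]]
  n <- length(x)
  if (grepl("^missing_", mode)) {
    record[[ch]] <- rep(mean(x), n)
  } else {
    withr::with_seed(as.integer(seed), {
      noise_sd <- if (ch == "abp") 120 else 5 * stats::sd(x)
      record[[ch]] <- 0.25 * x + rnorm(n, 0, noise_sd)
    })
  }
  record
}
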