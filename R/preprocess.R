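#' Zero-phase band-pass filtering and PPG derivatives
#'
#' ECG is conditioned with a Butterworth band-pass (default 0.5--40 Hz) and
#' PPG with a Chebyshev type-II band-pass (default 0.5--10 Hz, 20 dB
#' stopband attenuation). Both are applied forward and backward so the net
#' phase shift is zero; interval measurements between channels are therefore
#' not biased by filter group delay. The first and second forward
#' differences of the filtered PPG (scaled to per-second units) give the
#' velocity (VPG) and acceleration (APG) photoplethysmograms used for
#' fiducial detection.
#'
#' @name preprocess
NULL

# Second-order-section decomposition of a transfer function. High-order
# narrow band-pass polynomials (poles crowded near z = 1) are
# ill-conditioned in direct form; factoring into biquads keeps the
# recursion numerically clean. Poles are paired conjugate-with-conjugate
# (reals with reals), ordered nearest the unit circle first, and each pair
# takes its nearest zero pair.
tf_to_sos <- function(b, a) {
  b <- b / a[1]; a <- a / a[1]
  gain <- b[1]
  zs <- polyroot(rev(b / gain))
  ps <- polyroot(rev(a))
  pair_roots <- function(r) {
    used <- rep(FALSE, length(r))
    pairs <- list()
    for (i in order(-abs(r))) {
      if (used[i]) next
      used[i] <- TRUE
      cand <- which(!used & (abs(Im(r)) < 1e-8) == (abs(Im(r[i])) < 1e-8))
      j <- cand[which.min(abs(r[cand] - Conj(r[i])))]
      used[j] <- TRUE
      pairs[[length(pairs) + 1L]] <- c(r[i], r[j])
    }
    pairs
  }
  pp <- pair_roots(ps)
  zp <- pair_roots(zs)
  # match each pole pair (unit-circle-nearest first) with its closest
  # remaining zero pair
  sos <- vector("list", length(pp))
  taken <- rep(FALSE, length(zp))
  for (k in seq_along(pp)) {
    d <- vapply(seq_along(zp), function(j) {
      if (taken[j]) return(Inf)
      min(Mod(zp[[j]][1] - pp[[k]][1]), Mod(zp[[j]][2] - pp[[k]][1]))
    }, numeric(1))
    j <- which.min(d)
    taken[j] <- TRUE
    poly2 <- function(r) c(1, -Re(r[1] + r[2]), Re(r[1] * r[2]))
    sos[[k]] <- list(b = poly2(zp[[j]]), a = poly2(pp[[k]]))
  }
  sos[[1]]$b <- sos[[1]]$b * gain
  sos
}

# One biquad pass with steady-state initial conditions: the recursion
# starts as if the input had been constant at x[1] forever, so a constant
# signal maps to its steady-state response with no start-up transient.
biquad_filter <- function(sec, x) {
  b <- sec$b; a <- sec$a
  h1 <- sum(b) / sum(a)
  u <- stats::filter(c(x[1], x[1], x), b, sides = 1)[-(1:2)]
  y <- stats::filter(u, -a[2:3], method = "recursive",
                     init = rep(h1 * x[1], 2))
  as.numeric(y)
}

sos_pass <- function(sos, x) {
  for (sec in sos) x <- biquad_filter(sec, x)
  x
}

# Zero-phase filtering: odd-reflect padding (mirrored, sign-inverted copy
# at both ends, 3 s long) followed by a forward and a backward pass through
# the biquad cascade, so startup transients of the narrow 0.5 Hz high-pass
# edge decay inside the padding and the net phase shift is zero.
filtfilt_zero_phase <- function(b, a, x, fs) {
  n <- length(x)
  ncoef <- max(length(b), length(a))
  if (n <= 3L * ncoef) {
    stop("signal too short for zero-phase filtering: ", n,
         " samples, need more than ", 3L * ncoef)
  }
  sos <- tf_to_sos(b, a)
  pad <- min(n - 1L, as.integer(round(3 * fs)))
  left <- 2 * x[1L] - x[(pad + 1L):2L]
  right <- 2 * x[n] - x[(n - 1L):(n - pad)]
  xp <- c(left, x, right)
  y <- sos_pass(sos, xp)
  y <- rev(sos_pass(sos, rev(y)))
  y[(pad + 1L):(pad + n)]
}

# Band edges are clipped below Nyquist (with a warning) when fs is too low
# for the requested upper edge.
clip_band <- function(low, high, fs) {
  nyq <- fs / 2
  if (high >= nyq) {
    high <- 0.95 * nyq
    warning("upper band edge clipped to ", signif(high, 4),
            " Hz (Nyquist = ", nyq, " Hz)")
  }
  if (low <= 0 || low >= high) stop("invalid band edges [", low, ", ", high, "]")
  c(low, high)
}

#' Zero-phase Butterworth band-pass for ECG
#'
#' @param x numeric vector of ECG samples.
#' @param fs sampling rate in Hz (> 0).
#' @param band numeric length-2 pass band in Hz; default `c(0.5, 40)`.
#' @param order Butterworth prototype order (the band-pass doubles it).
#' @return Filtered signal, same length as `x`, with zero net phase shift.
#' @export
filter_ecg <- function(x, fs, band = c(0.5, 40), order = 4) {
  stopifnot(is.numeric(x), fs > 0)
  band <- clip_band(band[1], band[2], fs)
  flt <- signal::butter(order, band / (fs / 2), type = "pass")
  filtfilt_zero_phase(flt$b, flt$a, x, fs)
}

#' Zero-phase Chebyshev type-II band-pass for PPG
#'
#' @inheritParams filter_ecg
#' @param band numeric length-2 band in Hz; default `c(0.5, 10)`.
#' @param Rs stopband attenuation in dB (default 20).
#' @return Filtered signal, same length as `x`, with zero net phase shift.
#' @export
filter_ppg <- function(x, fs, band = c(0.5, 10), order = 4, Rs = 20) {
  stopifnot(is.numeric(x), fs > 0)
  band <- clip_band(band[1], band[2], fs)
  flt <- signal::cheby2(order, Rs, band / (fs / 2), type = "pass")
  filtfilt_zero_phase(flt$b, flt$a, x, fs)
}

#' Velocity and acceleration photoplethysmograms
#'
#' First and second forward differences of the (filtered) PPG, scaled by the
#' sampling rate so VPG is in signal-units/s and APG in signal-units/s^2,
#' making fiducial amplitudes invariant to `fs`. The final sample of each
#' derivative is replicated so all three arrays share the PPG's length.
#'
#' @param ppg numeric vector of filtered PPG samples (>= 3 samples).
#' @param fs sampling rate in Hz.
#' @return An object of class `derived_ppg`: list with elements `ppg`,
#'   `vpg`, `apg`, `fs`.
#' @export
derive_vpg_apg <- function(ppg, fs) {
  stopifnot(is.numeric(ppg), fs > 0)
  if (length(ppg) < 3L) stop("need at least 3 PPG samples for derivatives")
  vpg <- diff(ppg) * fs
  vpg <- c(vpg, vpg[length(vpg)])
  apg <- diff(vpg) * fs
  apg <- c(apg, apg[length(apg)])
  structure(list(ppg = ppg, vpg = vpg, apg = apg, fs = fs),
            class = "derived_ppg")
}
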