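# Shared fixtures: small synthetic records built in code at test time.

quick_config <- function(...) {
  args <- utils::modifyList(list(n_beats = 30L, seed = 101L), list(...))
  do.call(synthetic_config, args)
}

# A noise-free record where detectors should be sample-exact.
clean_config <- function(...) {
  quick_config(hr_sd = 0, pat_noise_sd = 0, amplitude_noise_sd = 0, ...)
}

# Run the detection chain on a record, returning paired beats.
detect_beats <- function(record) {
  fs <- record$fs
  r_times <- detect_r_peaks(filter_ecg(record$ecg, fs), fs)
  pair_beats(r_times,
             detect_abp_fiducials(record$abp, fs, r_times),
             detect_ppg_fiducials(derive_vpg_apg(filter_ppg(record$ppg, fs),
                                                 fs), r_times))
}

# Independent brute-force Pearson oracle: definition-level sums, no shared
# code with pearson().
pearson_bruteforce <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  num <- 0; sx <- 0; sy <- 0
  for (i in seq_len(n)) {
    num <- num + (x[i] - mx) * (y[i] - my)
    sx <- sx + (x[i] - mx)^2
    sy <- sy + (y[i] - my)^2
  }
  num / (sqrt(sx) * sqrt(sy))
}
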