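test_that("R peaks are found at ground truth on clean records", {
  gen <- generate_record(clean_config(n_beats = 40, seed = 3))
  fs <- gen$record$fs
  r <- detect_r_peaks(filter_ecg(gen$record$ecg, fs), fs)
  expect_length(r, 40)
  expect_true(all(diff(r) > 0))
  expect_true(all(abs(round((r - gen$truth$r_time) * fs)) <= 1))
})

test_that("flat or empty signals yield no detections", {
  expect_length(detect_r_peaks(rep(0, 1000), 125), 0)
  expect_length(detect_r_peaks(rep(5, 1000), 125), 0)
  expect_length(detect_r_peaks(numeric(0), 125), 0)
})

test_that("R detection stays near-perfect under default noise", {
  sens <- ppv <- numeric(0)
  for (s in c(11, 12, 13)) {
    gen <- generate_record(quick_config(n_beats = 80, seed = s))
    fs <- gen$record$fs
    det <- detect_r_peaks(filter_ecg(gen$record$ecg, fs), fs)
    hits <- vapply(gen$truth$r_time, function(t0) {
      any(abs(det - t0) * fs <= 3)
    }, logical(1))
    claimed <- vapply(det, function(t0) {
      any(abs(gen$truth$r_time - t0) * fs <= 3)
    }, logical(1))
    sens <- c(sens, mean(hits))
    ppv <- c(ppv, mean(claimed))
  }
  expect_gte(min(sens), 0.99)
  expect_gte(min(ppv), 0.99)
})

test_that("ABP fiducials: interior-peak contract and window edges", {
  gen <- generate_record(clean_config(n_beats = 30, seed = 5))
  fs <- gen$record$fs
  r <- detect_r_peaks(filter_ecg(gen$record$ecg, fs), fs)
  ab <- detect_abp_fiducials(gen$record$abp, fs, r)
  m <- merge(ab, gen$truth, by = "beat_index", suffixes = c("", ".gt"))
  expect_true(all(abs(round((m$sstar_time - m$sstar_time.gt) * fs)) <= 1))
  expect_true(all(m$dstar_time > m$sstar_time))
  # final partial beat (no following R) is excluded
  expect_false((length(r)) %in% ab$beat_index)

  # monotone segment in a window -> dropped (no interior peak)
  ramp <- seq(50, 150, length.out = 500)
  out <- detect_abp_fiducials(ramp, 125, c(0.2, 1.4, 2.6))
  expect_identical(nrow(out), 0L)
})

test_that("PPG fiducials localize and keep their ordering", {
  gen <- generate_record(clean_config(n_beats = 30, seed = 6))
  fs <- gen$record$fs
  r <- detect_r_peaks(filter_ecg(gen$record$ecg, fs), fs)
  pf <- detect_ppg_fiducials(derive_vpg_apg(filter_ppg(gen$record$ppg, fs),
                                            fs), r)
  m <- merge(pf, gen$truth, by = "beat_index", suffixes = c("", ".gt"))
  for (f in c("o_time", "a_time", "w_time", "b_time", "s_time")) {
    expect_true(all(abs(round((m[[f]] - m[[paste0(f, ".gt")]]) * fs)) <= 1),
                label = paste(f, "within one sample"))
  }
  expect_true(all(pf$o_time <= pf$a_time & pf$a_time <= pf$w_time &
                    pf$w_time <= pf$b_time & pf$b_time <= pf$s_time))

  # beats with a flattened PPG window are dropped
  rec <- gen$record
  kill <- round(r[10] * fs):round(r[11] * fs)
  rec$ppg[kill] <- rec$ppg[kill][1]
  pf2 <- detect_ppg_fiducials(
    derive_vpg_apg(filter_ppg(rec$ppg, fs), fs), r)
  expect_false(10L %in% pf2$beat_index)
})

test_that("pairing keeps only complete beats and preserves traceability", {
  gen <- generate_record(clean_config(n_beats = 25, seed = 7))
  beats <- detect_beats(gen$record)
  expect_identical(beats$beat_index, sort(beats$beat_index))
  expect_true(all(diff(beats$r_time) > 0))
  # all-complete case: one row per R-to-R window
  expect_identical(nrow(beats), 24L)

  # removing one beat's b wave removes exactly that beat
  fs <- gen$record$fs
  r <- detect_r_peaks(filter_ecg(gen$record$ecg, fs), fs)
  ab <- detect_abp_fiducials(gen$record$abp, fs, r)
  pf <- detect_ppg_fiducials(derive_vpg_apg(filter_ppg(gen$record$ppg, fs),
                                            fs), r)
  pf_cut <- pf[pf$beat_index != 5L, ]
  paired <- pair_beats(r, ab, pf_cut)
  expect_false(5L %in% paired$beat_index)
  expect_identical(nrow(paired), nrow(beats) - 1L)
})

test_that("pairing invariants hold across random records", {
  for (s in 201:215) {
    gen <- generate_record(quick_config(n_beats = 20, seed = s))
    beats <- detect_beats(gen$record)
    expect_gte(nrow(beats), 1)
    with(beats, {
      expect_true(all(r_time < o_time & o_time <= a_time &
                        a_time <= w_time & w_time <= b_time &
                        b_time <= s_time))
      expect_true(all(sstar_time > r_time & sstar_time <= s_time &
                        dstar_time > sstar_time))
      expect_true(all(s_time < next_r_time))
    })
  }
})

test_that("survival under default noise stays high", {
  surv <- vapply(c(21, 22, 23), function(s) {
    gen <- generate_record(quick_config(n_beats = 60, seed = s))
    nrow(detect_beats(gen$record)) / (nrow(gen$truth) - 1)
  }, numeric(1))
  expect_gte(min(surv), 0.95)
})
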