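test_that("config validation rejects degenerate parameters", {
  expect_error(synthetic_config(n_beats = 0), "n_beats")
  expect_error(synthetic_config(fs = -1), "fs")
  expect_error(synthetic_config(pat_rsstar_fraction = 1), "fraction")
  expect_error(synthetic_config(hr_mean = 0), "hr_mean")
  # PAT driven negative / beyond the beat period is rejected at generation
  expect_error(
    generate_record(quick_config(coupling_slope = -0.05, sbp_sd = 30)),
    "PAT")
})

test_that("bp series: zero variance, determinism, and stationary mean", {
  cfg0 <- quick_config(sbp_sd = 0, n_beats = 50)
  expect_true(all(generate_bp_series(cfg0)$sbp == cfg0$sbp_mean))

  cfg <- quick_config(n_beats = 200)
  expect_identical(generate_bp_series(cfg), generate_bp_series(cfg))

  bp <- generate_bp_series(cfg)
  expect_true(all(bp$dbp < bp$map & bp$map < bp$sbp))

  # sample mean of the AR(1) walk: SE is inflated by the autocorrelation
  # factor c = sqrt((1+phi)/(1-phi)) = sqrt(19) for phi = 0.9
  cfac <- sqrt(19)
  for (s in c(1, 2, 3, 4, 5)) {
    cfgm <- synthetic_config(n_beats = 500, sbp_mean = 120, sbp_sd = 10,
                             seed = s)
    m <- mean(generate_bp_series(cfgm)$sbp)
    expect_lt(abs(m - 120), 3 * cfac * 10 / sqrt(500))
  }
})

test_that("record construction matches the configured geometry", {
  cfg <- synthetic_config(n_beats = 10, hr_mean = 60, hr_sd = 0, seed = 1)
  gen <- generate_record(cfg)
  expect_equal(nrow(gen$truth), 10)
  expect_equal(gen$record$duration, 10, tolerance = 0.15)  # + lead-in
  expect_equal(gen$record$fs, 125)

  # constant-delay case: no coupling, no jitter
  cfg2 <- clean_config(coupling_slope = 0, n_beats = 12)
  tr2 <- generate_record(cfg2)$truth
  expect_equal(max(tr2$pat_rs) - min(tr2$pat_rs), 0)

  # determinism
  g1 <- generate_record(quick_config())
  g2 <- generate_record(quick_config())
  expect_identical(g1$record$ppg, g2$record$ppg)
  expect_identical(g1$truth, g2$truth)
})

test_that("ground truth satisfies ordering, additivity, and coupling", {
  gen <- generate_record(quick_config(n_beats = 100, seed = 31))
  tr <- gen$truth
  expect_true(all(diff(tr$r_time) > 0))
  expect_true(all(tr$r_time < tr$o_time & tr$o_time <= tr$a_time &
                    tr$a_time <= tr$w_time & tr$w_time <= tr$b_time &
                    tr$b_time <= tr$s_time))
  expect_true(all(tr$sstar_time > tr$r_time & tr$sstar_time < tr$s_time))
  expect_true(all(tr$dbp < tr$map & tr$map < tr$sbp))
  # interval additivity is exact by construction
  expect_identical((tr$s_time - tr$r_time),
                   (tr$sstar_time - tr$r_time) + (tr$s_time - tr$sstar_time))

  # strong programmed coupling shows up directly in the ground truth
  g2 <- generate_record(synthetic_config(n_beats = 500,
                                         coupling_slope = -0.002,
                                         pat_noise_sd = 0.002, seed = 8))
  expect_lt(pearson(g2$truth$pat_rs, g2$truth$sbp), -0.9)
})

test_that("programmed correlation approaches the analytic value", {
  # r = slope * sd_sbp / sqrt(slope^2 sd_sbp^2 + noise^2) = -0.8 here
  slope <- -0.002; sd_sbp <- 8; noise <- 0.012
  ra <- slope * sd_sbp / sqrt((slope * sd_sbp)^2 + noise^2)
  expect_equal(ra, -0.8, tolerance = 1e-12)
  rs <- vapply(3001:3005, function(s) {
    g <- generate_record(synthetic_config(n_beats = 2000,
                                          coupling_slope = slope,
                                          sbp_sd = sd_sbp,
                                          pat_noise_sd = noise, seed = s))
    pearson(g$truth$sbp, g$truth$pat_rs)
  }, numeric(1))
  expect_true(all(abs(rs - ra) < 0.05))
})

test_that("corruption modes are deterministic and well-typed", {
  rec <- generate_record(quick_config())$record
  expect_error(corrupt_record(rec, "good"), "good")

  flat <- corrupt_record(rec, "missing_abp")
  expect_identical(stats::sd(flat$abp), 0)
  expect_identical(flat$ecg, rec$ecg)

  b1 <- corrupt_record(rec, "abnormal_ppg", seed = 4)
  b2 <- corrupt_record(rec, "abnormal_ppg", seed = 4)
  expect_identical(b1$ppg, b2$ppg)
  expect_identical(b1$abp, rec$abp)
})
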