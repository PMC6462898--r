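test_that("pearson matches hand-derived exact cases", {
  expect_equal(pearson(c(1, 2, 3), c(2, 4, 6)), 1.0)
  expect_equal(pearson(c(1, 2, 3), c(3, 2, 1)), -1.0)
  expect_equal(pearson(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  expect_equal(pearson(c(1, 2, 3, 4), c(1, 3, 2, 4)),
               pearson_bruteforce(c(1, 2, 3, 4), c(1, 3, 2, 4)))
})

test_that("degenerate inputs are rejected explicitly", {
  expect_error(pearson(1:3, 1:4), "equal length")
  expect_error(pearson(1, 2), "at least 2")
  expect_error(pearson(c(1, NA, 3), 1:3), "finite")
  expect_error(pearson(c(2, 2, 2), 1:3), "zero variance")
})

test_that("pearson agrees with the brute-force oracle on random arrays", {
  withr::with_seed(17, {
    for (k in 1:300) {
      n <- sample(2:100, 1)
      x <- rnorm(n)
      y <- rnorm(n) + 0.3 * x
      r <- pearson(x, y)
      expect_lt(abs(r - pearson_bruteforce(x, y)), 1e-12)
      expect_identical(r, pearson(y, x))                  # symmetry
      a <- runif(1, -3, 3)
      if (abs(a) > 1e-3) {                                # affine invariance
        expect_lt(abs(pearson(a * x + 1.7, y) - sign(a) * r), 1e-12)
      }
    }
  })
})

test_that("strength bins partition |r| as published", {
  expect_identical(as.character(strength_bin(-0.92)), "very strong")
  expect_identical(as.character(strength_bin(-0.07)), "very weak")
  expect_identical(as.character(strength_bin(0)), "very weak")
  expect_identical(as.character(strength_bin(0.2)), "weak")
  expect_identical(as.character(strength_bin(0.4)), "moderate")
  expect_identical(as.character(strength_bin(0.6)), "strong")
  expect_identical(as.character(strength_bin(0.795)), "strong")
  expect_identical(as.character(strength_bin(0.8)), "very strong")
  expect_identical(as.character(strength_bin(1.0)), "very strong")
  expect_error(strength_bin(1.5), "not a correlation")
})

sim_cohort_features <- function(n_subjects, slope, seed0,
                                n_beats = 120, noise = 0.004) {
  recs <- lapply(seq_len(n_subjects), function(i) {
    generate_record(synthetic_config(n_beats = n_beats,
                                     coupling_slope = slope,
                                     pat_noise_sd = noise,
                                     seed = seed0 + i))$record
  })
  build_feature_table(recs)
}

test_that("subject-by-subject analysis recovers strong coupling", {
  ft <- sim_cohort_features(4, slope = -0.002, seed0 = 900)
  rep <- analyze_subject_by_subject(ft)
  expect_identical(nrow(rep$rows), 4L)
  expect_true(all(rep$rows$pat_rs < -0.8))
  expect_identical(sum(rep$strength_bins), 4L)
  expect_identical(unname(rep$strength_bins["very strong"]),
                   sum(abs(rep$rows$pat_rsstar) >= 0.8))
  expect_true(all(rep$rows$n_beats >= 2))
})

test_that("single-subject report equals its own summary with zero SD", {
  ft <- sim_cohort_features(1, slope = -0.002, seed0 = 950)
  rep <- analyze_subject_by_subject(ft)
  expect_identical(nrow(rep$rows), 1L)
  expect_equal(rep$summary$mean_r,
               unlist(rep$rows[patcor:::PAT_FEATURES], use.names = FALSE))
  expect_true(all(rep$summary$sd_r == 0))
})

test_that("null coupling gives per-subject mean r near zero", {
  ft <- sim_cohort_features(8, slope = 0, seed0 = 960, n_beats = 150,
                            noise = 0.01)
  rep <- analyze_subject_by_subject(ft)
  # mean of 8 independent null r values, each with SE ~ 1/sqrt(n_beats)
  se_mean <- 1 / sqrt(8 * min(rep$rows$n_beats))
  expect_lt(abs(mean(rep$rows$pat_rs)), 3 * se_mean)
})

test_that("collective analysis pools beats without centering", {
  ft <- sim_cohort_features(2, slope = -0.002, seed0 = 970)
  one <- ft[ft$subject_id == ft$subject_id[1], ]
  rep1 <- analyze_collective(one, "sbp")
  sub1 <- analyze_subject_by_subject(one)
  expect_equal(unlist(rep1$rows[patcor:::PAT_FEATURES]),
               unlist(sub1$rows[patcor:::PAT_FEATURES]),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_identical(rep1$rows$n_beats, nrow(one))

  # pooling != averaging: opposite within-subject slopes with offset
  # intercepts flip the pooled sign (verified by direct computation)
  ftx <- data.frame(
    subject_id = rep(c("a", "b"), each = 4),
    beat_index = rep(1:4, 2),
    sbp = c(100, 101, 102, 103, 140, 141, 142, 143),
    pat_rs = c(0.30, 0.299, 0.298, 0.297, 0.40, 0.399, 0.398, 0.397))
  for (f in setdiff(patcor:::PAT_FEATURES, "pat_rs")) ftx[[f]] <- ftx$pat_rs
  ftx$map <- ftx$dbp <- ftx$sbp
  within_a <- pearson(ftx$sbp[1:4], ftx$pat_rs[1:4])
  pooled <- analyze_collective(ftx, "sbp")$rows$pat_rs
  expect_lt(within_a, 0)
  expect_gt(pooled, 0)
  expect_equal(pooled, pearson_bruteforce(ftx$sbp, ftx$pat_rs))
})

test_that("collective coupling recovery approaches the analytic value", {
  ft <- extract_features(generate_record(
    synthetic_config(n_beats = 2000, coupling_slope = -0.002, sbp_sd = 8,
                     pat_noise_sd = 0.012, seed = 3001))$record)
  r <- analyze_collective(ft, "sbp")$rows$pat_rs
  expect_lt(abs(r - (-0.8)), 0.05)
})

test_that("one-excellent-beat analysis selects by SQI with stable ties", {
  ft <- sim_cohort_features(5, slope = -0.002, seed0 = 980, n_beats = 40)
  rep <- analyze_one_excellent_beat(ft)
  expect_identical(rep$rows$n_beats, 5L)
  sel <- attr(rep, "selected")
  expect_identical(nrow(sel), 5L)
  # selected beats exist in the table (never a beat pairing dropped)
  key <- paste(sel$subject_id, sel$beat_index)
  expect_true(all(key %in% paste(ft$subject_id, ft$beat_index)))
  # per subject, no other beat has a strictly higher score
  for (id in unique(ft$subject_id)) {
    expect_gte(sel$sqi[sel$subject_id == id],
               max(ft$sqi[ft$subject_id == id]))
  }
  # all-tied scores -> earliest beat wins
  ft2 <- ft
  ft2$sqi <- 0.5
  sel2 <- attr(analyze_one_excellent_beat(ft2), "selected")
  first <- tapply(ft$beat_index, ft$subject_id, min)
  expect_identical(sel2$beat_index, as.integer(first[sel2$subject_id]),
                   ignore_attr = TRUE)
})

test_that("rendered reports round-trip and carry the summary label", {
  ft <- sim_cohort_features(3, slope = -0.002, seed0 = 990, n_beats = 30)
  rep <- analyze_subject_by_subject(ft)
  dir <- withr::local_tempdir()
  files <- render_reports(rep, dir)
  expect_true(all(file.exists(files)))
  main <- read.csv(files[1], check.names = FALSE)
  expect_identical(main$subject_id[nrow(main)], "Mean ± STD")
  bins <- read.csv(files[2])
  expect_identical(sum(bins$count), nrow(rep$rows))
  expect_identical(
    as.integer(bins$count[match(names(rep$strength_bins), bins$strength)]),
    as.integer(rep$strength_bins))

  # empty report -> header-only main file
  empty <- patcor:::new_correlation_report(
    "subject_by_subject", rep$rows[0, ])
  f0 <- render_reports(empty, dir, prefix = "empty")
  expect_identical(nrow(read.csv(f0[1])), 0L)
})
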