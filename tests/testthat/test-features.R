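mk_beat <- function(r = 0, o = 0.20, a = 0.22, w = 0.25, b = 0.28,
                    s = 0.35, sstar = 0.10, dstar = 0.55, idx = 1L) {
  list(beat_index = idx, r_time = r, o_time = o, a_time = a, w_time = w,
       b_time = b, s_time = s, sstar_time = sstar, dstar_time = dstar)
}

test_that("interval arithmetic follows the definitions", {
  abp <- rep(80, 200)
  abp[round(0.10 * 125) + 1] <- 120   # SBP at S*
  abp[round(0.55 * 125) + 1] <- 60    # DBP at D*
  bf <- compute_beat_features(mk_beat(), next_r_time = 0.8, abp = abp,
                              fs = 125)
  expect_equal(bf$pat_rsstar, 0.10)
  expect_equal(bf$ptt_sstars, 0.25)
  expect_equal(bf$pat_rs, 0.35)
  expect_equal(bf$pat_ro, 0.20)
  expect_equal(bf$pat_ra, 0.22)
  expect_equal(bf$pat_rw1, 0.25)
  expect_equal(bf$pat_rb, 0.28)
  expect_equal(bf$rri, 0.8)
  expect_equal(bf$sbp, 120)
  expect_equal(bf$dbp, 60)
  expect_true(bf$pat_ro <= bf$pat_ra && bf$pat_ra <= bf$pat_rw1 &&
                bf$pat_rw1 <= bf$pat_rb && bf$pat_rb <= bf$pat_rs)
  # MAP rules: waveform mean vs DBP + PP/3
  expect_equal(bf$map, mean(abp[1:100]))
  bf2 <- compute_beat_features(mk_beat(), 0.8, abp, 125,
                               map_rule = "dbp_pp3")
  expect_equal(bf2$map, 60 + (120 - 60) / 3)
})

test_that("ordering violations reject the beat with a reason", {
  abp <- rep(80, 200)
  expect_error(compute_beat_features(mk_beat(o = 0.30, a = 0.22), 0.8,
                                     abp, 125), "ordering")
  expect_error(compute_beat_features(mk_beat(), 0.0, abp, 125), "next_r")
})

test_that("extracted PAT_RS matches the programmed ground truth", {
  gen <- generate_record(clean_config(n_beats = 40, seed = 13))
  ft <- extract_features(gen$record)
  m <- merge(ft, gen$truth[, c("beat_index", "pat_rs")],
             by = "beat_index", suffixes = c("", ".prog"))
  expect_true(all(abs(m$pat_rs - m$pat_rs.prog) * gen$record$fs <= 1))
})

test_that("additivity identity is exact for every extracted beat", {
  for (s in 301:310) {
    ft <- extract_features(
      generate_record(quick_config(n_beats = 15, seed = s))$record)
    expect_identical(ft$pat_rsstar + ft$ptt_sstars, ft$pat_rs)
    expect_true(all(ft$pat_ro <= ft$pat_ra & ft$pat_ra <= ft$pat_rw1 &
                      ft$pat_rw1 <= ft$pat_rb & ft$pat_rb <= ft$pat_rs))
    expect_true(all(ft$pat_rs < ft$rri & ft$pat_ro > 0))
    expect_true(all(ft$dbp < ft$map & ft$map < ft$sbp))
  }
})

test_that("feature table pools subjects with conserved counts", {
  recs <- lapply(c(41, 42), function(s) {
    generate_record(quick_config(n_beats = 11, seed = s))$record
  })
  ft <- build_feature_table(recs)
  expect_identical(nrow(ft), 20L)          # 10 complete beats per subject
  expect_setequal(
    names(ft),
    c("subject_id", "beat_index", patcor:::PAT_FEATURES,
      "sbp", "dbp", "map", "sqi"))
  counts <- attr(ft, "beat_counts")
  expect_identical(sum(counts), nrow(ft))
  expect_identical(as.vector(table(ft$subject_id)[names(counts)]),
                   as.vector(counts))
  # empty input is a valid empty table
  expect_identical(nrow(build_feature_table(list())), 0L)
})

test_that("negative coupling yields negative pooled r at modest n", {
  ft <- extract_features(
    generate_record(quick_config(n_beats = 100, seed = 55))$record)
  expect_gte(nrow(ft), 95)
  expect_lt(pearson(ft$pat_rs, ft$sbp), 0)
})
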