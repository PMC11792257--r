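test_that("degenerate or invalid inputs raise informative detection errors", {
  expect_error(detect_r_peaks(rep(0, 4000), 400), "no peaks")
  expect_error(detect_r_peaks(rnorm(100), fs = -1), "fs")
  expect_error(detect_r_peaks(rnorm(100), 400, threshold_factor = 1.5),
               "threshold_factor")
  expect_error(detect_r_peaks(rnorm(100), 400, refractory = 0), "refractory")
})

test_that("R-peak detection recovers generator beat times within one sample", {
  hp <- c(820, 760, 905, 850, 790, 880, 930, 800, 770, 860, 840, 810)
  bs <- beat_series(hp, rep(120, 12), rep(0, 12))
  rec <- simulate_raw_signals(bs, fs = 400, seed = 2)
  pk <- detect_r_peaks(rec$ecg, rec$fs)
  expect_length(pk, 13L)
  expect_true(all(abs(pk - rec$r_peak_times) <= 2.5e-3 + 1e-9))

  ## halving one QRS amplitude must not lose the detection
  ecg2 <- rec$ecg
  t5 <- rec$r_peak_times[5]
  idx <- which(abs(rec$t - t5) <= 0.03)
  ecg2[idx] <- ecg2[idx] * 0.5
  pk2 <- detect_r_peaks(ecg2, rec$fs)
  expect_length(pk2, 13L)
  expect_true(all(abs(pk2 - rec$r_peak_times) <= 2.5e-3 + 1e-9))
})

test_that("beat series construction follows the HP/SAP/RESP sampling conventions", {
  fs <- 400
  t <- seq(0, 4, by = 1 / fs)
  bs <- build_beat_series(c(0, 1, 2, 3), rep(120, length(t)), rep(0.5, length(t)), fs)
  expect_equal(bs$hp, c(1000, 1000, 1000))
  expect_equal(bs$sap, c(120, 120, 120))
  expect_equal(bs$resp, c(0.5, 0.5, 0.5))
  expect_equal(bs$n_beats, 3L)

  ## sine pressure attains its closed-form maximum inside each beat window
  ap <- 100 + 30 * sin(2 * pi * 1.25 * t)
  bs2 <- build_beat_series(c(0, 0.8, 1.6, 2.4), ap, rep(0, length(t)), fs)
  expect_equal(bs2$hp, c(800, 800, 800))
  expect_equal(bs2$sap, c(130, 130, 130))

  expect_error(build_beat_series(c(0, 0.8), ap, rep(0, length(t)), fs),
               "insufficient beats")
})

test_that("generator-known SAP values survive the raw-signal round trip", {
  cfg <- sim_config("HEALTHY_REST", n_beats = 64, seed = 31)
  bs <- simulate_subject(cfg)
  rec <- simulate_raw_signals(bs, fs = 400, seed = 31)
  out <- build_beat_series(detect_r_peaks(rec$ecg, rec$fs), rec$ap, rec$resp, rec$fs)
  expect_equal(out$n_beats, bs$n_beats)
  expect_true(all(abs(out$hp - bs$hp) <= 5))
  expect_true(all(abs(out$sap - bs$sap) <= 0.5))
})

test_that("repair interpolates out-of-range beats and reports the fraction", {
  b1 <- beat_series(c(800, 800, 2600, 800), rep(120, 4), rep(0, 4))
  r1 <- repair_series(b1, c(300, 2000))
  expect_equal(r1$hp, rep(800, 4))
  rep1 <- attr(r1, "repair_report")
  expect_equal(rep1$fraction, 0.25)
  expect_true(rep1$warn)
  expect_equal(r1$interpolated, c(FALSE, FALSE, TRUE, FALSE))

  ## identity on a clean series
  b2 <- beat_series(800 + 1:20, rep(120, 20), rep(0, 20))
  r2 <- repair_series(b2)
  expect_equal(r2$hp, b2$hp)
  expect_equal(attr(r2, "repair_report")$fraction, 0)
  expect_false(attr(r2, "repair_report")$warn)

  ## hand-computed linear interpolation between in-range neighbours
  ## (indices 2 and 5 bracket the gap: 900 + k*(700-900)/3)
  b3 <- beat_series(c(700, 900, 2500, 2500, 700), rep(120, 5), c(1, 2, 9, 9, 5))
  r3 <- repair_series(b3, c(300, 2000))
  expect_equal(r3$hp, c(700, 900, 900 - 200 / 3, 900 - 400 / 3, 700),
               tolerance = 1e-12)
  expect_equal(r3$resp, c(1, 2, 3, 4, 5))

  ## first/last out of range take the nearest in-range value
  b4 <- beat_series(c(2500, 800, 900, 2500), rep(120, 4), rep(0, 4))
  r4 <- repair_series(b4, c(300, 2000))
  expect_equal(r4$hp, c(800, 800, 900, 900))

  expect_error(repair_series(beat_series(rep(2500, 5), rep(1, 5), rep(0, 5)),
                             c(300, 2000)),
               "unrepairable")
})

test_that("repair is idempotent and never changes the beat count", {
  cfg <- sim_config("HEALTHY_REST", n_beats = 128, seed = 5)
  bs <- simulate_subject(cfg)
  bs$hp[c(10, 50, 51)] <- c(2600, 150, 2400)  # injected artefacts
  r1 <- repair_series(bs)
  r2 <- repair_series(r1)
  expect_equal(r1$n_beats, bs$n_beats)
  expect_equal(r2$hp, r1$hp)
  expect_equal(r2$sap, r1$sap)
  expect_equal(attr(r2, "repair_report")$fraction, 0)
})

test_that("segment selection is seeded, exhaustive when unique, and errors when short", {
  cfg <- sim_config("HEALTHY_REST", n_beats = 600, seed = 2)
  bs <- simulate_subject(cfg)

  s1 <- select_segment(bs, 256, seed = 7)
  s2 <- select_segment(bs, 256, seed = 7)
  expect_equal(s1$hp, s2$hp)
  expect_equal(attr(s1, "segment_start"), attr(s2, "segment_start"))

  whole <- select_segment(subset_256 <- select_segment(bs, 256, seed = 1), 256,
                          seed = 99)
  expect_equal(whole$hp, subset_256$hp)

  expect_error(select_segment(bs, 601, seed = 1), "too short")
})

test_that("segment start indices cover the valid range approximately uniformly", {
  cfg <- sim_config("HEALTHY_REST", n_beats = 600, seed = 2)
  bs <- simulate_subject(cfg)
  starts <- vapply(1:1000, function(i)
    attr(select_segment(bs, 256, seed = i), "segment_start"), integer(1))
  expect_true(min(starts) >= 1L && max(starts) <= 345L)
  bins <- cut(starts, breaks = seq(0.5, 345.5, length.out = 9L))
  p <- suppressWarnings(stats::chisq.test(table(bins))$p.value)
  expect_gt(p, 0.01)
})

test_that("beat-series CSV round-trips through write/read", {
  bs <- simulate_subject(sim_config("HEALTHY_REST", n_beats = 64, seed = 4))
  path <- withr::local_tempfile(fileext = ".csv")
  write_beat_series(bs, path)
  back <- read_beat_series(path)
  expect_equal(back$hp, bs$hp)
  expect_equal(back$sap, bs$sap)
  expect_equal(back$resp, bs$resp)
})
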