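test_that("interval summary computes HR, PP, RR and PR per definition", {
  f <- fiducial_series(r_times = c(0, 0.5, 1.0, 1.5))
  iv <- compute_intervals(f)
  expect_equal(iv$mean_rr, 0.5)
  expect_equal(iv$hr_bpm, 120)
  expect_null(iv$pp)
  expect_null(iv$qrs)

  f2 <- fiducial_series(p_times = c(0, 0.60), r_times = c(0.12, 0.72))
  iv2 <- compute_intervals(f2)
  expect_equal(iv2$pr, c(0.12, 0.12))
  expect_equal(iv2$mean_pp, 0.6)

  # fewer than 2 beats: HR flagged undefined, not zero
  iv3 <- compute_intervals(fiducial_series(r_times = 0.3))
  expect_false(iv3$hr_defined)
  expect_true(is.na(iv3$hr_bpm))

  # QRS/QT only when onset/offset fiducials exist
  f4 <- fiducial_series(p_times = c(0, 1), r_times = c(0.1, 1.1),
                        qrs_onsets = c(0.08, 1.08), qrs_offsets = c(0.16, 1.16),
                        t_ends = c(0.4, 1.4))
  iv4 <- compute_intervals(f4)
  expect_equal(iv4$mean_qrs, 0.08)
  expect_equal(iv4$mean_qt, 0.32)
})

test_that("interval summary tracks the generator ground truth", {
  tr <- gen_beat_train(beat_train_spec(hr = 100, n = 200, cl_jitter_sd = 0.01,
                                       seed = 7))
  iv <- compute_intervals(tr$fiducials)
  expect_lt(abs(iv$hr_bpm - 100), 1)
})

test_that("sinus-arrest calls require PP strictly above the threshold", {
  p <- cumsum(c(0, 0.6, 0.6, 1.6, 0.6))
  f <- fiducial_series(p_times = p, r_times = p + 0.1)
  ep <- detect_sa_episodes(f, threshold = 1.5)
  expect_equal(nrow(ep), 1L)
  expect_equal(ep$evidence, 1.6)
  expect_equal(ep$offset - ep$onset, 1.6)

  # boundary: a gap of exactly 1.5 s is not an episode
  pb <- cumsum(c(0, 0.6, 1.5, 0.6))
  fb <- fiducial_series(p_times = pb, r_times = pb + 0.1)
  expect_equal(nrow(detect_sa_episodes(fb, threshold = 1.5)), 0L)

  # threshold monotonicity: lowering the threshold never removes a call
  set.seed(3)
  gaps <- runif(40, 0.3, 2.5)
  fm <- fiducial_series(p_times = cumsum(c(0, gaps)), species = "mouse",
                        r_times = cumsum(c(0, gaps)) + 0.05)
  for (thr in c(2.0, 1.5, 1.0)) {
    hi <- detect_sa_episodes(fm, threshold = thr)
    lo <- detect_sa_episodes(fm, threshold = thr - 0.4)
    expect_true(all(hi$onset %in% lo$onset))
  }
  expect_error(detect_sa_episodes(f, threshold = 0), "positive")
})

test_that("sinus-arrest detection falls back to RR with a warning", {
  r <- cumsum(c(0, 0.6, 2.0, 0.6))
  f <- fiducial_series(r_times = r)
  expect_warning(ep <- detect_sa_episodes(f, threshold = 1.5), "RR")
  expect_equal(nrow(ep), 1L)
})

test_that("AV-block calls flag P waves without a ventricular response", {
  f <- fiducial_series(p_times = c(0, 0.5, 1.0, 1.5),
                       r_times = c(0.1, 0.6, 1.6))
  ep <- detect_avb_episodes(f, pr_window = 0.3)
  expect_equal(nrow(ep), 1L)
  expect_equal(ep$onset, 1.0)

  # all paired: no calls
  f2 <- fiducial_series(p_times = c(0, 0.5, 1.0), r_times = c(0.1, 0.6, 1.1))
  expect_equal(nrow(detect_avb_episodes(f2, pr_window = 0.3)), 0L)
  expect_error(detect_avb_episodes(fiducial_series(p_times = c(0, 1))), "both P and R")
})

test_that("episode calls lie inside the recording and do not overlap", {
  tr <- gen_beat_train(beat_train_spec(hr = 100, n = 300, cl_jitter_sd = 0.01,
                                       sa_pauses = list(c(40, 2), c(120, 2.5), c(250, 3)),
                                       avb_drops = c(60, 200), seed = 12))
  sa <- detect_sa_episodes(tr$fiducials, threshold = 1.5)
  avb <- detect_avb_episodes(tr$fiducials, pr_window = 0.3)
  for (ep in list(sa, avb)) {
    expect_true(all(ep$offset > ep$onset))
    expect_true(all(ep$onset >= 0 & ep$offset <= tr$fiducials$duration))
    if (nrow(ep) > 1) expect_true(all(ep$onset[-1] >= ep$offset[-nrow(ep)]))
  }
})

test_that("SANRT and its rate-corrected form follow their definitions", {
  r <- sanrt(pace_times = 10.0, spontaneous_beats = 10.35, resting_cl = 0.22)
  expect_equal(r$sanrt, 0.35)
  expect_equal(r$csanrt, 0.13)

  # first beat exactly one resting cycle after the last pace: csanrt = 0
  r2 <- sanrt(c(9, 9.1, 10), 10 + 0.22, 0.22)
  expect_equal(r2$csanrt, 0)

  # programmed post-pacing delay is recovered exactly
  pace <- seq(0, 10, by = 0.1)
  for (d in c(0.2, 0.45, 0.9)) {
    beats <- max(pace) + d + cumsum(c(0, rep(0.3, 5)))
    expect_equal(sanrt(pace, beats, 0.3)$sanrt, d)
  }
  expect_error(sanrt(10, 9.5, 0.2), "no spontaneous beat")
})

test_that("cycle-length variation is the sample SD of successive cycles", {
  expect_equal(cl_variation(seq(0, 5, by = 0.5)), 0)
  expect_equal(cl_variation(c(0, 0.5, 1.2)), stats::sd(c(0.5, 0.7)))
  expect_equal(cl_variation(c(0, 0.5, 1.2)), 0.1414, tolerance = 1e-3)
  expect_equal(cl_variation(c(0, 0.5, 1.2), metric = "cv"),
               stats::sd(c(0.5, 0.7)) / 0.6)
  expect_warning(v <- cl_variation(c(0, 1)), "fewer than 3")
  expect_true(is.na(v))
  # jittered generator train: SD estimate near the programmed jitter
  tr <- gen_beat_train(beat_train_spec(hr = 100, n = 500, cl_jitter_sd = 0.02,
                                       seed = 9))
  expect_lt(abs(cl_variation(tr$fiducials$p_times) - 0.02), 0.003)
})

test_that("R-peak detection recovers rendered peaks and ignores polarity", {
  tr <- gen_beat_train(beat_train_spec(hr = 100, n = 60, cl_jitter_sd = 0.01,
                                       seed = 21))
  wf <- gen_ecg_waveform(tr$fiducials, fs = 500, noise_sd = 0.02, seed = 3)
  pk <- detect_r_peaks(wf, fs = 500)
  truth <- tr$fiducials$r_times
  hits <- vapply(truth, function(t0) any(abs(pk - t0) <= 0.01), logical(1))
  expect_gte(mean(hits), 0.99)
  # no false positives: every reported peak near a true R
  near <- vapply(pk, function(t0) any(abs(truth - t0) <= 0.01), logical(1))
  expect_true(all(near))
  # polarity invariance
  pk_inv <- detect_r_peaks(-wf$mv, fs = 500)
  expect_equal(length(pk_inv), length(pk))
  # degenerate inputs
  expect_equal(detect_r_peaks(numeric(500), fs = 500), numeric())
  expect_error(detect_r_peaks(rnorm(100), fs = 0), "positive")
})

test_that("fiducial CSV round-trips through the on-disk format", {
  tr <- gen_beat_train(beat_train_spec(hr = 120, n = 20, seed = 2))
  path <- tempfile(fileext = ".csv")
  write_fiducials(tr$fiducials, path)
  back <- read_fiducials(path, species = "zebrafish",
                         duration = tr$fiducials$duration)
  expect_equal(back$p_times, tr$fiducials$p_times, tolerance = 1e-9)
  expect_equal(back$r_times, tr$fiducials$r_times, tolerance = 1e-9)
  unlink(path)
})
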