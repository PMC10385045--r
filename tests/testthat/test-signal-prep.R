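test_that("R-peak detection recovers every beat of a clean recording", {
  e <- gen_synthetic_ecg(mean_hr_bpm = 60, hr_sd = 0.02, duration_s = 60,
                         noise_sd = 0, seed = 1)
  det <- detect_r_peaks(e$waveform)
  tol <- 2 / e$fs
  miss <- vapply(e$true_beat_times,
                 function(b) min(abs(det$beat_times - b)), numeric(1))
  fp <- vapply(det$beat_times,
               function(b) min(abs(e$true_beat_times - b)), numeric(1))
  expect_true(all(miss <= tol))
  expect_true(all(fp <= tol))
  expect_false(any(det$artifact_mask))
})

test_that("R-peak detection keeps sensitivity and precision above 0.95 under noise", {
  stats <- vapply(1:20, function(s) {
    e <- gen_synthetic_ecg(mean_hr_bpm = 70, hr_sd = 0.04, duration_s = 60,
                           noise_sd = 0.1, wander_amp = 0.05, seed = s)
    det <- detect_r_peaks(e$waveform)
    tp <- sum(vapply(e$true_beat_times,
                     function(b) min(abs(det$beat_times - b)), numeric(1)) < 0.05)
    c(sens = tp / length(e$true_beat_times),
      prec = sum(vapply(det$beat_times,
                        function(b) min(abs(e$true_beat_times - b)),
                        numeric(1)) < 0.05) / length(det$beat_times))
  }, numeric(2))
  expect_gte(min(stats["sens", ]), 0.95)
  expect_gte(min(stats["prec", ]), 0.95)
})

test_that("R-peak detection rejects degenerate inputs", {
  flat <- uniform_series(rep(0, 250 * 20), fs = 250)
  expect_error(detect_r_peaks(flat), "flat")
  low_fs <- uniform_series(sin(1:500), fs = 50)
  expect_error(detect_r_peaks(low_fs), "sampling rate")
  short <- uniform_series(rnorm(500), fs = 250)
  expect_error(detect_r_peaks(short), "10 s")
})

test_that("RR artifact correction flags and restores a doubled interval", {
  iv <- c(rep(0.8, 50), 1.6, rep(0.8, 49))
  rr <- rr_series(cumsum(c(0, iv)))
  fixed <- correct_rr_artifacts(rr)
  expect_identical(which(fixed$artifact_mask), 51L)
  expect_lt(abs(fixed$rr_intervals[51] - 0.8), 0.02)
  # default threshold is the lowest detection threshold, 0.45 s
  expect_equal(eval(formals(correct_rr_artifacts)$threshold_s), 0.45)
})

test_that("RR artifact correction is the identity on clean data and idempotent", {
  rr <- rr_series(cumsum(c(0, rep(0.8, 60))))
  out <- correct_rr_artifacts(rr)
  expect_equal(out$beat_times, rr$beat_times)
  expect_false(any(out$artifact_mask))
  iv <- c(rep(0.8, 30), 1.7, rep(0.8, 30))
  once <- correct_rr_artifacts(rr_series(cumsum(c(0, iv))))
  twice <- correct_rr_artifacts(rr_series(once$beat_times))
  expect_equal(twice$rr_intervals, once$rr_intervals, tolerance = 1e-10)
  expect_error(correct_rr_artifacts(rr_series(c(0, 0.8, 1.6))), "at least 5")
})

test_that("RR interpolation reproduces constants and smooth trends on a 5 Hz grid", {
  rr <- rr_series(cumsum(c(0, rep(0.8, 200))))
  u <- rr_to_uniform(rr)
  expect_equal(u$fs, 5)
  expect_lt(max(abs(u$values - 0.8)), 1e-9)
  # ~150-s span -> 750 +/- 1 samples
  iv150 <- rep(0.75, 200)
  rr150 <- rr_series(cumsum(c(0, iv150)))  # knots span 149.25 s
  n_expect <- floor(149.25 * 5) + 1
  expect_equal(length(rr_to_uniform(rr150)$values), n_expect)
  expect_lt(abs(n_expect - 750), 5)
  # linearly drifting RR values follow the trend at grid points
  bt <- cumsum(c(0, 0.7 + 0.001 * (0:199)))
  ul <- rr_to_uniform(rr_series(bt))
  ref <- approx(bt[-1], diff(bt), xout = series_times(ul))$y
  expect_lt(max(abs(ul$values - ref)), 1e-3)
  expect_error(rr_to_uniform(rr_series(c(0, 0.8, 1.6, 2.4))), "at least 4")
})

test_that("EDA decomposition conserves the signal and separates the bands", {
  fs <- 5
  t <- (0:749) / fs
  dec_c <- decompose_eda(uniform_series(rep(2.7, 750), fs))
  expect_lt(max(abs(dec_c$tonic$values - 2.7)), 1e-4)
  expect_lt(max(abs(dec_c$phasic$values)), 1e-4)
  expect_match(dec_c$method, "lowpass-0.05Hz")

  tonic_true <- 2 + 0.3 * sin(2 * pi * 0.01 * t)
  phasic_true <- numeric(750)
  for (i in seq(50, 700, 60))
    phasic_true[i:(i + 4)] <- phasic_true[i:(i + 4)] + c(.3, .8, 1, .6, .2)
  dec <- decompose_eda(uniform_series(tonic_true + phasic_true, fs))
  expect_gt(cor(dec$tonic$values, tonic_true), 0.95)
  expect_equal(dec$tonic$values + dec$phasic$values, tonic_true + phasic_true)

  # 0.5 Hz content is rejected from the tonic band (measured away from the
  # filter's edge-settling region)
  fast <- decompose_eda(uniform_series(sin(2 * pi * 0.5 * t), fs))
  expect_lt(max(abs(fast$tonic$values[101:650])), 0.05)
  expect_error(decompose_eda(uniform_series(rnorm(100), fs)), "60 s")
})

test_that("downsampling preserves slow content and refuses upsampling", {
  hi_c <- uniform_series(rep(1.5, 37500), fs = 250)
  lo_c <- downsample(hi_c, 5)
  expect_equal(lo_c$fs, 5)
  expect_lt(max(abs(lo_c$values - 1.5)), 1e-6)
  expect_equal(length(lo_c$values), floor((37500 - 1) / 250 * 5) + 1)
  hi_s <- uniform_series(sin(2 * pi * 0.02 * (0:37499) / 250), fs = 250)
  lo_s <- downsample(hi_s, 5)
  expect_gt(max(abs(lo_s$values)), 0.99)
  expect_lt(max(abs(lo_s$values)), 1.01)
  expect_error(downsample(lo_c, 50), "upsampling")
})

test_that("segment selection takes the tail of rest and the head of stress", {
  ses <- uniform_series(seq_len(1500), fs = 5)
  expect_equal(select_segment(ses, "rest")$values, 751:1500)
  expect_equal(select_segment(ses, "stress")$values, 1:750)
  expect_equal(select_segment(ses, "rest")$t0, 150)
  short <- uniform_series(seq_len(600), fs = 5)
  expect_error(select_segment(short, "rest"), "too short")
})

test_that("interpolated clean RR processes preserve the mean within 1%", {
  set.seed(42)
  iv <- 0.8 + 0.05 * as.numeric(arima.sim(list(ar = 0.7), 200, sd = 0.3))
  rr <- correct_rr_artifacts(rr_series(cumsum(c(0, iv))))
  u <- rr_to_uniform(rr)
  expect_lt(abs(mean(u$values) - mean(rr$rr_intervals)) / mean(rr$rr_intervals),
            0.01)
})
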