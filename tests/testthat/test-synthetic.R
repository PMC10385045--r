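test_that("generators are pure functions of their arguments", {
  a <- gen_coupled_logistic(500, 3.8, 3.8, 0.1, 0.02, seed = 11)
  b <- gen_coupled_logistic(500, 3.8, 3.8, 0.1, 0.02, seed = 11)
  expect_identical(a$x, b$x)
  expect_identical(a$y, b$y)
  expect_false(identical(a$x, gen_coupled_logistic(500, 3.8, 3.8, 0.1, 0.02,
                                                   seed = 12)$x))
  l1 <- gen_lorenz(300, seed = 4)
  l2 <- gen_lorenz(300, seed = 4)
  expect_identical(l1$x$values, l2$x$values)
  t1 <- gen_physio_triplet(seed = 9)
  t2 <- gen_physio_triplet(seed = 9)
  expect_identical(t1$thermal$values, t2$thermal$values)
  e1 <- gen_synthetic_ecg(seed = 3)
  e2 <- gen_synthetic_ecg(seed = 3)
  expect_identical(e1$waveform$values, e2$waveform$values)
  expect_identical(e1$true_beat_times, e2$true_beat_times)
  expect_identical(gen_cohort(10, 5, seed = 2), gen_cohort(10, 5, seed = 2))
})

test_that("coupled logistic maps stay in [0,1] in valid regimes and report divergence", {
  cp <- gen_coupled_logistic(1000, 3.8, 3.8, beta_xy = 0.1, beta_yx = 0.02,
                             seed = 1)
  expect_length(cp$x, 1000)
  expect_true(all(cp$x >= 0 & cp$x <= 1))
  expect_true(all(cp$y >= 0 & cp$y <= 1))
  expect_error(gen_coupled_logistic(500, 3.8, 3.8, beta_xy = 2, seed = 1),
               "diverged")
  expect_error(gen_coupled_logistic(50, 3.8, 3.8, seed = 1), "at least 100")
  expect_error(gen_coupled_logistic(500, 3.2, 3.8, seed = 1), "3.5, 4")
  expect_error(gen_coupled_logistic(500, 3.8, 3.8, beta_xy = -1, seed = 1),
               "non-negative")
})

test_that("Lorenz trajectories are bounded on the attractor and collapse below rho = 1", {
  lor <- gen_lorenz(5000, dt = 0.01, seed = 1)
  expect_length(lor$x$values, 5000)
  expect_true(all(abs(lor$x$values) < 30))
  expect_true(all(abs(lor$y$values) < 30))
  expect_true(all(lor$z$values > 0 & lor$z$values < 60))
  fixed <- gen_lorenz(2000, dt = 0.01, rho = 0.5, seed = 1)
  expect_lt(var(tail(fixed$x$values, 500)), 1e-4)
})

test_that("physio triplets have the stated sampling geometry and coupling semantics", {
  tr <- gen_physio_triplet(seed = 5)
  for (ch in list(tr$thermal, tr$rr_like, tr$eda_tonic_like, tr$driver)) {
    expect_equal(ch$fs, 5)
    expect_length(ch$values, 750)
  }
  # an uncoupled channel is independent of the driver, a coupled one is not
  tr0 <- gen_physio_triplet(couplings = c(0, 1, 1), seed = 5)
  expect_lt(abs(cor(tr0$thermal$values, tr0$driver$values)), 0.25)
  expect_gt(abs(cor(tr0$eda_tonic_like$values, tr0$driver$values)), 0.8)
  expect_error(gen_physio_triplet(duration_s = -1), "positive")
  expect_error(gen_physio_triplet(couplings = c(1, 1)), "three")
})

test_that("uncoupled triplet channels pass the cross-map permutation null in >= 90% of runs", {
  sig <- vapply(1:50, function(s) {
    tr <- gen_physio_triplet(couplings = c(0, 0, 0), seed = s)
    r <- suppressWarnings(cross_map_pair(tr$eda_tonic_like, tr$thermal))
    vr <- r$valid_range[1]:r$valid_range[2]
    L <- max(1L, min(r$params_y$tau, length(vr) %/% 10L))
    block_permutation_test(tr$thermal$values[vr], r$y_hat, L,
                           n_perm = 500, seed = s)$p_value < 0.05
  }, logical(1))
  expect_gte(mean(!sig), 0.9)
})

test_that("synthetic ECG produces the advertised beat structure", {
  e <- gen_synthetic_ecg(mean_hr_bpm = 60, hr_sd = 0.02, duration_s = 60,
                         noise_sd = 0, seed = 1)
  expect_true(length(e$true_beat_times) >= 58 &&
                length(e$true_beat_times) <= 62)
  gaps <- diff(e$true_beat_times)
  expect_true(all(gaps > 0.3 & gaps < 2.0))
  expect_true(max(e$true_beat_times) <= series_duration(e$waveform))
  periodic <- gen_synthetic_ecg(mean_hr_bpm = 75, hr_sd = 0, duration_s = 30,
                                noise_sd = 0, seed = 2)
  expect_lt(diff(range(diff(periodic$true_beat_times))), 1e-9)
  expect_error(gen_synthetic_ecg(mean_hr_bpm = 20), "30, 200")
})

test_that("synthetic cohorts are balanced within subjects with the requested shape", {
  d <- gen_cohort(30, 20, seed = 1)
  expect_equal(nrow(d), 60)
  expect_equal(sum(tapply(d$gender, d$subject, unique) == "female"), 20)
  expect_true(all(table(d$subject, d$condition) == 1))
  expect_error(gen_cohort(10, 11, seed = 1), "exceed")
})
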