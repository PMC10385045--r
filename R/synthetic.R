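#' Coupled logistic maps with known coupling
#'
#' Generates the standard two-species benchmark for cross-mapping: a pair of
#' logistic maps where each series can drive the other through a bilinear
#' coupling term,
#' \deqn{x_{t+1} = x_t (r_x - r_x x_t - \beta_{xy} y_t)}
#' and symmetrically for `y`. With `beta_xy > 0` the `y` series drives `x`,
#' so information about `y` is recoverable from the delay embedding of `x`.
#' A 300-iteration burn-in is discarded to remove transients.
#'
#' @param n series length after burn-in (>= 100).
#' @param rx,ry logistic growth rates, in (3.5, 4] (chaotic regime).
#' @param beta_xy coupling of `y` into `x` (>= 0).
#' @param beta_yx coupling of `x` into `y` (>= 0).
#' @param seed integer seed; identical arguments give identical output.
#' @return object of class `coupled_pair` with numeric fields `x`, `y` and
#'   the generating parameters.
#' @examples
#' cp <- gen_coupled_logistic(1000, 3.8, 3.5, beta_xy = 0.1, seed = 1)
#' range(cp$x)
#' @export
gen_coupled_logistic <- function(n, rx = 3.8, ry = 3.5,
                                 beta_xy = 0, beta_yx = 0, seed = 1) {
  if (n < 100) stop("`n` must be at least 100")
  if (rx <= 3.5 || rx > 4 || ry <= 3.5 || ry > 4)
    stop("`rx` and `ry` must lie in (3.5, 4]")
  if (beta_xy < 0 || beta_yx < 0) stop("couplings must be non-negative")
  burn <- 300L
  total <- n + burn
  with_seed(seed, {
    x <- numeric(total); y <- numeric(total)
    # initial values drawn inside (0.2, 0.8): after one step the state obeys
    # x <= rx/4, which keeps moderately coupled regimes inside [0, 1]
    x[1] <- runif(1, 0.2, 0.8); y[1] <- runif(1, 0.2, 0.8)
    for (t in seq_len(total - 1L)) {
      x[t + 1L] <- x[t] * (rx - rx * x[t] - beta_xy * y[t])
      y[t + 1L] <- y[t] * (ry - ry * y[t] - beta_yx * x[t])
      if (x[t + 1L] < 0 || x[t + 1L] > 1 || y[t + 1L] < 0 || y[t + 1L] > 1)
        stop("coupled logistic map diverged outside [0, 1] at iteration ",
             t + 1L, "; reduce the coupling or growth rate")
    }
    structure(list(x = x[(burn + 1L):total], y = y[(burn + 1L):total],
                   rx = rx, ry = ry, beta_xy = beta_xy, beta_yx = beta_yx,
                   seed = seed),
              class = "coupled_pair")
  })
}

#' Lorenz system trajectory
#'
#' Integrates the Lorenz equations with fixed-step fourth-order Runge-Kutta
#' from a seeded random initial condition near the attractor, discarding a
#' burn-in prefix. Used as a continuous-attractor fixture for embedding
#' parameter selection.
#'
#' @param n number of retained samples per coordinate.
#' @param dt integration step, in (0, 0.05].
#' @param sigma,rho,beta Lorenz parameters.
#' @param seed integer seed for the initial condition.
#' @param burn number of initial samples discarded.
#' @return list of three [uniform_series()] (`x`, `y`, `z`) with `fs = 1/dt`.
#' @export
gen_lorenz <- function(n, dt = 0.01, sigma = 10, rho = 28, beta = 8 / 3,
                       seed = 1, burn = 500L) {
  stop_if_not_scalar(dt, "dt")
  if (dt > 0.05) stop("`dt` must be in (0, 0.05]")
  if (n < 10) stop("`n` must be at least 10")
  deriv <- function(t, state, parms) {
    with(as.list(c(state, parms)), {
      list(c(sigma * (y - x), x * (rho - z) - y, x * y - beta * z))
    })
  }
  ic <- with_seed(seed, c(x = 1 + rnorm(1), y = 1 + rnorm(1), z = 20 + rnorm(1)))
  times <- seq(0, by = dt, length.out = n + burn)
  sol <- deSolve::ode(y = ic, times = times, func = deriv,
                      parms = c(sigma = sigma, rho = rho, beta = beta),
                      method = "rk4")
  if (any(!is.finite(sol[, -1])))
    stop("Lorenz integration diverged (non-finite state)")
  keep <- (burn + 1L):(n + burn)
  fs <- 1 / dt
  list(x = uniform_series(sol[keep, "x"], fs, label = "lorenz_x"),
       y = uniform_series(sol[keep, "y"], fs, label = "lorenz_y"),
       z = uniform_series(sol[keep, "z"], fs, label = "lorenz_z"))
}

#' Physiological-like triplet driven by a shared slow latent process
#'
#' Emulates the co-recorded 5 Hz, 150-s segments the cross-mapping stage
#' consumes: a thermal-like, an RR/HRV-like and a tonic-EDA-like channel,
#' each a channel-specific monotone, lagged transform of one latent driver
#' (low-pass-filtered Gaussian noise, cutoff 0.05 Hz, unit variance) scaled
#' by its coupling, plus a small channel-specific baseline trend and white
#' observation noise. Setting a coupling to zero makes that channel
#' independent of the driver (trend + noise only).
#'
#' @param duration_s segment duration in seconds (default 150).
#' @param fs sampling rate in Hz (default 5).
#' @param couplings length-3 non-negative vector: thermal, RR, tonic-EDA
#'   coupling to the driver.
#' @param noise_sd white-noise standard deviation added to every channel.
#' @param seed integer seed.
#' @return object of class `physio_triplet` with [uniform_series()] fields
#'   `thermal`, `rr_like`, `eda_tonic_like`, the latent `driver`, and the
#'   coupling ground truth.
#' @examples
#' tr <- gen_physio_triplet(seed = 7)
#' length(tr$thermal$values)  # 750 samples = 150 s at 5 Hz
#' @export
gen_physio_triplet <- function(duration_s = 150, fs = 5,
                               couplings = c(1, 1, 1), noise_sd = 0.05,
                               seed = 1) {
  stop_if_not_scalar(duration_s, "duration_s")
  stop_if_not_scalar(fs, "fs")
  if (length(couplings) != 3L || any(couplings < 0))
    stop("`couplings` must be three non-negative numbers")
  n <- as.integer(round(duration_s * fs))
  # channel lags (samples): sweat/vasomotor responses trail the central drive
  lags <- c(thermal = 10L, rr = 5L, eda = 3L)
  maxlag <- max(lags)
  with_seed(seed, {
    raw <- rnorm(n + maxlag)
    drv <- zerophase_filter(raw, fs, cutoff = 0.05, order = 2L, type = "low")
    drv <- (drv - mean(drv)) / sd(drv)
    lagged <- function(lag) drv[(maxlag - lag + 1L):(maxlag - lag + n)]
    tt <- (seq_len(n) - 1) / (n - 1)
    thermal <- 34 - couplings[1] * lagged(lags["thermal"]) -
      0.02 * tt + rnorm(n, 0, noise_sd)
    rr_like <- 0.85 + couplings[2] * tanh(lagged(lags["rr"])) +
      rnorm(n, 0, noise_sd)
    eda <- 2 + couplings[3] * log1p(exp(lagged(lags["eda"]))) +
      0.02 * tt + rnorm(n, 0, noise_sd)
    structure(list(
      thermal = uniform_series(thermal, fs, label = "Thermal"),
      rr_like = uniform_series(rr_like, fs, label = "HRV"),
      eda_tonic_like = uniform_series(eda, fs, label = "EDAtonic"),
      driver = uniform_series(drv[(maxlag + 1L):(maxlag + n)], fs,
                              label = "driver"),
      coupling_thermal_driver = couplings[1],
      coupling_rr_driver = couplings[2],
      coupling_eda_driver = couplings[3],
      seed = seed), class = "physio_triplet")
  })
}

#' Synthetic ECG-like waveform with known beat times
#'
#' Beats are placed by a seeded AR(1) inter-beat-interval process around
#' `60 / mean_hr_bpm` seconds, each rendered as a narrow positive Gaussian
#' template, with optional sinusoidal baseline wander and white noise. The
#' exact generating beat times are returned as ground truth for validating
#' QRS detection.
#'
#' @param mean_hr_bpm mean heart rate in beats per minute, in (30, 200).
#' @param hr_sd standard deviation of the RR process in seconds
#'   (0 gives perfectly periodic beats).
#' @param duration_s waveform duration in seconds.
#' @param fs sampling rate in Hz (default 250).
#' @param noise_sd additive white-noise standard deviation (template peak
#'   amplitude is 1).
#' @param wander_amp amplitude of a 0.25 Hz baseline wander component.
#' @param seed integer seed.
#' @return object of class `synthetic_ecg` with fields `waveform`
#'   ([uniform_series()]), `true_beat_times` (seconds) and `fs`.
#' @export
gen_synthetic_ecg <- function(mean_hr_bpm = 60, hr_sd = 0.02,
                              duration_s = 60, fs = 250, noise_sd = 0,
                              wander_amp = 0, seed = 1) {
  if (mean_hr_bpm <= 30 || mean_hr_bpm >= 200)
    stop("`mean_hr_bpm` must lie in (30, 200)")
  stop_if_not_scalar(duration_s, "duration_s")
  mean_rr <- 60 / mean_hr_bpm
  phi <- 0.8
  with_seed(seed, {
    beats <- numeric(0)
    t_cur <- 0.5
    rr_prev <- mean_rr
    innov_sd <- hr_sd * sqrt(1 - phi^2)
    while (t_cur < duration_s - 0.2) {
      beats <- c(beats, t_cur)
      rr_new <- mean_rr + phi * (rr_prev - mean_rr) + rnorm(1, 0, innov_sd)
      rr_new <- min(max(rr_new, 0.31), 1.99)  # keep gaps inside (0.3, 2.0) s
      rr_prev <- rr_new
      t_cur <- t_cur + rr_new
    }
    n <- as.integer(round(duration_s * fs))
    t_grid <- (seq_len(n) - 1) / fs
    wave <- numeric(n)
    width <- 0.012  # Gaussian template sd, seconds (narrow QRS-like spike)
    for (b in beats) {
      lo <- max(1L, floor((b - 5 * width) * fs) + 1L)
      hi <- min(n, ceiling((b + 5 * width) * fs) + 1L)
      idx <- lo:hi
      wave[idx] <- wave[idx] + exp(-0.5 * ((t_grid[idx] - b) / width)^2)
    }
    if (wander_amp > 0)
      wave <- wave + wander_amp * sin(2 * pi * 0.25 * t_grid + runif(1, 0, 2 * pi))
    if (noise_sd > 0) wave <- wave + rnorm(n, 0, noise_sd)
    structure(list(waveform = uniform_series(wave, fs, label = "ECG"),
                   true_beat_times = beats, fs = fs, seed = seed),
              class = "synthetic_ecg")
  })
}

#' Synthetic cohort for split-plot designs
#'
#' Generates a balanced-within cohort: every subject is observed under both
#' conditions (`rest`, `stress`), with a between-subjects gender factor.
#' Values follow
#' `grand mean + gender effect + condition effect + interaction +
#' subject random intercept + residual`, with effect-coded factors (female
#' and stress at +1/2), so `gender_effect` is the female-minus-male marginal
#' difference and `condition_effect` the stress-minus-rest difference.
#'
#' @param n_subjects number of subjects.
#' @param n_female number of female subjects (<= `n_subjects`).
#' @param gender_effect,condition_effect,interaction_effect ground-truth
#'   effect sizes on the response scale.
#' @param noise_sd residual standard deviation.
#' @param subject_sd standard deviation of the subject random intercept.
#' @param seed integer seed.
#' @return data.frame with columns `subject`, `gender`, `condition`, `value`
#'   (two rows per subject).
#' @examples
#' head(gen_cohort(30, 20, seed = 1))
#' @export
gen_cohort <- function(n_subjects, n_female, gender_effect = 0,
                       condition_effect = 0, interaction_effect = 0,
                       noise_sd = 1, subject_sd = 1, seed = 1) {
  if (n_female > n_subjects) stop("`n_female` cannot exceed `n_subjects`")
  if (n_subjects < 4) stop("need at least 4 subjects")
  with_seed(seed, {
    gender <- rep(c("female", "male"), c(n_female, n_subjects - n_female))
    u <- rnorm(n_subjects, 0, subject_sd)
    subj <- sprintf("S%02d", seq_len(n_subjects))
    out <- expand.grid(condition = c("rest", "stress"), subject = subj,
                       stringsAsFactors = FALSE)[, c("subject", "condition")]
    out$gender <- gender[match(out$subject, subj)]
    gs <- ifelse(out$gender == "female", 0.5, -0.5)
    cs <- ifelse(out$condition == "stress", 0.5, -0.5)
    out$value <- gender_effect * gs + condition_effect * cs +
      interaction_effect * gs * cs * 2 +
      u[match(out$subject, subj)] +
      rnorm(nrow(out), 0, noise_sd)
    out
  })
}
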