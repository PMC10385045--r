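#' Detect R peaks in an ECG-like waveform
#'
#' Adaptive QRS detection in the Pan-Tompkins style: band-pass filtering
#' (5-15 Hz, removing power-line noise and baseline drift), squaring to
#' highlight peaks, moving-average integration over a 150 ms window, then
#' decision rules with an adaptive amplitude threshold and a predicted-RR
#' plausibility search-back, both updated on every accepted beat. Beat times
#' are refined to the local maximum of the raw waveform around each
#' integrated-signal peak.
#'
#' @param ecg a [uniform_series()]; `fs >= 100` Hz and duration >= 10 s.
#' @return an [rr_series()] with an all-`FALSE` artifact mask.
#' @export
detect_r_peaks <- function(ecg) {
  stopifnot(inherits(ecg, "uniform_series"))
  fs <- ecg$fs
  if (fs < 100) stop("sampling rate too low for QRS detection (need >= 100 Hz)")
  if (series_duration(ecg) < 10) stop("need at least 10 s of signal")
  x <- ecg$values
  if (sd(x) < 1e-10) stop("no beats detectable: flat signal")

  bp <- zerophase_filter(x, fs, cutoff = c(5, 15), order = 3L, type = "pass")
  d <- c(0, diff(bp)) * fs
  sq <- d^2
  w <- max(1L, as.integer(round(0.150 * fs)))
  integ <- as.numeric(stats::filter(sq, rep(1 / w, w), sides = 1))
  integ[is.na(integ)] <- 0

  # candidate peaks: local maxima separated by a 200 ms refractory period
  n <- length(integ)
  is_max <- c(FALSE, integ[2:(n - 1)] > integ[1:(n - 2)] &
                integ[2:(n - 1)] >= integ[3:n], FALSE)
  cand <- which(is_max)
  if (length(cand) == 0L) stop("no beats detectable: no candidate peaks")
  refr <- as.integer(round(0.2 * fs))
  keep <- logical(length(cand))
  last <- -Inf
  for (i in seq_along(cand)) {
    if (cand[i] - last >= refr) { keep[i] <- TRUE; last <- cand[i] }
    else if (integ[cand[i]] > integ[cand[which(keep)[sum(keep)]]]) {
      keep[which(keep)[sum(keep)]] <- FALSE; keep[i] <- TRUE; last <- cand[i]
    }
  }
  cand <- cand[keep]

  # adaptive thresholding (signal/noise peak running estimates)
  init <- integ[seq_len(min(n, as.integer(2 * fs)))]
  spki <- 0.5 * max(init); npki <- 0.5 * mean(init)
  thr <- npki + 0.25 * (spki - npki)
  accepted <- integer(0)
  rr_hist <- numeric(0)
  pending <- integer(0)  # sub-threshold candidates, for search-back
  for (p in cand) {
    rr_avg <- if (length(rr_hist) >= 2) mean(tail(rr_hist, 8)) else NA_real_
    if (integ[p] > thr) {
      ok <- TRUE
      if (length(accepted) > 0L && (p - tail(accepted, 1)) < refr) ok <- FALSE
      if (ok) {
        if (length(accepted) > 0L)
          rr_hist <- c(rr_hist, (p - tail(accepted, 1)) / fs)
        accepted <- c(accepted, p)
        spki <- 0.125 * integ[p] + 0.875 * spki
      }
    } else {
      npki <- 0.125 * integ[p] + 0.875 * npki
      pending <- c(pending, p)
      # search-back: if the expected beat is overdue, accept the strongest
      # pending candidate above half threshold
      if (!is.na(rr_avg) && length(accepted) > 0L &&
          (p - tail(accepted, 1)) / fs > 1.66 * rr_avg) {
        ok_pend <- pending[integ[pending] > 0.5 * thr &
                             pending > tail(accepted, 1)]
        if (length(ok_pend) > 0L) {
          pb <- ok_pend[which.max(integ[ok_pend])]
          rr_hist <- c(rr_hist, (pb - tail(accepted, 1)) / fs)
          accepted <- sort(c(accepted, pb))
          spki <- 0.25 * integ[pb] + 0.75 * spki
          pending <- integer(0)
        }
      }
    }
    thr <- npki + 0.25 * (spki - npki)
  }
  if (length(accepted) < 2L) stop("no beats detectable: fewer than two accepted beats")

  # refine beat time: raw-waveform maximum in a window trailing the
  # integrator peak (the causal moving average delays peaks by ~w/2)
  half <- as.integer(round(0.10 * fs))
  beat_idx <- vapply(accepted, function(p) {
    lo <- max(1L, p - w - half); hi <- min(length(x), p + half)
    lo + which.max(x[lo:hi]) - 1L
  }, integer(1))
  beat_idx <- sort(unique(beat_idx))
  beat_idx <- beat_idx[c(TRUE, diff(beat_idx) >= refr)]
  rr_series(ecg$t0 + (beat_idx - 1L) / fs)
}

#' Threshold-based RR artifact correction
#'
#' Compares each RR interval to a local average obtained by median filtering
#' (window of 5 intervals). Intervals deviating from the local median by
#' more than `threshold_s` are flagged as artifacts and replaced by cubic
#' spline interpolation over the surrounding clean intervals; beat times are
#' rebuilt from the first beat by cumulative summation of the corrected
#' intervals.
#'
#' @param rr an [rr_series()] with >= 5 intervals.
#' @param threshold_s absolute deviation threshold in seconds (default
#'   0.45 s, the lowest detection threshold).
#' @param window median-filter window, in intervals (odd).
#' @return corrected [rr_series()]; `artifact_mask` records the flags.
#' @export
correct_rr_artifacts <- function(rr, threshold_s = 0.45, window = 5L) {
  stopifnot(inherits(rr, "rr_series"))
  stop_if_not_scalar(threshold_s, "threshold_s")
  iv <- rr$rr_intervals
  if (length(iv) < 5L) stop("need at least 5 RR intervals")
  local_med <- runmed(iv, k = window, endrule = "median")
  flag <- abs(iv - local_med) > threshold_s
  if (all(flag)) stop("all RR intervals flagged as artifacts; uncorrectable")
  if (!any(flag))
    return(rr_series(rr$beat_times, artifact_mask = flag))
  clean <- which(!flag)
  if (length(clean) < 4L) stop("too few clean intervals for cubic interpolation")
  sf <- splinefun(clean, iv[clean], method = "fmm")
  corrected <- iv
  corrected[flag] <- sf(which(flag))
  if (any(corrected <= 0)) stop("artifact correction produced non-positive intervals")
  rr_series(rr$beat_times[1] + c(0, cumsum(corrected)), artifact_mask = flag)
}

#' Interpolate RR intervals onto a uniform grid
#'
#' Treats the RR value as a function of beat time (each interval attributed
#' to its ending beat) and interpolates it with a piecewise cubic spline
#' onto a uniform grid at `fs_out`, anchored at the first knot.
#'
#' @param rr an [rr_series()] with >= 4 intervals.
#' @param fs_out output sampling rate in Hz (default 5, matching the
#'   infrared sampling rate).
#' @return a [uniform_series()] of RR values in seconds.
#' @export
rr_to_uniform <- function(rr, fs_out = 5.0) {
  stopifnot(inherits(rr, "rr_series"))
  stop_if_not_scalar(fs_out, "fs_out")
  iv <- rr$rr_intervals
  if (length(iv) < 4L) stop("need at least 4 RR intervals for cubic interpolation")
  knot_t <- rr$beat_times[-1]
  n_out <- floor((knot_t[length(knot_t)] - knot_t[1]) * fs_out) + 1L
  grid <- knot_t[1] + (seq_len(n_out) - 1L) / fs_out
  sf <- splinefun(knot_t, iv, method = "fmm")
  uniform_series(sf(grid), fs = fs_out, t0 = grid[1], label = "HRV")
}

#' Split a skin-conductance series into tonic and phasic components
#'
#' The tonic component is defined spectrally as the sub-0.05 Hz content of
#' the signal and extracted with a zero-phase 4th-order Butterworth low-pass
#' (reflect-padded); the phasic component is the residual, so
#' `tonic + phasic` reconstructs the input exactly. An externally computed
#' decomposition can be substituted anywhere downstream by constructing an
#' [eda_decomposition()] directly.
#'
#' @param eda a [uniform_series()]; `fs >= 1` Hz and duration >= 60 s (the
#'   filter needs room to settle).
#' @param cutoff tonic/phasic split frequency in Hz.
#' @return an [eda_decomposition()] with method tag `"lowpass-<cutoff>Hz"`.
#' @export
decompose_eda <- function(eda, cutoff = 0.05) {
  stopifnot(inherits(eda, "uniform_series"))
  if (eda$fs < 1) stop("sampling rate too low (need >= 1 Hz)")
  if (series_duration(eda) < 60)
    stop("series too short for the tonic filter to settle (need >= 60 s)")
  tonic_v <- zerophase_filter(eda$values, eda$fs, cutoff = cutoff,
                              order = 4L, type = "low")
  tonic <- uniform_series(tonic_v, eda$fs, t0 = eda$t0,
                          label = paste0(eda$label, "_tonic"))
  phasic <- uniform_series(eda$values - tonic_v, eda$fs, t0 = eda$t0,
                           label = paste0(eda$label, "_phasic"))
  eda_decomposition(tonic, phasic, method = sprintf("lowpass-%gHz", cutoff))
}

#' Downsample a uniform series
#'
#' Anti-alias filters (zero-phase Butterworth, cutoff at 90% of the new
#' Nyquist rate) and resamples onto a uniform grid at `fs_out`. Output
#' length follows the `floor(duration * fs_out) + 1` convention.
#'
#' @param series a [uniform_series()].
#' @param fs_out output rate in Hz; must not exceed the input rate.
#' @return a [uniform_series()] at `fs_out`.
#' @export
downsample <- function(series, fs_out = 5.0) {
  stopifnot(inherits(series, "uniform_series"))
  stop_if_not_scalar(fs_out, "fs_out")
  if (fs_out > series$fs) stop("upsampling refused: `fs_out` exceeds input rate")
  if (fs_out == series$fs) return(series)
  v <- series$values
  if (length(v) >= 12L)
    v <- zerophase_filter(v, series$fs, cutoff = 0.45 * fs_out,
                          order = 4L, type = "low")
  dur <- series_duration(series)
  n_out <- floor(dur * fs_out) + 1L
  grid <- series$t0 + (seq_len(n_out) - 1L) / fs_out
  sf <- splinefun(series_times(series), v, method = "fmm")
  uniform_series(sf(grid), fs = fs_out, t0 = series$t0, label = series$label)
}

#' Select the analysis segment of a session
#'
#' Returns the baseline or stimulation segment of a recorded session: the
#' final `segment_s` seconds of a resting session (the subject has fully
#' recovered from setup) or the first `segment_s` seconds of a stressor
#' session (habituation is minimised).
#'
#' @param series a [uniform_series()] spanning the session.
#' @param session `"rest"` or `"stress"`.
#' @param session_duration_s nominal session duration (default 300 s).
#' @param segment_s segment length in seconds (default 150 s).
#' @return a [uniform_series()] of `round(segment_s * fs)` samples.
#' @export
select_segment <- function(series, session = c("rest", "stress"),
                           session_duration_s = 300, segment_s = 150) {
  stopifnot(inherits(series, "uniform_series"))
  session <- match.arg(session)
  n <- length(series$values)
  n_seg <- as.integer(round(segment_s * series$fs))
  if (n < n_seg)
    stop(sprintf("session too short: %d samples available, %d needed", n, n_seg))
  idx <- if (session == "rest") (n - n_seg + 1L):n else 1:n_seg
  uniform_series(series$values[idx], series$fs,
                 t0 = series$t0 + (idx[1] - 1L) / series$fs,
                 label = series$label)
}
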