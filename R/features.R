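#' Welch power spectral density estimate
#'
#' Averaged modified periodograms: the series is cut into `seg_s`-second
#' segments with fractional `overlap`, each segment is linearly detrended,
#' Hann-windowed, and its one-sided periodogram accumulated. Defaults (60-s
#' segments, 50% overlap) resolve 0.04 Hz within a 150-s record.
#'
#' @param x a [uniform_series()] or numeric vector.
#' @param fs sampling rate (ignored when `x` is a series).
#' @param seg_s segment length in seconds.
#' @param overlap fractional overlap between segments, in \[0, 1).
#' @param detrend linearly detrend each segment before windowing.
#' @return data.frame with columns `freq` (Hz) and `psd` (power per Hz).
#' @export
welch_psd <- function(x, fs = NULL, seg_s = 60, overlap = 0.5,
                      detrend = TRUE) {
  if (inherits(x, "uniform_series")) { fs <- x$fs; x <- x$values }
  if (is.null(fs)) stop("`fs` required for a plain numeric vector")
  n <- length(x)
  nseg <- min(n, as.integer(round(seg_s * fs)))
  if (nseg < 8L) stop("segment too short for a spectral estimate")
  step <- max(1L, as.integer(round(nseg * (1 - overlap))))
  starts <- seq(1L, n - nseg + 1L, by = step)
  k <- seq_len(nseg)
  win <- 0.5 * (1 - cos(2 * pi * (k - 1) / (nseg - 1)))
  u <- sum(win^2)
  nfreq <- nseg %/% 2L + 1L
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1L)]
    if (detrend) seg <- stats::lm.fit(cbind(1, k), seg)$residuals
    sp <- abs(fft(seg * win)[seq_len(nfreq)])^2 / (fs * u)
    # one-sided: double everything except DC (and Nyquist for even nseg)
    sp[-1L] <- 2 * sp[-1L]
    if (nseg %% 2L == 0L) sp[nfreq] <- sp[nfreq] / 2
    acc <- acc + sp
  }
  data.frame(freq = (seq_len(nfreq) - 1L) * fs / nseg,
             psd = acc / length(starts))
}

#' Integrated band power from a Welch estimate
#' @param psd data.frame from [welch_psd()].
#' @param lo,hi band edges in Hz; the band is `[lo, hi)` unless `hi` is the
#'   upper analysis limit, in which case it is closed.
#' @param closed_hi include the upper edge.
#' @keywords internal
band_power <- function(psd, lo, hi, closed_hi = FALSE) {
  df <- psd$freq[2] - psd$freq[1]
  sel <- psd$freq >= lo & (if (closed_hi) psd$freq <= hi else psd$freq < hi)
  sum(psd$psd[sel]) * df
}

#' HRV scalar features of a 150-s segment
#'
#' Time-domain features (`meanHRV`, `stdHRV` in seconds; `RMSSD` in ms;
#' `pNN50` in %) are computed from the corrected, non-interpolated RR
#' intervals; frequency-domain features from the uniformly resampled series
#' via [welch_psd()]. `LF` and `HF` are the percentage of total spectral
#' power (0-0.40 Hz, DC excluded) in the 0.04-0.15 Hz and 0.15-0.40 Hz
#' bands, and `LF_HF_ratio` their ratio.
#'
#' @param rr an [rr_series()] covering the segment (>= 30 intervals).
#' @param uniform_rr the matching 5 Hz [uniform_series()] of RR values.
#' @return object of class `hrv_features`; `LF_HF_ratio` is `NA` with
#'   `ratio_undefined = TRUE` when the HF band holds no power.
#' @examples
#' rr <- rr_series(cumsum(c(0, rep(c(0.7, 0.9), 20))))
#' hrv_features(rr, rr_to_uniform(rr))[c("RMSSD", "pNN50")]
#' @export
hrv_features <- function(rr, uniform_rr) {
  stopifnot(inherits(rr, "rr_series"), inherits(uniform_rr, "uniform_series"))
  iv <- rr$rr_intervals
  if (length(iv) < 2L) stop("need at least 2 RR intervals")
  d <- diff(iv)
  feats <- list(
    meanHRV = mean(iv),
    stdHRV = sd(iv),
    RMSSD = sqrt(mean(d^2)) * 1000,
    pNN50 = 100 * mean(abs(d) > 0.050))
  if (sd(uniform_rr$values) < 1e-12) {
    feats$LF <- 0; feats$HF <- 0
    feats$LF_HF_ratio <- NA_real_
    feats$ratio_undefined <- TRUE
  } else {
    psd <- welch_psd(uniform_rr)
    total <- band_power(psd, 1e-9, 0.40, closed_hi = TRUE)
    lf <- band_power(psd, 0.04, 0.15)
    hf <- band_power(psd, 0.15, 0.40, closed_hi = TRUE)
    feats$LF <- 100 * lf / total
    feats$HF <- 100 * hf / total
    feats$ratio_undefined <- hf <= 0
    feats$LF_HF_ratio <- if (hf > 0) lf / hf else NA_real_
  }
  structure(feats, class = "hrv_features")
}

# local maxima of v strictly above `height`; returns indices
find_peaks <- function(v, height) {
  n <- length(v)
  if (n < 3L) return(integer(0))
  idx <- which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n]) + 1L
  idx[v[idx] > height]
}

#' EDA scalar features of a 150-s segment
#'
#' Tonic statistics (`TonicMean`, `TonicStd`) are the per-window mean and
#' standard deviation over non-overlapping 30-s windows, averaged across
#' windows. Phasic statistics (`PhasicMean`, `PhasicStd`, `PksMax`, `NPks`,
#' `PksSum`) are computed per non-overlapping 5-s window and averaged;
#' peaks are local maxima of the phasic component above `peak_min_height`
#' (windows without peaks contribute zero to the peak statistics).
#' `EDASymp` is the Welch band power of the reconstructed conductance
#' (tonic + phasic) in 0.04-0.25 Hz.
#'
#' @param dec an [eda_decomposition()] (150-s segments at 5 Hz in the
#'   standard pipeline).
#' @param tonic_window_s,phasic_window_s window lengths in seconds.
#' @param peak_min_height minimum phasic peak amplitude, signal units.
#' @return object of class `eda_features`; the per-window tables are kept
#'   in the `windows` field.
#' @export
eda_features <- function(dec, tonic_window_s = 30, phasic_window_s = 5,
                         peak_min_height = 0.01) {
  stopifnot(inherits(dec, "eda_decomposition"))
  fs <- dec$tonic$fs
  n <- length(dec$tonic$values)
  wt <- as.integer(round(tonic_window_s * fs))
  wp <- as.integer(round(phasic_window_s * fs))
  if (n < wt || n < wp) stop("segment shorter than one analysis window")

  window_split <- function(v, w) {
    nw <- n %/% w
    lapply(seq_len(nw), function(i) v[((i - 1L) * w + 1L):(i * w)])
  }
  tw <- window_split(dec$tonic$values, wt)
  tonic_tab <- data.frame(window = seq_along(tw),
                          mean = vapply(tw, mean, 0),
                          sd = vapply(tw, sd, 0))
  pw <- window_split(dec$phasic$values, wp)
  pk_stats <- lapply(pw, function(v) {
    pk <- find_peaks(v, peak_min_height)
    c(mean = mean(v), sd = sd(v),
      npks = length(pk),
      pksmax = if (length(pk)) max(v[pk]) else 0,
      pkssum = if (length(pk)) sum(v[pk]) else 0)
  })
  phasic_tab <- cbind(data.frame(window = seq_along(pw)),
                      as.data.frame(do.call(rbind, pk_stats)))
  recon <- dec$tonic$values + dec$phasic$values
  symp <- band_power(welch_psd(recon, fs = fs), 0.04, 0.25, closed_hi = TRUE)
  structure(list(
    TonicMean = mean(tonic_tab$mean), TonicStd = mean(tonic_tab$sd),
    PhasicMean = mean(phasic_tab$mean), PhasicStd = mean(phasic_tab$sd),
    PksMax = mean(phasic_tab$pksmax), NPks = mean(phasic_tab$npks),
    PksSum = mean(phasic_tab$pkssum), EDASymp = symp,
    windows = list(tonic = tonic_tab, phasic = phasic_tab)),
    class = "eda_features")
}

#' Assemble a per-subject feature row
#'
#' Convenience wrapper producing one flat named vector from the HRV and EDA
#' feature objects, with the column names of the standard feature tables.
#'
#' @param hrv an `hrv_features` object or `NULL`.
#' @param eda an `eda_features` object or `NULL`.
#' @return named numeric vector.
#' @export
feature_row <- function(hrv = NULL, eda = NULL) {
  out <- numeric(0)
  if (!is.null(hrv))
    out <- c(out, unlist(hrv[c("meanHRV", "stdHRV", "RMSSD", "pNN50",
                               "LF", "HF", "LF_HF_ratio")]))
  if (!is.null(eda))
    out <- c(out, unlist(eda[c("TonicMean", "TonicStd", "PhasicMean",
                               "PhasicStd", "PksMax", "NPks", "PksSum",
                               "EDASymp")]))
  out
}
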