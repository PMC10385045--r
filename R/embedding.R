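#' Automutual information curve
#'
#' Histogram estimate of the mutual information (nats) between `x(t)` and
#' `x(t + lag)` for lags `0..max_lag`, using an equal-width 2-D histogram
#' over the series range. By default the number of bins is
#' `ceiling(sqrt(N / 5))` capped at 32, which is robust for 750-sample
#' segments. `MI(0)` equals the entropy of the binned marginal.
#'
#' @param x a [uniform_series()] or numeric vector.
#' @param max_lag maximum lag in samples (`< N/3`).
#' @param n_bins number of histogram bins per axis (>= 4).
#' @return numeric vector of length `max_lag + 1` (lag 0 first), with the
#'   bin count in attribute `n_bins`.
#' @export
automutual_information <- function(x, max_lag, n_bins = NULL) {
  if (inherits(x, "uniform_series")) x <- x$values
  n <- length(x)
  if (sd(x) < 1e-14) stop("mutual information undefined for a constant series")
  if (max_lag >= n / 3) stop("`max_lag` must be below N/3")
  if (is.null(n_bins)) n_bins <- min(32L, as.integer(ceiling(sqrt(n / 5))))
  n_bins <- as.integer(n_bins)
  if (n_bins < 4L) stop("`n_bins` must be at least 4")
  breaks <- seq(min(x), max(x), length.out = n_bins + 1L)
  ix <- .bincode(x, breaks, include.lowest = TRUE)
  mi <- numeric(max_lag + 1L)
  for (lag in 0:max_lag) {
    a <- ix[seq_len(n - lag)]
    b <- ix[(1L + lag):n]
    joint <- tabulate(a + n_bins * (b - 1L), nbins = n_bins * n_bins)
    pj <- joint / sum(joint)
    pa <- tabulate(a, n_bins) / length(a)
    pb <- tabulate(b, n_bins) / length(b)
    pout <- outer(pa, pb)
    nz <- pj > 0
    mi[lag + 1L] <- sum(pj[nz] * log(pj[nz] / pout[nz]))
  }
  attr(mi, "n_bins") <- n_bins
  mi
}

#' Select the embedding delay from the automutual information
#'
#' Returns the first local minimum of the smoothed MI curve, the lag at
#' which embedded coordinates become near-independent in both linear and
#' nonlinear terms. The curve is smoothed with a 5-point moving average
#' (suppressing the period-2 binning parity artifacts of oscillatory
#' signals) and a candidate lag must (a) be the unique minimum within
#' +/- 2 lags and (b) be followed, within the next 15 lags and before any
#' lower value occurs, by a rise of at least 1.5% of `MI(0)`. The
#' prominence requirement rejects the spurious single-sample dips of an
#' essentially flat MI curve (white noise), while the undercut veto skips
#' shallow pre-minimum wiggles in favour of the true bottom of a broad
#' basin. A curve with no internal minimum indicates map-like or
#' noise-like data whose dependence decays from the very first lag; the
#' fallback is then `tau = 1`, the standard unit delay for discrete maps
#' (recorded in the `"method"` attribute).
#'
#' @param x a [uniform_series()] or numeric vector.
#' @param max_lag maximum lag scanned (default `min(floor(N/3) - 1, 100)`).
#' @param n_bins passed to [automutual_information()].
#' @return integer lag (attribute `"method"` is `"first_local_min"` or
#'   `"fallback_threshold"`).
#' @export
select_tau <- function(x, max_lag = NULL, n_bins = NULL) {
  if (inherits(x, "uniform_series")) x <- x$values
  n <- length(x)
  if (is.null(max_lag)) max_lag <- min(as.integer(floor(n / 3)) - 1L, 100L)
  if (max_lag < 3L) stop("`max_lag` too small to scan for a minimum")
  mi <- automutual_information(x, max_lag, n_bins)
  sm <- as.numeric(stats::filter(mi, rep(1 / 5, 5), sides = 2))
  sm[is.na(sm)] <- mi[is.na(sm)]
  prom <- 0.015 * mi[1]
  win <- 2L
  for (lag in win:(max_lag - win)) {
    i <- lag + 1L
    neigh <- sm[(i - win):(i + win)]
    if (sm[i] == min(neigh) && sum(neigh == sm[i]) == 1L) {
      ok <- FALSE
      for (j in (i + 1L):min(i + 15L, max_lag + 1L)) {
        if (sm[j] < sm[i]) break
        if (sm[j] >= sm[i] + prom) { ok <- TRUE; break }
      }
      if (ok) return(structure(lag, method = "first_local_min"))
    }
  }
  structure(1L, method = "fallback_unit")
}

#' Select the embedding dimension by false nearest neighbours
#'
#' Computes the Kennel false-neighbour fraction for `m = 1..m_max` (distance
#' increase test `Rtol`, attractor-size test `Atol`) and returns the first
#' dimension at which the curve has effectively vanished (fraction below
#' `fnn_tol`) or flattened at a low level (drop from the previous dimension
#' below `change_threshold` while the fraction is below 0.1). If neither
#' happens -- as for noise, which has no finite-dimensional attractor --
#' `m_max` is returned with a warning.
#'
#' @param x a [uniform_series()] or numeric vector.
#' @param tau embedding delay in samples (>= 1).
#' @param m_max largest dimension scanned (>= 2).
#' @param change_threshold flattening criterion on consecutive fractions.
#' @param Rtol,Atol Kennel test constants.
#' @param fnn_tol absolute fraction below which the attractor is considered
#'   unfolded.
#' @return integer dimension, with the fraction curve in attribute
#'   `"fnn_fractions"`.
#' @export
select_m_fnn <- function(x, tau, m_max = 10L, change_threshold = 0.01,
                         Rtol = 15, Atol = 2, fnn_tol = 0.01) {
  if (inherits(x, "uniform_series")) x <- x$values
  tau <- as.integer(tau); m_max <- as.integer(m_max)
  if (tau < 1L) stop("`tau` must be >= 1")
  if (m_max < 2L) stop("`m_max` must be >= 2")
  if (length(x) - m_max * tau < 20L)
    stop("series too short for `m_max` at this `tau`")
  if (sd(x) < 1e-14) stop("embedding undefined for a constant series")
  frac <- fnn_core(x, tau, m_max, Rtol, Atol)
  pick <- NA_integer_
  for (m in seq_len(m_max)) {
    if (!is.na(frac[m]) && frac[m] <= fnn_tol) { pick <- m; break }
    if (m >= 2L && !any(is.na(frac[(m - 1L):m])) &&
        (frac[m - 1L] - frac[m]) < change_threshold && frac[m] <= 0.1) {
      pick <- m; break
    }
  }
  if (is.na(pick)) {
    warning("false-neighbour fraction never settled; returning m_max")
    pick <- m_max
  }
  structure(as.integer(pick), fnn_fractions = frac)
}

#' Embedding parameters
#'
#' @param tau delay in samples (positive integer).
#' @param m embedding dimension (positive integer).
#' @param diagnostics optional list (MI curve, FNN fraction curve).
#' @export
embedding_params <- function(tau, m, diagnostics = NULL) {
  tau <- as.integer(tau); m <- as.integer(m)
  if (tau < 1L || m < 1L) stop("`tau` and `m` must be positive integers")
  structure(list(tau = tau, m = m, diagnostics = diagnostics),
            class = "embedding_params")
}

#' Delay-embed a series into its shadow manifold
#'
#' Builds the Takens reconstruction with backward lags: row `t` of the point
#' matrix is `(x_t, x_{t - tau}, ..., x_{t - (m-1) tau})`, and `time_index`
#' records the original (1-based) sample index of the most recent
#' coordinate, so the valid time range is a suffix of the series.
#'
#' @param x a [uniform_series()] or numeric vector of length
#'   `N > (m - 1) * tau`.
#' @param params an [embedding_params()] (or a list with `tau` and `m`).
#' @return object of class `shadow_manifold` with fields `points`
#'   (`(N - (m-1) tau) x m` matrix), `time_index`, `tau`, `m`,
#'   `source_label`.
#' @export
delay_embed <- function(x, params) {
  label <- ""
  if (inherits(x, "uniform_series")) { label <- x$label; x <- x$values }
  tau <- as.integer(params$tau); m <- as.integer(params$m)
  n <- length(x)
  span <- (m - 1L) * tau
  if (n <= span) stop("series too short: need N > (m - 1) * tau")
  idx <- (span + 1L):n
  pts <- vapply(0:(m - 1L), function(j) x[idx - j * tau], numeric(length(idx)))
  pts <- matrix(pts, nrow = length(idx), ncol = m)
  structure(list(points = pts, time_index = idx, tau = tau, m = m,
                 source_label = label),
            class = "shadow_manifold")
}

#' @export
print.shadow_manifold <- function(x, ...) {
  cat(sprintf("<shadow_manifold> %s: %d points in %d-D (tau = %d)\n",
              if (nzchar(x$source_label)) x$source_label else "unlabelled",
              nrow(x$points), x$m, x$tau))
  invisible(x)
}
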