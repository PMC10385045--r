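#' Exponential cross-map neighbour weights
#'
#' Given the distances from a query point to its nearest neighbours (nearest
#' first), returns the normalised weights
#' \deqn{u_i = \exp(-d_i / d_1), \quad \omega_i = u_i / \sum_j u_j.}
#' When the nearest distance is zero the weights collapse uniformly onto the
#' zero-distance set, the continuous limit of the formula.
#'
#' @param d numeric vector of neighbour distances, nearest first.
#' @return numeric weights summing to 1.
#' @examples
#' crossmap_weights(c(0.1, 0.2, 0.4))
#' @export
crossmap_weights <- function(d) {
  if (length(d) < 1L || any(d < 0) || is.unsorted(d))
    stop("`d` must be non-negative distances sorted nearest-first")
  if (d[1] == 0) {
    w <- as.numeric(d == 0)
    return(w / sum(w))
  }
  u <- exp(-d / d[1])
  u / sum(u)
}

#' Cross-map a target series from a shadow manifold
#'
#' For every requested point of the predictor manifold `Mx`, finds its `k`
#' nearest neighbours by Euclidean distance (the query point itself and any
#' point within a Theiler window of `theiler` samples are excluded; ties
#' are broken by smaller time index), maps their time indices onto the
#' target series, and returns the weighted average under
#' [crossmap_weights()]. Every estimate is a convex combination of observed
#' target values.
#'
#' @param Mx a `shadow_manifold` from [delay_embed()].
#' @param y target series ([uniform_series()] or numeric vector) covering
#'   all manifold time indices.
#' @param k neighbour count (>= 2, < number of manifold points).
#' @param theiler temporal exclusion radius in samples (default: the
#'   manifold's own `tau`).
#' @param query_time_index optional subset of `Mx$time_index` at which to
#'   estimate (default: all manifold points).
#' @return numeric vector of estimates with attribute `time_index`.
#' @export
cross_map_estimate <- function(Mx, y, k, theiler = Mx$tau,
                               query_time_index = NULL) {
  stopifnot(inherits(Mx, "shadow_manifold"))
  if (inherits(y, "uniform_series")) y <- y$values
  n_pts <- nrow(Mx$points)
  if (k < 2L) stop("`k` must be at least 2")
  if (k >= n_pts) stop("`k` must be smaller than the number of manifold points")
  if (max(Mx$time_index) > length(y))
    stop("`y` must cover all manifold time indices")
  if (is.null(query_time_index)) {
    rows <- seq_len(n_pts)
  } else {
    rows <- match(query_time_index, Mx$time_index)
    if (any(is.na(rows))) stop("query times must be manifold time indices")
  }
  est <- crossmap_core(Mx$points, as.integer(Mx$time_index), y,
                       as.integer(k), as.integer(theiler),
                       as.integer(rows))
  attr(est, "time_index") <- Mx$time_index[rows]
  est
}

#' Spearman rank correlation
#'
#' Pearson correlation of average-ranked values (ties receive average
#' ranks); invariant under strictly monotone transforms of either argument.
#'
#' @param a,b numeric vectors of equal length (>= 3), non-constant.
#' @return correlation in \[-1, 1\].
#' @export
spearman_rho <- function(a, b) {
  if (length(a) != length(b)) stop("`a` and `b` must have equal length")
  if (length(a) < 3L) stop("need at least 3 observations")
  if (sd(a) == 0 || sd(b) == 0) stop("Spearman correlation undefined for a constant input")
  cor(a, b, method = "spearman")
}

#' Full cross-mapping of a series pair
#'
#' Runs the complete estimator for one (predictor, target) pair of
#' simultaneously recorded, equally sampled series: selects the embedding
#' delay (first automutual-information minimum) and dimension (false
#' nearest neighbours) independently for each series, embeds the
#' *predictor*, uses `k = max(m_x, m_y) + 1` neighbours, estimates the
#' target over the valid range (the intersection of both embeddings' valid
#' suffixes, so all compared samples are aligned), and scores the estimate
#' with the Spearman correlation against the observed target.
#'
#' The direction is explicit: `x` is the series whose manifold is used
#' (the physiological predictor in the thermal-coupling analysis), `y` the
#' series being estimated (the thermal signal).
#'
#' @param x predictor [uniform_series()].
#' @param y target [uniform_series()], same length and rate as `x`.
#' @param m_max,change_threshold passed to [select_m_fnn()].
#' @param max_lag passed to [select_tau()].
#' @return object of class `crossmap_result`: `y_hat`, `rho`, `params_x`,
#'   `params_y` ([embedding_params()]), `k`, `valid_range` (first and last
#'   1-based sample index), `theiler`.
#' @export
cross_map_pair <- function(x, y, m_max = 10L, change_threshold = 0.01,
                           max_lag = NULL) {
  stopifnot(inherits(x, "uniform_series"), inherits(y, "uniform_series"))
  if (length(x$values) != length(y$values)) stop("series must have equal length")
  if (x$fs != y$fs) stop("series must share the sampling rate")
  n <- length(x$values)
  tau_x <- select_tau(x, max_lag = max_lag)
  tau_y <- select_tau(y, max_lag = max_lag)
  # cap the scanned dimension so the embedding keeps enough points
  mm_x <- max(2L, min(m_max, (n - 20L) %/% tau_x))
  mm_y <- max(2L, min(m_max, (n - 20L) %/% tau_y))
  m_x <- select_m_fnn(x, tau_x, m_max = mm_x, change_threshold = change_threshold)
  m_y <- select_m_fnn(y, tau_y, m_max = mm_y, change_threshold = change_threshold)
  px <- embedding_params(tau_x, m_x,
                         diagnostics = list(fnn = attr(m_x, "fnn_fractions")))
  py <- embedding_params(tau_y, m_y,
                         diagnostics = list(fnn = attr(m_y, "fnn_fractions")))
  Mx <- delay_embed(x, px)
  k <- max(px$m, py$m) + 1L
  start <- max((px$m - 1L) * px$tau, (py$m - 1L) * py$tau) + 1L
  query <- Mx$time_index[Mx$time_index >= start]
  # Theiler exclusion of tau samples, capped so every query point keeps at
  # least k candidates even on short, long-delay manifolds
  theiler <- min(Mx$tau, max(0L, (nrow(Mx$points) - k - 1L) %/% 4L))
  y_hat <- cross_map_estimate(Mx, y, k = k, theiler = theiler,
                              query_time_index = query)
  rho <- spearman_rho(y$values[query], as.numeric(y_hat))
  structure(list(y_hat = as.numeric(y_hat), rho = rho,
                 params_x = px, params_y = py, k = k,
                 valid_range = c(start, n), theiler = theiler),
            class = "crossmap_result")
}

#' @export
print.crossmap_result <- function(x, ...) {
  cat(sprintf(paste0("<crossmap_result> rho = %.3f (tau_x = %d, m_x = %d; ",
                     "tau_y = %d, m_y = %d; k = %d; valid %d..%d)\n"),
              x$rho, x$params_x$tau, x$params_x$m,
              x$params_y$tau, x$params_y$m, x$k,
              x$valid_range[1], x$valid_range[2]))
  invisible(x)
}
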