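#' Uniformly sampled time series
#'
#' The universal currency of the pipeline: a numeric vector sampled at a
#' constant rate, with a start time and a label. All preprocessing stages
#' consume and return `uniform_series` objects.
#'
#' @param values numeric vector of finite samples (length >= 1).
#' @param fs sampling rate in Hz (> 0).
#' @param t0 time of the first sample, seconds.
#' @param label channel label (e.g. `"Nose"`, `"HRV"`, `"EDAtonic"`).
#' @return an object of class `uniform_series` with fields `values`, `fs`,
#'   `t0` and `label`.
#' @examples
#' s <- uniform_series(sin(2 * pi * 0.1 * (0:749) / 5), fs = 5, label = "demo")
#' s
#' @export
uniform_series <- function(values, fs, t0 = 0, label = "") {
  values <- as.numeric(values)
  if (length(values) < 1L) stop("`values` must contain at least one sample")
  if (!all(is.finite(values))) stop("`values` must be finite")
  stop_if_not_scalar(fs, "fs")
  structure(list(values = values, fs = fs, t0 = as.numeric(t0)[1],
                 label = as.character(label)[1]),
            class = "uniform_series")
}

#' Sample times of a uniform series
#' @param x a [uniform_series()].
#' @return numeric vector of sample times in seconds.
#' @export
series_times <- function(x) {
  stopifnot(inherits(x, "uniform_series"))
  x$t0 + (seq_along(x$values) - 1) / x$fs
}

#' Duration of a uniform series in seconds
#' @param x a [uniform_series()].
#' @export
series_duration <- function(x) {
  stopifnot(inherits(x, "uniform_series"))
  (length(x$values) - 1) / x$fs
}

#' @export
print.uniform_series <- function(x, ...) {
  cat(sprintf("<uniform_series> %s: %d samples @ %g Hz (%.1f s, t0 = %g)\n",
              if (nzchar(x$label)) x$label else "unlabelled",
              length(x$values), x$fs, series_duration(x), x$t0))
  invisible(x)
}

#' Beat-time / inter-beat interval series
#'
#' Pre-interpolation cardiac representation: strictly increasing beat times,
#' the implied RR intervals, and a per-interval artifact mask filled in by
#' [correct_rr_artifacts()].
#'
#' @param beat_times strictly increasing beat times in seconds (>= 2 beats).
#' @param artifact_mask optional logical vector, one flag per RR interval.
#' @return object of class `rr_series` with fields `beat_times`,
#'   `rr_intervals` and `artifact_mask`.
#' @export
rr_series <- function(beat_times, artifact_mask = NULL) {
  beat_times <- as.numeric(beat_times)
  if (length(beat_times) < 2L) stop("need at least two beats")
  if (!all(is.finite(beat_times))) stop("beat times must be finite")
  rr <- diff(beat_times)
  if (any(rr <= 0)) stop("`beat_times` must be strictly increasing")
  if (is.null(artifact_mask)) artifact_mask <- rep(FALSE, length(rr))
  if (length(artifact_mask) != length(rr))
    stop("`artifact_mask` must have one entry per RR interval")
  structure(list(beat_times = beat_times, rr_intervals = rr,
                 artifact_mask = as.logical(artifact_mask)),
            class = "rr_series")
}

#' @export
print.rr_series <- function(x, ...) {
  cat(sprintf("<rr_series> %d beats, mean RR %.3f s, %d flagged interval(s)\n",
              length(x$beat_times), mean(x$rr_intervals), sum(x$artifact_mask)))
  invisible(x)
}

#' Tonic/phasic decomposition of a skin-conductance series
#'
#' Container returned by [decompose_eda()]. Constructing it directly lets an
#' externally computed decomposition (e.g. a convex-optimisation method) be
#' used as a drop-in replacement anywhere the pipeline expects one; the only
#' contract is that `tonic + phasic` reconstructs the analysed signal.
#'
#' @param tonic,phasic [uniform_series()] sharing `fs` and length.
#' @param method text tag recording how the split was computed.
#' @export
eda_decomposition <- function(tonic, phasic, method) {
  stopifnot(inherits(tonic, "uniform_series"), inherits(phasic, "uniform_series"))
  if (tonic$fs != phasic$fs || length(tonic$values) != length(phasic$values))
    stop("tonic and phasic components must share sampling rate and length")
  structure(list(tonic = tonic, phasic = phasic, method = as.character(method)[1]),
            class = "eda_decomposition")
}

#' @export
print.eda_decomposition <- function(x, ...) {
  cat(sprintf("<eda_decomposition> method %s, %d samples @ %g Hz\n",
              x$method, length(x$tonic$values), x$tonic$fs))
  invisible(x)
}

#' Write a uniform series to CSV
#'
#' Two-column layout (`time_s`, `value`), one file per channel.
#'
#' @param x a [uniform_series()].
#' @param path output file path.
#' @export
write_series_csv <- function(x, path) {
  stopifnot(inherits(x, "uniform_series"))
  write.csv(data.frame(time_s = series_times(x), value = x$values),
            path, row.names = FALSE)
  invisible(path)
}

#' Read a uniform series from CSV
#'
#' Expects columns `time_s` and `value`; the sampling rate is recovered from
#' the time column and checked for uniformity.
#'
#' @param path input file path.
#' @param label channel label for the returned series.
#' @param tol maximum relative jitter tolerated in the time grid.
#' @export
read_series_csv <- function(path, label = "", tol = 1e-6) {
  d <- read.csv(path)
  if (!all(c("time_s", "value") %in% names(d)))
    stop("expected columns `time_s` and `value` in ", path)
  dt <- diff(d$time_s)
  if (length(dt) < 1L) stop("need at least two samples in ", path)
  if (max(abs(dt - dt[1])) > tol * dt[1])
    stop("time column in ", path, " is not uniformly sampled")
  uniform_series(d$value, fs = 1 / dt[1], t0 = d$time_s[1], label = label)
}

#' Write beat times to CSV
#' @param rr an [rr_series()].
#' @param path output file path.
#' @export
write_rr_csv <- function(rr, path) {
  stopifnot(inherits(rr, "rr_series"))
  write.csv(data.frame(beat_time_s = rr$beat_times,
                       artifact = c(FALSE, rr$artifact_mask)),
            path, row.names = FALSE)
  invisible(path)
}

#' Read beat times from CSV
#' @param path file with a `beat_time_s` column (optional `artifact` column).
#' @export
read_rr_csv <- function(path) {
  d <- read.csv(path)
  if (!"beat_time_s" %in% names(d)) stop("expected column `beat_time_s` in ", path)
  mask <- if ("artifact" %in% names(d)) as.logical(d$artifact)[-1] else NULL
  rr_series(d$beat_time_s, artifact_mask = mask)
}
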