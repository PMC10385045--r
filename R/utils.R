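#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the global random number generator seeded at `seed`,
#' restoring the caller's RNG state afterwards. All package generators are
#' pure functions of their arguments because every draw happens inside this
#' scope.
#'
#' @param seed single integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number")
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

#' Zero-phase Butterworth filtering with reflect padding
#'
#' Applies `signal::filtfilt` after mirroring the series at both ends so the
#' forward-backward pass has no startup transient on short segments. The pad
#' length is three periods of the lowest cutoff frequency, capped at the
#' series length.
#'
#' @param values numeric vector.
#' @param fs sampling rate in Hz.
#' @param cutoff scalar (low/high) or length-2 (pass) cutoff in Hz.
#' @param order filter order.
#' @param type `"low"`, `"high"` or `"pass"`.
#' @keywords internal
zerophase_filter <- function(values, fs, cutoff, order = 4L, type = "low") {
  ny <- fs / 2
  if (any(cutoff <= 0) || any(cutoff >= ny))
    stop("cutoff frequencies must lie strictly inside (0, fs/2)")
  filt <- signal::butter(order, cutoff / ny, type = type)
  n <- length(values)
  pad <- min(n - 1L, as.integer(round(6 * fs / min(cutoff))))
  if (pad > 0L) {
    # even (mirror) extension: keeps the signal range and gives the
    # forward-backward pass room to settle before the first real sample
    left <- values[(pad + 1L):2L]
    right <- values[(n - 1L):(n - pad)]
    x <- c(left, values, right)
  } else {
    x <- values
  }
  out <- signal::filtfilt(filt, x)
  out[(pad + 1L):(pad + n)]
}

stop_if_not_scalar <- function(x, name, positive = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number", name))
  if (positive && x <= 0)
    stop(sprintf("`%s` must be positive", name))
  invisible(x)
}
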