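# Independent reference implementations used to cross-check the package's
# estimators on small inputs. They deliberately share no code with the
# implementation under test.

# exhaustive-distance-scan cross-map estimator (same contract as
# cross_map_estimate: k neighbours, Theiler exclusion, ties by smaller
# time index, exponential weights, uniform weights on a zero-distance set)
brute_force_crossmap <- function(pts, time_index, y, k, theiler) {
  n <- nrow(pts)
  vapply(seq_len(n), function(i) {
    dists <- sqrt(rowSums((pts - matrix(pts[i, ], n, ncol(pts), byrow = TRUE))^2))
    ok <- seq_len(n) != i & abs(time_index - time_index[i]) > theiler
    ord <- order(dists[ok], time_index[ok])
    cand_t <- time_index[ok][ord][1:k]
    cand_d <- dists[ok][ord][1:k]
    if (cand_d[1] == 0) {
      z <- cand_d == 0
      mean(y[cand_t[z]])
    } else {
      u <- exp(-cand_d / cand_d[1])
      sum(u * y[cand_t]) / sum(u)
    }
  }, numeric(1))
}

# exact two-sided signed-rank p-value by enumeration over all 2^n sign
# assignments of the absolute differences
wilcoxon_enumerate <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  mu <- n * (n + 1) / 4
  mean(abs(v_all - mu) >= abs(v_obs - mu))
}

# classical balanced split-plot sums of squares from cell means
spanova_cellmeans <- function(d) {
  gm <- mean(d$value)
  ssA <- ssC <- ssI <- 0
  for (g in unique(d$gender))
    ssA <- ssA + sum(d$gender == g) * (mean(d$value[d$gender == g]) - gm)^2
  for (cc in unique(d$condition))
    ssC <- ssC + sum(d$condition == cc) * (mean(d$value[d$condition == cc]) - gm)^2
  for (g in unique(d$gender)) for (cc in unique(d$condition)) {
    sel <- d$gender == g & d$condition == cc
    ssI <- ssI + sum(sel) * (mean(d$value[sel]) - mean(d$value[d$gender == g]) -
                               mean(d$value[d$condition == cc]) + gm)^2
  }
  subj_means <- tapply(d$value, d$subject, mean)
  subj_g <- tapply(as.character(d$gender), d$subject, function(x) unique(x))
  ssS <- 2 * sum((subj_means -
                    sapply(subj_g, function(g) mean(d$value[d$gender == g])))^2)
  ssT <- sum((d$value - gm)^2)
  ssE <- ssT - ssA - ssC - ssI - ssS
  n <- length(unique(d$subject))
  list(F_between = (ssA / 1) / (ssS / (n - 2)),
       F_within = (ssC / 1) / (ssE / (n - 2)),
       F_interaction = (ssI / 1) / (ssE / (n - 2)),
       ss = c(gender = ssA, subjects = ssS, condition = ssC,
              interaction = ssI, residual = ssE, total = ssT))
}
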