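#' Block permutation test for a correlation
#'
#' Builds the null distribution of the Spearman correlation between a
#' series and a fixed estimate by cutting the observed series into
#' consecutive blocks of `block_length` samples (a final short block is
#' kept), shuffling block order with a seeded RNG at each of `n_perm`
#' iterations, and recomputing the correlation. Blocks of length equal to
#' the embedding delay preserve the short-range autocorrelation that makes
#' samplewise shuffles anticonservative. The two-sided p-value uses the
#' add-one estimator on `|rho|`.
#'
#' @param y observed series (numeric vector).
#' @param y_hat fixed estimate, same length.
#' @param block_length block size in samples (>= 1, <= length/2).
#' @param n_perm number of permutations (>= 100; default 1000).
#' @param seed integer seed.
#' @return object of class `permutation_result`: `observed_rho`,
#'   `null_rhos`, `p_value`, `block_length`, `n_perm`, `seed`.
#' @export
block_permutation_test <- function(y, y_hat, block_length, n_perm = 1000L,
                                   seed = 1L) {
  if (length(y) != length(y_hat)) stop("`y` and `y_hat` must have equal length")
  n <- length(y)
  block_length <- as.integer(block_length)
  if (block_length < 1L) stop("`block_length` must be >= 1")
  if (block_length > n %/% 2L)
    stop("degenerate permutation: `block_length` exceeds half the series")
  if (n_perm < 100L) stop("`n_perm` must be at least 100")
  ry <- rank(y)
  rh <- rank(y_hat)
  obs <- cor(ry, rh)
  n_blocks <- ceiling(n / block_length)
  block_id <- rep(seq_len(n_blocks), each = block_length)[seq_len(n)]
  blocks <- split(seq_len(n), block_id)
  null_rhos <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      idx <- unlist(blocks[sample.int(n_blocks)], use.names = FALSE)
      cor(ry[idx], rh)
    }, numeric(1))
  })
  p <- (1 + sum(abs(null_rhos) >= abs(obs))) / (n_perm + 1)
  structure(list(observed_rho = obs, null_rhos = null_rhos, p_value = p,
                 block_length = block_length, n_perm = as.integer(n_perm),
                 seed = as.integer(seed)),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("<permutation_result> rho = %.3f, p = %.4f (L = %d, %d perms)\n",
              x$observed_rho, x$p_value, x$block_length, x$n_perm))
  invisible(x)
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided paired test on `b - a` differences. Zero differences are
#' dropped (Wilcoxon's original rule); the exact null distribution is used
#' for up to 25 non-zero differences without ties in the absolute values,
#' otherwise the normal approximation with tie and continuity correction.
#'
#' @param a,b paired numeric vectors; >= 5 non-zero differences required.
#' @return list with `statistic` (sum of positive-difference ranks),
#'   `p_value`, `n` (pairs used) and `exact` (which path was taken).
#' @export
wilcoxon_signed_rank <- function(a, b) {
  if (length(a) != length(b)) stop("`a` and `b` must have equal length")
  d <- b - a
  d <- d[d != 0]
  if (length(d) == 0L) stop("all paired differences are zero")
  if (length(d) < 5L) stop("need at least 5 non-zero differences")
  exact <- length(d) <= 25L && !anyDuplicated(abs(d))
  wt <- suppressWarnings(wilcox.test(d, exact = exact, correct = TRUE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       n = length(d), exact = exact)
}

#' Two-stage step-up false discovery rate control
#'
#' The two-stage linear step-up procedure: stage one applies the
#' Benjamini-Hochberg step-up at level `q' = q / (1 + q)` to estimate the
#' number of true nulls as `m0 = m - r1`; stage two applies the step-up at
#' the inflated level `q * m / m0` (all hypotheses are rejected when
#' `m0 = 0`). The stage-two level never falls below `q`, so the rejection
#' set always contains the plain step-up rejections at `q`.
#'
#' @param p_values numeric p-values in \[0, 1\].
#' @param q target false discovery rate (default 0.05).
#' @return logical rejection mask.
#' @export
fdr_bky <- function(p_values, q = 0.05) {
  if (length(p_values) == 0L) stop("empty p-value vector")
  if (any(p_values < 0 | p_values > 1)) stop("p-values must lie in [0, 1]")
  m <- length(p_values)
  adj <- stats::p.adjust(p_values, method = "BH")
  r1 <- sum(adj <= q / (1 + q))
  m0 <- m - r1
  if (m0 == 0L) return(rep(TRUE, m))
  adj <= q * m / m0
}

#' Bonferroni correction
#'
#' @param p_values numeric p-values in \[0, 1\].
#' @param alpha family-wise error level (default 0.05).
#' @return logical rejection mask (`p < alpha / m`).
#' @export
bonferroni <- function(p_values, alpha = 0.05) {
  if (length(p_values) == 0L) stop("empty p-value vector")
  if (any(p_values < 0 | p_values > 1)) stop("p-values must lie in [0, 1]")
  p_values < alpha / length(p_values)
}

#' Split-plot (mixed design) analysis of variance
#'
#' Two-factor mixed ANOVA with one between-subjects factor (`gender`) and
#' one within-subjects factor (`condition`, two levels, both observed for
#' every subject). The between-subjects effect is tested against
#' subjects-within-groups variation; the condition main effect and the
#' gender-by-condition interaction against the condition-by-subjects
#' residual. Unbalanced group sizes are handled with Type-II sums of
#' squares (each term adjusted for every term not containing it). With two
#' within-subject levels sphericity holds automatically, so p-values come
#' straight from the F distribution.
#'
#' @param data data.frame with columns `subject`, `gender`, `condition`,
#'   `value`; every subject in one gender group and both conditions,
#'   >= 2 subjects per gender.
#' @return object of class `spanova_table` with F statistics, degree-of-
#'   freedom pairs, p-values and sums of squares for the three effects.
#' @examples
#' spanova(gen_cohort(12, 6, condition_effect = 2, seed = 1))
#' @export
spanova <- function(data) {
  req <- c("subject", "gender", "condition", "value")
  if (!all(req %in% names(data))) stop("`data` needs columns ", paste(req, collapse = ", "))
  data$subject <- factor(data$subject)
  data$gender <- factor(data$gender)
  data$condition <- factor(data$condition)
  conds <- levels(data$condition)
  if (length(conds) != 2L) stop("exactly two conditions required")
  tab <- table(data$subject, data$condition)
  if (any(tab != 1L)) stop("every subject must appear exactly once per condition")
  gmap <- unique(data[, c("subject", "gender")])
  if (nrow(gmap) != nlevels(data$subject))
    stop("each subject must belong to exactly one gender group")
  if (any(table(gmap$gender) < 2L)) stop("need >= 2 subjects per gender group")

  n_subj <- nlevels(data$subject)
  g <- nlevels(data$gender)
  cc <- 2L

  # between-subjects stratum, on subject means (x cc to stay on the
  # observation scale)
  sm <- aggregate(value ~ subject, data, mean)
  sm$gender <- gmap$gender[match(sm$subject, gmap$subject)]
  rss0 <- sum(lm(value ~ 1, sm)$residuals^2)
  rss1 <- sum(lm(value ~ gender, sm)$residuals^2)
  ss_gender <- (rss0 - rss1) * cc
  ss_subj <- rss1 * cc
  df_gender <- g - 1L
  df_subj <- n_subj - g

  # within-subjects stratum: Type-II via nested model comparison
  # (subject absorbs gender)
  f_s <- lm(value ~ subject, data)
  f_sc <- lm(value ~ subject + condition, data)
  f_full <- lm(value ~ subject + condition + gender:condition, data)
  ss_cond <- sum(f_s$residuals^2) - sum(f_sc$residuals^2)
  ss_int <- sum(f_sc$residuals^2) - sum(f_full$residuals^2)
  ss_err <- sum(f_full$residuals^2)
  df_cond <- cc - 1L
  df_int <- (g - 1L) * (cc - 1L)
  df_err <- f_full$df.residual

  f_between <- (ss_gender / df_gender) / (ss_subj / df_subj)
  f_within <- (ss_cond / df_cond) / (ss_err / df_err)
  f_inter <- (ss_int / df_int) / (ss_err / df_err)
  structure(list(
    F_between = f_between, df_between = c(df_gender, df_subj),
    p_between = pf(f_between, df_gender, df_subj, lower.tail = FALSE),
    F_within = f_within, df_within = c(df_cond, df_err),
    p_within = pf(f_within, df_cond, df_err, lower.tail = FALSE),
    F_interaction = f_inter, df_interaction = c(df_int, df_err),
    p_interaction = pf(f_inter, df_int, df_err, lower.tail = FALSE),
    ss = c(gender = ss_gender, subjects = ss_subj, condition = ss_cond,
           interaction = ss_int, residual = ss_err)),
    class = "spanova_table")
}

#' @export
print.spanova_table <- function(x, ...) {
  cat("<spanova_table>\n")
  cat(sprintf("  between (gender):      F(%d, %d) = %.3f, p = %.4f\n",
              x$df_between[1], x$df_between[2], x$F_between, x$p_between))
  cat(sprintf("  within (condition):    F(%d, %d) = %.3f, p = %.4f\n",
              x$df_within[1], x$df_within[2], x$F_within, x$p_within))
  cat(sprintf("  gender x condition:    F(%d, %d) = %.3f, p = %.4f\n",
              x$df_interaction[1], x$df_interaction[2], x$F_interaction,
              x$p_interaction))
  invisible(x)
}
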