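test_that("block permutation test detects a perfect estimate and respects its bounds", {
  set.seed(1)
  y <- rnorm(750)
  res <- block_permutation_test(y, y, block_length = 5, n_perm = 1000, seed = 2)
  expect_lte(res$p_value, 0.005)
  expect_equal(res$observed_rho, 1)
  expect_gte(res$p_value, 1 / (res$n_perm + 1))
  # same seed -> identical null distribution
  res2 <- block_permutation_test(y, y, block_length = 5, n_perm = 1000, seed = 2)
  expect_identical(res$null_rhos, res2$null_rhos)
  expect_error(block_permutation_test(y, y, block_length = 400),
               "degenerate")
  expect_error(block_permutation_test(y, y, block_length = 5, n_perm = 10),
               "at least 100")
  # default repetition count
  expect_equal(eval(formals(block_permutation_test)$n_perm), 1000L)
})

test_that("Wilcoxon signed-rank exact path matches textbook and enumeration values", {
  a <- c(1.2, 2.5, 0.3, 4.1, 3.3, 2.2)
  # six positive differences of distinct magnitude: the extreme rank sum
  # has exact two-sided probability 2/2^6
  res <- wilcoxon_signed_rank(a, a + seq(10, 15))
  expect_true(res$exact)
  expect_equal(res$p_value, 0.03125)
  expect_error(wilcoxon_signed_rank(a, a), "zero")
  # symmetric equal-magnitude differences sit at the null centre
  b <- c(1, 2, 3, 4, 5, 6) + c(2, -2, 2, -2, 2, -2)
  expect_equal(wilcoxon_signed_rank(c(1, 2, 3, 4, 5, 6), b)$p_value, 1)
  # exact path equals sign-assignment enumeration for n <= 10
  set.seed(8)
  for (i in 1:10) {
    n <- sample(5:10, 1)
    d <- round(rnorm(n), 3)
    d <- d[d != 0]
    if (length(d) < 5 || anyDuplicated(abs(d))) next
    expect_equal(wilcoxon_signed_rank(numeric(length(d)), d)$p_value,
                 wilcoxon_enumerate(d), tolerance = 1e-12)
  }
})

test_that("two-stage FDR control rejects obvious signals and spares nulls", {
  expect_true(all(fdr_bky(rep(0.001, 10))))
  expect_false(any(fdr_bky(seq(0.9, 0.99, length.out = 10))))
  expect_error(fdr_bky(numeric(0)), "empty")
  expect_error(fdr_bky(c(0.5, 1.2)), "0, 1")
})

test_that("two-stage FDR rejections contain the single-stage step-up rejections", {
  bh_mask <- function(p, q) stats::p.adjust(p, "BH") <= q
  set.seed(10)
  for (i in 1:50) {
    p <- c(rbeta(sample(0:30, 1), 0.2, 1), runif(sample(5:70, 1)))
    expect_true(all(bh_mask(p, 0.05) <= fdr_bky(p, 0.05)))
  }
  # monotone: lowering a p-value never removes rejections
  p <- c(0.001, 0.02, 0.04, 0.2, 0.6)
  r1 <- fdr_bky(p, 0.05)
  p2 <- p; p2[4] <- 0.01
  r2 <- fdr_bky(p2, 0.05)
  expect_true(all(r1[-4] <= r2[-4]))
})

test_that("Bonferroni masks use the alpha/m threshold", {
  expect_equal(bonferroni(c(0.01, 0.2, 0.04)), c(TRUE, FALSE, FALSE))
  expect_true(bonferroni(0.04))
  expect_equal(bonferroni(c(0.012, 0.013)), c(TRUE, TRUE))
  expect_error(bonferroni(numeric(0)), "empty")
})

test_that("split-plot ANOVA matches the cell-means oracle on balanced designs", {
  for (s in 1:5) {
    d <- gen_cohort(20, 10, gender_effect = 1, condition_effect = 2,
                    interaction_effect = 0.5, seed = s)
    sp <- spanova(d)
    oracle <- spanova_cellmeans(d)
    expect_equal(sp$F_between, oracle$F_between, tolerance = 1e-8)
    expect_equal(sp$F_within, oracle$F_within, tolerance = 1e-8)
    expect_equal(sp$F_interaction, oracle$F_interaction, tolerance = 1e-8)
    # total sums of squares decompose exactly
    expect_equal(sum(sp$ss), unname(oracle$ss["total"]), tolerance = 1e-8)
  }
  d <- gen_cohort(12, 6, seed = 3)
  sp <- spanova(d)
  expect_equal(sp$df_between, c(1, 10))
  expect_equal(sp$df_within, c(1, 10))
  expect_equal(sp$df_interaction, c(1, 10))
})

test_that("split-plot ANOVA has power for a gender-by-condition crossover", {
  hits <- mean(vapply(1:50, function(s) {
    d <- gen_cohort(30, 15, interaction_effect = 3, noise_sd = 1, seed = s)
    spanova(d)$p_interaction < 0.05
  }, logical(1)))
  expect_gte(hits, 0.9)
})

test_that("split-plot ANOVA validates the design", {
  d <- gen_cohort(10, 5, seed = 1)
  expect_error(spanova(d[-1, ]), "exactly once")
  d2 <- d
  d2$gender[d2$subject == "S01"] <- c("female", "male")
  expect_error(spanova(d2), "one gender")
  d3 <- gen_cohort(6, 1, seed = 1)
  expect_error(spanova(d3), ">= 2 subjects")
})
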