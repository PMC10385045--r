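test_that("exponential neighbour weights match the defining formula", {
  w <- crossmap_weights(c(0.1, 0.2, 0.4))
  u <- exp(-c(0.1, 0.2, 0.4) / 0.1)
  expect_equal(w, u / sum(u), tolerance = 1e-12)
  expect_equal(sum(w), 1, tolerance = 1e-12)
  # zero-distance neighbours take the uniform limit
  expect_equal(crossmap_weights(c(0, 0, 0.3)), c(0.5, 0.5, 0))
  set.seed(3)
  for (i in 1:20) {
    d <- sort(runif(5, 0.01, 2))
    w <- crossmap_weights(d)
    expect_true(all(w > 0))
    expect_equal(sum(w), 1, tolerance = 1e-12)
    expect_true(all(diff(w) <= 0))  # closer neighbours weigh more
  }
})

test_that("cross-map estimates are convex combinations of target values", {
  set.seed(5)
  x <- rnorm(200)
  M <- delay_embed(x, embedding_params(2, 3))
  y_const <- rep(3.7, 200)
  est <- cross_map_estimate(M, y_const, k = 4)
  expect_equal(as.numeric(est), rep(3.7, nrow(M$points)))
  y <- rnorm(200)
  est2 <- cross_map_estimate(M, y, k = 4)
  expect_true(all(est2 >= min(y) & est2 <= max(y)))
  expect_error(cross_map_estimate(M, y, k = 1), "at least 2")
  expect_error(cross_map_estimate(M, y, k = nrow(M$points)), "smaller")
})

test_that("the estimator agrees exactly with an exhaustive-distance oracle on small inputs", {
  set.seed(9)
  cases <- list(list(n = 30, tau = 1, m = 2, k = 3, theiler = 0),
                list(n = 50, tau = 2, m = 3, k = 4, theiler = 2),
                list(n = 40, tau = 1, m = 4, k = 5, theiler = 1),
                list(n = 25, tau = 3, m = 2, k = 3, theiler = 3))
  for (cs in cases) {
    x <- rnorm(cs$n)
    y <- rnorm(cs$n)
    M <- delay_embed(x, embedding_params(cs$tau, cs$m))
    est <- cross_map_estimate(M, y, k = cs$k, theiler = cs$theiler)
    oracle <- brute_force_crossmap(M$points, M$time_index, y, cs$k, cs$theiler)
    expect_equal(as.numeric(est), oracle, tolerance = 1e-12)
  }
  # exact duplicate points exercise the zero-distance branch
  x <- rep(c(0.2, 0.7, 0.4, 0.9), 10)
  y <- rnorm(40)
  M <- delay_embed(x, embedding_params(1, 2))
  est <- cross_map_estimate(M, y, k = 3, theiler = 0)
  oracle <- brute_force_crossmap(M$points, M$time_index, y, 3, 0)
  expect_equal(as.numeric(est), oracle, tolerance = 1e-12)
})

test_that("Spearman correlation has the textbook values and rank invariance", {
  expect_equal(spearman_rho(1:5, 5:1), -1)
  expect_equal(spearman_rho(c(1, 2, 3, 4), c(2, 1, 4, 3)), 0.6)
  set.seed(4)
  a <- rnorm(50)
  b <- a^3 + 2  # strictly monotone transform
  expect_equal(spearman_rho(a, b), 1)
  expect_equal(spearman_rho(exp(a), b), spearman_rho(a, b))
  expect_error(spearman_rho(rep(1, 10), rnorm(10)), "constant")
  expect_error(spearman_rho(1:4, 1:5), "equal length")
})

test_that("self cross-mapping of a deterministic map is near perfect", {
  cp <- gen_coupled_logistic(1000, 3.8, 3.55, seed = 5)
  x <- uniform_series(cp$x, fs = 5)
  r <- suppressWarnings(cross_map_pair(x, x))
  expect_gt(r$rho, 0.99)
  expect_equal(r$k, max(r$params_x$m, r$params_y$m) + 1L)
})

test_that("the driven series recovers the driver but independent noise does not", {
  rhos <- vapply(1:25, function(s) {
    cp <- gen_coupled_logistic(1000, 3.8, 3.55, beta_xy = 0, beta_yx = 0.4,
                               seed = s)
    suppressWarnings(cross_map_pair(uniform_series(cp$y, 5),
                                    uniform_series(cp$x, 5))$rho)
  }, numeric(1))
  expect_gte(median(rhos), 0.7)

  null_rhos <- vapply(1:50, function(s) {
    set.seed(s)
    suppressWarnings(cross_map_pair(uniform_series(rnorm(750), 5),
                                    uniform_series(rnorm(750), 5))$rho)
  }, numeric(1))
  expect_lt(median(abs(null_rhos)), 0.15)
})

test_that("independent logistic maps cross-map to near-zero skill", {
  rhos <- vapply(1:50, function(s) {
    cp <- gen_coupled_logistic(750, 3.8, 3.8, seed = 100 + s)
    suppressWarnings(cross_map_pair(uniform_series(cp$x, 5),
                                    uniform_series(cp$y, 5))$rho)
  }, numeric(1))
  expect_lt(mean(abs(rhos)), 0.2)
})

test_that("cross_map_pair validates its inputs", {
  a <- uniform_series(rnorm(300), 5)
  expect_error(cross_map_pair(a, uniform_series(rnorm(200), 5)), "equal length")
  expect_error(cross_map_pair(a, uniform_series(rnorm(300), 10)),
               "sampling rate")
  expect_error(suppressWarnings(
    cross_map_pair(uniform_series(rep(1, 300), 5), a)), "constant")
})
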