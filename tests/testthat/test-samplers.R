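std_normal_lp <- function(X) {
  X <- if (is.matrix(X)) X else matrix(X, nrow = 1)
  -0.5 * rowSums(X^2)
}

test_that("slice sampling recovers a standard normal target", {
  ch <- slice_sample(std_normal_lp, -10, 10, 0, min_samples = 5000,
                     seed = 81)
  x <- ch$draws[, 1]
  expect_lt(abs(mean(x)), 3 * sd(x) / sqrt(500)) # generous ESS allowance
  expect_lt(abs(var(x) - 1), 0.1)
  expect_gte(nrow(ch$draws), 2000)
})

test_that("slice sampling covers a uniform box target", {
  lp <- function(X) rep(0, if (is.matrix(X)) nrow(X) else 1)
  ch <- slice_sample(lp, c(0, -1), c(2, 1), c(1, 0), min_samples = 3000,
                     seed = 82)
  expect_true(all(ch$draws[, 1] >= 0 & ch$draws[, 1] <= 2))
  expect_true(all(ch$draws[, 2] >= -1 & ch$draws[, 2] <= 1))
  ks <- suppressWarnings(ks.test(ch$draws[, 1], "punif", 0, 2))
  expect_gt(ks$p.value, 0.01)
})

test_that("slice sampling refuses an infeasible start", {
  lp <- function(X) rep(-Inf, if (is.matrix(X)) nrow(X) else 1)
  expect_error(slice_sample(lp, -1, 1, 0, min_samples = 100), "finite")
})

test_that("the Geweke statistic is calibrated and detects trends", {
  set.seed(83)
  zs <- replicate(400, geweke_statistic(rnorm(3000)))
  expect_gte(mean(abs(zs) < 2), 0.93)
  trend <- seq(0, 1, length.out = 5000) + rnorm(5000, 0, 0.05)
  expect_gt(abs(geweke_statistic(trend)), 4)
  # identical first and last windows give exactly zero
  y <- rnorm(1000)
  chain <- c(y[1:100], rnorm(400), y[1:100])
  z <- geweke_statistic(chain, frac1 = 1 / 6, frac2 = 1 / 6)
  expect_equal(z, 0)
  expect_error(geweke_statistic(rep(1, 200)), "variance")
  expect_error(geweke_statistic(rnorm(50)), "short")
})

test_that("DEMCMC reflects out-of-box proposals across the violated face", {
  expect_equal(reflect_into_box(matrix(c(1.3), 1, 1), 0, 1),
               matrix(0.7, 1, 1))
  expect_equal(reflect_into_box(c(-0.2, 0.5), c(0, 0), c(1, 1)),
               c(0.2, 0.5))
  # repeated folding for far-out points, always inside afterwards
  set.seed(84)
  X <- matrix(rnorm(300, 0, 10), 100, 3)
  R <- reflect_into_box(X, c(-1, 0, 2), c(1, 1, 5))
  expect_true(all(R >= matrix(c(-1, 0, 2), 100, 3, byrow = TRUE)))
  expect_true(all(R <= matrix(c(1, 1, 5), 100, 3, byrow = TRUE)))
})

test_that("DEMCMC recovers a correlated Gaussian and sizes its ensemble", {
  S <- matrix(c(1, 0.7, 0.7, 1), 2)
  Si <- solve(S)
  lp <- function(X) {
    X <- if (is.matrix(X)) X else matrix(X, 1)
    -0.5 * rowSums((X %*% Si) * X)
  }
  ch <- demcmc_sample(lp, c(-8, -8), c(8, 8), seed = 85, min_gens = 1500,
                      max_gens = 1500)
  expect_equal(dim(ch$draws)[2], 10) # 5 chains per dimension
  ps <- posterior_summary(ch)
  expect_lt(max(abs(ps$mean)), 0.1)
  expect_lt(abs(ps$var[1] - 1), 0.1)
  expect_lt(abs(cov(ps$draws)[1, 2] - 0.7), 0.1)
  d4 <- demcmc_sample(std_normal_lp, rep(-5, 4), rep(5, 4), seed = 86,
                      min_gens = 100, max_gens = 150)
  expect_equal(dim(d4$draws)[2], 20)
  expect_true(all(d4$draws >= -5 & d4$draws <= 5))
})

test_that("the Gelman-Rubin statistic matches a reference implementation", {
  reference <- function(M) { # chains in columns
    n <- nrow(M)
    W <- mean(apply(M, 2, var))
    B <- n * var(colMeans(M))
    sqrt(((n - 1) / n * W + B / n) / W)
  }
  set.seed(87)
  for (k in 1:5) {
    M <- matrix(rnorm(400 * 4, sd = runif(1, 0.5, 2)), 400, 4)
    arr <- array(M, dim = c(400, 4, 1))
    expect_equal(gelman_rubin(arr)[1], reference(M), tolerance = 1e-10)
  }
  copies <- array(rep(rnorm(800), 3), dim = c(800, 1, 1))[, rep(1, 3), ,
                                                          drop = FALSE]
  expect_equal(gelman_rubin(copies), 1, tolerance = 1e-2)
  apart <- array(rnorm(2000), dim = c(1000, 2, 1))
  apart[, 2, ] <- apart[, 2, ] + 10
  expect_gt(gelman_rubin(apart), 1.1)
  expect_error(gelman_rubin(array(1, dim = c(10, 1, 1))), "chains")
})

test_that("importance weights, ESS and perplexity obey their identities", {
  # proposal identical to the target: all weights equal
  mix <- t_mixture(1, matrix(0, 1, 1), list(matrix(1, 1, 1)), nu = 1e7)
  lp_t <- function(X) dtmix_log(mix, X)
  ws <- importance_iteration(lp_t, mix, n = 1000, gamma = 1, seed = 88)
  expect_equal(ws$weights, rep(1 / 1000, 1000), tolerance = 1e-12)
  expect_equal(ws$ess, 1000)
  expect_equal(ws$perplexity, 1)
  # one-hot weights collapse the ESS to 1
  onehot <- c(1, rep(0, 99))
  expect_equal(1 / sum(onehot^2), 1)
  ws2 <- ws
  ws2$weights <- onehot
  expect_equal(1 / sum(ws2$weights^2), 1)
})

test_that("ESS matches the closed form for a Gaussian pair", {
  # target N(0,1), proposal N(0,2): ESS/N -> 1 / integral f^2/g
  mix <- t_mixture(1, matrix(0, 1, 1), list(matrix(2, 1, 1)), nu = 1e7)
  lp <- function(X) {
    X <- if (is.matrix(X)) X else matrix(X, 1)
    dnorm(X[, 1], log = TRUE)
  }
  f2g <- integrate(function(x) dnorm(x)^2 / dnorm(x, 0, sqrt(2)),
                   -12, 12)$value
  ws <- importance_iteration(lp, mix, n = 200000, gamma = 1, seed = 89)
  expect_equal(ws$ess / 200000, 1 / f2g, tolerance = 0.05)
})

test_that("tempering at gamma = 1 leaves the target untouched", {
  mix <- t_mixture(1, matrix(0, 1, 1), list(matrix(4, 1, 1)), nu = 5)
  lp <- function(X) {
    X <- if (is.matrix(X)) X else matrix(X, 1)
    dnorm(X[, 1], log = TRUE)
  }
  set.seed(90)
  w1 <- importance_iteration(lp, mix, n = 500, gamma = 1, seed = 91)
  lw_direct <- lp(w1$draws) - dtmix_log(mix, w1$draws)
  expect_equal(w1$log_weights, lw_direct)
})

test_that("the annealing schedule follows max(64 / 2^(i-1), 1)", {
  expect_equal(annealing_gamma(1), 64)
  expect_equal(annealing_gamma(2), 32)
  expect_equal(annealing_gamma(7), 1)
  expect_equal(annealing_gamma(12), 1)
  expect_equal(annealing_gamma(1:12),
               pmax(64 / 2^(0:11), 1))
})

test_that("mixture updates are normalized and track the target location", {
  set.seed(92)
  X <- matrix(rnorm(5000, 3, 1.2), ncol = 1)
  mix <- t_mixture(1, matrix(0, 1, 1), list(matrix(9, 1, 1)), nu = 5)
  lw <- dnorm(X[, 1], 3, 1.2, log = TRUE) - dtmix_log(mix, X)
  w <- exp(lw - max(lw)); w <- w / sum(w)
  samp <- structure(list(draws = X, weights = w, ess = 1 / sum(w^2)),
                    class = "weighted_sample")
  up <- update_tmixture(mix, samp)
  expect_equal(sum(up$weights), 1)
  se <- 1.2 / sqrt(samp$ess)
  expect_lt(abs(up$mu[1, 1] - 3), 3 * se + 0.15)
})

test_that("iterated importance sampling recovers a 2-D Gaussian", {
  S <- matrix(c(1, 0.5, 0.5, 1), 2)
  Si <- solve(S)
  lp <- function(X) {
    X <- if (is.matrix(X)) X else matrix(X, 1)
    -0.5 * rowSums((X %*% Si) * X)
  }
  res <- iterated_importance_sampler(lp, c(-8, -8), c(8, 8),
                                     centers = rbind(c(0.5, 0.5),
                                                     c(-0.5, 0),
                                                     c(0, -0.5),
                                                     c(0.3, 0.3)),
                                     n_per_iter = 4000, seed = 93)
  expect_equal(res$gamma_trace[1], 64)
  expect_true(all(diff(res$gamma_trace) <= 0))
  m <- colMeans(res$draws)
  V <- cov(res$draws)
  expect_lt(max(abs(m)), 0.05 * 3) # means within 5% of the prior scale
  expect_lt(abs(V[1, 1] - 1), 0.1)
  expect_lt(abs(V[1, 2] - 0.5), 0.1)
  # perplexity improves over the annealed adaptation
  expect_gt(tail(res$perplexity_trace, 1), res$perplexity_trace[1])
})

test_that("proposal adaptation raises perplexity on a bimodal target", {
  lp <- function(X) {
    X <- if (is.matrix(X)) X else matrix(X, 1)
    log(0.5 * dnorm(X[, 1], -2, 0.5) + 0.5 * dnorm(X[, 1], 2, 0.5))
  }
  wins <- 0L
  for (s in 1:10) {
    res <- iterated_importance_sampler(lp, -8, 8,
                                       centers = matrix(c(-2, 2, 0, 1),
                                                        4, 1),
                                       n_per_iter = 1500, max_iter = 10,
                                       seed = 930 + s)
    n <- length(res$perplexity_trace)
    if (res$perplexity_trace[n] > res$perplexity_trace[1]) wins <- wins + 1L
  }
  expect_gte(wins, 9L)
})
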