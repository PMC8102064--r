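test_that("Huber loss matches both branch conventions", {
  expect_equal(huber_loss(1, 1), 0)
  expect_equal(huber_loss(0, 1), 0.5)
  expect_equal(huber_loss(0, 0.4), 0.08)
  expect_equal(huber_loss(0, 3), 2.5)
  expect_equal(huber_loss(0, 3, literal = TRUE), 3.5)
  expect_equal(huber_loss(c(0, 0), c(0.5, 2)), c(0.125, 1.5))
})

test_that("KL divergence is zero at identity, positive elsewhere", {
  p <- matrix(c(0.2, 0.3, 0.4, 0.1), 1)
  expect_equal(kl_divergence(p, p), 0)
  pred <- matrix(rep(0.25, 4), 1)
  lab <- matrix(c(0.5, 0.5, 0, 0), 1)
  hand <- 2 * (0.25 * log(0.25 / 0.5)) + 2 * (0.25 * log(0.25 / 1e-10))
  expect_equal(kl_divergence(pred, lab), hand)
  set.seed(61)
  for (i in 1:200) {
    a <- matrix(rexp(8), 1); a <- a / sum(a)
    b <- matrix(rexp(8), 1); b <- b / sum(b)
    expect_gte(kl_divergence(a, b), 0)
  }
  expect_error(kl_divergence(matrix(1, 1, 2), matrix(1, 1, 3)), "shape")
})

toy_regression_set <- function(n = 10000, seed = 62) {
  set.seed(seed)
  x <- matrix(runif(n, -2, 2), ncol = 1)
  structure(list(features = cbind(x, runif(n), runif(n)),
                 labels = sin(2 * x[, 1]) + 0.5 * x[, 1],
                 theta_id = NULL, model = "toy"),
            class = "mlp_training_set")
}

test_that("training shrinks the loss by an order of magnitude on a toy task", {
  ts <- toy_regression_set()
  lan <- train_network(ts, mlp_config(hidden = c(32, 32), epochs = 40,
                                      batch_size = 256), seed = 63)
  expect_lt(tail(lan$history$train, 1), lan$history$train[1] / 10)
  expect_equal(lan$kind, "pointwise")
})

test_that("early stopping fires after patience + 1 flat epochs", {
  # constant labels: the network fits them almost immediately, after which
  # validation loss cannot improve by the relative threshold
  set.seed(64)
  ts <- structure(list(features = cbind(matrix(runif(600), ncol = 3)),
                       labels = rep(2, 200), theta_id = NULL,
                       model = "toy"),
                  class = "mlp_training_set")
  lan <- train_network(ts, mlp_config(hidden = c(4), epochs = 100,
                                      batch_size = 50, patience = 3),
                       seed = 65)
  stale_run <- lan$epochs_run - which.min(lan$history$validation)
  expect_lte(lan$epochs_run, 100)
  expect_gte(stale_run, 0)
  # the run must end no later than patience + 1 epochs after the last
  # improving epoch
  imp <- c(TRUE, diff(cummin(lan$history$validation)) < 0)
  last_improve <- max(which(imp))
  expect_lte(lan$epochs_run, last_improve + 3 + 1)
})

test_that("training aborts with a diagnostic on a non-finite loss", {
  ts <- toy_regression_set(500)
  ts$labels[17] <- NaN
  expect_error(
    train_network(ts, mlp_config(hidden = c(8), epochs = 5,
                                 batch_size = 50), seed = 66),
    "diverged")
})

test_that("pointwise evaluation is vectorized consistently", {
  lan <- fx_ddm_mlp()
  th <- c(1, 1.4, 0.5, 0.3)
  rt <- c(0.5, 0.9, 1.4, 2.2)
  cc <- c(1, -1, 1, -1)
  batch <- lan_logpdf(lan, th, rt, cc)
  loop <- vapply(1:4, function(i) lan_logpdf(lan, th, rt[i], cc[i]), 0)
  expect_equal(batch, loop)
  thm <- rbind(c(1, 1.4, 0.5, 0.3), c(0, 1, 0.4, 0.2))
  batch2 <- lan_logpdf(lan, thm, 0.8, 1)
  expect_equal(batch2[1], lan_logpdf(lan, thm[1, ], 0.8, 1))
  expect_equal(batch2[2], lan_logpdf(lan, thm[2, ], 0.8, 1))
})

test_that("the pointwise network reproduces analytic log-likelihoods", {
  lan <- fx_ddm_mlp()
  spec <- ssm_model("ddm")
  set.seed(67)
  newth <- sample_parameter_space(spec, 20, seed = 68, pilot_trials = 300,
                                  dt = 0.002)
  maes <- vapply(seq_len(nrow(newth)), function(i) {
    th <- newth[i, ]
    d <- absorbed(simulate_trials(spec, th,
                                  sim_config(n_trials = 400,
                                             seed = 600 + i)))
    la <- ddm_logpdf(th, d$rt, d$choice)
    keep <- la > log(1e-5)
    mean(abs(lan_logpdf(lan, th, d$rt[keep], d$choice[keep]) - la[keep]))
  }, 0)
  expect_lt(mean(maes), 0.1)
})

test_that("the pointwise network drives negative datapoints to the floor", {
  lan <- fx_ddm_mlp()
  preds <- lan_logpdf(lan, c(1, 1.4, 0.5, 0.3), c(-0.8, -0.4, -0.1),
                      c(1, -1, 1))
  expect_true(all(abs(preds - log(1e-29)) < 2))
})

test_that("learned likelihood manifolds are smooth and finite", {
  lan <- fx_ddm_mlp()
  vs <- seq(-2.5, 2.5, length.out = 120)
  for (rt in c(0.6, 1.2)) {
    curve <- vapply(vs, function(v)
      lan_logpdf(lan, c(v, 1.4, 0.5, 0.3), rt, 1), 0)
    expect_true(all(is.finite(curve)))
    expect_lt(max(abs(diff(curve))), 0.6) # no jumps on a fine drift sweep
  }
})

test_that("trained networks round-trip through JSON bitwise", {
  lan <- fx_ddm_cnn()
  path <- tempfile(fileext = ".json")
  save_lan(lan, path)
  lan2 <- load_lan(path)
  th <- c(1, 1.4, 0.5, 0.3)
  expect_identical(lan_histogram(lan, th), lan_histogram(lan2, th))
  mlp <- fx_ddm_mlp()
  path2 <- tempfile(fileext = ".json")
  save_lan(mlp, path2)
  mlp2 <- load_lan(path2)
  expect_identical(lan_logpdf(mlp, th, 0.9, 1), lan_logpdf(mlp2, th, 0.9, 1))
  unlink(c(path, path2))
})

test_that("histogram-network output is a strictly positive distribution", {
  lan <- fx_ddm_cnn()
  set.seed(69)
  pri <- uniform_prior(ssm_model("ddm"))
  ths <- pri$sample(100)
  P <- lan_histogram(lan, ths)
  expect_equal(rowSums(P), rep(1, 100), tolerance = 1e-6)
  expect_true(all(P > 0))
  h1 <- lan_histogram(lan, ths[1, ])
  expect_s3_class(h1, "likelihood_histogram")
  expect_equal(sum(h1), 1, tolerance = 1e-6)
})

test_that("histogram dataset log-likelihood is a binned sum", {
  lan <- fx_ddm_cnn()
  th <- c(0.8, 1.3, 0.5, 0.4)
  one <- trial_data(rt = 0.9, choice = 1L, spec = ssm_model("ddm"))
  h <- lan_histogram(lan, th)
  bin <- floor(0.9 / (20 / 128)) + 1
  expect_equal(dataset_loglik_histogram(lan, th, one),
               unname(log(unclass(h)["1", bin])))
  d <- simulate_trials(ssm_model("ddm"), th, sim_config(n_trials = 64,
                                                        seed = 70))
  per_trial <- vapply(seq_len(nrow(d)), function(i)
    dataset_loglik_histogram(lan, th, d[i, , drop = FALSE]), 0)
  expect_equal(dataset_loglik_histogram(lan, th, d), sum(per_trial),
               tolerance = 1e-8)
})

test_that("histogram network tracks empirical histograms on held-out theta", {
  lan <- fx_ddm_cnn()
  spec <- ssm_model("ddm")
  set.seed(71)
  ths <- sample_parameter_space(spec, 6, seed = 72, pilot_trials = 300,
                                dt = 0.002)
  kls <- vapply(seq_len(nrow(ths)), function(i) {
    d <- simulate_trials(spec, ths[i, ], sim_config(n_trials = 1e5,
                                                    seed = 700 + i,
                                                    dt = 0.002))
    emp <- build_histogram(d, n_bins = 128, t_max = 20,
                           choices = c(-1L, 1L))
    kl_divergence(unclass(lan_histogram(lan, ths[i, ])), unclass(emp))
  }, 0)
  expect_lt(median(kls), 0.15)
})

test_that("dataset log-likelihood correlates with the analytic one", {
  lan <- fx_ddm_cnn()
  spec <- ssm_model("ddm")
  d <- fx_ddm_dataset()$data
  set.seed(73)
  ths <- uniform_prior(spec)$sample(50)
  ll_net <- dataset_loglik_histogram(lan, ths, d)
  ll_an <- vapply(seq_len(50), function(i)
    sum(ddm_logpdf(ths[i, ], d$rt, d$choice)), 0)
  expect_gt(cor(ll_net, ll_an, method = "spearman"), 0.7)
  top <- rank(-ll_an) <= 25 # where the posterior mass lives
  expect_gt(cor(ll_net[top], ll_an[top], method = "spearman"), 0.8)
})

test_that("network likelihoods track the KDE cloud at its noise scale", {
  # at a test parameter vector the trained surface should deviate from the
  # pointwise mean of 20 independent 1e4-simulation KDE curves by no more
  # than a small multiple of the KDE sampling spread over the bulk grid
  lan <- fx_ddm_mlp()
  spec <- ssm_model("ddm")
  th <- c(0.6, 1.3, 0.5, 0.35)
  tt <- seq(0.45, 3, length.out = 40)
  env <- vapply(1:20, function(k) {
    d <- simulate_trials(spec, th, sim_config(n_trials = 1e4,
                                              seed = 800 + k))
    kde_logpdf(build_kde(d, choices = c(-1L, 1L)), tt, rep(1, length(tt)))
  }, numeric(length(tt)))
  dev <- abs(lan_logpdf(lan, th, tt, rep(1, length(tt))) - rowMeans(env))
  expect_lt(median(dev), 0.25)
  expect_lt(unname(quantile(dev, 0.95)), 0.75)
})
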