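test_that("the log-posterior composes likelihood and prior", {
  fx <- fx_ddm_dataset()
  be <- likelihood_backend(fx$spec, "analytic")
  pri <- fx$prior
  # outside the prior box
  expect_equal(log_posterior(be, pri, fx$data, c(5, 1, 0.5, 0.3)), -Inf)
  # one trial: likelihood plus the flat-prior constant
  one <- fx$data[1, , drop = FALSE]
  lp <- log_posterior(be, pri, one, c(1, 1.4, 0.5, 0.3))
  expect_equal(lp,
               ddm_logpdf(c(1, 1.4, 0.5, 0.3), one$rt, one$choice) +
                 pri$log_density(c(1, 1.4, 0.5, 0.3)))
  # matrix contract
  thm <- rbind(c(1, 1.4, 0.5, 0.3), c(9, 1, 0.5, 0.3), c(0, 1, 0.4, 0.2))
  lps <- log_posterior(be, pri, fx$data, thm)
  expect_length(lps, 3)
  expect_true(is.infinite(lps[2]))
})

test_that("network and analytic dataset log-likelihoods agree closely", {
  fx <- fx_ddm_dataset()
  lan <- fx_ddm_mlp()
  be_mlp <- likelihood_backend(fx$spec, "mlp", lan = lan)
  be_an <- likelihood_backend(fx$spec, "analytic")
  pri <- fx$prior
  for (th in list(c(0.8, 1.4, 0.45, 0.4), c(0.5, 1.2, 0.5, 0.3))) {
    la <- log_posterior(be_an, pri, fx$data, th)
    lm <- log_posterior(be_mlp, pri, fx$data, th)
    expect_lt(abs(lm - la) / abs(la), 0.03)
  }
})

test_that("backend pairing mismatches are rejected", {
  expect_error(likelihood_backend(ssm_model("ou"), "analytic"), "analytic")
  expect_error(likelihood_backend(ssm_model("ddm"), "mlp"), "trained_lan")
  expect_error(likelihood_backend(ssm_model("ou"), "mlp",
                                  lan = fx_ddm_mlp()), "trained for")
  expect_error(likelihood_backend(ssm_model("ddm"), "cnn",
                                  lan = fx_ddm_mlp()), "kind")
})

test_that("the minority-choice filter uses the inclusive 5% rule", {
  mk <- function(n_min, n = 1024) {
    trial_data(rt = runif(n, 0.4, 1.5),
               choice = c(rep(-1L, n_min), rep(1L, n - n_min)),
               spec = ssm_model("ddm"))
  }
  expect_false(filter_min_choice_fraction(mk(40)))   # 3.9%
  expect_true(filter_min_choice_fraction(mk(52)))    # 5.08%
  # exactly 5% kept (boundary inclusive)
  expect_true(filter_min_choice_fraction(mk(50, n = 1000)))
  expect_equal(attr(filter_min_choice_fraction(mk(50, n = 1000)),
                    "minority_fraction"), 0.05)
})

test_that("differential evolution finds the MAP of a large dataset", {
  spec <- ssm_model("ddm")
  th0 <- c(1, 1.5, 0.5, 0.3)
  d <- simulate_trials(spec, th0, sim_config(n_trials = 8192, seed = 95))
  be <- likelihood_backend(spec, "analytic")
  maps <- fit_map_de(be, uniform_prior(spec), d, restarts = 5,
                     generations = 80, seed = 96)
  expect_equal(nrow(maps), 5)
  b <- range_bounds(spec)
  expect_true(all(sweep(maps, 2, b$lower, `>=`)))
  expect_true(all(sweep(maps, 2, b$upper, `<=`)))
  best <- maps[which.max(attr(maps, "value")), ]
  expect_true(all(abs(best - th0) < 0.1))
})

test_that("inference refuses heavily one-sided datasets with a reason", {
  spec <- ssm_model("ddm")
  skew <- trial_data(rt = runif(500, 0.4, 1),
                     choice = c(rep(-1L, 10), rep(1L, 490)), spec = spec)
  be <- likelihood_backend(spec, "analytic")
  expect_error(run_inference(be, uniform_prior(spec), skew), "rejected")
})

test_that("posterior inference recovers parameters with the analytic backend", {
  fx <- fx_ddm_dataset()
  be <- likelihood_backend(fx$spec, "analytic")
  fit <- run_inference(be, fx$prior, fx$data, sampler = "demcmc",
                       seed = 97, max_gens = 600)
  expect_true(all(abs(fit$mean - fx$theta) < 3.5 * sqrt(fit$var) + 0.05))
  expect_true(all(fit$draws >= matrix(fx$prior$lower, nrow(fit$draws), 4,
                                      byrow = TRUE)))
})

test_that("recovery reports aggregate means, variances and R-squared", {
  # degenerate identity check: posterior means equal to truths give R2 = 1
  expect_equal(recovery_r_squared(1:10, 1:10), 1)
  expect_equal(recovery_r_squared(1:10, 2 * (1:10) + 3), 1) # affine map
  set.seed(99)
  expect_lt(recovery_r_squared(1:10, rnorm(10)), 0.6)
})

test_that("posterior predictive reproduces the generating data pattern", {
  spec <- ssm_model("ddm")
  th <- c(0.8, 1.3, 0.45, 0.35)
  obs <- simulate_trials(spec, th, sim_config(n_trials = 2000, seed = 100))
  draws <- matrix(th, 30, 4, byrow = TRUE) # point mass at the truth
  pp <- posterior_predictive(spec, draws, n_sim = 512, data = obs,
                             seed = 101)
  expect_lt(abs(pp$choice_fractions[["1"]] -
                  pp$observed$choice_fractions[2]), 0.03)
  for (h in pp$rt_histograms) {
    expect_true(all(h$density >= 0))
  }
  # defective per-choice densities integrate to the choice fractions
  mass <- vapply(pp$rt_histograms, function(h)
    sum(h$density * diff(h$breaks)), 0)
  expect_equal(sum(mass), 1, tolerance = 0.02)
})

test_that("bound trajectories are emitted and tight for collapsing bounds", {
  spec <- ssm_model("ddm_lc")
  th <- c(v = 0.6, w = 0.5, tau = 0.3, a = 1.2, angle = 0.6)
  obs <- simulate_trials(spec, th, sim_config(n_trials = 500, seed = 102))
  jitter <- matrix(rnorm(20 * 5, 0, 0.01), 20, 5)
  draws <- matrix(th, 20, 5, byrow = TRUE) + jitter
  pp <- posterior_predictive(spec, draws, n_sim = 128, data = obs,
                             seed = 103)
  expect_false(is.null(pp$bound_trajectories))
  truth <- pmax(boundary_linear_collapse(pp$bound_times, th[["a"]],
                                         th[["angle"]]), 0)
  dev <- apply(abs(sweep(pp$bound_trajectories, 2, truth)), 1, max)
  expect_lt(max(dev) / th[["a"]], 0.1)
})

test_that("linear collapse at angle zero is the fixed-bound model", {
  cfg <- sim_config(n_trials = 3000, seed = 104)
  d1 <- simulate_trials(ssm_model("ddm"), c(0.7, 1.2, 0.45, 0.3), cfg)
  d2 <- simulate_trials(ssm_model("ddm_lc"),
                        c(v = 0.7, w = 0.45, tau = 0.3, a = 1.2, angle = 0),
                        cfg)
  expect_identical(d1$rt, d2$rt)
  expect_identical(d1$choice, d2$choice)
})
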