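test_that("unbiased zero-drift diffusion splits choices evenly", {
  d <- simulate_trials(ssm_model("ddm"), c(0, 1, 0.5, 0.3),
                       sim_config(n_trials = 20000, seed = 1))
  up <- mean(absorbed(d)$choice == 1)
  se <- sqrt(0.25 / 20000)
  expect_lt(abs(up - 0.5), 3 * se)
})

test_that("simulated choice fractions match the analytic boundary mass", {
  theta <- c(1, 1.5, 0.5, 0.3)
  n <- 40000
  d <- simulate_trials(ssm_model("ddm"), theta, sim_config(n_trials = n,
                                                           seed = 2))
  mass <- ddm_choice_mass(theta)
  se <- sqrt(mass * (1 - mass) / n)
  expect_lt(abs(mean(absorbed(d)$choice == 1) - mass), 3.5 * se)
})

test_that("returned trials respect the time and choice-set contracts", {
  for (nm in c("ddm", "full_ddm", "ou", "levy", "ddm_weibull", "ddm_lc")) {
    spec <- ssm_model(nm)
    b <- range_bounds(spec)
    th <- (b$lower + b$upper) / 2
    cfg <- sim_config(n_trials = 300, seed = 3, t_max = 10)
    d <- simulate_trials(spec, th, cfg, strict = FALSE)
    ab <- absorbed(d)
    tau <- th[match(c("tau"), spec$param_names)]
    expect_true(all(ab$rt >= tau - 1e-12))
    expect_true(all(ab$rt <= cfg$t_max + tau + 1e-12))
    expect_true(all(ab$choice %in% spec$choices))
  }
  r <- simulate_trials(ssm_model("race_3"),
                       c(1, 1, 1, 1.5, 0.3, 0.3, 0.3, 0.2),
                       sim_config(n_trials = 300, seed = 4))
  expect_true(all(absorbed(r)$choice %in% 0:2))
})

test_that("Ornstein-Uhlenbeck with zero feedback reproduces the DDM pathwise", {
  cfg <- sim_config(n_trials = 400, seed = 5)
  d1 <- simulate_trials(ssm_model("ddm"), c(0.7, 1.2, 0.4, 0.25), cfg)
  d2 <- simulate_trials(ssm_model("ou"), c(0.7, 1.2, 0.4, 0.25, 0), cfg)
  expect_identical(d1$rt, d2$rt)
  expect_identical(d1$choice, d2$choice)
})

test_that("mirrored noise with mirrored parameters swaps choices exactly", {
  cfg <- sim_config(n_trials = 400, seed = 6)
  d1 <- simulate_trials(ssm_model("ddm"), c(0.8, 1.3, 0.35, 0.3), cfg)
  d2 <- simulate_trials(ssm_model("ddm"), c(-0.8, 1.3, 0.65, 0.3), cfg,
                        mirror_noise = TRUE)
  expect_identical(d1$rt, d2$rt)
  expect_identical(d1$choice, -d2$choice)
})

test_that("identical seeds reproduce identical data", {
  cfg <- sim_config(n_trials = 200, seed = 7)
  d1 <- simulate_trials(ssm_model("levy"), c(1, 1, 0.5, 0.3, 1.6), cfg)
  d2 <- simulate_trials(ssm_model("levy"), c(1, 1, 0.5, 0.3, 1.6), cfg)
  expect_identical(d1, d2)
})

test_that("alpha-stable draws follow the documented law", {
  x <- sample_alpha_stable(2, 1e6, seed = 8)
  # L(2,0,1,0) = N(0, 2); sampling sd of the variance estimator is
  # sqrt(2 sigma^4 / (n - 1))
  expect_lt(abs(var(x) - 2), 3 * sqrt(2 * 4 / (1e6 - 1)))
  expect_lt(abs(median(sample_alpha_stable(1.5, 1e6, seed = 9))), 0.01)
  set.seed(10)
  ks <- ks.test(sample_alpha_stable(2, 1e5), sqrt(2) * rnorm(1e5))
  expect_gt(ks$p.value, 0.01)
  expect_error(sample_alpha_stable(0.9, 10), "alpha")
  expect_error(sample_alpha_stable(2.1, 10), "alpha")
})

test_that("Levy flight at alpha = 2 matches the rescaled diffusion law", {
  # increments N(0, 2 dt) on bounds +/- a equal unit-noise diffusion with
  # drift v/sqrt(2) on bounds +/- a/sqrt(2)
  n <- 50000
  dl <- simulate_trials(ssm_model("levy"), c(1, 1.2, 0.5, 0.3, 2),
                        sim_config(n_trials = n, seed = 11))
  dd <- simulate_trials(ssm_model("ddm"),
                        c(1 / sqrt(2), 1.2 / sqrt(2), 0.5, 0.3),
                        sim_config(n_trials = n, seed = 12))
  for (cc in c(-1, 1)) {
    ks <- suppressWarnings(
      ks.test(absorbed(dl)$rt[absorbed(dl)$choice == cc],
              absorbed(dd)$rt[absorbed(dd)$choice == cc]))
    expect_gt(ks$p.value, 0.01)
  }
})

test_that("boundary functions evaluate their closed forms", {
  expect_equal(boundary_weibull(0, 2.3, 1.7, 0.9), 2.3)
  expect_equal(boundary_weibull(1, 1, 1, 1), exp(-1))
  expect_equal(boundary_weibull(1, 2, 2, 2), 2 * exp(-0.5))
  expect_equal(boundary_weibull(1, 2, 2, 2, alternative = TRUE),
               2 * exp(-(1 / 2)^2))
  expect_error(boundary_weibull(-1, 1, 1, 1), "non-negative")
  tt <- seq(0, 5, by = 0.1)
  expect_true(all(diff(boundary_weibull(tt, 1.5, 2, 3)) <= 0))
  expect_equal(boundary_linear_collapse(c(0, 1, 7), 1.2, 0), rep(1.2, 3))
  expect_equal(boundary_linear_collapse(0.5, 1, pi / 4), 0.5)
  expect_error(boundary_linear_collapse(1, 1, pi / 2), "angle")
})

test_that("a fully collapsed linear bound forces absorption at the meet", {
  # bounds meet at t* = a / tan(angle) = 1; all decision times <= t*
  th <- c(v = 0, w = 0.5, tau = 0.2, a = 1, angle = pi / 4)
  d <- simulate_trials(ssm_model("ddm_lc"), th,
                       sim_config(n_trials = 500, seed = 13))
  expect_true(all(d$rt >= 0)) # nothing censored
  expect_true(all(d$rt <= 1 + 0.2 + 0.001 + 1e-9))
})

test_that("symmetric race accumulators win equally often", {
  n <- 20000
  d <- simulate_trials(ssm_model("race_2"), c(1, 1, 1.5, 0.3, 0.3, 0.2),
                       sim_config(n_trials = n, seed = 14))
  p0 <- mean(absorbed(d)$choice == 0)
  expect_lt(abs(p0 - 0.5), 3 * sqrt(0.25 / n))
})

test_that("defective screening flags the documented degeneracies", {
  one_sided <- trial_data(rt = runif(1000, 0.4, 1), choice = rep(1L, 1000),
                          spec = ssm_model("ddm"))
  v <- screen_defective(one_sided)
  expect_true(v$defective)
  expect_true("choice-degeneracy" %in% v$reasons)

  slow <- trial_data(rt = runif(1000, 11, 13),
                     choice = sample(c(-1L, 1L), 1000, TRUE))
  expect_true("slow" %in% screen_defective(slow)$reasons)

  spike <- trial_data(rt = c(rep(0.5004, 600), runif(400, 0.3, 2)),
                      choice = sample(c(-1L, 1L), 1000, TRUE))
  expect_true("rt-concentration" %in% screen_defective(spike)$reasons)

  set.seed(15)
  healthy <- trial_data(rt = runif(2000, 0.3, 2) * 0.8 + 0.25,
                        choice = sample(c(-1L, 1L), 2000, TRUE))
  expect_false(screen_defective(healthy)$defective)
  expect_error(screen_defective(healthy[0, ]), "empty")
})

test_that("per-choice response-time mass is conserved", {
  d <- simulate_trials(ssm_model("ddm"), c(0.5, 1, 0.5, 0.3),
                       sim_config(n_trials = 20000, seed = 16))
  ab <- absorbed(d)
  fr <- table(factor(ab$choice, levels = c(-1, 1))) / nrow(ab)
  expect_equal(sum(fr), 1)
  h <- build_histogram(d, n_bins = 256, t_max = 20, choices = c(-1L, 1L))
  expect_equal(unname(rowSums(unclass(h))), unname(c(fr)),
               tolerance = 1e-12)
})

test_that("trial data round-trips through delimited text", {
  d <- simulate_trials(ssm_model("ddm"), c(1, 1, 0.5, 0.3),
                       sim_config(n_trials = 50, seed = 17))
  d$subject <- rep(1:2, 25)
  path <- tempfile(fileext = ".csv")
  write_trial_data(d, path)
  d2 <- read_trial_data(path)
  expect_equal(d2$rt, d$rt)
  expect_equal(d2$choice, d$choice)
  expect_equal(d2$subject, d$subject)
  unlink(path)
})

test_that("invalid inputs are rejected", {
  expect_error(simulate_trials(ssm_model("ddm"), c(9, 1, 0.5, 0.3),
                               sim_config(n_trials = 10)), "outside")
  expect_error(simulate_trials(ssm_model("ddm"), c(NaN, 1, 0.5, 0.3),
                               sim_config(n_trials = 10)), "finite")
  expect_error(sim_config(dt = 0), "dt")
})
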