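# Shared heavyweight fixtures, built lazily and cached for the whole run.
# Training a likelihood network takes minutes; several test files probe the
# same trained networks, so they are constructed once here. All sizes are
# desk-scale analogues of the full study designs (see the methods vignette
# for the rationale behind each choice).

.fx <- new.env(parent = emptyenv())

fx_get <- function(name, builder) {
  if (!exists(name, envir = .fx)) assign(name, builder(), envir = .fx)
  get(name, envir = .fx)
}

# pointwise DDM network trained on analytic labels: 2000 parameter vectors
# x 50 mixture datapoints = 1e5 rows
fx_ddm_mlp <- function() fx_get("ddm_mlp", function() {
  spec <- ssm_model("ddm")
  theta <- sample_parameter_space(spec, 2000, seed = 101,
                                  pilot_trials = 500, dt = 0.002)
  ts <- make_mlp_training_set(
    spec, training_budget(n_param_vectors = 2000, points_per_vector = 50,
                          seed = 102),
    labels = "analytic", theta = theta)
  train_network(ts, mlp_config(epochs = 120, batch_size = 512,
                               patience = 8), seed = 103)
})

# histogram DDM network at smoke scale: 128 bins, 800 parameter vectors x
# 5000 simulations each (coarser integration step to keep the corpus quick)
fx_ddm_cnn <- function() fx_get("ddm_cnn", function() {
  spec <- ssm_model("ddm")
  theta <- sample_parameter_space(spec, 800, seed = 201,
                                  pilot_trials = 500, dt = 0.002)
  ts <- make_cnn_training_set(
    spec, training_budget(n_param_vectors = 800, sims_per_vector = 5000,
                          seed = 202),
    n_bins = 128, t_max = 20, theta = theta, dt = 0.002)
  train_network(ts, cnn_config(epochs = 100, batch_size = 32), seed = 203)
})

# paired recovery study on the simple DDM: the same simulated datasets are
# fit with the analytic backend (the reference) and the pointwise network
fx_ddm_recovery <- function() fx_get("ddm_recovery", function() {
  spec <- ssm_model("ddm")
  prior <- uniform_prior(spec)
  n_ds <- 8L
  set.seed(301)
  d <- length(spec$param_names)
  truths <- matrix(NA_real_, n_ds, d,
                   dimnames = list(NULL, spec$param_names))
  got <- 0L
  while (got < n_ds) {
    th <- drop(prior$sample(1))
    dat <- simulate_trials(spec, th, sim_config(n_trials = 1024),
                           strict = FALSE)
    if (screen_defective(dat)$defective) next
    if (!filter_min_choice_fraction(dat)) next
    got <- got + 1L
    truths[got, ] <- th
  }
  an <- run_recovery_study(spec, likelihood_backend(spec, "analytic"),
                           n_datasets = n_ds, n_trials = 1024L, seed = 302,
                           truths = truths, min_gens = 120L,
                           check_every = 40L, max_gens = 350L)
  ml <- run_recovery_study(spec,
                           likelihood_backend(spec, "mlp",
                                              lan = fx_ddm_mlp()),
                           n_datasets = n_ds, n_trials = 1024L, seed = 302,
                           truths = truths, n_chains = 12L,
                           min_gens = 120L, check_every = 40L,
                           max_gens = 350L)
  list(analytic = an, mlp = ml, truths = truths)
})

# one fixed DDM dataset reused by the sampler cross-validation checks
fx_ddm_dataset <- function() fx_get("ddm_dataset", function() {
  spec <- ssm_model("ddm")
  theta <- c(v = 0.8, a = 1.4, w = 0.45, tau = 0.4)
  data <- simulate_trials(spec, theta, sim_config(n_trials = 1024,
                                                  seed = 401))
  list(spec = spec, theta = theta, data = data,
       prior = uniform_prior(spec))
})

# pointwise linear-collapse network trained on KDE labels: 600 parameter
# vectors x 3000 simulations, 100 mixture datapoints each
fx_lc_mlp <- function() fx_get("lc_mlp", function() {
  spec <- ssm_model("ddm_lc")
  theta <- sample_parameter_space(spec, 600, seed = 501,
                                  pilot_trials = 500, dt = 0.002)
  ts <- make_mlp_training_set(
    spec, training_budget(n_param_vectors = 600, sims_per_vector = 3000,
                          points_per_vector = 100, seed = 502),
    labels = "kde", theta = theta)
  train_network(ts, mlp_config(epochs = 40, batch_size = 512,
                               patience = 6), seed = 503)
})

# analytic-backend recovery at two dataset sizes, for the variance
# shrinkage property
fx_ddm_shrinkage <- function() fx_get("ddm_shrinkage", function() {
  spec <- ssm_model("ddm")
  rec <- fx_ddm_recovery()
  truths <- rec$truths[1:6, , drop = FALSE]
  be <- likelihood_backend(spec, "analytic")
  n4096 <- run_recovery_study(spec, be, n_datasets = 6L, n_trials = 4096L,
                              seed = 312, truths = truths,
                              min_gens = 120L, check_every = 40L,
                              max_gens = 350L)
  # the 1024-trial reference reuses the paired recovery (same truths)
  n1024 <- rec$analytic
  n1024$posterior_var <- n1024$posterior_var[1:6, , drop = FALSE]
  list(n1024 = n1024, n4096 = n4096)
})
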