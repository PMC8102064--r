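#' Uniform prior over the trained parameter region
#'
#' The uninformative default: independent uniforms over each parameter's
#' trained range.
#'
#' @param spec an [ssm_model()].
#' @return a `ssm_prior` with `lower`, `upper`, `log_density(theta)` and
#'   `sample(n)`.
#' @export
uniform_prior <- function(spec) {
  b <- range_bounds(spec)
  const <- -sum(log(b$upper - b$lower))
  structure(list(
    lower = b$lower, upper = b$upper,
    log_density = function(theta) {
      th <- if (is.matrix(theta)) theta else matrix(theta, nrow = 1)
      inside <- apply(sweep(th, 2, b$lower, `>=`) &
                        sweep(th, 2, b$upper, `<=`), 1, all)
      ifelse(inside, const, -Inf)
    },
    sample = function(n) {
      d <- length(b$lower)
      m <- matrix(stats::runif(n * d), n, d)
      sweep(sweep(m, 2, b$upper - b$lower, `*`), 2, b$lower, `+`)
    }), class = "ssm_prior")
}

#' Likelihood backends
#'
#' A backend wraps one way of evaluating the likelihood of a trial-level
#' dataset: the analytic density (simple and full DDM), a trained pointwise
#' network, or a trained histogram network. All backends expose the same
#' dataset log-likelihood contract consumed by [log_posterior()].
#'
#' @param spec an [ssm_model()].
#' @param type `"analytic"`, `"mlp"` or `"cnn"`.
#' @param lan the `trained_lan` (required for network backends).
#' @param config an [analytic_config()] for the analytic types.
#' @return a `likelihood_backend`.
#' @export
likelihood_backend <- function(spec, type = c("analytic", "mlp", "cnn"),
                               lan = NULL, config = analytic_config()) {
  type <- match.arg(type)
  if (type == "analytic" && !spec$name %in% c("ddm", "full_ddm"))
    stop("analytic likelihoods exist only for ddm and full_ddm")
  if (type %in% c("mlp", "cnn")) {
    if (is.null(lan)) stop("network backends need a trained_lan")
    .check_pairing(lan, spec)
    want <- if (type == "mlp") "pointwise" else "histogram"
    if (lan$kind != want) stop("trained_lan kind does not match backend type")
  }
  structure(list(spec = spec, type = type, lan = lan, config = config),
            class = "likelihood_backend")
}

# dataset log-likelihood, vectorized over theta rows
.backend_dataset_loglik <- function(backend, data_or_counts, theta) {
  th <- if (is.matrix(theta)) theta else matrix(theta, nrow = 1)
  switch(backend$type,
    analytic = {
      dat <- data_or_counts
      if (backend$spec$name == "ddm") {
        # one flat series evaluation over all (theta row, trial) pairs
        n <- nrow(dat); m <- nrow(th)
        lp <- .nf_logpdf(rep(th[, 1], each = n), rep(th[, 2], each = n),
                         rep(th[, 3], each = n), rep(th[, 4], each = n),
                         rep(dat$rt, m), rep(dat$choice, m),
                         eps = backend$config$series_tolerance,
                         floor = backend$config$likelihood_floor)
        colSums(matrix(lp, n, m))
      } else {
        vapply(seq_len(nrow(th)), function(i)
          sum(full_ddm_logpdf(th[i, ], dat$rt, dat$choice,
                              backend$config)), 0)
      }
    },
    mlp = {
      lan <- backend$lan
      d <- ncol(th)
      trial_s <- if (is.list(data_or_counts) &&
                       !is.null(data_or_counts$trial_s))
        data_or_counts$trial_s
      else .standardize_trials(lan, data_or_counts, d)
      L <- length(lan$params) / 2
      theta_s <- sweep(sweep(th, 2, lan$norm$mu[seq_len(d)]), 2,
                       lan$norm$sd[seq_len(d)], `/`)
      mlp_dataset_loglik_cpp(lan$params[paste0("W", seq_len(L))],
                             lan$params[paste0("b", seq_len(L))],
                             theta_s, trial_s)
    },
    cnn = dataset_loglik_histogram(backend$lan, th, data_or_counts)
  )
}

# standardize the (rt, choice) trial block with the network's training
# statistics; the theta block is standardized per evaluation
.standardize_trials <- function(lan, dat, d) {
  mu <- lan$norm$mu; sdev <- lan$norm$sd
  cbind((dat$rt - mu[d + 1]) / sdev[d + 1],
        (dat$choice - mu[d + 2]) / sdev[d + 2])
}

#' Log-posterior of a model given trial data
#'
#' `sum_i log lhat(theta | x_i) + log prior(theta)`; `-Inf` outside the
#' prior support. Vectorized over rows when `theta` is a matrix.
#'
#' @param backend a [likelihood_backend()].
#' @param prior a [uniform_prior()] (or compatible).
#' @param data a nonempty `trial_data`.
#' @param theta parameter vector or matrix of rows.
#' @return numeric vector of log-posterior values.
#' @export
log_posterior <- function(backend, prior, data, theta) {
  make_log_posterior(backend, prior, data)(theta)
}

#' @rdname log_posterior
#' @return `make_log_posterior` returns a function mapping a theta matrix
#'   to log-posterior values, with observed data pre-processed once (the
#'   histogram backend bins the dataset a single time).
#' @export
make_log_posterior <- function(backend, prior, data) {
  if (nrow(data) == 0) stop("empty data")
  ab <- absorbed(data)
  pre <- if (backend$type == "cnn")
    bin_counts(ab, n_bins = backend$lan$n_bins, t_max = backend$lan$t_max,
               choices = backend$lan$choices)
  else if (backend$type == "mlp")
    list(trial_s = .standardize_trials(
      backend$lan, ab, length(backend$lan$norm$mu) - 2L))
  else ab
  function(theta) {
    th <- if (is.matrix(theta)) theta else matrix(theta, nrow = 1)
    lpri <- prior$log_density(th)
    out <- rep(-Inf, nrow(th))
    ok <- is.finite(lpri)
    if (any(ok))
      out[ok] <- .backend_dataset_loglik(backend, pre,
                                         th[ok, , drop = FALSE]) + lpri[ok]
    out
  }
}

#' Minimum minority-choice filter
#'
#' Datasets whose less frequently chosen option received fewer than
#' `threshold` (default 5%, inclusive) of the choices are rejected from
#' inference, mirroring the screening applied to network training data.
#'
#' @param data a `trial_data`.
#' @param threshold minority-fraction threshold (default 0.05).
#' @return `TRUE` (keep) or `FALSE` (reject), with attribute
#'   `minority_fraction`.
#' @export
filter_min_choice_fraction <- function(data, threshold = 0.05) {
  ab <- absorbed(data)
  choices <- attr(data, "choices")
  if (is.null(choices)) choices <- sort(unique(ab$choice))
  counts <- vapply(choices, function(c) sum(ab$choice == c), 0L)
  frac <- min(counts) / max(nrow(ab), 1L)
  structure(frac >= threshold, minority_fraction = frac)
}

#' Bounded differential-evolution MAP/MLE fit
#'
#' Classic rand/1/bin differential evolution on the log-posterior (maximum
#' likelihood when the prior is flat), clipped to the support box; one
#' optimum per restart. Used to initialize the samplers.
#'
#' @param backend,prior,data as in [log_posterior()].
#' @param restarts number of independent runs (default 5).
#' @param pop_size population per run (default 10 * dim).
#' @param generations DE generations (default 150).
#' @param seed optional seed.
#' @return matrix (restarts x dim) of optima, attribute `value` holding the
#'   attained log-posteriors.
#' @export
fit_map_de <- function(backend, prior, data, restarts = 5L, pop_size = NULL,
                       generations = 150L, seed = NULL) {
  lp <- make_log_posterior(backend, prior, data)
  de_optimize(lp, prior$lower, prior$upper, restarts = restarts,
              pop_size = pop_size, generations = generations, seed = seed)
}

#' @rdname fit_map_de
#' @param fn objective (log scale, maximized), vectorized over matrix rows.
#' @param lower,upper box bounds.
#' @export
de_optimize <- function(fn, lower, upper, restarts = 5L, pop_size = NULL,
                        generations = 150L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fnv <- .vectorize_lp(fn)
  d <- length(lower)
  if (is.null(pop_size)) pop_size <- max(10L * d, 20L)
  Fw <- 0.8; CR <- 0.9
  best <- matrix(NA_real_, restarts, d)
  vals <- numeric(restarts)
  for (r in seq_len(restarts)) {
    P <- matrix(stats::runif(pop_size * d), pop_size, d)
    P <- sweep(sweep(P, 2, upper - lower, `*`), 2, lower, `+`)
    fP <- fnv(P)
    for (g in seq_len(generations)) {
      idx <- t(vapply(seq_len(pop_size), function(i)
        sample(setdiff(seq_len(pop_size), i), 3L), integer(3)))
      V <- P[idx[, 1], , drop = FALSE] +
        Fw * (P[idx[, 2], , drop = FALSE] - P[idx[, 3], , drop = FALSE])
      V <- pmin(pmax(V, matrix(lower, pop_size, d, byrow = TRUE)),
                matrix(upper, pop_size, d, byrow = TRUE))
      cross <- matrix(stats::runif(pop_size * d) < CR, pop_size, d)
      force_j <- cbind(seq_len(pop_size), sample.int(d, pop_size, TRUE))
      cross[force_j] <- TRUE
      U <- ifelse(cross, V, P)
      fU <- fnv(U)
      take <- is.finite(fU) & fU > fP
      P[take, ] <- U[take, ]
      fP[take] <- fU[take]
    }
    i0 <- which.max(fP)
    best[r, ] <- P[i0, ]
    vals[r] <- fP[i0]
  }
  attr(best, "value") <- vals
  best
}

#' Posterior inference for one dataset
#'
#' Applies the minority-choice filter, initializes from differential-
#' evolution optima, runs the requested sampler and returns draws plus
#' diagnostics.
#'
#' @param backend a [likelihood_backend()].
#' @param prior a [uniform_prior()].
#' @param data a `trial_data` passing [filter_min_choice_fraction()].
#' @param sampler `"demcmc"` (default), `"slice"` or `"iterated_is"`.
#' @param seed integer seed.
#' @param restarts optimizer restarts for initialization (default 5).
#' @param filter_threshold minority-choice threshold (default 0.05).
#' @param ... passed to the chosen sampler.
#' @return list with `draws` (matrix), `mean`, `var`, `sampler`,
#'   `diagnostics`.
#' @export
run_inference <- function(backend, prior, data,
                          sampler = c("demcmc", "slice", "iterated_is"),
                          seed = 1L, restarts = 5L, filter_threshold = 0.05,
                          n_chains = NULL, ...) {
  sampler <- match.arg(sampler)
  keep <- filter_min_choice_fraction(data, filter_threshold)
  if (!keep)
    stop("dataset rejected: minority-choice fraction ",
         signif(attr(keep, "minority_fraction"), 3), " below ",
         filter_threshold)
  set.seed(seed)
  lp <- make_log_posterior(backend, prior, data)
  d <- length(prior$lower)
  # a rough mode on a trial subsample is enough to seed the samplers
  init_data <- if (nrow(data) > 256)
    data[sample.int(nrow(data), 256), , drop = FALSE]
  else data
  lp_init <- make_log_posterior(backend, prior, init_data)
  maps <- de_optimize(lp_init, prior$lower, prior$upper,
                      restarts = restarts, pop_size = 20L,
                      generations = 40L)
  if (sampler == "slice") {
    ch <- slice_sample(lp, prior$lower, prior$upper,
                       init = maps[which.max(attr(maps, "value")), ], ...)
    ps <- posterior_summary(ch)
    diag <- list(geweke_z = ch$geweke_z, converged = ch$converged)
  } else if (sampler == "demcmc") {
    if (is.null(n_chains)) n_chains <- 5L * d
    # perturbed replications of the optimizer restarts
    base <- maps[rep_len(seq_len(nrow(maps)), n_chains), , drop = FALSE]
    span <- matrix(prior$upper - prior$lower, n_chains, d, byrow = TRUE)
    init <- base + 0.02 * span * matrix(stats::rnorm(n_chains * d),
                                        n_chains, d)
    init <- reflect_into_box(init, prior$lower, prior$upper)
    ch <- demcmc_sample(lp, prior$lower, prior$upper, init = init,
                        n_chains = n_chains, ...)
    ps <- posterior_summary(ch)
    diag <- list(rhat = ch$rhat, accept_rate = ch$accept_rate,
                 converged = ch$converged)
  } else {
    res <- iterated_importance_sampler(lp, prior$lower, prior$upper,
                                       centers = maps, ...)
    ps <- list(mean = colMeans(res$draws),
               var = apply(res$draws, 2, stats::var), draws = res$draws)
    diag <- list(perplexity = res$perplexity_trace,
                 ess = res$final$ess, gamma = res$gamma_trace)
  }
  list(draws = ps$draws, mean = ps$mean, var = ps$var, sampler = sampler,
       diagnostics = diag)
}

#' Parameter-recovery study
#'
#' Samples ground-truth parameter vectors from the prior (screening out
#' defective setups and datasets failing the minority-choice filter),
#' simulates datasets, runs posterior inference on each, and aggregates
#' per-parameter recovery (ordinary-least-squares R-squared of posterior
#' means on truths) and posterior variances.
#'
#' @param spec an [ssm_model()].
#' @param backend a [likelihood_backend()] for `spec`.
#' @param n_datasets number of simulated datasets (the study design uses
#'   dozens, e.g. 40).
#' @param n_trials trials per dataset (1024 and 4096 in the study designs).
#' @param seed integer seed; dataset i uses seed + i.
#' @param sampler,prior,truths,... see [run_inference()]; `truths` may
#'   pre-specify the ground-truth matrix.
#' @param dt simulation step size.
#' @return a `recovery_report`: per-dataset truths, posterior means and
#'   variances, and per-parameter `r_squared`.
#' @export
run_recovery_study <- function(spec, backend, n_datasets = 40L,
                               n_trials = 1024L, seed = 1L,
                               sampler = "demcmc", prior = NULL,
                               truths = NULL, dt = 0.001, ...) {
  if (is.null(prior)) prior <- uniform_prior(spec)
  set.seed(seed)
  d <- length(spec$param_names)
  if (is.null(truths)) {
    truths <- matrix(NA_real_, n_datasets, d,
                     dimnames = list(NULL, spec$param_names))
    datasets <- vector("list", n_datasets)
    got <- 0L; tries <- 0L
    while (got < n_datasets) {
      tries <- tries + 1L
      if (tries > 50L * n_datasets) stop("could not draw enough datasets")
      th <- drop(prior$sample(1))
      dat <- simulate_trials(spec, th, sim_config(dt = dt,
                                                  n_trials = n_trials),
                             strict = FALSE)
      if (screen_defective(dat)$defective) next
      if (!filter_min_choice_fraction(dat)) next
      got <- got + 1L
      truths[got, ] <- th
      datasets[[got]] <- dat
    }
  } else {
    datasets <- lapply(seq_len(n_datasets), function(i)
      simulate_trials(spec, truths[i, ], sim_config(dt = dt,
                                                    n_trials = n_trials,
                                                    seed = seed + i),
                      strict = FALSE))
  }
  means <- matrix(NA_real_, n_datasets, d)
  vars <- matrix(NA_real_, n_datasets, d)
  for (i in seq_len(n_datasets)) {
    fit <- run_inference(backend, prior, datasets[[i]], sampler = sampler,
                         seed = seed + 1000L + i, ...)
    means[i, ] <- fit$mean
    vars[i, ] <- fit$var
  }
  colnames(means) <- colnames(vars) <- spec$param_names
  r2 <- vapply(seq_len(d), function(j)
    recovery_r_squared(truths[, j], means[, j]), 0)
  names(r2) <- spec$param_names
  structure(list(model = spec$name, truths = truths,
                 posterior_mean = means, posterior_var = vars,
                 r_squared = r2, n_trials = n_trials,
                 n_datasets = n_datasets, sampler = sampler,
                 datasets = datasets),
            class = "recovery_report")
}

#' Coefficient of determination of posterior means on ground truths
#'
#' Ordinary least-squares R-squared of the regression of posterior means on
#' true parameter values.
#'
#' @param truth,estimate numeric vectors of equal length.
#' @return R-squared in `[0, 1]` (0 when the truths are constant).
#' @export
recovery_r_squared <- function(truth, estimate) {
  if (stats::var(truth) == 0)
    return(if (all(estimate == truth)) 1 else 0)
  if (stats::var(estimate) == 0) return(0)
  # R-squared of the simple OLS regression of estimates on truths
  stats::cor(truth, estimate)^2
}

#' Posterior predictive simulation
#'
#' Simulates from parameter draws, summarizing predicted choice fractions
#' and per-choice response-time histograms; for collapsing-bound models the
#' per-draw net bound trajectories B(t) over the observed response-time
#' range are also returned.
#'
#' @param spec an [ssm_model()].
#' @param draws matrix of posterior draws (rows = parameter vectors).
#' @param n_sim simulated trials per retained draw (default 512).
#' @param n_draws number of retained draws (default 50, thinned evenly).
#' @param data optional observed `trial_data` for overlay summaries.
#' @param seed integer seed.
#' @param dt simulation step size.
#' @return list with `simulated` (pooled `trial_data`), `choice_fractions`,
#'   `rt_histograms` (per choice, density-normalized), `observed` summaries
#'   when `data` is given, and `bound_trajectories` for Weibull / linear-
#'   collapse models.
#' @export
posterior_predictive <- function(spec, draws, n_sim = 512L, n_draws = 50L,
                                 data = NULL, seed = 1L, dt = 0.001) {
  stopifnot(nrow(draws) >= 1)
  set.seed(seed)
  take <- unique(round(seq(1, nrow(draws), length.out = min(n_draws,
                                                            nrow(draws)))))
  sims <- lapply(take, function(i)
    simulate_trials(spec, draws[i, ], sim_config(dt = dt, n_trials = n_sim),
                    strict = FALSE))
  pooled <- do.call(rbind, lapply(sims, as.data.frame))
  pooled <- trial_data(pooled$rt, pooled$choice, spec = spec)
  ab <- absorbed(pooled)
  cf <- vapply(spec$choices, function(c) mean(ab$choice == c), 0)
  names(cf) <- as.character(spec$choices)
  t_hi <- if (!is.null(data)) max(absorbed(data)$rt) else
    stats::quantile(ab$rt, 0.99)
  brks <- seq(0, t_hi * 1.05, length.out = 41)
  hists <- lapply(spec$choices, function(c) {
    rts <- ab$rt[ab$choice == c & ab$rt <= max(brks)]
    h <- graphics::hist(rts, breaks = brks, plot = FALSE)
    h$density <- h$density * length(rts) / nrow(ab) # defective scaling
    h
  })
  names(hists) <- as.character(spec$choices)
  out <- list(simulated = pooled, choice_fractions = cf,
              rt_histograms = hists)
  if (!is.null(data)) {
    oab <- absorbed(data)
    out$observed <- list(
      choice_fractions = vapply(spec$choices,
                                function(c) mean(oab$choice == c), 0),
      rt = oab$rt)
  }
  if (spec$bound %in% c("weibull", "linear_collapse")) {
    tt <- seq(0, t_hi, length.out = 100)
    out$bound_trajectories <- t(vapply(take, function(i) {
      th <- draws[i, ]
      names(th) <- spec$param_names
      if (spec$bound == "weibull")
        boundary_weibull(tt, th[["a"]], th[["alpha"]], th[["beta"]],
                         alternative = spec$weibull_alternative)
      else
        pmax(boundary_linear_collapse(tt, th[["a"]], th[["angle"]]), 0)
    }, tt))
    out$bound_times <- tt
  }
  out
}
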