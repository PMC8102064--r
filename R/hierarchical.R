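#' Hierarchical / condition-split model structure
#'
#' Assigns every model parameter exactly one role: `global` (one value for
#' all trials), `subject` (one value per subject, drawn from a group-level
#' Normal(mu, sigma) truncated to the trained range, with a uniform
#' hyperprior on mu and a half-normal hyperprior on sigma), or `condition`
#' (one independent value per experimental condition, uniform prior).
#'
#' @param spec an [ssm_model()].
#' @param subject_params parameter names varying per subject.
#' @param condition_params parameter names varying per condition.
#' @param n_subjects,n_conditions design sizes.
#' @param sigma_scale scale of the half-normal hyperprior on each group
#'   sigma; defaults to a quarter of the parameter's trained range.
#' @param fixed optional named numeric vector of parameters held at known
#'   values (excluded from sampling).
#' @return a `hierarchical_spec` with the stacked parameter layout used by
#'   the sampler (`par_names`, `lower`, `upper`).
#' @export
hierarchical_spec <- function(spec, subject_params = character(),
                              condition_params = character(),
                              n_subjects = 1L, n_conditions = 1L,
                              sigma_scale = NULL, fixed = NULL) {
  stopifnot(inherits(spec, "ssm_model"))
  roles <- c(subject_params, condition_params, names(fixed))
  if (anyDuplicated(roles) || !all(roles %in% spec$param_names))
    stop("each parameter must have exactly one role")
  global_params <- setdiff(spec$param_names, roles)
  b <- range_bounds(spec)
  nm <- lo <- hi <- c()
  add <- function(names, lows, highs) {
    nm <<- c(nm, names); lo <<- c(lo, lows); hi <<- c(hi, highs)
  }
  for (p in subject_params) {
    r <- spec$ranges[[p]]
    add(paste0(p, "_s", seq_len(n_subjects)), rep(r[1], n_subjects),
        rep(r[2], n_subjects))
    sc <- if (is.null(sigma_scale)) (r[2] - r[1]) / 4 else sigma_scale
    add(paste0(p, c("_mu", "_sigma")), c(r[1], 1e-3), c(r[2], r[2] - r[1]))
  }
  for (p in condition_params) {
    r <- spec$ranges[[p]]
    add(paste0(p, "_c", seq_len(n_conditions)), rep(r[1], n_conditions),
        rep(r[2], n_conditions))
  }
  for (p in global_params) {
    r <- spec$ranges[[p]]
    add(p, r[1], r[2])
  }
  sig_scales <- vapply(subject_params, function(p) {
    r <- spec$ranges[[p]]
    if (is.null(sigma_scale)) (r[2] - r[1]) / 4 else sigma_scale
  }, 0)
  structure(list(spec = spec, subject_params = subject_params,
                 condition_params = condition_params,
                 global_params = global_params, fixed = fixed,
                 n_subjects = as.integer(n_subjects),
                 n_conditions = as.integer(n_conditions),
                 sigma_scales = sig_scales,
                 par_names = nm, lower = stats::setNames(lo, nm),
                 upper = stats::setNames(hi, nm)),
            class = "hierarchical_spec")
}

# assemble the model-level theta for one (subject, condition) cell from the
# stacked parameter vector
.assemble_theta <- function(hier, params, subject, condition) {
  th <- stats::setNames(numeric(length(hier$spec$param_names)),
                        hier$spec$param_names)
  for (p in hier$subject_params)
    th[p] <- params[[paste0(p, "_s", subject)]]
  for (p in hier$condition_params)
    th[p] <- params[[paste0(p, "_c", condition)]]
  for (p in hier$global_params)
    th[p] <- params[[p]]
  for (p in names(hier$fixed))
    th[p] <- hier$fixed[[p]]
  th
}

.log_dtruncnorm <- function(x, mu, sigma, lo, hi) {
  z <- stats::pnorm(hi, mu, sigma) - stats::pnorm(lo, mu, sigma)
  ifelse(x < lo | x > hi, -Inf,
         stats::dnorm(x, mu, sigma, log = TRUE) - log(pmax(z, 1e-300)))
}

#' Hierarchical log-posterior
#'
#' Sums the backend's dataset log-likelihood over all (subject, condition)
#' cells with the cell-assembled parameter vector, plus the group-level
#' truncated-normal log densities of subject parameters, the half-normal
#' log hyperprior on each group sigma, and uniform log priors (constant,
#' omitted) on everything else. With one subject, one condition and no
#' subject parameters this reduces to [log_posterior()] up to the uniform
#' prior constant.
#'
#' @param backend a [likelihood_backend()] for `hier$spec`.
#' @param hier a [hierarchical_spec()].
#' @param data `trial_data` with `subject` (and `condition`) columns
#'   matching the design.
#' @param params stacked parameter vector in `hier$par_names` order (or a
#'   matrix of row vectors).
#' @return numeric vector of log-posterior values.
#' @export
hierarchical_log_posterior <- function(backend, hier, data, params) {
  make_hierarchical_log_posterior(backend, hier, data)(params)
}

#' @rdname hierarchical_log_posterior
#' @return `make_hierarchical_log_posterior` returns the log-posterior
#'   closure with the per-cell data split (and any backend preprocessing)
#'   done once; this is what the samplers consume.
#' @export
make_hierarchical_log_posterior <- function(backend, hier, data) {
  sub <- if (!is.null(data$subject)) data$subject else rep(1L, nrow(data))
  con <- if (!is.null(data$condition)) data$condition else rep(1L, nrow(data))
  if (length(hier$subject_params) && is.null(data$subject))
    stop("data lacks subject labels required by the hierarchy")
  if (length(hier$condition_params) && is.null(data$condition))
    stop("data lacks condition labels required by the hierarchy")
  cells <- unique(data.frame(s = sub, c = con))
  cell_data <- lapply(seq_len(nrow(cells)), function(k)
    absorbed(data[sub == cells$s[k] & con == cells$c[k], , drop = FALSE]))
  function(params) {
  P <- if (is.matrix(params)) params else matrix(params, nrow = 1)
  colnames(P) <- hier$par_names
  vapply(seq_len(nrow(P)), function(r) {
    pv <- stats::setNames(P[r, ], hier$par_names)
    if (any(pv < hier$lower | pv > hier$upper)) return(-Inf)
    ll <- 0
    for (k in seq_len(nrow(cells))) {
      th <- .assemble_theta(hier, pv, cells$s[k], cells$c[k])
      ll <- ll + .backend_dataset_loglik(backend, cell_data[[k]],
                                         matrix(th, nrow = 1))
    }
    for (p in hier$subject_params) {
      r0 <- hier$spec$ranges[[p]]
      mu <- pv[[paste0(p, "_mu")]]
      sg <- pv[[paste0(p, "_sigma")]]
      xs <- pv[paste0(p, "_s", seq_len(hier$n_subjects))]
      ll <- ll + sum(.log_dtruncnorm(xs, mu, sg, r0[1], r0[2]))
      sc <- hier$sigma_scales[[p]]
      ll <- ll + (log(2) - log(sc) - 0.5 * log(2 * pi) -
                    0.5 * (sg / sc)^2) # half-normal hyperprior
    }
    ll
  }, 0)
  }
}

#' Hierarchical posterior sampling
#'
#' Slice-samples the stacked hierarchical parameter vector.
#'
#' @param backend,hier,data as in [hierarchical_log_posterior()].
#' @param seed integer seed.
#' @param init optional start vector; defaults to the box midpoint with
#'   subject values at their group means.
#' @param ... passed to [slice_sample()].
#' @return the `ssm_chain`, with `par_names` attached.
#' @export
run_hierarchical_inference <- function(backend, hier, data, seed = 1L,
                                       init = NULL, ...) {
  set.seed(seed)
  lp <- make_hierarchical_log_posterior(backend, hier, data)
  if (is.null(init)) init <- (hier$lower + hier$upper) / 2
  ch <- slice_sample(lp, hier$lower, hier$upper, init = init, seed = seed,
                     ...)
  ch$par_names <- hier$par_names
  ch
}

#' Simulate a hierarchical dataset
#'
#' Draws per-subject parameters from truncated Normal(mu, sigma) group laws
#' (and per-condition values where configured), simulates each cell and
#' stacks the labeled trials.
#'
#' @param hier a [hierarchical_spec()].
#' @param group_mu,group_sigma named values for each subject parameter.
#' @param condition_values named list: for each condition parameter, a
#'   vector of length `n_conditions`.
#' @param global_values named values for the global parameters.
#' @param n_trials trials per (subject, condition) cell.
#' @param seed integer seed.
#' @param dt simulation step size.
#' @return list with `data` (labeled `trial_data`) and `truth` (the stacked
#'   generating vector in `hier$par_names` order).
#' @export
simulate_hierarchical <- function(hier, group_mu = NULL, group_sigma = NULL,
                                  condition_values = NULL,
                                  global_values = NULL, n_trials = 500L,
                                  seed = 1L, dt = 0.001) {
  set.seed(seed)
  spec <- hier$spec
  truth <- stats::setNames(numeric(length(hier$par_names)), hier$par_names)
  for (p in hier$subject_params) {
    r <- spec$ranges[[p]]
    mu <- group_mu[[p]]; sg <- group_sigma[[p]]
    vals <- numeric(hier$n_subjects)
    for (j in seq_len(hier$n_subjects)) {
      repeat {
        x <- stats::rnorm(1, mu, sg)
        if (x >= r[1] && x <= r[2]) break
      }
      vals[j] <- x
    }
    truth[paste0(p, "_s", seq_len(hier$n_subjects))] <- vals
    truth[paste0(p, "_mu")] <- mu
    truth[paste0(p, "_sigma")] <- sg
  }
  for (p in hier$condition_params)
    truth[paste0(p, "_c", seq_len(hier$n_conditions))] <-
      condition_values[[p]]
  for (p in hier$global_params)
    truth[p] <- global_values[[p]]
  rows <- list()
  for (j in seq_len(hier$n_subjects)) {
    for (k in seq_len(hier$n_conditions)) {
      th <- .assemble_theta(hier, truth, j, k)
      dat <- simulate_trials(spec, th, sim_config(dt = dt,
                                                  n_trials = n_trials),
                             strict = FALSE)
      dat$subject <- j
      dat$condition <- k
      rows[[length(rows) + 1]] <- as.data.frame(dat)
    }
  }
  all <- do.call(rbind, rows)
  data <- trial_data(all$rt, all$choice, subject = all$subject,
                     condition = all$condition, spec = spec)
  list(data = data, truth = truth)
}
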