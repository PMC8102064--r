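#' Simulation configuration
#'
#' @param dt Euler-Maruyama step size in seconds (default 0.001).
#' @param t_max maximum first-passage time in seconds before a trial is
#'   censored (default 20).
#' @param n_trials number of trials to simulate.
#' @param seed optional integer seed applied before simulation.
#' @return a `sim_config` list.
#' @export
sim_config <- function(dt = 0.001, t_max = 20, n_trials = 1000L, seed = NULL) {
  stopifnot(dt > 0, t_max > dt, n_trials >= 1)
  structure(list(dt = dt, t_max = t_max, n_trials = as.integer(n_trials),
                 seed = seed), class = "sim_config")
}

#' Simulate choice / response-time trials from a sequential sampling model
#'
#' Integrates the model's stochastic differential equation with the
#' Euler-Maruyama scheme `X[t+dt] = X[t] + a(t,x) dt + b(t,x) dB` until the
#' particle (or the first of the racing particles) leaves the decision
#' region. Returned response times are first-passage times plus the
#' nondecision time; trials still unabsorbed at `t_max` are censored and
#' carry the sentinel `rt = -1` with an `NA` choice.
#'
#' @param spec an [ssm_model()].
#' @param theta parameter vector for `spec` (validated against the trained
#'   ranges; use `strict = FALSE` to simulate outside them with a warning).
#' @param config a [sim_config()]; `n_trials`, `dt`, `t_max` may also be
#'   passed directly.
#' @param strict passed to [check_theta()].
#' @param mirror_noise replay the sign-flipped noise path (for
#'   common-random-number mirror-symmetry checks).
#' @return a `trial_data` data.frame with columns `rt` (seconds) and
#'   `choice` (-1/+1 for two-choice models, 0..N-1 for race models).
#' @examples
#' d <- simulate_trials(ssm_model("ddm"), c(v = 0.5, a = 1, w = 0.5, tau = 0.3),
#'                      sim_config(n_trials = 200, seed = 1))
#' table(d$choice)
#' @export
simulate_trials <- function(spec, theta, config = sim_config(),
                            n_trials = NULL, dt = NULL, t_max = NULL,
                            seed = NULL, strict = TRUE,
                            mirror_noise = FALSE) {
  stopifnot(inherits(spec, "ssm_model"))
  if (!is.null(n_trials)) config$n_trials <- as.integer(n_trials)
  if (!is.null(dt)) config$dt <- dt
  if (!is.null(t_max)) config$t_max <- t_max
  if (!is.null(seed)) config$seed <- seed
  theta <- check_theta(spec, theta, strict = strict)
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_trials
  sgn <- if (isTRUE(mirror_noise)) -1 else 1

  if (spec$n_accumulators > 1L) {
    nA <- spec$n_accumulators
    out <- sim_race_cpp(n, theta[paste0("v", seq_len(nA))], theta[["a"]],
                        theta[paste0("w", seq_len(nA))], theta[["ndt"]],
                        config$dt, config$t_max)
  } else {
    v <- theta[["v"]]; a <- theta[["a"]]; w <- theta[["w"]]
    tau <- theta[["tau"]]
    g <- if (spec$name == "ou") theta[["g"]] else 0
    noise_type <- if (spec$noise == "alpha_stable") 1L else 0L
    alpha <- if (noise_type == 1L) theta[["alpha"]] else 2
    bt <- switch(spec$bound, constant = 0L, weibull = 1L, linear_collapse = 2L)
    bp1 <- bp2 <- 0
    if (spec$bound == "weibull") { bp1 <- theta[["alpha"]]; bp2 <- theta[["beta"]] }
    if (spec$bound == "linear_collapse") bp1 <- theta[["angle"]]
    if (spec$name == "full_ddm") {
      # trial-to-trial perturbations, centered on the base parameters
      v <- v + stats::rnorm(n, 0, theta[["sv"]])
      w <- pmin(1 - 1e-6, pmax(1e-6, w + stats::runif(n, -theta[["sw"]], theta[["sw"]])))
      tau <- pmax(0, tau + stats::runif(n, -theta[["st"]], theta[["st"]]))
    }
    out <- sim_single_cpp(n, v, a, w, tau, g, noise_type, alpha, bt,
                          bp1, bp2, as.integer(spec$weibull_alternative),
                          config$dt, config$t_max, sgn)
  }
  trial_data(rt = out$rt, choice = out$choice, spec = spec)
}

#' Construct a trial-data container
#'
#' The universal observed-data container: response times in seconds and
#' integer choice codes, with optional per-trial subject and condition
#' labels. Censored trials carry `rt = -1` and `NA` choice.
#'
#' @param rt numeric response times (seconds); -1 marks a censored trial.
#' @param choice integer choice codes.
#' @param subject,condition optional per-trial labels.
#' @param spec optional `ssm_model` used to validate choice codes.
#' @return a data.frame of class `trial_data`.
#' @export
trial_data <- function(rt, choice, subject = NULL, condition = NULL,
                       spec = NULL) {
  stopifnot(length(rt) == length(choice))
  d <- data.frame(rt = as.numeric(rt), choice = as.integer(choice))
  if (!is.null(subject)) d$subject <- subject
  if (!is.null(condition)) d$condition <- condition
  if (!is.null(spec)) {
    bad <- !is.na(d$choice) & !(d$choice %in% spec$choices)
    if (any(bad)) stop("choice codes outside the model's choice set")
    attr(d, "model") <- spec$name
    attr(d, "choices") <- spec$choices
  }
  class(d) <- c("trial_data", "data.frame")
  d
}

#' @rdname trial_data
#' @param data a `trial_data` object.
#' @export
absorbed <- function(data) data[data$rt >= 0 & !is.na(data$choice), , drop = FALSE]

#' Draw from the symmetric, centered, unit-scale alpha-stable law
#'
#' Chambers-Mallows-Stuck sampler for L(alpha, 0, 1, 0), the incremental
#' noise law of the Levy flight model. At `alpha = 2` the law is N(0, 2).
#'
#' @param alpha stability index in (1, 2].
#' @param n number of draws.
#' @param seed optional integer seed.
#' @return numeric vector of n draws.
#' @export
sample_alpha_stable <- function(alpha, n, seed = NULL) {
  if (!is.numeric(alpha) || length(alpha) != 1 || !is.finite(alpha) ||
      alpha <= 1 || alpha > 2)
    stop("alpha must lie in (1, 2]")
  if (!is.null(seed)) set.seed(seed)
  sample_alpha_stable_cpp(as.integer(n), alpha)
}

#' Weibull collapsing decision bound
#'
#' Default reading B(t) = a exp(-t^beta / alpha); set `alternative = TRUE`
#' for a exp(-(t/beta)^alpha). Strictly positive and non-increasing in t.
#'
#' @param t time in seconds (vectorized), >= 0.
#' @param a bound scale at t = 0.
#' @param alpha,beta positive shape parameters.
#' @param alternative use the alternative functional reading.
#' @return bound height(s).
#' @export
boundary_weibull <- function(t, a, alpha, beta, alternative = FALSE) {
  if (any(t < 0)) stop("t must be non-negative")
  stopifnot(a > 0, alpha > 0, beta > 0)
  if (alternative) a * exp(-(t / beta)^alpha) else a * exp(-t^beta / alpha)
}

#' Linearly collapsing decision bound
#'
#' B(t) = a - t * tan(angle); values <= 0 mean the upper and lower bounds
#' have met, at which point the simulator absorbs the trial by particle sign.
#'
#' @param t time in seconds (vectorized), >= 0.
#' @param a bound scale at t = 0.
#' @param angle collapse angle in radians, 0 <= angle < pi/2.
#' @return bound height(s), possibly non-positive after the collapse time.
#' @export
boundary_linear_collapse <- function(t, a, angle) {
  if (any(t < 0)) stop("t must be non-negative")
  if (angle < 0 || angle >= pi / 2) stop("angle must lie in [0, pi/2)")
  stopifnot(a > 0)
  a - t * tan(angle)
}

#' Screen simulated data for defective parameter setups
#'
#' A parameter vector is "defective" for training purposes when its data are
#' degenerate: (i) some choice is (almost) never produced - minority-choice
#' probability below 1/100000; (ii) more than half of all response times fall
#' into a single 1 ms bin; or (iii) the mean response time exceeds 10 s.
#'
#' @param data a `trial_data` object with at least one trial.
#' @return list with `defective` (logical) and `reasons` (character vector
#'   among "choice-degeneracy", "rt-concentration", "slow").
#' @export
screen_defective <- function(data) {
  if (is.null(data) || nrow(data) == 0) stop("empty data")
  reasons <- character(0)
  n_total <- nrow(data)
  ab <- absorbed(data)
  choices <- attr(data, "choices")
  if (is.null(choices)) choices <- sort(unique(ab$choice))
  counts <- vapply(choices, function(c) sum(ab$choice == c), 0L)
  # censored trials count toward total probability but toward no choice
  if (length(counts) && min(counts) / n_total < 1e-5)
    reasons <- c(reasons, "choice-degeneracy")
  if (nrow(ab)) {
    bins <- table(floor(ab$rt / 0.001))
    if (max(bins) > 0.5 * nrow(ab))
      reasons <- c(reasons, "rt-concentration")
    if (mean(ab$rt) > 10)
      reasons <- c(reasons, "slow")
  } else {
    reasons <- c(reasons, "slow")
  }
  list(defective = length(reasons) > 0, reasons = reasons)
}

#' Read / write trial data as delimited text
#'
#' Plain CSV/TSV with header columns `rt`, `choice` and optional `subject`,
#' `condition`; response times in seconds as decimal floats.
#'
#' @param data a `trial_data` object.
#' @param path file path; `.tsv` extension selects tab separation.
#' @export
write_trial_data <- function(data, path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  data.table::fwrite(as.data.frame(data), path, sep = sep)
  invisible(path)
}

#' @rdname write_trial_data
#' @export
read_trial_data <- function(path) {
  d <- as.data.frame(data.table::fread(path))
  if (!all(c("rt", "choice") %in% names(d)))
    stop("trial data file needs 'rt' and 'choice' columns")
  trial_data(rt = d$rt, choice = d$choice, subject = d$subject,
             condition = d$condition)
}
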