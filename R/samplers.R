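# Posterior sampling machinery: coordinate-wise step-out slice sampling,
# differential-evolution MCMC with reflecting boundaries, annealed adaptive
# importance sampling with Student-t mixture proposals, and the associated
# convergence diagnostics (Geweke, Gelman-Rubin, ESS, normalized perplexity).

# wrap a log-posterior so it always maps a matrix of row-points to a vector
.vectorize_lp <- function(logpost) {
  force(logpost)
  function(X) {
    X <- if (is.matrix(X)) X else matrix(X, nrow = 1)
    out <- tryCatch(logpost(X), error = function(e) NULL)
    if (!is.null(out) && length(out) == nrow(X)) return(as.numeric(out))
    apply(X, 1, function(r) as.numeric(logpost(r)))
  }
}

#' Coordinate-wise step-out slice sampler
#'
#' Univariate slice updates with the step-out procedure applied to each
#' coordinate in turn, on a box support. Runs at least `min_samples`
#' iterations, then checks the Geweke statistic of every coordinate once
#' every `check_every` draws and stops at convergence (all |z| below
#' `geweke_threshold`) or at `max_samples`.
#'
#' @param logpost log-posterior; called with a parameter vector (or a matrix
#'   of row vectors, vectorized implementations are exploited when offered).
#' @param lower,upper support box.
#' @param init starting point inside the box with finite log-posterior.
#' @param min_samples minimum chain length (default 2000).
#' @param max_samples iteration cap (default 3 * min_samples).
#' @param check_every Geweke cadence (default 100).
#' @param geweke_threshold |z| threshold per coordinate (default 2).
#' @param width0 initial step-out widths; default (upper - lower) / 10.
#' @param seed optional seed.
#' @return an `ssm_chain`: list with `draws` (iterations x dims),
#'   `log_post`, `geweke_z`, `converged`, `n_evals`.
#' @export
slice_sample <- function(logpost, lower, upper, init, min_samples = 2000L,
                         max_samples = NULL, check_every = 100L,
                         geweke_threshold = 2, width0 = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lp <- .vectorize_lp(logpost)
  d <- length(lower)
  stopifnot(length(upper) == d, length(init) == d,
            all(init >= lower & init <= upper))
  if (is.null(max_samples)) max_samples <- 3L * min_samples
  if (is.null(width0)) width0 <- (upper - lower) / 10
  x <- as.numeric(init)
  fx <- lp(x)
  if (!is.finite(fx)) stop("log-posterior not finite at init")
  draws <- matrix(NA_real_, max_samples, d)
  lps <- numeric(max_samples)
  n_evals <- 1L
  zs <- rep(NA_real_, d)
  converged <- FALSE
  it <- 0L
  while (it < max_samples) {
    it <- it + 1L
    for (j in seq_len(d)) {
      level <- fx - stats::rexp(1)
      w <- width0[j]
      L <- max(lower[j], x[j] - w * stats::runif(1))
      R <- min(upper[j], L + w)
      # step out by doubling-free linear expansion, clamped to the support
      xj <- x
      repeat {
        if (L <= lower[j]) break
        xj[j] <- L
        fl <- lp(xj); n_evals <- n_evals + 1L
        if (fl < level) break
        L <- max(lower[j], L - w)
      }
      repeat {
        if (R >= upper[j]) break
        xj[j] <- R
        fr <- lp(xj); n_evals <- n_evals + 1L
        if (fr < level) break
        R <- min(upper[j], R + w)
      }
      # shrinkage sampling on [L, R]
      reject <- 0L
      repeat {
        u <- stats::runif(1, L, R)
        xj[j] <- u
        fu <- lp(xj); n_evals <- n_evals + 1L
        if (fu >= level) { x <- xj; fx <- fu; break }
        if (u < x[j]) L <- u else R <- u
        reject <- reject + 1L
        if (reject > 1000L) stop("slice shrank to a point; log-posterior ",
                                 "may be -Inf on the whole slice")
      }
    }
    draws[it, ] <- x
    lps[it] <- fx
    if (it >= min_samples && it %% check_every == 0L) {
      zs <- vapply(seq_len(d), function(j)
        geweke_statistic(draws[seq_len(it), j]), 0)
      if (all(abs(zs) < geweke_threshold)) { converged <- TRUE; break }
    }
  }
  keep <- seq_len(it)
  structure(list(draws = draws[keep, , drop = FALSE], log_post = lps[keep],
                 geweke_z = zs, converged = converged, n_evals = n_evals,
                 sampler = "slice"),
            class = "ssm_chain")
}

#' Geweke convergence statistic
#'
#' z-score comparing the mean of the first 10% of a chain against the mean
#' of the last 50%, with variances estimated from the spectral density at
#' frequency zero (autoregressive estimator) of each window.
#'
#' @param x numeric chain (length >= 100).
#' @param frac1,frac2 early / late window fractions (defaults 0.1 / 0.5).
#' @return the z statistic.
#' @export
geweke_statistic <- function(x, frac1 = 0.1, frac2 = 0.5) {
  n <- length(x)
  if (n < 100) stop("chain too short for the Geweke statistic")
  if (stats::var(x) == 0) stop("zero-variance chain")
  x1 <- x[seq_len(max(2, floor(frac1 * n)))]
  x2 <- x[seq(floor((1 - frac2) * n) + 1, n)]
  s1 <- .spectrum0(x1); s2 <- .spectrum0(x2)
  (mean(x1) - mean(x2)) / sqrt(s1 / length(x1) + s2 / length(x2))
}

# spectral density at frequency zero via an AIC-selected AR fit; falls back
# to the sample variance for white-noise-like or degenerate windows
.spectrum0 <- function(x) {
  v <- stats::var(x)
  if (!is.finite(v) || v == 0) return(v)
  fit <- tryCatch(stats::ar(x, aic = TRUE,
                            order.max = min(20, length(x) %/% 5)),
                  error = function(e) NULL)
  if (is.null(fit) || length(fit$ar) == 0) return(v)
  fit$var.pred / (1 - sum(fit$ar))^2
}

#' Differential-evolution MCMC with reflecting boundaries
#'
#' Runs `5 * dim` parallel chains by default; each proposal is the chain
#' state plus a scaled difference of two other randomly chosen chain states
#' plus a small uniform jitter, reflected back across any violated face of
#' the support box before evaluation. Every `check_every` generations
#' (after `min_gens`) the per-parameter Gelman-Rubin statistic of the
#' second half of the run is computed; sampling stops when all are below
#' `rhat_threshold` or at `max_gens`.
#'
#' @param logpost log-posterior (vector or matrix contract as in
#'   [slice_sample()]).
#' @param lower,upper support box.
#' @param init optional n_chains x dim start matrix; defaults to uniform
#'   draws over the box.
#' @param n_chains number of chains (default 5 * dim).
#' @param min_gens,max_gens,check_every stopping controls.
#' @param rhat_threshold Gelman-Rubin threshold (default 1.1).
#' @param gamma_scale difference scaling; default 2.38 / sqrt(2 dim).
#' @param jitter half-width of the uniform proposal jitter (default 1e-4).
#' @param seed optional seed.
#' @return an `ssm_chain` with `draws` (generations x chains x dims),
#'   `rhat`, `accept_rate`, `converged`.
#' @export
demcmc_sample <- function(logpost, lower, upper, init = NULL, n_chains = NULL,
                          min_gens = 200L, max_gens = 1000L,
                          check_every = 50L, rhat_threshold = 1.1,
                          gamma_scale = NULL, jitter = 1e-4, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lp <- .vectorize_lp(logpost)
  d <- length(lower)
  if (is.null(n_chains)) n_chains <- 5L * d
  if (n_chains < d + 2L) stop("need at least dim + 2 chains")
  if (is.null(gamma_scale)) gamma_scale <- 2.38 / sqrt(2 * d)
  if (is.null(init)) {
    init <- matrix(stats::runif(n_chains * d), n_chains, d)
    init <- sweep(sweep(init, 2, upper - lower, `*`), 2, lower, `+`)
  }
  stopifnot(nrow(init) == n_chains, ncol(init) == d)
  X <- init
  fX <- lp(X)
  draws <- array(NA_real_, dim = c(max_gens, n_chains, d))
  lptrace <- matrix(NA_real_, max_gens, n_chains)
  acc <- 0L
  rhat <- rep(NA_real_, d)
  converged <- FALSE
  gen <- 0L
  while (gen < max_gens) {
    gen <- gen + 1L
    r1 <- integer(n_chains); r2 <- integer(n_chains)
    for (i in seq_len(n_chains)) {
      pick <- sample.int(n_chains - 1L, 2L)
      pick <- ifelse(pick >= i, pick + 1L, pick)
      r1[i] <- pick[1]; r2[i] <- pick[2]
    }
    prop <- X + gamma_scale * (X[r1, , drop = FALSE] - X[r2, , drop = FALSE]) +
      matrix(stats::runif(n_chains * d, -jitter, jitter), n_chains, d)
    prop <- reflect_into_box(prop, lower, upper)
    fP <- lp(prop)
    u <- log(stats::runif(n_chains))
    take <- is.finite(fP) & (u < fP - fX)
    X[take, ] <- prop[take, ]
    fX[take] <- fP[take]
    acc <- acc + sum(take)
    draws[gen, , ] <- X
    lptrace[gen, ] <- fX
    if (gen >= min_gens && gen %% check_every == 0L) {
      half <- draws[seq(floor(gen / 2) + 1, gen), , , drop = FALSE]
      rhat <- gelman_rubin(half)
      if (all(rhat < rhat_threshold)) { converged <- TRUE; break }
    }
  }
  keep <- seq_len(gen)
  structure(list(draws = draws[keep, , , drop = FALSE],
                 log_post = lptrace[keep, , drop = FALSE], rhat = rhat,
                 accept_rate = acc / (gen * n_chains), converged = converged,
                 sampler = "demcmc"),
            class = "ssm_chain")
}

#' Reflect points across the faces of a box
#'
#' A coordinate `b + e` beyond the upper bound `b` maps to `b - e` (and
#' symmetrically at the lower bound), repeated until inside.
#'
#' @param X matrix of row points (or a vector).
#' @param lower,upper box bounds.
#' @return reflected points, same shape as `X`.
#' @export
reflect_into_box <- function(X, lower, upper) {
  vec <- !is.matrix(X)
  if (vec) X <- matrix(X, nrow = 1)
  span <- upper - lower
  for (j in seq_along(lower)) {
    x <- X[, j]
    # fold into [lower, lower + 2*span) then mirror the upper half
    y <- (x - lower[j]) %% (2 * span[j])
    y <- ifelse(y > span[j], 2 * span[j] - y, y)
    X[, j] <- lower[j] + y
  }
  if (vec) drop(X) else X
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Between/within-chain variance ratio per parameter,
#' `sqrt(((n - 1)/n * W + B/n) / W)` with `B` the between-chain variance of
#' chain means scaled by `n`.
#'
#' @param draws array (iterations x chains x dims) or list of equal-length
#'   chain matrices (iterations x dims).
#' @return numeric vector of per-dimension R-hat values.
#' @export
gelman_rubin <- function(draws) {
  if (is.list(draws) && !is.array(draws)) {
    stopifnot(length(draws) >= 2)
    n <- nrow(draws[[1]])
    draws <- array(unlist(lapply(draws, as.matrix)),
                   dim = c(n, ncol(draws[[1]]), length(draws)))
    draws <- aperm(draws, c(1, 3, 2))
  }
  dd <- dim(draws)
  if (length(dd) != 3 || dd[2] < 2) stop("need >= 2 chains of equal length")
  n <- dd[1]
  vapply(seq_len(dd[3]), function(j) {
    M <- draws[, , j]
    W <- mean(apply(M, 2, stats::var))
    B <- n * stats::var(colMeans(M))
    vhat <- (n - 1) / n * W + B / n
    if (W == 0) return(1)
    sqrt(vhat / W)
  }, 0)
}

## ---- Student-t mixture proposals and importance sampling ----------------

#' Student-t mixture proposal
#'
#' @param weights component weights (sum to 1).
#' @param mu matrix of component locations (components x dims).
#' @param sigma list of symmetric positive-definite scale matrices.
#' @param nu degrees of freedom (default 5).
#' @return a `t_mixture` object.
#' @export
t_mixture <- function(weights, mu, sigma, nu = 5) {
  mu <- if (is.matrix(mu)) mu else matrix(mu, nrow = 1)
  stopifnot(length(weights) == nrow(mu), length(sigma) == nrow(mu),
            abs(sum(weights) - 1) < 1e-8)
  for (S in sigma) {
    if (any(abs(S - t(S)) > 1e-8)) stop("scale matrix not symmetric")
    if (any(eigen(S, symmetric = TRUE, only.values = TRUE)$values <= 0))
      stop("scale matrix not positive definite")
  }
  structure(list(weights = weights, mu = mu, sigma = sigma, nu = nu),
            class = "t_mixture")
}

# multivariate-t log density for one component
.dmvt_log <- function(X, mu, sigma, nu) {
  d <- ncol(X)
  ch <- chol(sigma)
  z <- forwardsolve(t(ch), t(X) - mu)
  q <- colSums(z^2)
  lgamma((nu + d) / 2) - lgamma(nu / 2) - (d / 2) * log(nu * pi) -
    sum(log(diag(ch))) - ((nu + d) / 2) * log1p(q / nu)
}

#' @rdname t_mixture
#' @param mix a `t_mixture`.
#' @param X matrix of row points.
#' @return `dtmix_log`: log mixture density at each row of `X`.
#' @export
dtmix_log <- function(mix, X) {
  X <- if (is.matrix(X)) X else matrix(X, nrow = 1)
  comp <- vapply(seq_along(mix$weights), function(m)
    log(mix$weights[m]) + .dmvt_log(X, mix$mu[m, ], mix$sigma[[m]], mix$nu),
    numeric(nrow(X)))
  comp <- matrix(comp, nrow = nrow(X))
  mx <- apply(comp, 1, max)
  mx + log(rowSums(exp(comp - mx)))
}

#' @rdname t_mixture
#' @param n number of draws.
#' @return `rtmix`: matrix of n draws.
#' @export
rtmix <- function(mix, n) {
  d <- ncol(mix$mu)
  comp <- sample.int(length(mix$weights), n, replace = TRUE,
                     prob = mix$weights)
  out <- matrix(NA_real_, n, d)
  for (m in unique(comp)) {
    idx <- which(comp == m)
    z <- MASS::mvrnorm(length(idx), mu = rep(0, d), Sigma = mix$sigma[[m]])
    z <- matrix(z, ncol = d)
    u <- stats::rchisq(length(idx), df = mix$nu)
    out[idx, ] <- sweep(z / sqrt(u / mix$nu), 2, mix$mu[m, ], `+`)
  }
  out
}

#' One importance-sampling iteration against a tempered target
#'
#' Draws `n` points from the proposal, weights them against the tempered
#' target `f(x)^(1/gamma)`, and attaches the effective sample size
#' `1 / sum(wbar^2)` and the normalized perplexity
#' `exp(-sum(wbar log wbar)) / n`.
#'
#' @param logpost log target density (vector/matrix contract).
#' @param proposal a [t_mixture()].
#' @param n number of importance draws (full study scale 2e5; desk default 5000).
#' @param gamma annealing factor >= 1 (1 = untempered target).
#' @param seed optional seed.
#' @return a `weighted_sample`: draws, log_weights (raw), weights
#'   (normalized), `ess`, `perplexity`, `gamma`.
#' @export
importance_iteration <- function(logpost, proposal, n = 5000L, gamma = 1,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lp <- .vectorize_lp(logpost)
  X <- rtmix(proposal, n)
  lw <- lp(X) / gamma - dtmix_log(proposal, X)
  if (all(!is.finite(lw))) stop("all importance weights are zero")
  lw[!is.finite(lw)] <- -Inf
  m <- max(lw)
  w <- exp(lw - m)
  wbar <- w / sum(w)
  ess <- 1 / sum(wbar^2)
  H <- -sum(wbar[wbar > 0] * log(wbar[wbar > 0]))
  structure(list(draws = X, log_weights = lw, weights = wbar, ess = ess,
                 perplexity = exp(H) / n, gamma = gamma, n = n),
            class = "weighted_sample")
}

#' Update a Student-t mixture proposal from a weighted sample
#'
#' Plain weighted EM update of the mixture: posterior responsibilities under
#' the current mixture, then importance-weighted component weights,
#' locations and scale matrices (Student-t moment weights with fixed
#' degrees of freedom). Components whose scale matrix collapses are pruned
#' with a warning.
#'
#' @param proposal the current [t_mixture()].
#' @param sample a `weighted_sample` from [importance_iteration()].
#' @return the updated `t_mixture`.
#' @export
update_tmixture <- function(proposal, sample) {
  X <- sample$draws
  wbar <- sample$weights
  if (sum(wbar > 0) < 2) stop("weighted sample has no effective draws")
  d <- ncol(X)
  M <- length(proposal$weights)
  comp_log <- vapply(seq_len(M), function(m)
    log(proposal$weights[m]) +
      .dmvt_log(X, proposal$mu[m, ], proposal$sigma[[m]], proposal$nu),
    numeric(nrow(X)))
  comp_log <- matrix(comp_log, nrow = nrow(X))
  mx <- apply(comp_log, 1, max)
  R <- exp(comp_log - mx)
  R <- R / rowSums(R) # responsibilities
  alpha <- colSums(wbar * R)
  keep <- alpha > 1e-12
  mus <- list(); sigmas <- list(); ws <- numeric(0)
  for (m in which(keep)) {
    rw <- wbar * R[, m]
    # Student-t moment weights u = (nu + d) / (nu + mahalanobis)
    ch <- chol(proposal$sigma[[m]])
    z <- forwardsolve(t(ch), t(X) - proposal$mu[m, ])
    u <- (proposal$nu + d) / (proposal$nu + colSums(z^2))
    mu_new <- colSums(X * (rw * u)) / sum(rw * u)
    Xc <- sweep(X, 2, mu_new)
    S <- crossprod(Xc * (rw * u), Xc) / sum(rw)
    S <- (S + t(S)) / 2
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < 1e-12 * max(ev) || max(ev) <= 0) {
      warning("pruning collapsed mixture component")
      next
    }
    mus[[length(mus) + 1]] <- mu_new
    sigmas[[length(sigmas) + 1]] <- S
    ws <- c(ws, alpha[m])
  }
  if (!length(ws)) stop("all mixture components collapsed")
  t_mixture(ws / sum(ws), do.call(rbind, mus), sigmas, nu = proposal$nu)
}

#' Annealed iterated importance sampler
#'
#' Adaptive importance sampling with a Student-t mixture proposal: the
#' initial mixture is centered on supplied mode estimates (e.g. optimizer
#' restarts) with scale matrices from a numerical Hessian of the target;
#' iterations run against the tempered target with annealing factor
#' `gamma_i = max(gamma0 / 2^(i-1), 1)`, updating the proposal after each
#' round, and continue past `gamma = 1` until the relative improvement of
#' the normalized perplexity falls below `perplexity_tol`. The returned
#' posterior draws are an equal-weight resample (with replacement) of the
#' final weighted sample.
#'
#' @param logpost log target (vector/matrix contract).
#' @param lower,upper support box (used to keep Hessian probes inside).
#' @param centers matrix of mode estimates, one row per mixture component.
#' @param n_per_iter importance draws per iteration (default 5000).
#' @param gamma0 initial annealing factor (default 64).
#' @param nu degrees of freedom of the t components (default 5).
#' @param perplexity_tol relative-improvement stopping threshold (default
#'   0.01).
#' @param max_iter iteration cap (default 20).
#' @param seed optional seed.
#' @return list with `draws` (equal-weight resample), `final`
#'   (`weighted_sample`), `proposal`, `perplexity_trace`, `gamma_trace`.
#' @export
iterated_importance_sampler <- function(logpost, lower, upper, centers,
                                        n_per_iter = 5000L, gamma0 = 64,
                                        nu = 5, perplexity_tol = 0.01,
                                        max_iter = 20L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lp <- .vectorize_lp(logpost)
  centers <- if (is.matrix(centers)) centers else matrix(centers, nrow = 1)
  M <- nrow(centers)
  sigmas <- lapply(seq_len(M), function(m)
    .hessian_scale(lp, centers[m, ], lower, upper))
  prop <- t_mixture(rep(1 / M, M), centers, sigmas, nu = nu)
  perp <- numeric(0); gammas <- numeric(0)
  ws <- NULL
  for (i in seq_len(max_iter)) {
    gamma_i <- annealing_gamma(i, gamma0)
    ws <- importance_iteration(lp, prop, n = n_per_iter, gamma = gamma_i)
    prop <- update_tmixture(prop, ws)
    perp <- c(perp, ws$perplexity); gammas <- c(gammas, gamma_i)
    if (gamma_i == 1 && length(perp) >= 2 &&
        gammas[length(gammas) - 1] == 1) {
      rel <- (perp[length(perp)] - perp[length(perp) - 1]) /
        max(perp[length(perp) - 1], 1e-12)
      if (rel < perplexity_tol) break
    }
  }
  # final untempered round with the adapted proposal
  final <- importance_iteration(lp, prop, n = n_per_iter, gamma = 1)
  idx <- sample.int(final$n, final$n, replace = TRUE, prob = final$weights)
  list(draws = final$draws[idx, , drop = FALSE], final = final,
       proposal = prop, perplexity_trace = perp, gamma_trace = gammas)
}

#' Annealing schedule of the iterated importance sampler
#'
#' @param i iteration index (1-based).
#' @param gamma0 initial factor (default 64).
#' @return `max(gamma0 / 2^(i - 1), 1)`.
#' @export
annealing_gamma <- function(i, gamma0 = 64) {
  pmax(gamma0 / 2^(i - 1), 1)
}

# scale matrix from a central-difference Hessian of the log target at a
# mode; falls back to a floored-eigenvalue or diagonal-curvature repair
# when the negative Hessian is not positive definite
.hessian_scale <- function(lp, x, lower, upper, h_frac = 1e-3) {
  d <- length(x)
  h <- pmax((upper - lower) * h_frac, 1e-8)
  clamp <- function(p) pmin(pmax(p, lower), upper)
  H <- matrix(0, d, d)
  f0 <- lp(x)
  for (i in seq_len(d)) {
    ei <- replace(numeric(d), i, h[i])
    H[i, i] <- (lp(clamp(x + ei)) - 2 * f0 + lp(clamp(x - ei))) / h[i]^2
    if (i > 1) for (j in seq_len(i - 1)) {
      ej <- replace(numeric(d), j, h[j])
      H[i, j] <- H[j, i] <-
        (lp(clamp(x + ei + ej)) - lp(clamp(x + ei - ej)) -
           lp(clamp(x - ei + ej)) + lp(clamp(x - ei - ej))) /
        (4 * h[i] * h[j])
    }
  }
  A <- -(H + t(H)) / 2
  eg <- eigen(A, symmetric = TRUE)
  floor_ev <- pmax(eg$values, 1e-6 * max(abs(eg$values), 1))
  Ainv <- eg$vectors %*% diag(1 / floor_ev, d) %*% t(eg$vectors)
  S <- (Ainv + t(Ainv)) / 2
  if (any(!is.finite(S)) ||
      any(eigen(S, symmetric = TRUE, only.values = TRUE)$values <= 0)) {
    S <- diag(pmax((upper - lower) / 20, 1e-4)^2, d)
  }
  S
}

#' Posterior summaries of a chain or weighted sample
#'
#' @param x an `ssm_chain` or the draw matrix from the importance sampler.
#' @param burn_fraction fraction of initial draws discarded for MCMC chains
#'   (default 0.5).
#' @return list with `mean` and `var` per dimension, and the pooled draws.
#' @export
posterior_summary <- function(x, burn_fraction = 0.5) {
  draws <- if (inherits(x, "ssm_chain")) {
    dd <- x$draws
    if (length(dim(dd)) == 3) {
      keep <- seq(floor(dim(dd)[1] * burn_fraction) + 1, dim(dd)[1])
      matrix(aperm(dd[keep, , , drop = FALSE], c(1, 2, 3)),
             ncol = dim(dd)[3])
    } else {
      dd[seq(floor(nrow(dd) * burn_fraction) + 1, nrow(dd)), , drop = FALSE]
    }
  } else as.matrix(x)
  list(mean = colMeans(draws), var = apply(draws, 2, stats::var),
       draws = draws)
}
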