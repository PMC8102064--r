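#' Configuration for analytic likelihood evaluation
#'
#' @param series_tolerance absolute density error bound used to pick the
#'   number of series terms (default 1e-7).
#' @param quad_nodes quadrature nodes per integrated trial-variability
#'   dimension for the full-DDM (default 11).
#' @param likelihood_floor minimum likelihood; evaluations never fall below
#'   it (default 1e-29).
#' @return an `analytic_config` list.
#' @export
analytic_config <- function(series_tolerance = 1e-7, quad_nodes = 11L,
                            likelihood_floor = 1e-29) {
  stopifnot(series_tolerance > 0, quad_nodes >= 2, likelihood_floor > 0)
  structure(list(series_tolerance = series_tolerance,
                 quad_nodes = as.integer(quad_nodes),
                 likelihood_floor = likelihood_floor),
            class = "analytic_config")
}

# First-passage density of the constant-drift, constant-bound diffusion in
# the package's +/- a geometry (boundary separation 2a, relative start w,
# unit noise), via the small-time / large-time series pair with the
# tolerance-driven term counts of the fast series approximation.
#
# All arguments are vectors of equal length (recycled by the callers).
.nf_logpdf <- function(v, a, w, tau, rt, choice, eps = 1e-7, floor = 1e-29) {
  n <- length(rt)
  out <- rep(log(floor), n)
  s <- 2 * a                       # boundary separation
  # density at the *hit* boundary: upper hits mirror to the lower-bound form
  vv <- ifelse(choice > 0, -v, v)
  ww <- ifelse(choice > 0, 1 - w, w)
  t0 <- rt - tau
  ok <- is.finite(t0) & t0 > 0
  if (!any(ok)) return(out)
  u <- t0[ok] / s[ok]^2            # normalized decision time
  vs <- vv[ok] * s[ok]
  wk <- ww[ok]

  # term counts for target density tolerance eps (scaled to unit separation)
  ks <- rep(2, length(u))
  cond <- 2 * sqrt(2 * pi * u) * eps < 1
  ks[cond] <- pmax(2 + sqrt(-2 * u[cond] *
                              log(2 * eps * sqrt(2 * pi * u[cond]))),
                   sqrt(u[cond]) + 1)
  kl <- 1 / (pi * sqrt(u))
  cond <- pi * u * eps < 1
  kl[cond] <- pmax(sqrt(-2 * log(pi * u[cond] * eps) / (pi^2 * u[cond])),
                   1 / (pi * sqrt(u[cond])))
  small <- ks < kl

  f0 <- numeric(length(u))
  if (any(small)) {
    K <- min(ceiling(max(ks[small])), 60)
    kk <- seq(-K, K)
    us <- u[small]; wks <- wk[small]
    arg <- outer(wks, 2 * kk, `+`)               # w + 2k
    f0[small] <- rowSums(arg * exp(-arg^2 / (2 * us))) / sqrt(2 * pi * us^3)
  }
  if (any(!small)) {
    K <- min(ceiling(max(kl[!small])), 200)
    kk <- seq_len(K)
    ul <- u[!small]; wkl <- wk[!small]
    f0[!small] <- pi * rowSums(
      outer(ul, kk, function(uu, k) k * exp(-k^2 * pi^2 * uu / 2)) *
        outer(wkl, kk, function(wwv, k) sin(k * pi * wwv)))
  }
  dens <- pmax(f0, 0) * exp(-vs * wk - vv[ok]^2 * t0[ok] / 2) / s[ok]^2
  out[ok] <- log(pmax(dens, floor))
  out
}

#' Log-likelihood of the simple drift diffusion model
#'
#' Evaluates the log of the defective first-passage-time density of the DDM
#' with parameters theta = (v, a, w, tau) in the symmetric +/- a geometry, by
#' a small-time / large-time series approximation whose branch and term
#' count are selected per datapoint to meet `series_tolerance`. Response
#' times at or before the nondecision time, and any density below
#' `likelihood_floor`, return `log(likelihood_floor)`.
#'
#' Vectorization contract: either `theta` is a single parameter vector and
#' `rt`/`choice` are arrays (per-trial evaluation), or `theta` is a matrix of
#' parameter rows and `rt`/`choice` are scalars (per-parameter evaluation).
#'
#' @param theta DDM parameters (v, a, w, tau), or a matrix with those
#'   columns.
#' @param rt response time(s) in seconds.
#' @param choice choice code(s), -1 (lower) or +1 (upper).
#' @param config an [analytic_config()].
#' @return vector of log-likelihoods.
#' @export
ddm_logpdf <- function(theta, rt, choice, config = analytic_config()) {
  if (is.matrix(theta)) {
    v <- theta[, 1]; a <- theta[, 2]; w <- theta[, 3]; tau <- theta[, 4]
  } else {
    stopifnot(length(theta) == 4)
    v <- theta[[1]]; a <- theta[[2]]; w <- theta[[3]]; tau <- theta[[4]]
  }
  if (any(a <= 0) || any(w <= 0) || any(w >= 1) || any(tau < 0))
    stop("require a > 0, 0 < w < 1, tau >= 0")
  if (!all(choice %in% c(-1, 1))) stop("choice must be -1 or +1")
  n <- max(length(v), length(rt), length(choice))
  .nf_logpdf(rep_len(v, n), rep_len(a, n), rep_len(w, n), rep_len(tau, n),
             rep_len(rt, n), rep_len(choice, n),
             eps = config$series_tolerance, floor = config$likelihood_floor)
}

#' Log-likelihood of the full drift diffusion model
#'
#' Integrates the simple-DDM density over the three trial-wise perturbation
#' laws (drift N(v, sv), start w + U(-sw, sw), nondecision tau + U(-st, st),
#' floored at 0) by tensor-product quadrature: Gauss-Hermite in the normal
#' drift dimension, Gauss-Legendre in the two uniform dimensions. Degenerate
#' dimensions (zero variability) are skipped exactly.
#'
#' @param theta full-DDM parameters (v, a, w, tau, sv, st, sw).
#' @param rt,choice as in [ddm_logpdf()] (per-trial vectorization).
#' @param config an [analytic_config()]; `quad_nodes` controls accuracy.
#' @return vector of log-likelihoods.
#' @export
full_ddm_logpdf <- function(theta, rt, choice, config = analytic_config()) {
  stopifnot(length(theta) == 7)
  v <- theta[[1]]; a <- theta[[2]]; w <- theta[[3]]; tau <- theta[[4]]
  sv <- theta[[5]]; st <- theta[[6]]; sw <- theta[[7]]
  if (sv < 0 || st < 0 || sw < 0) stop("variability parameters must be >= 0")
  if (sw > 0 && (w - sw <= 0 || w + sw >= 1))
    stop("start-point variability puts mass outside (0, 1)")
  m <- config$quad_nodes
  # nodes and normalized weights per dimension (weights sum to 1 = averaging)
  dims <- list()
  if (sv > 0) {
    gh <- .gauss_nodes("hermite", m)
    dims$v <- list(x = v + sqrt(2) * sv * gh$x, w = gh$w / sqrt(pi))
  } else dims$v <- list(x = v, w = 1)
  if (sw > 0) {
    gl <- .gauss_nodes("legendre", m)
    dims$w <- list(x = w - sw + (gl$x + 1) * sw, w = gl$w / 2)
  } else dims$w <- list(x = w, w = 1)
  if (st > 0) {
    gl <- .gauss_nodes("legendre", m)
    dims$tau <- list(x = pmax(0, tau - st + (gl$x + 1) * st), w = gl$w / 2)
  } else dims$tau <- list(x = tau, w = 1)

  grid <- expand.grid(iv = seq_along(dims$v$x), iw = seq_along(dims$w$x),
                      it = seq_along(dims$tau$x))
  wts <- dims$v$w[grid$iv] * dims$w$w[grid$iw] * dims$tau$w[grid$it]
  G <- nrow(grid)
  n <- max(length(rt), length(choice))
  rt <- rep_len(rt, n); choice <- rep_len(choice, n)
  # one flat series evaluation over all (grid node, datapoint) pairs
  lp <- .nf_logpdf(rep(dims$v$x[grid$iv], each = n), rep(a, G * n),
                   rep(dims$w$x[grid$iw], each = n),
                   rep(dims$tau$x[grid$it], each = n),
                   rep(rt, times = G), rep(choice, times = G),
                   eps = config$series_tolerance,
                   floor = .Machine$double.xmin)
  dens <- as.vector(matrix(exp(lp), nrow = n) %*% wts)
  log(pmax(dens, config$likelihood_floor))
}

# quadrature rules are re-used constantly during inference; cache by kind
# and node count (Legendre nodes cached on [-1, 1] and rescaled by callers)
.gauss_cache <- new.env(parent = emptyenv())
.gauss_nodes <- function(kind, m) {
  key <- paste0(kind, m)
  if (!exists(key, envir = .gauss_cache)) {
    r <- if (kind == "hermite") pracma::gaussHermite(m)
         else pracma::gaussLegendre(m, -1, 1)
    assign(key, r, envir = .gauss_cache)
  }
  get(key, envir = .gauss_cache)
}

#' Total upper-boundary probability mass of the simple DDM
#'
#' Computed by adaptive quadrature of the analytic density; used as an
#' independent oracle for simulator choice fractions.
#'
#' @param theta DDM parameters (v, a, w, tau).
#' @param choice which boundary's mass (default +1).
#' @param upper_time integration cap in seconds.
#' @return probability mass in (0, 1).
#' @export
ddm_choice_mass <- function(theta, choice = 1, upper_time = 60) {
  f <- function(t) exp(ddm_logpdf(theta, t, rep(choice, length(t))))
  stats::integrate(f, theta[[4]], theta[[4]] + upper_time,
                   rel.tol = 1e-8, subdivisions = 500L)$value
}
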