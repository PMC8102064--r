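#' Per-choice kernel density estimate of an empirical likelihood
#'
#' Builds the defective empirical likelihood p(c) * f_c(t) from simulated
#' trials: response times are log-transformed per choice, a Gaussian-kernel
#' KDE with Silverman's rule-of-thumb bandwidth (floored at 1e-3) is fitted
#' on the log scale, and densities are mapped back with the 1/t Jacobian -
#' the standard positive-support treatment for skewed response-time data.
#' Censored trials are excluded from the density mass but their existence is
#' recorded. Choices with zero absorbed trials receive the smoothing
#' probability 0.5 / N (half a pseudo-count, other choice probabilities
#' renormalized) and a flat floor density.
#'
#' @param data a `trial_data` object with at least 2 absorbed trials.
#' @param choices choice code set; defaults to the codes recorded on `data`
#'   or observed in it.
#' @param likelihood_floor minimum likelihood (default 1e-29).
#' @return an object of class `choice_kde`.
#' @export
build_kde <- function(data, choices = NULL, likelihood_floor = 1e-29) {
  ab <- absorbed(data)
  if (nrow(ab) < 2) stop("need at least 2 absorbed trials")
  if (any(ab$rt <= 0)) stop("absorbed response times must be positive")
  if (is.null(choices)) choices <- attr(data, "choices")
  if (is.null(choices)) choices <- sort(unique(ab$choice))
  n_sim <- nrow(ab)
  per <- lapply(choices, function(cc) {
    lt <- log(ab$rt[ab$choice == cc])
    n <- length(lt)
    if (n == 0) return(list(n = 0L, log_rt = numeric(0), h = NA_real_))
    h <- .silverman(lt)
    list(n = n, log_rt = lt, h = h)
  })
  names(per) <- as.character(choices)
  counts <- vapply(per, function(p) p$n, 0L)
  p_c <- counts / n_sim
  zero <- counts == 0L
  if (any(zero)) {
    p_c[zero] <- 0.5 / n_sim
    p_c[!zero] <- p_c[!zero] * (1 - sum(p_c[zero]))
  }
  structure(list(choices = choices, per_choice = per, p_choice = p_c,
                 n_sim = n_sim,
                 censored_fraction = 1 - n_sim / nrow(data),
                 floor = likelihood_floor),
            class = "choice_kde")
}

# Silverman's rule of thumb on the (log) samples, floored at 1e-3
.silverman <- function(x) {
  n <- length(x)
  if (n < 2) return(1e-3)
  sdx <- stats::sd(x)
  iqr <- stats::IQR(x) / 1.34
  spread <- min(sdx, iqr)
  if (!is.finite(spread) || spread <= 0) spread <- sdx
  h <- 0.9 * spread * n^(-1 / 5)
  if (!is.finite(h) || h < 1e-3) h <- 1e-3
  h
}

#' Evaluate a per-choice KDE log-likelihood
#'
#' Returns `log(max(p(c) * f_c(rt), floor))`; non-positive response times
#' return `log(floor)` (no mass at or before zero).
#'
#' @param kde a [build_kde()] object.
#' @param rt response time(s) in seconds.
#' @param choice choice code(s), recycled against `rt`.
#' @return vector of log-likelihoods, never below `log(floor)`.
#' @export
kde_logpdf <- function(kde, rt, choice) {
  n <- max(length(rt), length(choice))
  rt <- rep_len(rt, n); choice <- rep_len(choice, n)
  if (!all(choice %in% kde$choices)) stop("unknown choice code")
  out <- rep(log(kde$floor), n)
  pos <- rt > 0
  for (cc in unique(choice[pos])) {
    idx <- pos & choice == cc
    p <- kde$per_choice[[as.character(cc)]]
    pc <- kde$p_choice[[as.character(cc)]]
    if (p$n == 0L) next # flat floor density for unseen choices
    y <- log(rt[idx])
    # mean Gaussian kernel on the log scale, Jacobian 1/t back-transform
    dens <- vapply(y, function(yy)
      mean(stats::dnorm((yy - p$log_rt) / p$h)) / p$h, 0) / rt[idx]
    out[idx] <- log(pmax(pc * dens, kde$floor))
  }
  out
}

#' Sample (rt, choice) pairs from a fitted per-choice KDE
#'
#' Draws a stored trial uniformly and jitters its log response time by the
#' kernel; used for the "where it matters" component of the training-data
#' mixture.
#'
#' @param kde a [build_kde()] object.
#' @param n number of draws.
#' @return data.frame with columns `rt`, `choice`.
#' @export
kde_sample <- function(kde, n) {
  nz <- kde$choices[vapply(kde$per_choice, function(p) p$n > 0L, TRUE)]
  probs <- kde$p_choice[as.character(nz)]
  probs <- probs / sum(probs)
  cc <- sample(nz, n, replace = TRUE, prob = probs)
  rt <- numeric(n)
  for (c1 in unique(cc)) {
    idx <- cc == c1
    p <- kde$per_choice[[as.character(c1)]]
    base <- sample(p$log_rt, sum(idx), replace = TRUE)
    rt[idx] <- exp(base + p$h * stats::rnorm(sum(idx)))
  }
  data.frame(rt = rt, choice = as.integer(cc))
}

#' Bin simulated trials into a normalized likelihood histogram
#'
#' Counts of (choice, response-time bin) over uniform, half-open bins
#' `[i*D, (i+1)*D)` with `D = t_max / n_bins`, divided by the number of
#' absorbed trials. Response times at or beyond `t_max` fall into the last
#' bin; censored trials are excluded.
#'
#' @param data a `trial_data` with at least 1 absorbed trial.
#' @param n_bins number of response-time bins (default 512).
#' @param t_max histogram time range in seconds (default 20).
#' @param choices choice code set (defaults as in [build_kde()]).
#' @return a `likelihood_histogram`: matrix (choices x bins) summing to 1,
#'   with attributes `choices`, `t_max`, `breaks`.
#' @export
build_histogram <- function(data, n_bins = 512L, t_max = 20, choices = NULL) {
  ab <- absorbed(data)
  if (nrow(ab) == 0) stop("no absorbed trials to bin")
  if (is.null(choices)) choices <- attr(data, "choices")
  if (is.null(choices)) choices <- sort(unique(ab$choice))
  n_bins <- as.integer(n_bins)
  delta <- t_max / n_bins
  bin <- pmin(floor(ab$rt / delta), n_bins - 1L)
  grid <- matrix(0, nrow = length(choices), ncol = n_bins,
                 dimnames = list(as.character(choices), NULL))
  for (i in seq_along(choices)) {
    tb <- tabulate(bin[ab$choice == choices[i]] + 1L, nbins = n_bins)
    grid[i, ] <- tb
  }
  grid <- grid / nrow(ab)
  structure(grid, class = c("likelihood_histogram", "matrix"),
            choices = choices, t_max = t_max, n_bins = n_bins)
}

#' Bin observed trials to counts on a histogram grid
#'
#' @param data a `trial_data`.
#' @param n_bins,t_max,choices grid definition as in [build_histogram()].
#' @return integer matrix of counts (choices x bins).
#' @export
bin_counts <- function(data, n_bins = 512L, t_max = 20, choices = NULL) {
  ab <- absorbed(data)
  if (is.null(choices)) choices <- attr(data, "choices")
  if (is.null(choices)) choices <- sort(unique(ab$choice))
  delta <- t_max / as.integer(n_bins)
  bin <- pmin(floor(ab$rt / delta), n_bins - 1L)
  out <- matrix(0L, nrow = length(choices), ncol = n_bins)
  for (i in seq_along(choices))
    out[i, ] <- tabulate(bin[ab$choice == choices[i]] + 1L, nbins = n_bins)
  out
}
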