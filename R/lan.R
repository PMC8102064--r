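#' Evaluate a pointwise likelihood network
#'
#' One forward pass through a trained pointwise (MLP) network. Either
#' `theta` is a single parameter vector and `rt`/`choice` are per-trial
#' arrays, or `theta` is a matrix of parameter rows and `rt`/`choice` are
#' scalars. Parameter values outside the trained ranges are legal but
#' flagged with a warning (the network extrapolates there).
#'
#' @param lan a `trained_lan` of kind `"pointwise"`.
#' @param theta parameter vector or matrix.
#' @param rt response time(s) in seconds.
#' @param choice choice code(s).
#' @param spec optional `ssm_model` used to check the model pairing and the
#'   trained ranges.
#' @return vector of approximate log-likelihoods.
#' @export
lan_logpdf <- function(lan, theta, rt, choice, spec = NULL) {
  stopifnot(inherits(lan, "trained_lan"))
  if (lan$kind != "pointwise") stop("lan is not a pointwise network")
  .check_pairing(lan, spec)
  if (!is.matrix(theta)) theta <- matrix(theta, nrow = 1)
  n <- max(nrow(theta), length(rt), length(choice))
  if (nrow(theta) == 1 && n > 1)
    theta <- theta[rep(1, n), , drop = FALSE]
  X <- cbind(theta, rep_len(rt, n), rep_len(choice, n))
  if (ncol(X) != length(lan$norm$mu))
    stop("feature dimension mismatch for this network")
  if (!is.null(spec)) .flag_out_of_range(spec, theta)
  Xs <- sweep(sweep(X, 2, lan$norm$mu), 2, lan$norm$sd, `/`)
  L <- length(lan$params) / 2
  drop(mlp_forward_cpp(lan$params[paste0("W", seq_len(L))],
                       lan$params[paste0("b", seq_len(L))], Xs))
}

#' Evaluate a histogram likelihood network
#'
#' One forward pass through a trained histogram (CNN) network: maps a
#' parameter vector to a normalized likelihood histogram over the
#' (choice x time-bin) grid. The softmax output sums to 1 by construction
#' and every cell is strictly positive.
#'
#' @param lan a `trained_lan` of kind `"histogram"`.
#' @param theta parameter vector (or matrix of rows for batch evaluation).
#' @param spec optional `ssm_model` for pairing checks.
#' @return for a single theta, a `likelihood_histogram` matrix
#'   (choices x bins); for a matrix input, a plain matrix with one
#'   flattened histogram per row.
#' @export
lan_histogram <- function(lan, theta, spec = NULL) {
  stopifnot(inherits(lan, "trained_lan"))
  if (lan$kind != "histogram") stop("lan is not a histogram network")
  .check_pairing(lan, spec)
  single <- !is.matrix(theta)
  if (single) theta <- matrix(theta, nrow = 1)
  if (!is.null(spec)) .flag_out_of_range(spec, theta)
  Xs <- sweep(sweep(theta, 2, lan$norm$mu), 2, lan$norm$sd, `/`)
  P <- exp(.cnn_forward(lan$params, lan$net, Xs))
  if (single) {
    grid <- matrix(P[1, ], nrow = lan$net$n_choices, byrow = TRUE,
                   dimnames = list(as.character(lan$choices), NULL))
    return(structure(grid, class = c("likelihood_histogram", "matrix"),
                     choices = lan$choices, t_max = lan$t_max,
                     n_bins = lan$n_bins))
  }
  P
}

#' Dataset log-likelihood under a histogram network
#'
#' Bins the observed trials once onto the network's grid and computes
#' `sum(count(cell) * log(pred(cell)))`; the cost is independent of the
#' number of trials. Vectorized over parameter rows.
#'
#' @param lan a `trained_lan` of kind `"histogram"`.
#' @param theta parameter vector or matrix of rows.
#' @param data a `trial_data`, or a precomputed count matrix from
#'   [bin_counts()] on the network's grid.
#' @return vector of dataset log-likelihoods (one per theta row).
#' @export
dataset_loglik_histogram <- function(lan, theta, data) {
  stopifnot(inherits(lan, "trained_lan"), lan$kind == "histogram")
  counts <- if (inherits(data, "trial_data"))
    bin_counts(data, n_bins = lan$n_bins, t_max = lan$t_max,
               choices = lan$choices)
  else data
  cvec <- as.vector(t(counts)) # choice-major blocks, matching the output
  if (!is.matrix(theta)) theta <- matrix(theta, nrow = 1)
  Xs <- sweep(sweep(theta, 2, lan$norm$mu), 2, lan$norm$sd, `/`)
  logp <- .cnn_forward(lan$params, lan$net, Xs)
  drop(logp %*% cvec)
}

.check_pairing <- function(lan, spec) {
  if (!is.null(spec) && !is.null(lan$model) && spec$name != lan$model)
    stop("network was trained for model '", lan$model,
         "', not '", spec$name, "'")
}

.flag_out_of_range <- function(spec, theta) {
  b <- range_bounds(spec)
  d <- length(b$lower)
  th <- theta[, seq_len(d), drop = FALSE]
  out <- sweep(th, 2, b$lower, `<`) | sweep(th, 2, b$upper, `>`)
  if (any(out))
    warning("evaluating outside the trained parameter region")
  invisible(any(out))
}

#' Save / load a trained network as JSON
#'
#' Serializes the architecture descriptor, weight tensors, input
#' normalization and provenance to a single JSON file at full floating
#' point precision, so that a reloaded network reproduces its outputs
#' bitwise.
#'
#' @param lan a `trained_lan`.
#' @param path file path (conventionally `.json`).
#' @export
save_lan <- function(lan, path) {
  ser <- unclass(lan)
  ser$params <- lapply(lan$params, function(p)
    list(dim = if (is.null(dim(p))) length(p) else dim(p),
         data = as.numeric(p)))
  ser$history <- NULL
  ser$config <- unclass(ser$config)
  # 17 significant digits round-trips IEEE doubles exactly
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

#' @rdname save_lan
#' @return `load_lan` returns the reconstructed `trained_lan`.
#' @export
load_lan <- function(path) {
  ser <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- lapply(ser$params, function(p) {
    d <- as.integer(p$dim)
    if (length(d) == 1) as.numeric(p$data)
    else array(as.numeric(p$data), dim = d)
  })
  lan <- ser
  lan$params <- params
  lan$norm <- list(mu = as.numeric(ser$norm$mu), sd = as.numeric(ser$norm$sd))
  if (!is.null(ser$net))
    lan$net <- list(n_bins = as.integer(ser$net$n_bins),
                    n_choices = as.integer(ser$net$n_choices))
  if (!is.null(lan$t_max)) lan$t_max <- as.numeric(lan$t_max)
  if (!is.null(lan$n_bins)) lan$n_bins <- as.integer(lan$n_bins)
  if (!is.null(lan$choices)) lan$choices <- as.integer(lan$choices)
  class(lan) <- "trained_lan"
  lan
}

#' @export
print.trained_lan <- function(x, ...) {
  cat("<trained_lan>", x$kind, "network for model", x$model, "\n")
  cat("  epochs:", x$epochs_run,
      " final val loss:", signif(utils::tail(x$history$validation, 1), 4),
      "\n")
  invisible(x)
}
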