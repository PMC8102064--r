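#' Sequential sampling model specifications
#'
#' A model specification bundles everything the simulator, the training-data
#' generator and the inference harness need to know about one generative
#' model: the ordered parameter names, the box of parameter ranges over which
#' likelihood networks are trained (the "trained region"), the number of
#' choice alternatives and the drift / noise / boundary laws.
#'
#' Registered models:
#' \describe{
#'   \item{`ddm`}{standard drift diffusion model, theta = (v, a, w, tau);
#'     symmetric fixed bounds at +/- a, start (2w-1)a, unit Gaussian noise.}
#'   \item{`full_ddm`}{DDM with trial-to-trial variability,
#'     theta = (v, a, w, tau, sv, st, sw): per-trial drift v + N(0, sv),
#'     nondecision tau + U(-st, st), start w + U(-sw, sw).}
#'   \item{`ou`}{Ornstein-Uhlenbeck: state-dependent drift v + g x;
#'     theta = (v, a, w, tau, g). g = 0 recovers the DDM.}
#'   \item{`levy`}{Levy flight: alpha-stable increments L(alpha, 0, 1, 0)
#'     scaled by dt^(1/alpha); theta = (v, a, w, tau, alpha).}
#'   \item{`ddm_weibull`}{DDM with Weibull collapsing bound
#'     B(t) = a exp(-t^beta / alpha); theta = (v, w, tau, a, alpha, beta).}
#'   \item{`ddm_lc`}{DDM with linearly collapsing bound
#'     B(t) = a - t tan(angle); theta = (v, w, tau, a, angle).}
#'   \item{`race_N`}{N-accumulator race to a shared bound a,
#'     theta = (v1..vN, a, w1..wN, ndt); see [race_model()].}
#' }
#'
#' Two-choice models code choices as -1 (lower bound) and +1 (upper bound);
#' the race model codes them 0..N-1.
#'
#' @param name model identifier (see above); `"race_3"` etc. is accepted as
#'   shorthand for `race_model(3)`.
#' @param ranges optional named list of length-2 numeric vectors overriding
#'   the default trained ranges for a subset of parameters.
#' @param weibull_alternative if `TRUE` the Weibull bound uses the
#'   alternative reading a exp(-(t/beta)^alpha).
#' @return an object of class `ssm_model`: a list with fields `name`,
#'   `param_names`, `ranges` (named list of c(lower, upper)), `n_choices`,
#'   `choices` (the legal choice codes) and internal simulator selectors.
#' @examples
#' m <- ssm_model("ddm")
#' m$param_names
#' @export
ssm_model <- function(name, ranges = NULL, weibull_alternative = FALSE) {
  if (grepl("^race_[0-9]+$", name)) {
    return(race_model(as.integer(sub("race_", "", name)), ranges = ranges))
  }
  base <- switch(name,
    ddm = list(
      param_names = c("v", "a", "w", "tau"),
      ranges = .default_ranges[c("v", "a", "w", "tau")],
      drift = "constant", noise = "gaussian", bound = "constant"),
    full_ddm = list(
      param_names = c("v", "a", "w", "tau", "sv", "st", "sw"),
      ranges = .default_ranges[c("v", "a", "w", "tau", "sv", "st", "sw")],
      drift = "constant", noise = "gaussian", bound = "constant"),
    ou = list(
      param_names = c("v", "a", "w", "tau", "g"),
      ranges = .default_ranges[c("v", "a", "w", "tau", "g")],
      drift = "linear_state", noise = "gaussian", bound = "constant"),
    levy = list(
      param_names = c("v", "a", "w", "tau", "alpha"),
      ranges = .default_ranges[c("v", "a", "w", "tau", "alpha")],
      drift = "constant", noise = "alpha_stable", bound = "constant"),
    ddm_weibull = list(
      param_names = c("v", "w", "tau", "a", "alpha", "beta"),
      ranges = .default_ranges[c("v", "w", "tau", "a", "alpha_wb", "beta_wb")],
      drift = "constant", noise = "gaussian", bound = "weibull"),
    ddm_lc = list(
      param_names = c("v", "w", "tau", "a", "angle"),
      ranges = .default_ranges[c("v", "w", "tau", "a", "angle")],
      drift = "constant", noise = "gaussian", bound = "linear_collapse"),
    stop("unknown model: ", name)
  )
  names(base$ranges) <- base$param_names
  spec <- c(list(name = name, n_choices = 2L, choices = c(-1L, 1L),
                 n_accumulators = 1L,
                 weibull_alternative = isTRUE(weibull_alternative)), base)
  class(spec) <- "ssm_model"
  .override_ranges(spec, ranges)
}

# trained-region defaults; chosen to yield response-time distributions broader
# than typically observed so that realistic datasets fall inside the box
.default_ranges <- list(
  v = c(-3, 3), a = c(0.3, 2.5), w = c(0.1, 0.9), tau = c(0, 2),
  g = c(-1, 1), alpha = c(1.01, 2), sv = c(0, 2), st = c(0, 0.25),
  sw = c(0, 0.1), alpha_wb = c(0.3, 5), beta_wb = c(0.3, 7),
  angle = c(0, 1.45), ndt = c(0, 2)
)

#' N-accumulator race model specification
#'
#' @param n_accumulators number of racing accumulators (= choices), >= 2.
#' @param ranges optional range overrides as in [ssm_model()].
#' @return an `ssm_model` with parameters (v1..vN, a, w1..wN, ndt) and
#'   choice codes 0..N-1 (index of the winning accumulator).
#' @export
race_model <- function(n_accumulators, ranges = NULL) {
  n <- as.integer(n_accumulators)
  stopifnot(n >= 2L)
  pn <- c(paste0("v", seq_len(n)), "a", paste0("w", seq_len(n)), "ndt")
  rg <- c(rep(list(c(0, 2.5)), n), list(.default_ranges$a),
          rep(list(.default_ranges$w), n), list(.default_ranges$ndt))
  names(rg) <- pn
  spec <- list(name = paste0("race_", n), param_names = pn, ranges = rg,
               n_choices = n, choices = 0:(n - 1L), n_accumulators = n,
               drift = "constant", noise = "gaussian", bound = "constant",
               weibull_alternative = FALSE)
  class(spec) <- "ssm_model"
  .override_ranges(spec, ranges)
}

.override_ranges <- function(spec, ranges) {
  if (!is.null(ranges)) {
    for (nm in names(ranges)) {
      if (!nm %in% spec$param_names)
        stop("range override for unknown parameter: ", nm)
      r <- as.numeric(ranges[[nm]])
      if (length(r) != 2 || !all(is.finite(r)) || r[1] >= r[2])
        stop("invalid range for ", nm, ": need finite lower < upper")
      spec$ranges[[nm]] <- r
    }
  }
  stopifnot(length(spec$ranges) == length(spec$param_names))
  spec
}

#' List registered model names
#' @return character vector of model identifiers accepted by [ssm_model()].
#' @export
list_models <- function() {
  c("ddm", "full_ddm", "ou", "levy", "ddm_weibull", "ddm_lc", "race_N")
}

#' @export
print.ssm_model <- function(x, ...) {
  cat("<ssm_model>", x$name, "|", x$n_choices, "choices\n")
  rr <- vapply(x$ranges, function(r) sprintf("[%g, %g]", r[1], r[2]), "")
  cat(paste0("  ", format(x$param_names), "  ", rr, collapse = "\n"), "\n")
  invisible(x)
}

#' Validate a parameter vector against a model specification
#'
#' @param spec an `ssm_model`.
#' @param theta numeric vector (optionally named) aligned with
#'   `spec$param_names`.
#' @param strict error (`TRUE`, default) or warn-and-flag when theta falls
#'   outside the trained ranges.
#' @return theta (named), invisibly flagged with attribute `out_of_range`.
#' @export
check_theta <- function(spec, theta, strict = TRUE) {
  if (!is.numeric(theta) || length(theta) != length(spec$param_names))
    stop("theta must be numeric of length ", length(spec$param_names),
         " for model ", spec$name)
  if (any(!is.finite(theta))) stop("theta contains non-finite values")
  if (!is.null(names(theta)) && all(spec$param_names %in% names(theta)))
    theta <- theta[spec$param_names]
  names(theta) <- spec$param_names
  lo <- vapply(spec$ranges, `[`, 0, 1)
  hi <- vapply(spec$ranges, `[`, 0, 2)
  out <- theta < lo | theta > hi
  if (any(out)) {
    msg <- paste0("theta outside trained range: ",
                  paste(spec$param_names[out], collapse = ", "))
    if (strict) stop(msg) else warning(msg)
  }
  attr(theta, "out_of_range") <- any(out)
  theta
}

#' Lower/upper bounds of the trained parameter box
#'
#' @param spec an [ssm_model()].
#' @return list with numeric vectors `lower` and `upper` in
#'   `spec$param_names` order.
#' @export
range_bounds <- function(spec) {
  list(lower = vapply(spec$ranges, `[`, 0, 1),
       upper = vapply(spec$ranges, `[`, 0, 2))
}
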