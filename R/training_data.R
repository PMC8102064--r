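#' Training budget for likelihood-network corpora
#'
#' Bundles the sizes and mixture constants that define a training corpus.
#' Full-study presets are 1.5e6 (pointwise) / 3e6 (histogram) parameter
#' vectors with 1e5 simulations each; desk-scale defaults are deliberately
#' small so that corpora regenerate in minutes.
#'
#' @param n_param_vectors number of accepted parameter vectors.
#' @param sims_per_vector simulations per parameter vector.
#' @param points_per_vector training datapoints drawn per parameter vector
#'   (pointwise corpora; default 1000).
#' @param mixture_probs probabilities of the three datapoint components:
#'   KDE resample ("where it matters"), Uniform on `uniform_pos_range`, and
#'   Uniform on `uniform_neg_range`; default c(0.8, 0.1, 0.1).
#' @param uniform_pos_range,uniform_neg_range supports of the uniform
#'   components in seconds (defaults `[0, 20]` and `[-1, 0]`).
#' @param seed integer seed making corpus generation reproducible.
#' @return a `training_budget` list.
#' @export
training_budget <- function(n_param_vectors = 10000L,
                            sims_per_vector = 10000L,
                            points_per_vector = 1000L,
                            mixture_probs = c(0.8, 0.1, 0.1),
                            uniform_pos_range = c(0, 20),
                            uniform_neg_range = c(-1, 0),
                            seed = 1L) {
  stopifnot(n_param_vectors >= 1, sims_per_vector >= 1,
            points_per_vector >= 1, length(mixture_probs) == 3,
            abs(sum(mixture_probs) - 1) < 1e-12)
  structure(list(n_param_vectors = as.integer(n_param_vectors),
                 sims_per_vector = as.integer(sims_per_vector),
                 points_per_vector = as.integer(points_per_vector),
                 mixture_probs = mixture_probs,
                 uniform_pos_range = uniform_pos_range,
                 uniform_neg_range = uniform_neg_range,
                 seed = as.integer(seed)),
            class = "training_budget")
}

#' Sample parameter vectors uniformly over the trained region
#'
#' Draws uniformly over the box of parameter ranges and rejects vectors
#' whose pilot simulations are defective (one-sided choices, ultra-
#' concentrated or overly slow response times, see [screen_defective()]).
#'
#' @param spec an [ssm_model()].
#' @param n number of accepted vectors to return.
#' @param seed integer seed.
#' @param pilot_trials pilot simulation size per candidate (default 1000).
#' @param dt,t_max simulator settings for the pilot runs.
#' @return matrix (n x n_params) of accepted vectors, with attribute
#'   `n_rejected`.
#' @export
sample_parameter_space <- function(spec, n, seed = NULL, pilot_trials = 1000L,
                                   dt = 0.001, t_max = 20) {
  if (!is.null(seed)) set.seed(seed)
  b <- range_bounds(spec)
  d <- length(spec$param_names)
  out <- matrix(NA_real_, nrow = n, ncol = d,
                dimnames = list(NULL, spec$param_names))
  accepted <- 0L; tried <- 0L
  cfg <- sim_config(dt = dt, t_max = t_max, n_trials = pilot_trials)
  while (accepted < n) {
    th <- b$lower + stats::runif(d) * (b$upper - b$lower)
    tried <- tried + 1L
    if (tried > 100L && accepted / tried < 0.01)
      stop("acceptance rate below 1%; check parameter ranges")
    dat <- simulate_trials(spec, th, cfg)
    if (!screen_defective(dat)$defective) {
      accepted <- accepted + 1L
      out[accepted, ] <- th
    }
  }
  attr(out, "n_rejected") <- tried - n
  out
}

#' Build a pointwise (MLP) training corpus
#'
#' For each accepted parameter vector: simulate, fit the per-choice KDE,
#' draw `points_per_vector` datapoints from the three-component mixture
#' (KDE resample / Uniform positive / Uniform negative), and label them -
#' positive response times by the KDE log-likelihood (or the analytic DDM
#' log-likelihood when `labels = "analytic"`), negative ones by the training
#' floor log(1e-29). Choices for the uniform components are drawn uniformly
#' from the model's choice set.
#'
#' @param spec an [ssm_model()].
#' @param budget a [training_budget()].
#' @param labels `"kde"` (default) or `"analytic"` (simple DDM only; labels
#'   by [ddm_logpdf()], no simulation needed).
#' @param theta optional pre-sampled parameter matrix (bypasses
#'   [sample_parameter_space()]).
#' @param dt,t_max simulator settings.
#' @return an `mlp_training_set`: list with `features` (theta columns, rt,
#'   choice), `labels`, `component` (1 = KDE, 2 = uniform positive,
#'   3 = uniform negative), and provenance metadata.
#' @export
make_mlp_training_set <- function(spec, budget = training_budget(),
                                  labels = c("kde", "analytic"),
                                  theta = NULL, dt = 0.001, t_max = 20) {
  labels <- match.arg(labels)
  if (labels == "analytic" && spec$name != "ddm")
    stop("analytic labels are available for the simple DDM only")
  set.seed(budget$seed)
  if (is.null(theta))
    theta <- sample_parameter_space(spec, budget$n_param_vectors)
  npt <- budget$points_per_vector
  d <- ncol(theta)
  feats <- vector("list", nrow(theta))
  labs <- vector("list", nrow(theta))
  comps <- vector("list", nrow(theta))
  keep <- logical(nrow(theta))
  cfg <- sim_config(dt = dt, t_max = t_max, n_trials = budget$sims_per_vector)

  for (i in seq_len(nrow(theta))) {
    th <- theta[i, ]
    kde <- NULL
    if (labels == "kde") {
      dat <- simulate_trials(spec, th, cfg, strict = FALSE)
      if (screen_defective(dat)$defective || nrow(absorbed(dat)) < 2) next
      kde <- build_kde(dat, choices = spec$choices)
    }
    comp <- sample.int(3L, npt, replace = TRUE, prob = budget$mixture_probs)
    rt <- numeric(npt); ch <- integer(npt)
    n1 <- sum(comp == 1L)
    if (n1 > 0) {
      if (labels == "kde") {
        s <- kde_sample(kde, n1)
        rt[comp == 1L] <- s$rt; ch[comp == 1L] <- s$choice
      } else {
        # analytic labels: resample "where it matters" from the model itself
        s <- simulate_trials(spec, th, sim_config(n_trials = max(n1, 2)),
                             strict = FALSE)
        s <- absorbed(s)
        if (nrow(s) < 1) next
        idx <- sample.int(nrow(s), n1, replace = TRUE)
        rt[comp == 1L] <- s$rt[idx]; ch[comp == 1L] <- s$choice[idx]
      }
    }
    for (k in 2:3) {
      nk <- sum(comp == k)
      if (nk == 0) next
      rg <- if (k == 2L) budget$uniform_pos_range else budget$uniform_neg_range
      rt[comp == k] <- stats::runif(nk, rg[1], rg[2])
      ch[comp == k] <- sample(spec$choices, nk, replace = TRUE)
    }
    lab <- rep(log(1e-29), npt)
    pos <- rt > 0
    if (labels == "kde") {
      lab[pos] <- kde_logpdf(kde, rt[pos], ch[pos])
    } else {
      lab[pos] <- ddm_logpdf(th, rt[pos], ch[pos])
    }
    feats[[i]] <- cbind(matrix(th, nrow = npt, ncol = d, byrow = TRUE),
                        rt, ch)
    labs[[i]] <- lab
    comps[[i]] <- comp
    keep[i] <- TRUE
  }
  if (!any(keep)) stop("all parameter vectors were screened out")
  features <- do.call(rbind, feats[keep])
  colnames(features) <- c(spec$param_names, "rt", "choice")
  structure(list(features = features,
                 labels = unlist(labs[keep]),
                 component = unlist(comps[keep]),
                 theta_id = rep(which(keep), each = npt),
                 theta = theta[keep, , drop = FALSE],
                 model = spec$name, labels_source = labels,
                 budget = budget, n_screened = sum(!keep)),
            class = "mlp_training_set")
}

#' Build a histogram (CNN) training corpus
#'
#' For each accepted parameter vector, simulates `sims_per_vector` trials
#' and bins them into a normalized (choices x bins) histogram label; the
#' parameter vector is the feature row.
#'
#' @param spec an [ssm_model()].
#' @param budget a [training_budget()].
#' @param n_bins,t_max histogram grid (defaults 512 bins over 20 s).
#' @param theta optional pre-sampled parameter matrix.
#' @param dt simulator step size.
#' @return a `cnn_training_set`: list with `features` (theta rows) and
#'   `labels` (n x (choices*bins) matrix, rows summing to 1).
#' @export
make_cnn_training_set <- function(spec, budget = training_budget(),
                                  n_bins = 512L, t_max = 20, theta = NULL,
                                  dt = 0.001) {
  set.seed(budget$seed)
  if (is.null(theta))
    theta <- sample_parameter_space(spec, budget$n_param_vectors)
  cfg <- sim_config(dt = dt, t_max = t_max,
                    n_trials = budget$sims_per_vector)
  keep <- logical(nrow(theta))
  labs <- vector("list", nrow(theta))
  for (i in seq_len(nrow(theta))) {
    dat <- simulate_trials(spec, theta[i, ], cfg, strict = FALSE)
    if (screen_defective(dat)$defective || nrow(absorbed(dat)) == 0) next
    h <- build_histogram(dat, n_bins = n_bins, t_max = t_max,
                         choices = spec$choices)
    labs[[i]] <- as.vector(t(unclass(h))) # row-major: choice-blocks of bins
    keep[i] <- TRUE
  }
  if (!any(keep)) stop("all parameter vectors were screened out")
  structure(list(features = theta[keep, , drop = FALSE],
                 labels = do.call(rbind, labs[keep]),
                 model = spec$name, n_bins = as.integer(n_bins),
                 t_max = t_max, choices = spec$choices,
                 budget = budget, n_screened = sum(!keep)),
            class = "cnn_training_set")
}

#' Write / read a training corpus as delimited text plus JSON metadata
#'
#' Feature and label arrays go to `<path>.csv` (data.table CSV); metadata
#' (model, budget, provenance) to `<path>.json`.
#'
#' @param x an `mlp_training_set` or `cnn_training_set`.
#' @param path file stem (no extension).
#' @export
write_training_set <- function(x, path) {
  meta <- list(class = class(x), model = x$model,
               budget = unclass(x$budget), n_screened = x$n_screened,
               labels_source = x$labels_source, n_bins = x$n_bins,
               t_max = x$t_max, choices = x$choices,
               package_version = as.character(utils::packageVersion("lanssm")))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  tab <- if (inherits(x, "mlp_training_set")) {
    cbind(as.data.frame(x$features), label = x$labels,
          component = x$component, theta_id = x$theta_id)
  } else {
    cbind(as.data.frame(x$features),
          as.data.frame(x$labels))
  }
  data.table::fwrite(tab, paste0(path, ".csv"))
  invisible(path)
}

#' @rdname write_training_set
#' @param path file stem used by `write_training_set`.
#' @return `read_training_set` reconstructs the training-set object.
#' @export
read_training_set <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  tab <- as.data.frame(data.table::fread(paste0(path, ".csv")))
  if ("mlp_training_set" %in% meta$class) {
    fc <- setdiff(names(tab), c("label", "component", "theta_id"))
    structure(list(features = as.matrix(tab[fc]), labels = tab$label,
                   component = tab$component, theta_id = tab$theta_id,
                   model = meta$model, labels_source = meta$labels_source,
                   n_screened = meta$n_screened),
              class = "mlp_training_set")
  } else {
    d <- length(meta$choices) * meta$n_bins
    nf <- ncol(tab) - d
    structure(list(features = as.matrix(tab[seq_len(nf)]),
                   labels = as.matrix(tab[nf + seq_len(d)]),
                   model = meta$model, n_bins = as.integer(meta$n_bins),
                   t_max = meta$t_max,
                   choices = as.integer(meta$choices),
                   n_screened = meta$n_screened),
              class = "cnn_training_set")
  }
}
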