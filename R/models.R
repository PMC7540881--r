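#' Configuration for a presence-only suitability algorithm
#'
#' Three deterministic algorithm families are provided behind one interface,
#' so that an ensemble of [0,1] predictions can be built, evaluated and
#' combined by consensus. Additional algorithms can be plugged in by giving
#' `fit_niche_model()`/`predict()` methods for a new class.
#'
#' * `bioclim` — classic climate-envelope: suitability 1 inside the core
#'   envelope (mean +/- `sd_cutoff` standard deviations on every variable),
#'   0.5 inside the min-max envelope, else 0. `sd_cutoff` defaults to 0.674,
#'   the half-probability envelope of a normal distribution.
#' * `envelope_score` — the fraction of variables whose cell value lies
#'   within the training min-max range.
#' * `env_distance` — variables are rescaled to [0,1] by their study-area
#'   range; suitability is `max(0, 1 - d/d_max)` where `d` is the distance
#'   (`euclidean`, `mahalanobis`, `gower` or `chebyshev`) from the cell to
#'   the mean of its `n_nearest_points` nearest training points, and
#'   `d_max = max_distance_fraction` times the metric-specific maximum
#'   (sqrt(p) for euclidean, 1 for gower/chebyshev, and the largest distance
#'   observed over the study area for mahalanobis, which has no finite
#'   theoretical bound).
#'
#' @param algorithm One of `"bioclim"`, `"envelope_score"`, `"env_distance"`.
#' @param sd_cutoff Bioclim core-envelope width in standard deviations.
#' @param metric Distance metric for `env_distance`.
#' @param max_distance_fraction Fraction of the metric maximum at which
#'   suitability reaches 0 (default 0.5).
#' @param n_nearest_points Number of nearest training points averaged before
#'   the distance is taken (default 1).
#' @param model_id Optional identifier used in consensus provenance.
#' @return An `algorithm_config` object.
#' @export
algorithm_config <- function(algorithm = c("bioclim", "envelope_score",
                                           "env_distance"),
                             sd_cutoff = 0.674,
                             metric = c("euclidean", "mahalanobis", "gower",
                                        "chebyshev"),
                             max_distance_fraction = 0.5,
                             n_nearest_points = 1,
                             model_id = NULL) {
  algorithm <- match.arg(algorithm)
  metric <- match.arg(metric)
  stopifnot(sd_cutoff > 0, max_distance_fraction > 0, n_nearest_points >= 1)
  if (is.null(model_id))
    model_id <- if (algorithm == "env_distance")
      paste0(algorithm, "_", metric) else algorithm
  structure(list(algorithm = algorithm, sd_cutoff = sd_cutoff,
                 metric = metric,
                 max_distance_fraction = max_distance_fraction,
                 n_nearest_points = as.integer(n_nearest_points),
                 model_id = model_id),
            class = "algorithm_config")
}

#' Fit a presence-only niche model
#'
#' Computes per-variable training statistics (mean, sd, min, max) and, for
#' the Mahalanobis metric, the sample covariance of the training vectors. A
#' singular covariance is ridge-regularised on the diagonal by
#' `1e-6 * trace/p` with a warning.
#'
#' @param config An [algorithm_config()].
#' @param env_vectors Numeric matrix (>= 2 rows) of training environmental
#'   vectors with variable column names; no missing values.
#' @return A `niche_model` object.
#' @export
fit_niche_model <- function(config, env_vectors) {
  x <- as.matrix(env_vectors)
  if (nrow(x) < 2) stop("need at least 2 training vectors")
  if (anyNA(x)) stop("training vectors contain missing values")
  if (is.null(colnames(x))) stop("training vectors need variable names")
  stats_tab <- list(mean = colMeans(x),
                    sd = apply(x, 2, stats::sd),
                    min = apply(x, 2, min),
                    max = apply(x, 2, max))
  covm <- NULL
  if (config$algorithm == "env_distance" && config$metric == "mahalanobis") {
    covm <- stats::cov(x)
    if (inherits(try(solve(covm), silent = TRUE), "try-error") ||
        min(eigen(covm, symmetric = TRUE, only.values = TRUE)$values) < 1e-10) {
      eps <- 1e-6 * sum(diag(covm)) / ncol(x)
      if (eps <= 0) eps <- 1e-6
      covm <- covm + diag(eps, ncol(x))
      warning("singular training covariance; ridge-regularised")
    }
  }
  structure(list(config = config, stats = stats_tab, covariance = covm,
                 training = x, variables = colnames(x)),
            class = "niche_model")
}

#' @export
print.niche_model <- function(x, ...) {
  cat(sprintf("<niche_model> %s, %d training points, %d variables\n",
              x$config$model_id, nrow(x$training), length(x$variables)))
  invisible(x)
}

# cell matrix (n x p) of stack values for the model's variables
stack_cell_matrix <- function(stack, variables) {
  missing <- setdiff(variables, names(stack$layers))
  if (length(missing) > 0)
    stop("variables missing from stack: ", paste(missing, collapse = ", "))
  n <- stack$grid$n_rows * stack$grid$n_cols
  matrix(vapply(variables, function(v) as.vector(stack$layers[[v]]),
                numeric(n)),
         nrow = n, dimnames = list(NULL, variables))
}

#' Predict a suitability map from a fitted niche model
#'
#' @param object A `niche_model`.
#' @param stack An [eln_stack()] containing every training variable.
#' @param ... Unused.
#' @return A `suitability_map`: values matrix in [0,1] (NA on nodata),
#'   `grid`, `provenance` (the model id), and `omission_threshold` (NA until
#'   [fixed_sensitivity_threshold()] is applied).
#' @export
predict.niche_model <- function(object, stack, ...) {
  cfg <- object$config
  X <- stack_cell_matrix(stack, object$variables)
  ok <- stats::complete.cases(X)
  suit <- rep(NA_real_, nrow(X))
  s <- object$stats
  if (cfg$algorithm == "bioclim") {
    lo <- s$mean - cfg$sd_cutoff * s$sd
    hi <- s$mean + cfg$sd_cutoff * s$sd
    in_core <- rowSums(sweep(X, 2, lo, `>=`) & sweep(X, 2, hi, `<=`)) == ncol(X)
    in_env  <- rowSums(sweep(X, 2, s$min, `>=`) &
                       sweep(X, 2, s$max, `<=`)) == ncol(X)
    suit[ok] <- ifelse(in_core[ok], 1, ifelse(in_env[ok], 0.5, 0))
  } else if (cfg$algorithm == "envelope_score") {
    frac <- rowMeans(sweep(X, 2, s$min, `>=`) & sweep(X, 2, s$max, `<=`))
    suit[ok] <- frac[ok]
  } else {
    suit[ok] <- env_distance_suitability(object, X[ok, , drop = FALSE])
  }
  structure(list(group_id = NA_character_,
                 values = matrix(suit, stack$grid$n_rows, stack$grid$n_cols),
                 grid = stack$grid,
                 provenance = list(list(model_id = cfg$model_id, weight = 1)),
                 omission_threshold = NA_real_),
            class = "suitability_map")
}

# env_distance core: X rows are complete cell vectors
env_distance_suitability <- function(model, X) {
  cfg <- model$config
  # rescale by study-area range (the prediction domain), not training range
  rng_lo <- apply(X, 2, min); rng_hi <- apply(X, 2, max)
  span <- rng_hi - rng_lo
  span[span == 0] <- 1                    # constant variable: no contribution
  scale01 <- function(m) sweep(sweep(m, 2, rng_lo, `-`), 2, span, `/`)
  Xs <- scale01(X)
  Ts <- scale01(model$training)
  p <- ncol(Xs)

  pair_dist <- function(A, B, metric, covm = NULL) {
    # distances from each row of A to each row of B
    switch(metric,
      euclidean = {
        d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * A %*% t(B)
        sqrt(pmax(d2, 0))
      },
      chebyshev = {
        out <- matrix(0, nrow(A), nrow(B))
        for (j in seq_len(nrow(B)))
          out[, j] <- apply(abs(sweep(A, 2, B[j, ], `-`)), 1, max)
        out
      },
      gower = {
        out <- matrix(0, nrow(A), nrow(B))
        for (j in seq_len(nrow(B)))
          out[, j] <- rowMeans(abs(sweep(A, 2, B[j, ], `-`)))
        out
      },
      mahalanobis = {
        out <- matrix(0, nrow(A), nrow(B))
        for (j in seq_len(nrow(B)))
          out[, j] <- sqrt(stats::mahalanobis(A, B[j, ], covm))
        out
      })
  }
  covm_s <- NULL
  if (cfg$metric == "mahalanobis") {
    covm_s <- stats::cov(Ts)
    if (min(eigen(covm_s, symmetric = TRUE, only.values = TRUE)$values) < 1e-10) {
      eps <- 1e-6 * max(sum(diag(covm_s)), 1) / p
      covm_s <- covm_s + diag(eps, p)
    }
  }
  D <- pair_dist(Xs, Ts, cfg$metric, covm_s)
  k <- min(cfg$n_nearest_points, nrow(Ts))
  if (k == 1) {
    d <- apply(D, 1, min)
    # distance to the single nearest point equals distance to its "mean"
  } else {
    d <- numeric(nrow(Xs))
    ord <- t(apply(D, 1, order))
    for (i in seq_len(nrow(Xs))) {
      ref <- colMeans(Ts[ord[i, 1:k], , drop = FALSE])
      d[i] <- pair_dist(Xs[i, , drop = FALSE], matrix(ref, 1), cfg$metric,
                        covm_s)[1, 1]
    }
  }
  d_theo <- switch(cfg$metric,
                   euclidean = sqrt(p), chebyshev = 1, gower = 1,
                   mahalanobis = max(apply(D, 1, min), 1e-12))
  pmax(0, 1 - d / (cfg$max_distance_fraction * d_theo))
}

#' @export
print.suitability_map <- function(x, ...) {
  cat(sprintf(
    "<suitability_map> group %s, %d x %d, max %.3f, omission threshold %s\n",
    x$group_id, nrow(x$values), ncol(x$values),
    suppressWarnings(max(x$values, na.rm = TRUE)),
    if (is.na(x$omission_threshold)) "unset"
    else sprintf("%.3f", x$omission_threshold)))
  invisible(x)
}
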