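#' Sample background (pseudo-absence) cells
#'
#' Draws `n` uniformly random valid cells from the stack, excluding cells
#' that contain any of the supplied presence points. Presence-only models
#' need such background points for ROC-style evaluation.
#'
#' @param stack An [eln_stack()].
#' @param n Number of background cells.
#' @param seed Integer seed (sampling is reproducible and leaves the
#'   caller's RNG state untouched).
#' @param exclude Optional data frame of `lon`, `lat` presence points whose
#'   cells are excluded.
#' @return Data frame with `row`, `col`, `lon`, `lat` of the sampled cell
#'   centers.
#' @export
sample_background <- function(stack, n, seed = 1L, exclude = NULL) {
  mask <- stack_nodata_mask(stack)
  valid <- which(!mask)
  if (!is.null(exclude) && nrow(exclude) > 0) {
    loc <- locate_cells(stack$grid, exclude$lon, exclude$lat)
    occ_cells <- (loc$col - 1L) * stack$grid$n_rows + loc$row
    valid <- setdiff(valid, occ_cells[!is.na(occ_cells)])
  }
  if (n > length(valid))
    stop("requested ", n, " background cells but only ", length(valid),
         " valid cells available")
  old <- .Random.seed_save(); set.seed(seed)
  cells <- sample(valid, n)
  .Random.seed_restore(old)
  row <- ((cells - 1L) %% stack$grid$n_rows) + 1L
  col <- ((cells - 1L) %/% stack$grid$n_rows) + 1L
  cc <- cell_centers(stack$grid)
  data.frame(row = row, col = col, lon = cc$lon[col], lat = cc$lat[row])
}

#' Rank-based AUC of presence vs background scores
#'
#' The probability that a randomly chosen presence point outscores a randomly
#' chosen background point, ties counting one half (Mann-Whitney statistic).
#'
#' @param presence_scores,background_scores Numeric score vectors.
#' @return AUC in [0, 1].
#' @export
compute_auc <- function(presence_scores, background_scores) {
  np <- length(presence_scores); nb <- length(background_scores)
  stopifnot(np > 0, nb > 0)
  r <- rank(c(presence_scores, background_scores))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nb)
}

#' Accuracy of a thresholded prediction
#'
#' Presences scoring at or above the threshold count as true positives,
#' background points scoring below it as true negatives;
#' ACC = (TP + TN) / (TP + TN + FP + FN).
#'
#' @param presence_scores,background_scores Numeric score vectors.
#' @param threshold Decision threshold.
#' @return Accuracy in [0, 1].
#' @export
compute_acc <- function(presence_scores, background_scores, threshold) {
  tp <- sum(presence_scores >= threshold)
  tn <- sum(background_scores < threshold)
  (tp + tn) / (length(presence_scores) + length(background_scores))
}

# step ROC curve: (fpr, tpr) points over all distinct score thresholds
roc_points <- function(presence, background) {
  th <- sort(unique(c(presence, background, -Inf)), decreasing = TRUE)
  tpr <- vapply(th, function(t) mean(presence >= t), numeric(1))
  fpr <- vapply(th, function(t) mean(background >= t), numeric(1))
  cbind(fpr = c(0, fpr), tpr = c(0, tpr))
}

# area under the piecewise-linear curve for fpr >= x0, with an interpolated
# vertex inserted at fpr = x0
partial_auc_above <- function(curve, x0) {
  x <- curve[, 1]; y <- curve[, 2]
  keep <- x >= x0
  if (!any(keep)) return(0)
  xs <- x[keep]; ys <- y[keep]
  if (min(xs) > x0) {
    i <- max(which(!keep))
    # interpolate the curve at x0 between vertex i and i+1
    if (x[i + 1] > x[i]) {
      y0 <- y[i] + (y[i + 1] - y[i]) * (x0 - x[i]) / (x[i + 1] - x[i])
    } else y0 <- y[i]
    xs <- c(x0, xs); ys <- c(y0, ys)
  }
  sum(diff(xs) * (utils::head(ys, -1) + utils::tail(ys, -1)) / 2)
}

#' Partial-ROC ratio (fixed-omission model evaluation)
#'
#' Bootstrap mean of the ratio between the model's partial AUC and the null
#' (diagonal) partial AUC, both restricted to the high-sensitivity region of
#' the ROC curve (sensitivity >= 1 - `omission_e`). Each bootstrap replicate
#' resamples 50% of the presence points with replacement; the background is
#' held fixed. Ratios near 1 mean no-better-than-random; ratios well above 1
#' indicate predictive signal in the region of usable (low-omission) models.
#'
#' @param presence_scores,background_scores Numeric score vectors (at least
#'   2 presences).
#' @param omission_e Accepted omission error E (default 0.10).
#' @param n_boot Number of bootstrap replicates (default 100).
#' @param seed Integer seed.
#' @return The mean partial-AUC ratio over replicates.
#' @export
partial_roc_ratio <- function(presence_scores, background_scores,
                              omission_e = 0.10, n_boot = 100, seed = 1L) {
  if (length(presence_scores) < 2)
    stop("partial ROC needs at least 2 presence points")
  half <- max(1, ceiling(length(presence_scores) / 2))
  old <- .Random.seed_save(); set.seed(seed)
  ratios <- vapply(seq_len(n_boot), function(b) {
    pres <- sample(presence_scores, half, replace = TRUE)
    partial_roc_ratio_once(pres, background_scores, omission_e)
  }, numeric(1))
  .Random.seed_restore(old)
  mean(ratios)
}

# single (non-bootstrap) partial-AUC ratio
partial_roc_ratio_once <- function(presence, background, omission_e = 0.10) {
  curve <- roc_points(presence, background)
  sens0 <- 1 - omission_e
  # x0 = smallest fpr at which the model curve reaches sensitivity 1 - E
  reach <- which(curve[, 2] >= sens0)
  if (length(reach) == 0) return(0)
  i <- min(reach)
  if (i == 1 || curve[i, 2] == sens0) {
    x0 <- curve[i, 1]
  } else {
    # interpolate along the segment that crosses sens0
    x1 <- curve[i - 1, 1]; y1 <- curve[i - 1, 2]
    x2 <- curve[i, 1]; y2 <- curve[i, 2]
    x0 <- if (y2 > y1) x1 + (x2 - x1) * (sens0 - y1) / (y2 - y1) else x2
  }
  x0 <- unname(x0)
  model_area <- partial_auc_above(curve, x0)
  null_area <- (1 - x0^2) / 2            # area under y = x over [x0, 1]
  if (null_area <= 0) return(1)
  unname(model_area / null_area)
}

#' Evaluate a suitability map against held-out presences and background
#'
#' @param map A `suitability_map`.
#' @param presence Data frame of `lon`, `lat` test presences.
#' @param background Data frame of `row`, `col` background cells from
#'   [sample_background()].
#' @param threshold Threshold for ACC (default 0.5).
#' @param omission_e,n_boot,seed Passed to [partial_roc_ratio()].
#' @return An `evaluation_result`: `model_id`, `acc`, `auc`, `proc_ratio`,
#'   `n_presence`, `n_background`, `seed`.
#' @export
evaluate_model <- function(map, presence, background, threshold = 0.5,
                           omission_e = 0.10, n_boot = 100, seed = 1L) {
  ps <- suitability_at_points(map, presence)
  bs <- map$values[cbind(background$row, background$col)]
  ps <- ps[!is.na(ps)]; bs <- bs[!is.na(bs)]
  structure(list(model_id = map$provenance[[1]]$model_id,
                 acc = compute_acc(ps, bs, threshold),
                 auc = compute_auc(ps, bs),
                 proc_ratio = partial_roc_ratio(ps, bs, omission_e, n_boot,
                                                seed),
                 n_presence = length(ps), n_background = length(bs),
                 seed = as.integer(seed)),
            class = "evaluation_result")
}

# suitability values at point locations (nearest cell)
suitability_at_points <- function(map, points) {
  loc <- locate_cells(map$grid, points$lon, points$lat)
  v <- rep(NA_real_, nrow(loc))
  ok <- !is.na(loc$row)
  v[ok] <- map$values[cbind(loc$row[ok], loc$col[ok])]
  v
}

#' Weighted elitist consensus of suitability maps
#'
#' Three-step consensus: (1) retain the `top_k` predictions ranked by AUC
#' (ties broken by partial-ROC ratio, then model id); (2) weight each
#' retained prediction, either proportionally to its AUC
#' (`score_proportional`) or equally; (3) add the weighted predictions
#' cellwise. Weights sum to 1, so the consensus is a convex combination and
#' stays in [0, 1].
#'
#' @param predictions List of `suitability_map`s on one grid.
#' @param evaluations List of `evaluation_result`s, one per prediction.
#' @param top_k Number of models retained (default: half, rounded up);
#'   clamped with a warning if larger than the number of models.
#' @param weighting `"score_proportional"` or `"equal"`.
#' @return A `suitability_map` whose `provenance` lists the retained model
#'   ids and weights.
#' @export
weighted_elitist_consensus <- function(predictions, evaluations,
                                       top_k = NULL,
                                       weighting = c("score_proportional",
                                                     "equal")) {
  weighting <- match.arg(weighting)
  stopifnot(length(predictions) == length(evaluations),
            length(predictions) >= 1)
  g <- predictions[[1]]$grid
  for (p in predictions)
    if (!grids_equal(g, p$grid)) stop("predictions on mismatched grids")
  if (is.null(top_k)) top_k <- ceiling(length(predictions) / 2)
  if (top_k > length(predictions)) {
    warning("top_k exceeds the number of models; clamped")
    top_k <- length(predictions)
  }
  auc <- vapply(evaluations, function(e) e$auc, numeric(1))
  proc <- vapply(evaluations, function(e) e$proc_ratio, numeric(1))
  ids <- vapply(evaluations, function(e) e$model_id, character(1))
  sel <- order(-auc, -proc, ids)[seq_len(top_k)]
  w <- if (weighting == "score_proportional") {
    s <- auc[sel]
    if (sum(s) <= 0) rep(1 / top_k, top_k) else s / sum(s)
  } else rep(1 / top_k, top_k)
  vals <- Reduce(`+`, Map(function(i, wi) predictions[[i]]$values * wi,
                          sel, w))
  structure(list(group_id = predictions[[1]]$group_id,
                 values = vals, grid = g,
                 provenance = Map(function(i, wi)
                   list(model_id = ids[i], weight = wi), sel, w),
                 omission_threshold = NA_real_),
            class = "suitability_map")
}

#' Fixed-sensitivity omission threshold
#'
#' Chooses the omission threshold tau as the (k+1)-th smallest suitability at
#' the training occurrences, with `k = floor(s * n)`: at most a fraction `s`
#' of occurrences fall below tau. Map values below tau are reduced to zero
#' (other values are unchanged) to limit the influence of aberrant minority
#' occurrences; tau is stored on the returned map. Order statistics are used
#' directly (no interpolation), so the behaviour is exact.
#'
#' @param map A `suitability_map`.
#' @param occurrences Data frame of `lon`, `lat` training occurrences, or a
#'   numeric vector of occurrence suitabilities.
#' @param s Accepted omission sensitivity (default 0.10).
#' @return The thresholded `suitability_map` with `omission_threshold` set.
#' @export
fixed_sensitivity_threshold <- function(map, occurrences, s = 0.10) {
  stopifnot(s >= 0, s < 1)
  v <- if (is.numeric(occurrences)) occurrences
       else suitability_at_points(map, occurrences)
  v <- v[!is.na(v)]
  if (length(v) == 0) stop("no occurrence suitabilities available")
  k <- floor(s * length(v))
  tau <- sort(v)[k + 1]
  out <- map
  out$values[!is.na(out$values) & out$values < tau] <- 0
  out$omission_threshold <- tau
  out
}
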