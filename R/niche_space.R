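#' PCA of the available environment
#'
#' Principal component analysis of all valid study-area cells, on the
#' correlation matrix (variables standardised to zero mean and unit sd, since
#' they carry heterogeneous units). Components are ordered by descending
#' eigenvalue; the sign of each component is fixed so that its
#' largest-magnitude loading is positive.
#'
#' @param stack An [eln_stack()].
#' @param variables Variable names to use (default: all stack layers with
#'   non-zero variance).
#' @return An `env_pca` object: `variables`, `means`, `sds`, `loadings`
#'   (variables x components), `eigenvalues`, `explained` (fractions summing
#'   to 1).
#' @export
fit_env_pca <- function(stack, variables = NULL) {
  if (is.null(variables)) variables <- names(stack$layers)
  X <- stack_cell_matrix(stack, variables)
  X <- X[stats::complete.cases(X), , drop = FALSE]
  if (nrow(X) < 3) stop("need at least 3 valid cells for a PCA")
  sds <- apply(X, 2, stats::sd)
  keep <- sds > 0
  if (sum(keep) < 2) stop("need at least 2 variables with variance")
  X <- X[, keep, drop = FALSE]
  variables <- variables[keep]
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  load <- pc$rotation
  for (j in seq_len(ncol(load))) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) load[, j] <- -load[, j]
  }
  ev <- pc$sdev^2
  structure(list(variables = variables,
                 means = pc$center, sds = pc$scale,
                 loadings = load, eigenvalues = ev,
                 explained = ev / sum(ev)),
            class = "env_pca")
}

#' @export
print.env_pca <- function(x, ...) {
  cat(sprintf("<env_pca> %d variables; PC1 %.1f%%, PC2 %.1f%% of variance\n",
              length(x$variables), 100 * x$explained[1], 100 * x$explained[2]))
  invisible(x)
}

#' Project the high-probability cells of a niche into PCA space
#'
#' Takes the cells whose suitability strictly exceeds `threshold` (default
#' 0.9, which suppresses the low-probability background noise produced by
#' consensus averaging) and returns their component scores in the common
#' environmental space.
#'
#' @param pca An `env_pca`.
#' @param eln A `suitability_map`.
#' @param stack The [eln_stack()] the PCA was fitted on.
#' @param threshold Suitability cutoff (default 0.9).
#' @param n_components Number of leading components to return (default 2).
#' @return An `eln_cloud`: `group_id`, `scores` (cells x components), and
#'   `empty` flag (TRUE when no cell exceeds the threshold).
#' @export
project_eln <- function(pca, eln, stack, threshold = 0.9, n_components = 2) {
  X <- stack_cell_matrix(stack, pca$variables)
  suit <- as.vector(eln$values)
  sel <- !is.na(suit) & suit > threshold & stats::complete.cases(X)
  nc <- min(n_components, ncol(pca$loadings))
  if (!any(sel)) {
    return(structure(list(group_id = eln$group_id,
                          scores = matrix(numeric(0), 0, nc), empty = TRUE),
                     class = "eln_cloud"))
  }
  Z <- sweep(sweep(X[sel, , drop = FALSE], 2, pca$means, `-`), 2, pca$sds, `/`)
  structure(list(group_id = eln$group_id,
                 scores = Z %*% pca$loadings[, seq_len(nc), drop = FALSE],
                 empty = FALSE),
            class = "eln_cloud")
}

#' Inertia ellipse of a point cloud
#'
#' Gaussian-calibrated coverage ellipse: centered on the cloud mean, shaped
#' by the sample covariance scaled by the chi-square (2 df) quantile at
#' `coverage`, so that for Gaussian clouds the ellipse contains about
#' `coverage` of the points. The default 0.61 summarises the bulk of a
#' niche's scatter while trimming tails.
#'
#' @param cloud An `eln_cloud` or a 2-column score matrix.
#' @param coverage Target coverage fraction in [0, 1) (default 0.61).
#' @return An `inertia_ellipse` object: `center`, `covariance`, `coverage`,
#'   `radius2` (the squared Mahalanobis radius).
#' @export
inertia_ellipse <- function(cloud, coverage = 0.61) {
  stopifnot(coverage >= 0, coverage < 1)
  S <- if (inherits(cloud, "eln_cloud")) cloud$scores else as.matrix(cloud)
  stopifnot(ncol(S) == 2, nrow(S) >= 3)
  structure(list(center = colMeans(S), covariance = stats::cov(S),
                 coverage = coverage,
                 radius2 = stats::qchisq(coverage, df = 2)),
            class = "inertia_ellipse")
}

#' Test whether points fall inside an inertia ellipse
#'
#' @param ellipse An [inertia_ellipse()].
#' @param points 2-column matrix of points.
#' @return Logical vector.
#' @export
ellipse_contains <- function(ellipse, points) {
  d2 <- stats::mahalanobis(as.matrix(points), ellipse$center,
                           ellipse$covariance)
  d2 <= ellipse$radius2
}

# normalise two maps to probability distributions over shared valid cells
normalized_pair <- function(map1, map2) {
  v1 <- if (inherits(map1, "suitability_map")) as.vector(map1$values)
        else as.vector(map1)
  v2 <- if (inherits(map2, "suitability_map")) as.vector(map2$values)
        else as.vector(map2)
  if (length(v1) != length(v2)) stop("maps must share a grid")
  ok <- !is.na(v1) & !is.na(v2)
  v1 <- v1[ok]; v2 <- v2[ok]
  if (sum(v1) <= 0 || sum(v2) <= 0)
    stop("cannot normalise an all-zero suitability map")
  list(p1 = v1 / sum(v1), p2 = v2 / sum(v2))
}

#' Schoener's D niche overlap
#'
#' Both maps are normalised to sum to 1 over their shared valid cells;
#' `D = 1 - 0.5 * sum(|p1 - p2|)`. 1 means identical niches, 0 a perfect
#' disjunction.
#'
#' @param map1,map2 `suitability_map`s (or matrices) on the same grid.
#' @return D in [0, 1].
#' @export
schoener_d <- function(map1, map2) {
  p <- normalized_pair(map1, map2)
  1 - 0.5 * sum(abs(p$p1 - p$p2))
}

#' Hellinger's I niche overlap
#'
#' `I = 1 - 0.5 * sum((sqrt(p1) - sqrt(p2))^2)` over the shared-cell
#' normalised distributions; same 0 (disjunct) to 1 (identical) scale as
#' Schoener's D.
#'
#' @inheritParams schoener_d
#' @return I in [0, 1].
#' @export
hellinger_i <- function(map1, map2) {
  p <- normalized_pair(map1, map2)
  1 - 0.5 * sum((sqrt(p$p1) - sqrt(p$p2))^2)
}

#' Pairwise niche-overlap matrices
#'
#' @param elns Named list of `suitability_map`s on one grid.
#' @return A list with symmetric matrices `d` and `i` (unit diagonal) and
#'   their dissimilarity counterparts `d_dissim = 1 - d`,
#'   `i_dissim = 1 - i` (zero diagonal).
#' @export
overlap_matrix <- function(elns) {
  n <- length(elns)
  ids <- names(elns)
  if (is.null(ids)) ids <- vapply(elns, function(e) e$group_id, character(1))
  D <- I <- matrix(1, n, n, dimnames = list(ids, ids))
  for (a in seq_len(n)) for (b in seq_len(n)) if (b > a) {
    D[a, b] <- D[b, a] <- schoener_d(elns[[a]], elns[[b]])
    I[a, b] <- I[b, a] <- hellinger_i(elns[[a]], elns[[b]])
  }
  list(d = D, i = I, d_dissim = 1 - D, i_dissim = 1 - I)
}

#' Complete-linkage clustering of niche dissimilarities
#'
#' Agglomerative complete-linkage clustering of the rows of a dissimilarity
#' matrix, using Euclidean distances between rows (so each niche is
#' characterised by its dissimilarity profile against all niches). Merge
#' order is deterministic; equal-height candidates merge lowest-index first
#' (the `stats::hclust` convention).
#'
#' @param dissim Symmetric dissimilarity matrix with zero diagonal.
#' @return An `hclust` object.
#' @export
cluster_niches <- function(dissim) {
  stopifnot(is.matrix(dissim), nrow(dissim) == ncol(dissim))
  if (max(abs(dissim - t(dissim))) > 1e-8) stop("dissimilarity not symmetric")
  stats::hclust(stats::dist(dissim, method = "euclidean"),
                method = "complete")
}

#' Export a niche dendrogram as Newick text
#'
#' @param hc An `hclust` from [cluster_niches()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}
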