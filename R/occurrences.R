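#' Assign point localities to language-group polygons
#'
#' Each point is assigned to the polygon containing it (boundary points count
#' as contained). When several polygons contain the same point — overlapping
#' territories or a shared border — the smallest-area polygon wins and a
#' warning is raised; this makes assignment deterministic. Points contained
#' by no polygon are left unassigned (`NA`).
#'
#' @param points Data frame with columns `id`, `lon`, `lat`.
#' @param groups List of groups (`group_id`, `polygon`), as from
#'   [read_groups_geojson()].
#' @return `points` with an added character column `group_id` (`NA` where
#'   unassigned).
#' @export
assign_points_to_polygons <- function(points, groups) {
  stopifnot(all(c("lon", "lat") %in% names(points)))
  areas <- vapply(groups, function(g) polygon_area(g$polygon), numeric(1))
  ids <- vapply(groups, function(g) g$group_id, character(1))
  hit <- vapply(groups, function(g)
    polygon_contains(g$polygon, points$lon, points$lat),
    logical(nrow(points)))
  hit <- matrix(hit, nrow = nrow(points))
  assigned <- apply(hit, 1, function(h) {
    w <- which(h)
    if (length(w) == 0) return(NA_character_)
    ids[w[which.min(areas[w])]]
  })
  if (any(rowSums(hit) > 1))
    warning(sum(rowSums(hit) > 1),
            " point(s) inside multiple polygons; assigned to smallest area")
  points$group_id <- assigned
  points
}

#' Sample occurrence points for one language group
#'
#' Mirrors the occurrence protocol: when a group has more candidate
#' localities than `cap` (default 50), a uniform random subsample of size
#' `cap` is drawn without replacement (seeded, reproducible); otherwise all
#' candidates are kept. Groups with fewer than `minimum` candidates are still
#' modelled but flagged `low_confidence`, since presence-only algorithms are
#' unreliable below roughly 10-20 occurrences.
#'
#' @param group A group list with `group_id` and `polygon`.
#' @param candidates Data frame with `lon`, `lat` columns, all inside the
#'   group's polygon.
#' @param cap Maximum occurrences retained (default 50).
#' @param minimum Minimum for a confident model (default 10).
#' @param seed Integer seed for the subsample.
#' @return An object of class `occurrence_set`: `group_id`, `points`
#'   (data frame lon/lat), `low_confidence`, `seed`, and `env_vectors`
#'   (NULL until [extract_env()] is applied).
#' @export
sample_occurrences <- function(group, candidates, cap = 50, minimum = 10,
                               seed = 1L) {
  n <- nrow(candidates)
  if (is.null(n) || n == 0) stop("no candidate localities for group ",
                                 group$group_id)
  if (!all(polygon_contains(group$polygon, candidates$lon, candidates$lat)))
    stop("candidate localities outside the group polygon")
  pts <- candidates[, c("lon", "lat")]
  if (n > cap) {
    old <- .Random.seed_save()
    set.seed(seed)
    keep <- sample.int(n, cap)
    .Random.seed_restore(old)
    pts <- pts[keep, , drop = FALSE]
  }
  rownames(pts) <- NULL
  structure(list(group_id = group$group_id, points = pts,
                 env_vectors = NULL,
                 low_confidence = n < minimum, seed = as.integer(seed)),
            class = "occurrence_set")
}

# save/restore the RNG state so seeded helpers do not disturb the caller
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Extract environmental vectors at point localities
#'
#' Nearest-cell rule: each point takes the values of the grid cell containing
#' it. Points falling on nodata cells (or outside the grid) are dropped with
#' a warning; if all points are dropped this is an error.
#'
#' @param points Data frame with `lon`, `lat`, or an `occurrence_set`.
#' @param stack An [eln_stack()].
#' @return For a data frame input: a matrix (points x variables) with an
#'   attribute `kept` (row indices of retained points). For an
#'   `occurrence_set`: the set with `env_vectors` filled and dropped points
#'   removed.
#' @export
extract_env <- function(points, stack) {
  if (inherits(points, "occurrence_set")) {
    env <- extract_env(points$points, stack)
    points$points <- points$points[attr(env, "kept"), , drop = FALSE]
    rownames(points$points) <- NULL
    attr(env, "kept") <- NULL
    points$env_vectors <- env
    return(points)
  }
  loc <- locate_cells(stack$grid, points$lon, points$lat)
  idx <- cbind(loc$row, loc$col)
  vals <- vapply(stack$layers, function(m) {
    v <- rep(NA_real_, nrow(idx))
    ok <- !is.na(idx[, 1])
    v[ok] <- m[idx[ok, , drop = FALSE]]
    v
  }, numeric(nrow(idx)))
  vals <- matrix(vals, nrow = nrow(idx),
                 dimnames = list(NULL, names(stack$layers)))
  kept <- which(stats::complete.cases(vals))
  if (length(kept) == 0) stop("all points fall on nodata cells")
  if (length(kept) < nrow(vals))
    warning(nrow(vals) - length(kept), " point(s) on nodata cells dropped")
  out <- vals[kept, , drop = FALSE]
  attr(out, "kept") <- kept
  out
}
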