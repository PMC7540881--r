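#' Accessibility filter for a niche's geographic range
#'
#' A range grid is the boolean footprint of an ELN (suitability > 0 after
#' omission thresholding). Predicted patches disconnected from the group's
#' territory are usually unreachable and are removed: only 8-connected
#' components that intersect the group's polygon are kept. For maritime
#' groups (Austronesian-style seafaring), components touching the sea are
#' also kept, since overseas patches remain reachable by boat.
#'
#' @param range Logical matrix (presence grid) or a `suitability_map`
#'   (converted via `values > 0`).
#' @param polygon The group's [eln_polygon()].
#' @param grid The [eln_grid()] of the range (taken from the map if given).
#' @param maritime Keep components adjacent to sea cells (default FALSE).
#' @param sea Logical matrix marking sea/nodata cells (required when
#'   `maritime = TRUE`).
#' @return Logical presence matrix with inaccessible components removed.
#' @export
accessibility_filter <- function(range, polygon, grid = NULL,
                                 maritime = FALSE, sea = NULL) {
  if (inherits(range, "suitability_map")) {
    grid <- range$grid
    range <- !is.na(range$values) & range$values > 0
  }
  stopifnot(is.matrix(range), is.logical(range))
  lab <- label_components(range)
  if (max(lab, na.rm = TRUE) == 0) return(range & FALSE)
  keep <- logical(max(lab))
  if (!is.null(grid)) {
    cc <- cell_centers(grid)
    cells <- which(range, arr.ind = TRUE)
    inside <- polygon_contains(polygon, cc$lon[cells[, 2]], cc$lat[cells[, 1]])
    keep[unique(lab[cells[inside, , drop = FALSE]])] <- TRUE
  }
  if (maritime) {
    if (is.null(sea)) stop("maritime filtering needs a sea mask")
    coast <- range & neighbors_any(sea)
    if (any(coast)) keep[unique(lab[coast])] <- TRUE
  }
  out <- range
  out[range] <- keep[lab[range]]
  out
}

# 8-connected component labels of a logical matrix (0 = background)
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  cells <- which(mask)
  lab <- matrix(0L, nr, nc)
  if (length(cells) == 0) return(lab)
  idx <- match(seq_len(nr * nc), cells)      # cell -> vertex id
  edges <- integer(0)
  row <- ((cells - 1L) %% nr) + 1L
  col <- ((cells - 1L) %/% nr) + 1L
  for (d in list(c(1, 0), c(0, 1), c(1, 1), c(-1, 1))) {
    r2 <- row + d[1]; c2 <- col + d[2]
    ok <- r2 >= 1 & r2 <= nr & c2 >= 1 & c2 <= nc
    nb <- (c2[ok] - 1L) * nr + r2[ok]
    has <- !is.na(idx[nb])
    if (any(has)) {
      a <- which(ok)[has]
      edges <- c(edges, rbind(a, idx[nb[has]]))
    }
  }
  g <- igraph::make_graph(edges = edges, n = length(cells), directed = FALSE)
  comp <- igraph::components(g)$membership
  lab[cells] <- as.integer(comp)
  lab
}

# TRUE where any 8-neighbour of the cell is TRUE in `mask`
neighbors_any <- function(mask) {
  m <- mask; m[is.na(m)] <- FALSE
  out <- matrix(FALSE, nrow(m), ncol(m))
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    s <- shift_mat(m + 0, dr, dc)
    out <- out | (!is.na(s) & s > 0)
  }
  out
}

#' Geographic overlap of two ranges (Jaccard index)
#'
#' @param r1,r2 Logical presence matrices (or `suitability_map`s, converted
#'   via `values > 0`) on the same grid.
#' @return `|intersection| / |union|` in [0, 1] (1 when both are empty).
#' @export
geographic_overlap <- function(r1, r2) {
  as_mask <- function(r)
    if (inherits(r, "suitability_map")) !is.na(r$values) & r$values > 0 else r
  r1 <- as_mask(r1); r2 <- as_mask(r2)
  stopifnot(identical(dim(r1), dim(r2)))
  uni <- sum(r1 | r2, na.rm = TRUE)
  if (uni == 0) return(1)
  sum(r1 & r2, na.rm = TRUE) / uni
}

#' Identify eco-linguistic patterns (ELPs)
#'
#' Groups whose niches have both high geographic overlap (Jaccard >= `g_min`)
#' and high environmental overlap (Schoener's D >= `d_min`) are linked; ELPs
#' are the connected components of this graph (so chains are merged
#' transitively, and groups linked to nobody form singleton ELPs). The
#' thresholds make the grouping an explicit, reproducible rule; both are
#' reported in the output.
#'
#' @param group_ids Character vector of group ids (row order of the
#'   matrices).
#' @param geo_overlap Symmetric Jaccard matrix.
#' @param env_overlap Symmetric Schoener's D matrix.
#' @param g_min,d_min Edge thresholds (defaults 0.4 and 0.6).
#' @return A list of `elp_record`s: `elp_label`, `member_ids`, `n_groups`,
#'   plus an attribute `thresholds`. ELPs are labelled in decreasing size
#'   order (ties: smallest member id first).
#' @export
identify_elps <- function(group_ids, geo_overlap, env_overlap,
                          g_min = 0.4, d_min = 0.6) {
  n <- length(group_ids)
  stopifnot(all(dim(geo_overlap) == n), all(dim(env_overlap) == n))
  adj <- (geo_overlap >= g_min) & (env_overlap >= d_min)
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  members <- split(group_ids, comp)
  ord <- order(-vapply(members, length, integer(1)),
               vapply(members, min, character(1)))
  members <- members[ord]
  out <- Map(function(lbl, ids)
    structure(list(elp_label = lbl, member_ids = sort(ids),
                   n_groups = length(ids)), class = "elp_record"),
    paste("ELP", seq_along(members)), members)
  attr(out, "thresholds") <- c(g_min = g_min, d_min = d_min)
  unname_keep_attr(out)
}

unname_keep_attr <- function(x) {
  at <- attributes(x)
  x <- unname(x)
  attr(x, "thresholds") <- at$thresholds
  x
}

#' Language-diversity summary of ELPs (Table-1-style)
#'
#' One row per ELP with its members, families present, number of groups, and
#' number of languages (the sum of per-group language counts from the
#' metadata; `NA` when any member's count is unknown).
#'
#' @param elps List of `elp_record`s from [identify_elps()] (or any list
#'   with `elp_label` and `member_ids`).
#' @param metadata Data frame with columns `group_id`, `family`,
#'   `n_languages`.
#' @return Data frame with columns `elp_label`, `member_ids`
#'   (comma-separated), `families`, `n_groups`, `n_languages`.
#' @export
diversity_summary <- function(elps, metadata) {
  if (length(elps) == 0)
    return(data.frame(elp_label = character(0), member_ids = character(0),
                      families = character(0), n_groups = integer(0),
                      n_languages = integer(0)))
  rows <- lapply(elps, function(e) {
    m <- metadata[match(e$member_ids, metadata$group_id), , drop = FALSE]
    data.frame(
      elp_label = e$elp_label,
      member_ids = paste(e$member_ids, collapse = ", "),
      families = paste(sort(unique(stats::na.omit(m$family))), collapse = ", "),
      n_groups = length(e$member_ids),
      n_languages = if (anyNA(m$n_languages)) NA_integer_
                    else as.integer(sum(m$n_languages)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
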