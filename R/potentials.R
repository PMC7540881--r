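#' Family-level eco-linguistic potential
#'
#' Cellwise arithmetic mean of a language family's niche predictions. The
#' divisor is the family's total group count (including groups with zero
#' suitability at a cell), so the value at a location is the average
#' suitability across the family's groups — a score for how favourable the
#' local environment is to that family.
#'
#' @param elns List of the family's `suitability_map`s (one per group, same
#'   grid).
#' @param family Family label stored on the result.
#' @return A `family_potential`: `family`, `values` (matrix in [0,1]),
#'   `grid`, `n_groups`.
#' @export
eco_linguistic_potential <- function(elns, family) {
  stopifnot(length(elns) >= 1)
  g <- elns[[1]]$grid
  for (e in elns) if (!grids_equal(g, e$grid))
    stop("family maps on mismatched grids")
  vals <- Reduce(`+`, lapply(elns, function(e) e$values)) / length(elns)
  structure(list(family = family, values = vals, grid = g,
                 n_groups = length(elns)),
            class = "family_potential")
}

#' Suitability differential between two family potentials
#'
#' Cellwise difference `first - second` between two family-level mean
#' suitability grids; bounded in [-1, 1]. Positive cells favour the first
#' family, negative cells the second, and zero cells are equally (un)suited
#' to both.
#'
#' @param pot1,pot2 `family_potential`s on one grid (conventionally the TNG
#'   and the Austronesian potential).
#' @return A `delta_map`: `values` in [-1, 1], `grid`, `families`.
#' @export
delta_eln <- function(pot1, pot2) {
  if (!grids_equal(pot1$grid, pot2$grid))
    stop("potentials on mismatched grids")
  structure(list(values = pot1$values - pot2$values, grid = pot1$grid,
                 families = c(pot1$family, pot2$family)),
            class = "delta_map")
}

#' Growing-season length from monthly climate
#'
#' Le Houerou-style count of growing months per cell: a month counts towards
#' the growing season when the mean temperature strictly exceeds 6 degrees C
#' and the monthly precipitation (mm) strictly exceeds twice the mean
#' temperature (degrees C). The precipitation condition is evaluated
#' multiplicatively (`prec > 2 * tmean`), never as a ratio, so temperatures
#' at or below zero need no special casing.
#'
#' @param tmean List of 12 monthly mean-temperature matrices (degrees C), or
#'   NULL to derive `(tmin + tmax)/2`.
#' @param prec List of 12 monthly precipitation matrices (mm).
#' @param tmin,tmax Used only when `tmean` is NULL.
#' @return Integer matrix of growing-season month counts (0-12).
#' @export
growing_season <- function(tmean = NULL, prec, tmin = NULL, tmax = NULL) {
  if (is.null(tmean)) {
    stopifnot(!is.null(tmin), !is.null(tmax))
    tmean <- Map(function(a, b) (as.matrix(a) + as.matrix(b)) / 2, tmin, tmax)
  }
  stopifnot(length(tmean) == 12, length(prec) == 12)
  gs <- 0
  na <- FALSE
  for (m in 1:12) {
    t <- as.matrix(tmean[[m]]); p <- as.matrix(prec[[m]])
    na <- na | is.na(t) | is.na(p)
    inc <- (p > 2 * t) & (t > 6)
    inc[is.na(inc)] <- FALSE
    gs <- gs + inc
  }
  gs[na] <- NA_integer_
  gs
}

#' Ecological risk of a region
#'
#' The mean growing season (MGS) is the average growing-season length over
#' the region's cells; ecological risk is its reciprocal `1/MGS`. Short
#' growing seasons mean high risk of subsistence failure. When MGS is 0 the
#' risk is undefined and flagged.
#'
#' @param gs Growing-season matrix from [growing_season()].
#' @param mask Optional logical matrix selecting the region (default: all
#'   non-NA cells).
#' @return List with `mgs`, `risk` (NA when undefined), and
#'   `risk_undefined` flag.
#' @export
ecological_risk <- function(gs, mask = NULL) {
  if (is.null(mask)) mask <- !is.na(gs)
  v <- gs[mask & !is.na(gs)]
  if (length(v) == 0) stop("no valid cells in the region mask")
  mgs <- mean(v)
  undefined <- mgs == 0
  list(mgs = mgs, risk = if (undefined) NA_real_ else 1 / mgs,
       risk_undefined = undefined)
}
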