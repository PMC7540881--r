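# shift(m, dr, dc): matrix whose [r, c] holds m[r + dr, c + dc] (NA off-grid)
shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(NA_real_, nr, nc)
  rs <- seq_len(nr) + dr; cs <- seq_len(nc) + dc
  ok_r <- rs >= 1 & rs <= nr; ok_c <- cs >= 1 & cs <= nc
  out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
  out
}

#' Terrain derivatives from a DEM
#'
#' Computes six derivatives over 3x3 moving windows:
#'
#' * `Slope` (degrees) and `Aspect` (degrees) from Horn's 8-neighbour finite
#'   differences. Aspect is the azimuth of steepest *descent*, measured
#'   clockwise from north (a plane rising to the east drains west: aspect
#'   270); it is NA on flat cells.
#' * `Flowdir`: D8 code of the steepest-descent neighbour (E=1, SE=2, S=4,
#'   SW=8, W=16, NW=32, N=64, NE=128; 0 where no neighbour is lower; ties go
#'   to the lowest code). Diagonal drops are divided by sqrt(2).
#' * `TRI`: mean absolute difference between the center and its 8 neighbours.
#' * `TPI`: center minus the mean of its 8 neighbours.
#' * `Roughness`: max minus min over the 9-cell window.
#'
#' Border cells and any window containing nodata are masked. `xres`/`yres`
#' are the horizontal cell spacings in the DEM's elevation units (for
#' geographic grids, supply metres per cell); they affect Slope/Aspect/
#' Flowdir only.
#'
#' @param dem An [eln_layer()] or numeric matrix of elevations (>= 3x3).
#' @param xres,yres Horizontal cell spacing in elevation units (default 1).
#' @return Named list of matrices: `Slope`, `Aspect`, `Flowdir`, `TPI`,
#'   `TRI`, `Roughness` (grid metadata preserved when `dem` is a layer).
#' @export
terrain_derivatives <- function(dem, xres = 1, yres = xres) {
  z <- if (inherits(dem, "eln_layer")) dem$values else as.matrix(dem)
  if (nrow(z) < 3 || ncol(z) < 3) stop("DEM must be at least 3x3")
  # neighbours, raster layout: z1 NW, z2 N, z3 NE, z4 W, z6 E, z7 SW, z8 S, z9 SE
  z1 <- shift_mat(z, -1, -1); z2 <- shift_mat(z, -1, 0); z3 <- shift_mat(z, -1, 1)
  z4 <- shift_mat(z,  0, -1);                             z6 <- shift_mat(z, 0, 1)
  z7 <- shift_mat(z,  1, -1); z8 <- shift_mat(z,  1, 0); z9 <- shift_mat(z, 1, 1)
  nbrs <- list(z1, z2, z3, z4, z6, z7, z8, z9)
  valid <- !is.na(z)
  for (n in nbrs) valid <- valid & !is.na(n)

  gx <- ((z3 + 2 * z6 + z9) - (z1 + 2 * z4 + z7)) / (8 * xres)  # +east
  gy <- ((z1 + 2 * z2 + z3) - (z7 + 2 * z8 + z9)) / (8 * yres)  # +north
  slope <- atan(sqrt(gx^2 + gy^2)) * 180 / pi
  aspect <- (atan2(-gx, -gy) * 180 / pi) %% 360
  aspect[!is.na(slope) & slope == 0] <- NA_real_

  absdiff <- lapply(nbrs, function(n) abs(z - n))
  tri <- Reduce(`+`, absdiff) / 8
  tpi <- z - Reduce(`+`, nbrs) / 8
  all9 <- c(list(z), nbrs)
  rough <- Reduce(pmax, all9) - Reduce(pmin, all9)

  # D8: codes clockwise from east; drop rate = (center - neighbour)/distance
  codes <- c(1, 2, 4, 8, 16, 32, 64, 128)
  dn <- list(z6, z9, z8, z7, z4, z1, z2, z3)        # E SE S SW W NW N NE
  dd <- c(1, sqrt(2), 1, sqrt(2), 1, sqrt(2), 1, sqrt(2))
  best <- matrix(0, nrow(z), ncol(z))
  flow <- matrix(0, nrow(z), ncol(z))
  for (k in seq_along(codes)) {
    drop <- (z - dn[[k]]) / dd[k]
    better <- !is.na(drop) & drop > best & drop > 0
    flow[better] <- codes[k]
    best[better] <- drop[better]
  }

  out <- list(Slope = slope, Aspect = aspect, Flowdir = flow,
              TPI = tpi, TRI = tri, Roughness = rough)
  lapply(out, function(m) { m[!valid] <- NA_real_; m })
}
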