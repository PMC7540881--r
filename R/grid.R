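#' Grid geometry for raster layers
#'
#' A grid describes the geometry shared by all layers of an environmental
#' stack: number of rows and columns, the position of the north-west corner
#' (cell edge, not cell center), and the square cell size. Coordinates are
#' geographic degrees (WGS84-style lon/lat); rows run north to south and
#' columns west to east, the usual raster convention.
#'
#' @param n_rows,n_cols Grid dimensions (>= 1).
#' @param origin_lon,origin_lat Longitude/latitude of the outer edge of the
#'   north-west cell, in degrees.
#' @param cell_size Cell edge length in degrees (> 0).
#' @return An object of class `eln_grid`.
#' @export
eln_grid <- function(n_rows, n_cols, origin_lon, origin_lat, cell_size) {
  stopifnot(n_rows >= 1, n_cols >= 1, cell_size > 0)
  structure(
    list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         origin_lon = origin_lon, origin_lat = origin_lat,
         cell_size = cell_size,
         crs_note = "geographic lon/lat degrees (WGS84-style)"),
    class = "eln_grid")
}

#' @export
print.eln_grid <- function(x, ...) {
  cat(sprintf("<eln_grid> %d x %d cells, %.6g deg, NW corner (%.6g, %.6g)\n",
              x$n_rows, x$n_cols, x$cell_size, x$origin_lon, x$origin_lat))
  invisible(x)
}

grids_equal <- function(a, b, tol = 1e-9) {
  a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    abs(a$origin_lon - b$origin_lon) < tol &&
    abs(a$origin_lat - b$origin_lat) < tol &&
    abs(a$cell_size - b$cell_size) < tol
}

#' Cell-center coordinates of a grid
#'
#' @param grid An [eln_grid()].
#' @return A list with vectors `lon` (length `n_cols`) and `lat`
#'   (length `n_rows`, north to south).
#' @export
cell_centers <- function(grid) {
  list(lon = grid$origin_lon + (seq_len(grid$n_cols) - 0.5) * grid$cell_size,
       lat = grid$origin_lat - (seq_len(grid$n_rows) - 0.5) * grid$cell_size)
}

#' Locate points on a grid
#'
#' Nearest-cell rule: each point falls in the cell whose extent contains it;
#' points exactly on an interior cell edge go to the cell to the south/east
#' (floor rule). Points outside the grid get NA.
#'
#' @param grid An [eln_grid()].
#' @param lon,lat Point coordinates (degrees).
#' @return A data.frame with integer columns `row`, `col` (NA outside grid).
#' @export
locate_cells <- function(grid, lon, lat) {
  col <- floor((lon - grid$origin_lon) / grid$cell_size) + 1L
  row <- floor((grid$origin_lat - lat) / grid$cell_size) + 1L
  bad <- col < 1L | col > grid$n_cols | row < 1L | row > grid$n_rows
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col))
}

#' Raster layer: a named matrix on a grid
#'
#' Values are stored as an `n_rows x n_cols` numeric matrix with row 1 at the
#' northern edge. Nodata cells are `NA`; all non-NA values must be finite.
#'
#' @param values Numeric matrix.
#' @param grid An [eln_grid()] whose shape matches `values`, or NULL to build
#'   a unit grid (origin 0,0, cell size 1) of matching shape.
#' @param name Layer name.
#' @return An object of class `eln_layer`.
#' @export
eln_layer <- function(values, grid = NULL, name = "layer") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(grid)) {
    grid <- eln_grid(nrow(values), ncol(values),
                     origin_lon = 0, origin_lat = nrow(values), cell_size = 1)
  }
  stopifnot(nrow(values) == grid$n_rows, ncol(values) == grid$n_cols)
  if (any(is.infinite(values)))
    stop("layer values must be finite or NA")
  structure(list(values = values, grid = grid, name = name),
            class = "eln_layer")
}

#' @export
print.eln_layer <- function(x, ...) {
  v <- x$values
  cat(sprintf("<eln_layer> '%s' %d x %d, %d nodata, range [%.4g, %.4g]\n",
              x$name, nrow(v), ncol(v), sum(is.na(v)),
              suppressWarnings(min(v, na.rm = TRUE)),
              suppressWarnings(max(v, na.rm = TRUE))))
  invisible(x)
}

# Table 2 layer codes expected in a fully assembled stack.
BIOCLIM_CODES <- paste0("bio", 1:19)
TERRAIN_CODES <- c("Aspect", "DEM", "Flowdir", "Slope", "TPI", "TRI", "Roughness")
STACK_CODES <- c(BIOCLIM_CODES, TERRAIN_CODES)

#' Environmental stack: aligned named layers on one grid
#'
#' @param layers Named list of matrices or [eln_layer()]s sharing one grid.
#' @param grid The shared [eln_grid()] (taken from the first `eln_layer` if
#'   omitted).
#' @param monthly Optional list with elements `tmin`, `tmax`, `prec`, each a
#'   list of 12 matrices (degrees C / mm), kept alongside the derived layers.
#' @return An object of class `eln_stack`. The stack's shared nodata mask is
#'   the union of the member layers' NA cells.
#' @export
eln_stack <- function(layers, grid = NULL, monthly = NULL) {
  stopifnot(is.list(layers), length(layers) >= 1, !is.null(names(layers)))
  mats <- lapply(layers, function(l) {
    if (inherits(l, "eln_layer")) {
      if (is.null(grid)) grid <<- l$grid
      else if (!grids_equal(grid, l$grid))
        stop("layers are on mismatched grids; resample explicitly first")
      l$values
    } else as.matrix(l)
  })
  if (is.null(grid))
    grid <- eln_grid(nrow(mats[[1]]), ncol(mats[[1]]),
                     origin_lon = 0, origin_lat = nrow(mats[[1]]), cell_size = 1)
  dims <- vapply(mats, dim, integer(2))
  if (any(dims[1, ] != grid$n_rows) || any(dims[2, ] != grid$n_cols))
    stop("all layers in a stack must share the grid shape")
  mats <- lapply(mats, function(m) { storage.mode(m) <- "double"; m })
  structure(list(grid = grid, layers = mats, monthly = monthly),
            class = "eln_stack")
}

#' @export
print.eln_stack <- function(x, ...) {
  cat(sprintf("<eln_stack> %d layers on %d x %d grid: %s\n",
              length(x$layers), x$grid$n_rows, x$grid$n_cols,
              paste(names(x$layers), collapse = ", ")))
  invisible(x)
}

#' Shared nodata mask of a stack
#'
#' @param stack An [eln_stack()].
#' @return Logical matrix, TRUE where any member layer is NA.
#' @export
stack_nodata_mask <- function(stack) {
  m <- Reduce(`|`, lapply(stack$layers, is.na))
  if (!is.null(stack$monthly)) {
    for (nm in names(stack$monthly))
      m <- m | Reduce(`|`, lapply(stack$monthly[[nm]], is.na))
  }
  m
}

#' Study extent (the accessible area M)
#'
#' Rectangular lat/lon box bounding the area within which models are
#' calibrated and allowed to extrapolate.
#'
#' @param lat_min,lat_max,lon_min,lon_max Degrees; min strictly below max.
#' @return An object of class `eln_extent`.
#' @export
study_extent <- function(lat_min, lat_max, lon_min, lon_max) {
  stopifnot(lat_min < lat_max, lon_min < lon_max)
  structure(list(lat_min = lat_min, lat_max = lat_max,
                 lon_min = lon_min, lon_max = lon_max),
            class = "eln_extent")
}

#' Crop a stack (or layer) to a study extent
#'
#' Cells whose centers fall outside the extent are dropped; grid metadata is
#' updated. Cell-center containment uses closed bounds.
#'
#' @param x An [eln_stack()] or [eln_layer()].
#' @param extent A [study_extent()].
#' @return Object of the same class on the cropped grid.
#' @export
crop_to_extent <- function(x, extent) {
  grid <- x$grid
  cc <- cell_centers(grid)
  keep_col <- which(cc$lon >= extent$lon_min & cc$lon <= extent$lon_max)
  keep_row <- which(cc$lat >= extent$lat_min & cc$lat <= extent$lat_max)
  if (length(keep_col) == 0 || length(keep_row) == 0)
    stop("study extent does not intersect the grid")
  new_grid <- eln_grid(
    length(keep_row), length(keep_col),
    origin_lon = grid$origin_lon + (min(keep_col) - 1) * grid$cell_size,
    origin_lat = grid$origin_lat - (min(keep_row) - 1) * grid$cell_size,
    cell_size = grid$cell_size)
  if (inherits(x, "eln_layer")) {
    return(eln_layer(x$values[keep_row, keep_col, drop = FALSE],
                     new_grid, x$name))
  }
  stopifnot(inherits(x, "eln_stack"))
  layers <- lapply(x$layers, function(m) m[keep_row, keep_col, drop = FALSE])
  monthly <- x$monthly
  if (!is.null(monthly)) {
    monthly <- lapply(monthly, function(ms)
      lapply(ms, function(m) m[keep_row, keep_col, drop = FALSE]))
  }
  eln_stack(layers, new_grid, monthly)
}
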