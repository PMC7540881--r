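#' Read a raster layer from an ESRI ASCII grid file
#'
#' The package's raster format of record is the ESRI ASCII grid (`.asc`): a
#' plain-text header (`ncols`, `nrows`, `xllcorner`, `yllcorner`, `cellsize`,
#' optional `NODATA_value`) followed by row-major values, row 1 at the
#' northern edge. The format is readable by any GIS stack and round-trips
#' double-precision values exactly when written by [write_raster()].
#'
#' @param path Path to an existing `.asc` file.
#' @param name Layer name; defaults to the file name without extension.
#' @return An [eln_layer()] with grid metadata populated and the nodata value
#'   translated to `NA`.
#' @export
read_raster <- function(path, name = NULL) {
  if (!file.exists(path)) stop("raster file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- list(); i <- 0
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) == 2 && grepl("^[A-Za-z_]+$", parts[1]) &&
        !is.na(suppressWarnings(as.numeric(parts[2])))) {
      hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
      i <- i + 1
    } else break
  }
  req <- c("ncols", "nrows", "cellsize")
  if (!all(req %in% names(hdr)))
    stop("not a georeferenced ASCII grid (missing header): ", path)
  if (!("xllcorner" %in% names(hdr)) || !("yllcorner" %in% names(hdr)))
    stop("missing georeferencing (xllcorner/yllcorner) in: ", path)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  vals <- scan(text = paste(lines[(i + 1):length(lines)], collapse = "\n"),
               what = double(), quiet = TRUE)
  if (length(vals) != nr * nc)
    stop(sprintf("unreadable raster: expected %d values, found %d in %s",
                 nr * nc, length(vals), path))
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA_real_
  grid <- eln_grid(nr, nc,
                   origin_lon = hdr$xllcorner,
                   origin_lat = hdr$yllcorner + nr * hdr$cellsize,
                   cell_size = hdr$cellsize)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  eln_layer(m, grid, name)
}

#' Write a raster layer to an ESRI ASCII grid file
#'
#' Values are written with full double precision (17 significant digits) so a
#' write/read round trip is bit-exact. `NA` cells are written as the nodata
#' value.
#'
#' @param layer An [eln_layer()].
#' @param path Output path.
#' @param nodata Numeric nodata sentinel (default -9999).
#' @return `path`, invisibly.
#' @export
write_raster <- function(layer, path, nodata = -9999) {
  g <- layer$grid
  v <- layer$values
  if (any(v == nodata, na.rm = TRUE))
    stop("layer contains the nodata sentinel as a real value; pick another")
  v[is.na(v)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", g$n_cols),
    sprintf("nrows %d", g$n_rows),
    sprintf("xllcorner %.17g", g$origin_lon),
    sprintf("yllcorner %.17g", g$origin_lat - g$n_rows * g$cell_size),
    sprintf("cellsize %.17g", g$cell_size),
    sprintf("NODATA_value %.17g", nodata)), con)
  apply(v, 1, function(row)
    writeLines(paste(sprintf("%.17g", row), collapse = " "), con))
  invisible(path)
}
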