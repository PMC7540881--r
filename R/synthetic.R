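#' Configuration of the synthetic world generator
#'
#' Describes a fully synthetic New-Guinea-like study system: a north-facing
#' coast with an offshore island, elevation rising southwards to a highland
#' ridge, tropical climate driven by elevation (lapse rate) with mild
#' seasonality and smooth spatial noise, and language groups planted in
#' elevation strata. Groups sharing a stratum occupy adjacent longitudinal
#' slices of the same environmental band, so they form a planted multi-group
#' eco-linguistic pattern; strata with a single group form planted
#' singletons. Coastal strata are maritime (seafaring families), so their
#' island patches count as accessible.
#'
#' @param n_rows,n_cols Grid size (default 200 x 200).
#' @param seed Integer seed; the whole world is reproducible from it.
#' @param strata Named list of strata; each entry is a list with `interval`
#'   (elevation interval in metres, left-open/right-closed), `family`,
#'   `n_groups`, `maritime`.
#' @param villages_range Min/max villages per group (default 60-120).
#' @param smoothness Gaussian length-scale of the spatial noise fields, in
#'   cells (default 3: short-range terrain and weather texture whose
#'   statistics are stationary across the map).
#' @param dem_noise_sd Elevation noise sd in metres (default 25).
#' @param temp_noise_sd,prec_noise_sd Spatial noise sd of temperature
#'   (degrees C) and monthly precipitation (mm).
#' @param lapse Temperature lapse rate, degrees C per km of elevation.
#' @param sea_fraction Approximate fraction of rows below sea level at the
#'   northern edge (default 0.15).
#' @return A `synthetic_world_config` list.
#' @export
synthetic_world_config <- function(
    n_rows = 200, n_cols = 200, seed = 1L,
    strata = list(
      highland = list(interval = c(2600, Inf), family = "TNG",
                      n_groups = 3, maritime = FALSE),
      midland  = list(interval = c(1200, 1700), family = "TNG",
                      n_groups = 2, maritime = FALSE),
      lowland  = list(interval = c(400, 800), family = "TNG",
                      n_groups = 1, maritime = FALSE),
      coastal  = list(interval = c(0, 120), family = "Austronesian",
                      n_groups = 2, maritime = TRUE)),
    villages_range = c(60, 120),
    smoothness = 3, dem_noise_sd = 25,
    temp_noise_sd = 0.2, prec_noise_sd = 8,
    lapse = 5.5, sea_fraction = 0.15) {
  stopifnot(n_rows >= 20, n_cols >= 20, length(villages_range) == 2,
            villages_range[1] >= 10)
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 seed = as.integer(seed), strata = strata,
                 villages_range = villages_range, smoothness = smoothness,
                 dem_noise_sd = dem_noise_sd, temp_noise_sd = temp_noise_sd,
                 prec_noise_sd = prec_noise_sd, lapse = lapse,
                 sea_fraction = sea_fraction),
            class = "synthetic_world_config")
}

# smooth Gaussian random field via spectral filtering of white noise,
# rescaled to the requested marginal sd (assumes RNG already seeded)
gaussian_field <- function(nr, nc, lengthscale, sd = 1) {
  w <- matrix(stats::rnorm(nr * nc), nr, nc)
  fx <- c(0:(nc %/% 2), -((nc - nc %/% 2 - 1):1)) / nc
  fy <- c(0:(nr %/% 2), -((nr - nr %/% 2 - 1):1)) / nr
  filt <- exp(-2 * pi^2 * lengthscale^2 *
                (outer(fy^2, rep(1, nc)) + outer(rep(1, nr), fx^2)))
  f <- Re(stats::fft(stats::fft(w) * filt, inverse = TRUE)) / (nr * nc)
  s <- stats::sd(as.vector(f))
  if (s == 0) return(matrix(0, nr, nc))
  f / s * sd
}

#' Generate synthetic monthly climate and elevation
#'
#' Builds the physical world of a [synthetic_world_config()]: a DEM rising
#' linearly from the northern sea (elevation < 0, masked NA) to a southern
#' highland ridge, plus a low offshore island; monthly mean temperature
#' follows the elevation lapse (so altitude and temperature covary) with a
#' small seasonal cycle; precipitation increases mildly with elevation and
#' has its own seasonal cycle. All fields carry smooth, seeded spatial noise.
#'
#' @param config A [synthetic_world_config()].
#' @return List with `grid`, `dem` (matrix, NA at sea), `sea` (logical
#'   matrix), `tmin`, `tmax`, `prec` (lists of 12 matrices).
#' @export
generate_climate_dem <- function(config) {
  nr <- config$n_rows; nc <- config$n_cols
  old <- .Random.seed_save(); set.seed(config$seed)
  grid <- eln_grid(nr, nc, origin_lon = 130, origin_lat = 0,
                   cell_size = 11 / nr)

  f <- (row(matrix(0, nr, nc)) - 0.5) / nr       # 0 north -> 1 south
  u <- (f - config$sea_fraction) / (1 - config$sea_fraction)
  # gentle coastal shelf, steep highland rise (power-law hypsometry)
  base <- 3400 * sign(u) * abs(u)^1.6
  # offshore island: low bump in the sea strip
  ir <- nr * config$sea_fraction * 0.45; ic <- nc * 0.75
  r <- row(base); cl <- col(base)
  island <- 150 * exp(-((r - ir)^2 + (cl - ic)^2) / (2 * (nr / 40)^2))
  # ruggedness grows with elevation: near-flat coastal plain, rugged ridge
  rugged <- 0.2 + 1.8 * pmax(u, 0)^0.7
  dem <- base + island + rugged * gaussian_field(nr, nc, config$smoothness,
                                                 config$dem_noise_sd)
  sea <- dem < 0
  dem[sea] <- NA_real_

  lat_c <- matrix(cell_centers(grid)$lat, nr, nc)
  tnoise <- gaussian_field(nr, nc, config$smoothness, config$temp_noise_sd)
  pnoise <- gaussian_field(nr, nc, config$smoothness, config$prec_noise_sd)
  tbase <- 27 - config$lapse * dem / 1000 - 0.15 * abs(lat_c) + tnoise
  # maritime rainfall: roughly flat over the coastal plain, fading inland
  pbase <- 150 + 0.04 * dem + 120 / (1 + exp((pmax(u, 0) - 0.15) / 0.03)) +
    pnoise

  tmin <- tmax <- prec <- vector("list", 12)
  for (m in 1:12) {
    seas_t <- 0.8 * cos(2 * pi * (m - 1) / 12)
    seas_p <- 60 * cos(2 * pi * (m - 4) / 12)
    tm <- tbase + seas_t
    tmin[[m]] <- tm - 4
    tmax[[m]] <- tm + 4
    pm <- pmax(pbase + seas_p, 0)
    pm[sea] <- NA_real_
    prec[[m]] <- pm
  }
  .Random.seed_restore(old)
  list(grid = grid, dem = dem, sea = sea, tmin = tmin, tmax = tmax,
       prec = prec)
}

#' Assemble the full environmental stack of a synthetic (or real) world
#'
#' Derives the 19 bioclimatic layers from the monthly climate and the 7
#' terrain layers from the DEM, and stacks all 26 with the monthly fields
#' attached. Border cells are masked by the terrain windows.
#'
#' @param dem Elevation matrix (metres, NA at sea).
#' @param tmin,tmax,prec Lists of 12 monthly matrices.
#' @param grid The shared [eln_grid()].
#' @param xres,yres Horizontal spacing passed to [terrain_derivatives()].
#' @return An [eln_stack()] holding the 26 standard layers plus monthly
#'   climate.
#' @export
build_env_stack <- function(dem, tmin, tmax, prec, grid, xres = 1,
                            yres = xres) {
  bio <- compute_bioclim(tmin, tmax, prec)
  terr <- terrain_derivatives(dem, xres = xres, yres = yres)
  # Aspect is undefined (NA) on flat cells; a shared-mask stack would lose
  # those cells entirely, so encode flat as -1 (a code outside [0, 360))
  flat <- !is.na(dem) & is.na(terr$Aspect) & !is.na(terr$Slope)
  terr$Aspect[flat] <- -1
  layers <- c(bio, list(Aspect = terr$Aspect, DEM = dem,
                        Flowdir = terr$Flowdir, Slope = terr$Slope,
                        TPI = terr$TPI, TRI = terr$TRI,
                        Roughness = terr$Roughness))
  eln_stack(layers, grid, monthly = list(tmin = tmin, tmax = tmax,
                                         prec = prec))
}

#' Plant language groups, villages and ground-truth niches
#'
#' Splits each stratum's elevation band into longitudinal slices, one per
#' group; the group's territory polygon is the rectangle hugging the central
#' 90% of the stratum's rows within its slice (so at least ~90% of the
#' polygon lies inside the planted stratum). Villages are sampled uniformly
#' in geographic space within the polygon (kept when they fall on valid
#' land), so occurrence sampling carries the same geographic bias as real
#' village data. The ground-truth niche of a group is the binary grid of
#' cells whose elevation falls in its stratum interval.
#'
#' @param env Output of [generate_climate_dem()].
#' @param config The [synthetic_world_config()].
#' @return List with `groups` (each: `group_id`, `family`, `stratum`,
#'   `maritime`, `polygon`), `villages` (data frame `id`, `lon`, `lat`,
#'   `group_id`), `true_niche` (named list of binary matrices), and
#'   `planted_elps` (named list: stratum -> member group ids).
#' @export
plant_language_world <- function(env, config) {
  dem <- env$dem; grid <- env$grid
  nr <- grid$n_rows; nc <- grid$n_cols
  old <- .Random.seed_save(); set.seed(config$seed + 1L)
  cc <- cell_centers(grid)
  groups <- list(); villages <- list(); true_niche <- list()
  planted <- list()
  gi <- 0
  for (sname in names(config$strata)) {
    st <- config$strata[[sname]]
    in_stratum <- !is.na(dem) & dem > st$interval[1] & dem <= st$interval[2]
    # mainland band only for territories (drop island patches for placement)
    members <- character(0)
    slice_edges <- round(seq(1, nc + 1, length.out = st$n_groups + 1))
    for (k in seq_len(st$n_groups)) {
      gid <- sprintf("%02d", gi); gi <- gi + 1
      c1 <- slice_edges[k]; c2 <- slice_edges[k + 1] - 1
      land_sl <- !is.na(dem[, c1:c2, drop = FALSE])
      strat_sl <- in_stratum[, c1:c2, drop = FALSE]
      if (sum(strat_sl) < 20)
        stop("stratum '", sname, "' too small for its groups")
      # contiguous mainland band: rows of the slice that are mostly land and
      # mostly in-stratum (skips the offshore island and noise outliers)
      frac <- rowSums(strat_sl) / pmax(rowSums(land_sl), 1)
      full_land <- rowSums(land_sl) >= 0.97 * (c2 - c1 + 1)
      cand <- which(frac >= 0.5 & full_land)
      if (length(cand) == 0) cand <- which.max(frac * full_land)
      runs <- split(cand, cumsum(c(1, diff(cand) != 1)))
      band <- runs[[which.max(lengths(runs))]]
      rq <- range(band)
      if (rq[1] >= rq[2]) rq[1] <- max(1, rq[2] - 1)
      lat_hi <- cc$lat[rq[1]] + grid$cell_size / 2   # northern edge
      lat_lo <- cc$lat[rq[2]] - grid$cell_size / 2
      lon_w <- cc$lon[c1] - grid$cell_size / 2
      lon_e <- cc$lon[c2] + grid$cell_size / 2
      poly <- eln_polygon(rbind(c(lon_w, lat_lo), c(lon_e, lat_lo),
                                c(lon_e, lat_hi), c(lon_w, lat_hi)))
      n_vil <- sample(config$villages_range[1]:config$villages_range[2], 1)
      pts <- matrix(numeric(0), 0, 2)
      tries <- 0
      while (nrow(pts) < n_vil && tries < 200) {
        m <- 3 * (n_vil - nrow(pts))
        lon <- stats::runif(m, lon_w, lon_e)
        lat <- stats::runif(m, lat_lo, lat_hi)
        loc <- locate_cells(grid, lon, lat)
        ok <- !is.na(loc$row) & !is.na(dem[cbind(loc$row, loc$col)])
        pts <- rbind(pts, cbind(lon[ok], lat[ok]))
        tries <- tries + 1
      }
      if (nrow(pts) < n_vil)
        stop("could not place villages for group ", gid)
      pts <- pts[seq_len(n_vil), , drop = FALSE]
      groups[[gid]] <- list(group_id = gid, family = st$family,
                            stratum = sname, maritime = st$maritime,
                            polygon = poly)
      villages[[gid]] <- data.frame(lon = pts[, 1], lat = pts[, 2],
                                    group_id = gid)
      true_niche[[gid]] <- in_stratum
      members <- c(members, gid)
    }
    planted[[sname]] <- members
  }
  .Random.seed_restore(old)
  villages <- do.call(rbind, villages)
  villages <- data.frame(id = seq_len(nrow(villages)), villages)
  rownames(villages) <- NULL
  list(groups = groups, villages = villages, true_niche = true_niche,
       planted_elps = planted)
}

#' Generate a complete synthetic world
#'
#' Convenience wrapper: climate + DEM, full 26-layer stack, planted language
#' groups, villages and ground-truth niches, all reproducible from the
#' config seed.
#'
#' @param config A [synthetic_world_config()].
#' @return List with `config`, `grid`, `sea`, `stack`, `groups`, `villages`,
#'   `true_niche`, `planted_elps`.
#' @export
generate_synthetic_world <- function(config = synthetic_world_config()) {
  env <- generate_climate_dem(config)
  # horizontal spacing in metres (1 degree ~ 111.32 km near the equator)
  stack <- build_env_stack(env$dem, env$tmin, env$tmax, env$prec, env$grid,
                           xres = env$grid$cell_size * 111320)
  world <- plant_language_world(env, config)
  c(list(config = config, grid = env$grid, sea = env$sea, stack = stack),
    world)
}

#' Load the packaged eco-linguistic pattern fixture
#'
#' Returns the transcription of the published 17-pattern membership table
#' for the 29 New Guinea language groups (20 TNG, 9 Austronesian): per-ELP
#' region notes, member group ids, families, group counts and language
#' counts, plus the per-group metadata table. Per-group language counts are
#' only known for groups that form singleton patterns; they are `NA` for
#' members of multi-group patterns, whose totals were published per pattern.
#'
#' @return List with data frames `elps` (one row per ELP; `member_ids`
#'   semicolon-separated) and `groups` (`group_id`, `family`,
#'   `n_languages`).
#' @export
load_table1_fixture <- function() {
  dir <- system.file("extdata", package = "elnm")
  elps <- utils::read.csv(file.path(dir, "table1_elps.csv"),
                          colClasses = c(n_groups = "integer",
                                         n_languages = "integer",
                                         member_ids = "character"))
  groups <- utils::read.csv(file.path(dir, "group_metadata.csv"),
                            colClasses = c(group_id = "character",
                                           n_languages = "integer"))
  list(elps = elps, groups = groups)
}
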