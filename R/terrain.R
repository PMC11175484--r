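#' Terrain predictor derivation
#'
#' Derives the predictor rasters used by the niche models: slope, aspect,
#' ruggedness (TRI), Euclidean distance rasters and region buffers, all on a
#' projected square-cell grid.
#'
#' @name terrain
NULL

# shift a matrix by (di, dj), padding with NA
shift_mat <- function(m, di, dj) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(NA_real_, nr, nc)
  ri <- seq_len(nr); rj <- seq_len(nc)
  si <- ri + di; sj <- rj + dj
  ok_i <- si >= 1 & si <= nr
  ok_j <- sj >= 1 & sj <= nc
  out[ri[ok_i], rj[ok_j]] <- m[si[ok_i], sj[ok_j]]
  out
}

#' Slope and aspect by Horn's method
#'
#' Slope and aspect from a projected DEM with square cells, using Horn's
#' 8-neighbour weighted finite differences (the method of common GIS terrain
#' tools). Slope is `atan(sqrt(gx^2 + gy^2))` in degrees; aspect is the
#' azimuth of the downslope direction, clockwise from north in `[0, 360)`,
#' with flat cells assigned 0. Edge cells (and cells with any missing
#' neighbour) are nodata.
#'
#' @param elevation `raster_grid` of elevation in metres.
#' @return A list with `slope` and `aspect` raster grids (degrees).
#' @export
slope_aspect <- function(elevation) {
  if (!is_raster_grid(elevation))
    stop("unsupported grid: elevation must be a raster_grid", call. = FALSE)
  z <- elevation$values
  cs <- elevation$cellsize
  nw <- shift_mat(z, -1, -1); n <- shift_mat(z, -1, 0); ne <- shift_mat(z, -1, 1)
  w  <- shift_mat(z,  0, -1);                           e  <- shift_mat(z,  0, 1)
  sw <- shift_mat(z,  1, -1); s <- shift_mat(z,  1, 0); se <- shift_mat(z,  1, 1)
  gx <- ((ne + 2 * e + se) - (nw + 2 * w + sw)) / (8 * cs)  # dz/dx, eastward
  gy <- ((nw + 2 * n + ne) - (sw + 2 * s + se)) / (8 * cs)  # dz/dy, northward
  slope <- atan(sqrt(gx^2 + gy^2)) * 180 / pi
  # azimuth of the downslope vector (-gx, -gy), clockwise from north
  aspect <- (atan2(-gx, -gy) * 180 / pi) %% 360
  flat <- !is.na(gx) & !is.na(gy) & gx == 0 & gy == 0
  aspect[flat] <- 0
  aspect[is.na(slope)] <- NA_real_
  list(slope = rg_like(elevation, slope), aspect = rg_like(elevation, aspect))
}

#' Terrain ruggedness index
#'
#' Mean absolute elevation difference between each cell and its eight
#' neighbours. Edge cells and cells with missing neighbours are nodata.
#'
#' @param elevation `raster_grid` of elevation in metres.
#' @return `raster_grid` of ruggedness (m), non-negative.
#' @export
ruggedness <- function(elevation) {
  z <- elevation$values
  if (nrow(z) < 3L || ncol(z) < 3L)
    stop("unsupported grid: ruggedness needs at least a 3x3 grid", call. = FALSE)
  acc <- matrix(0, nrow(z), ncol(z))
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0L && dj == 0L) next
    acc <- acc + abs(z - shift_mat(z, di, dj))
  }
  rg_like(elevation, acc / 8)
}

# 1D squared distance transform (lower envelope of parabolas)
dt1d <- function(f) {
  n <- length(f)
  if (n == 1L) return(f)
  d <- numeric(n)
  v <- integer(n)
  zb <- numeric(n + 1L)
  k <- 1L; v[1L] <- 1L; zb[1L] <- -Inf; zb[2L] <- Inf
  for (q in 2:n) {
    repeat {
      s <- ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2 * q - 2 * v[k])
      if (s <= zb[k]) k <- k - 1L else break
    }
    k <- k + 1L
    v[k] <- q; zb[k] <- s; zb[k + 1L] <- Inf
  }
  k <- 1L
  for (q in 1:n) {
    while (zb[k + 1L] < q) k <- k + 1L
    d[q] <- (q - v[k])^2 + f[v[k]]
  }
  d
}

#' Euclidean distance raster
#'
#' Exact Euclidean distance (cell centre to cell centre, metres) from every
#' cell to the nearest source cell, computed with the two-pass separable
#' distance transform. Source cells get distance zero.
#'
#' @param source_mask binary `raster_grid`; cells equal to 1 are sources.
#' @return `raster_grid` of distances in metres.
#' @export
distance_raster <- function(source_mask) {
  m <- source_mask$values
  src <- !is.na(m) & m == 1
  if (!any(src)) stop("empty-source error: no source pixels in mask", call. = FALSE)
  BIG <- 1e15
  f <- matrix(BIG, nrow(m), ncol(m))
  f[src] <- 0
  # pass 1: along columns, pass 2: along rows
  f <- apply(f, 2L, dt1d)
  d2 <- t(apply(f, 1L, dt1d))
  rg_like(source_mask, sqrt(d2) * source_mask$cellsize)
}

#' Buffer a binary region mask by a distance
#'
#' Includes every cell whose centre lies within `distance` metres of a region
#' cell centre (computed through [distance_raster()]), emulating the
#' buffered-study-area convention used to avoid edge effects in distance
#' predictors.
#'
#' @param region_mask binary `raster_grid`.
#' @param distance buffer distance in metres, `>= 0`.
#' @return binary `raster_grid`, a superset of `region_mask`.
#' @export
buffer_region <- function(region_mask, distance) {
  if (!is.numeric(distance) || length(distance) != 1L || distance < 0)
    stop("configuration error: buffer distance must be >= 0", call. = FALSE)
  d <- distance_raster(region_mask)
  out <- ifelse(!is.na(d$values) & d$values <= distance + 1e-9, 1, 0)
  rg_like(region_mask, out)
}

#' Merge creek and river masks
#'
#' Logical OR of two binary stream masks (value 1 wherever creeks + rivers
#' exceed zero).
#'
#' @param creeks,rivers co-registered binary `raster_grid`s.
#' @return binary `raster_grid`.
#' @export
merge_stream_masks <- function(creeks, rivers) {
  rg_check_aligned(creeks, rivers)
  a <- creeks$values; b <- rivers$values
  out <- ifelse(is.na(a) | is.na(b), NA_real_,
                as.numeric((a == 1) | (b == 1)))
  rg_like(creeks, out)
}

#' Build the named predictor stack
#'
#' Assembles the predictor layers used by the distribution models: elevation,
#' slope, aspect, ruggedness and distance to streams; plus, for the
#' encroachment model, distance to the year-1 evergreen extent and the year-1
#' suitability surface.
#'
#' @param elevation DEM `raster_grid` (m).
#' @param streams binary stream mask `raster_grid`.
#' @param evergreen_t1 optional binary evergreen-forest map for the first
#'   date; adds `dist_forest2015`.
#' @param suit_t1 optional suitability `raster_grid` in `[0, 1]`; added as
#'   `suit2015`.
#' @return Named list of co-registered `raster_grid`s.
#' @export
build_predictors <- function(elevation, streams, evergreen_t1 = NULL,
                             suit_t1 = NULL) {
  rg_check_aligned(elevation, streams)
  sa <- slope_aspect(elevation)
  stack <- list(
    elevation  = elevation,
    slope      = sa$slope,
    aspect     = sa$aspect,
    ruggedness = ruggedness(elevation),
    dist_creek = distance_raster(streams)
  )
  if (!is.null(evergreen_t1)) {
    rg_check_aligned(elevation, evergreen_t1)
    stack$dist_forest2015 <- distance_raster(evergreen_t1)
  }
  if (!is.null(suit_t1)) {
    rg_check_aligned(elevation, suit_t1)
    stack$suit2015 <- suit_t1
  }
  stack
}
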