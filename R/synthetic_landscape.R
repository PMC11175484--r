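#' Synthetic landscape generation
#'
#' Seeded generators for the raster stacks the analysis consumes: a smooth
#' correlated elevation field, a stream network threading low terrain, truth
#' maps of evergreen/deciduous forest for two dates driven by a known
#' suitability function, and radar/NDVI sensor bands constructed so that the
#' decision-rule classifier recovers the truth. Every downstream stage of the
#' pipeline is thereby testable offline against known answers.
#'
#' @name synthetic_landscape
NULL

# evaluate expr with a temporary RNG state seeded at `seed`
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Synthetic landscape configuration
#'
#' Bundles and validates all knobs of the synthetic landscape. Defaults
#' describe a 100 x 100 cell, 30 m grid with a 200 m relief, a sparse stream
#' network and clustered evergreen patches whose presence probability peaks at
#' intermediate elevation and declines with distance to streams.
#'
#' @param grid_width,grid_height grid size in cells (>= 16).
#' @param cell_size cell edge (m), default 30.
#' @param seed integer master seed; all stochastic draws derive from it.
#' @param elevation_range numeric length-2, min and max elevation (m).
#' @param stream_density target fraction of cells carrying streams, in
#'   `[0, 0.5)`.
#' @param patch_intensity expected evergreen patch seeds per 1000 cells.
#' @param suitability_coeffs named coefficients of the true presence model on
#'   the logit scale: `intercept`, `elev` and `elev2` act on elevation scaled
#'   to `[-1, 1]` across `elevation_range`, `dist_stream` acts on
#'   distance-to-stream in km. The defaults place peak suitability at
#'   intermediate elevations and near streams, with the two effects of
#'   comparable realized magnitude across the landscape.
#' @param smoothing_sigma Gaussian kernel sd (cells) for the terrain field.
#' @param deciduous_intensity expected deciduous patch seeds per 1000 cells.
#' @param encroach_rate scale of the per-cell encroachment probability.
#' @param encroach_decay e-folding distance (m) of encroachment probability
#'   with distance to the first-date evergreen extent.
#' @param label_noise fraction of cells whose sensor-band regime is flipped,
#'   for classifier-robustness experiments. Default 0.
#' @return A validated list of class `landscape_config`.
#' @export
landscape_config <- function(grid_width = 100, grid_height = 100,
                             cell_size = 30, seed = 1,
                             elevation_range = c(300, 500),
                             stream_density = 0.02,
                             patch_intensity = 12,
                             suitability_coeffs = c(intercept = 0.5, elev = 0,
                                                    elev2 = -8,
                                                    dist_stream = -3),
                             smoothing_sigma = 5,
                             deciduous_intensity = 2,
                             encroach_rate = 0.5,
                             encroach_decay = 150,
                             label_noise = 0) {
  if (grid_width < 16 || grid_height < 16)
    stop("configuration error: grid must be at least 16 x 16 cells", call. = FALSE)
  if (cell_size <= 0)
    stop("configuration error: cell_size must be positive", call. = FALSE)
  if (stream_density < 0 || stream_density >= 0.5)
    stop("configuration error: stream_density must lie in [0, 0.5)", call. = FALSE)
  if (length(elevation_range) != 2L || diff(elevation_range) <= 0)
    stop("configuration error: elevation_range must be increasing (min, max)",
         call. = FALSE)
  need <- c("intercept", "elev", "elev2", "dist_stream")
  cf <- rep(0, 4); names(cf) <- need
  cf[intersect(names(suitability_coeffs), need)] <-
    suitability_coeffs[intersect(names(suitability_coeffs), need)]
  structure(list(
    grid_width = as.integer(grid_width), grid_height = as.integer(grid_height),
    cell_size = cell_size, seed = as.integer(seed),
    elevation_range = elevation_range, stream_density = stream_density,
    patch_intensity = patch_intensity, suitability_coeffs = cf,
    smoothing_sigma = smoothing_sigma,
    deciduous_intensity = deciduous_intensity,
    encroach_rate = encroach_rate, encroach_decay = encroach_decay,
    label_noise = label_noise
  ), class = "landscape_config")
}

# separable Gaussian smoothing with edge renormalisation
gauss_smooth <- function(m, sigma) {
  h <- max(1L, ceiling(3 * sigma))
  w <- stats::dnorm(-h:h, sd = sigma)
  smooth_axis <- function(m, vertical) {
    num <- matrix(0, nrow(m), ncol(m))
    den <- num
    for (k in -h:h) {
      s <- if (vertical) shift_mat(m, k, 0) else shift_mat(m, 0, k)
      ok <- !is.na(s)
      s[!ok] <- 0
      num <- num + w[k + h + 1L] * s
      den <- den + w[k + h + 1L] * ok
    }
    num / den
  }
  smooth_axis(smooth_axis(m, TRUE), FALSE)
}

#' Generate a synthetic elevation field
#'
#' Low-pass-filtered Gaussian white noise rescaled linearly onto
#' `elevation_range`: a smooth, spatially autocorrelated surface standing in
#' for a digital elevation model. Deterministic for a fixed seed.
#'
#' @param config a [landscape_config()].
#' @return `raster_grid` of elevation (m) spanning exactly `elevation_range`.
#' @export
generate_terrain <- function(config) {
  stopifnot(inherits(config, "landscape_config"))
  z <- with_seed(config$seed + 101L, {
    noise <- matrix(stats::rnorm(config$grid_height * config$grid_width),
                    config$grid_height, config$grid_width)
    gauss_smooth(noise, config$smoothing_sigma)
  })
  r <- range(z)
  lo <- config$elevation_range[1]; hi <- config$elevation_range[2]
  z <- lo + (z - r[1]) / (r[2] - r[1]) * (hi - lo)
  raster_grid(z, cellsize = config$cell_size)
}

#' Generate a synthetic stream network
#'
#' Streams are traced as downhill walks: each walk starts on high terrain and
#' steps to the (slightly jittered) lowest unvisited 8-neighbour until it
#' reaches the grid edge, joins an existing stream, or stalls. Walks are added
#' until the target cell count `stream_density * n_cells` is reached; the
#' final walk is truncated at the target, so the realised stream fraction
#' matches the configured density to within one cell.
#'
#' @param config a [landscape_config()].
#' @param elevation elevation `raster_grid` from [generate_terrain()].
#' @return binary `raster_grid` (1 = stream).
#' @export
generate_streams <- function(config, elevation) {
  z <- elevation$values
  nr <- nrow(z); nc <- ncol(z)
  mask <- matrix(0, nr, nc)
  target <- ceiling(config$stream_density * nr * nc)
  if (target == 0L) return(rg_like(elevation, mask))
  with_seed(config$seed + 202L, {
    count <- 0L
    # drainage is space-filling at landscape scale: walks start round-robin
    # across vertical bands (headwaters in the upper-elevation half of each
    # band), and individual segments are kept moderate in length so the
    # network spreads rather than collapsing into one basin-length channel
    n_bands <- max(2L, min(6L, nc %/% 16L))
    band_of <- pmin(n_bands, 1L + (col(z) - 1L) %/% ceiling(nc / n_bands))
    hi_bands <- lapply(seq_len(n_bands), function(b) {
      cells <- which(band_of == b)
      cells[z[cells] >= stats::quantile(z[cells], 0.5)]
    })
    max_steps <- max(20L, as.integer(round((nr + nc) / 6)))
    band <- 0L
    while (count < target) {
      band <- band %% n_bands + 1L
      cur <- sample(hi_bands[[band]], 1L)
      visited <- integer(0)
      for (step in seq_len(max_steps)) {
        i <- (cur - 1L) %% nr + 1L
        j <- (cur - 1L) %/% nr + 1L
        if (mask[cur] == 0) {
          mask[cur] <- 1
          count <- count + 1L
          if (count >= target) break
        } else if (step > 1L) break  # joined an existing stream
        visited <- c(visited, cur)
        ni <- i + c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
        nj <- j + c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
        ok <- ni >= 1L & ni <= nr & nj >= 1L & nj <= nc
        if (!any(ok)) break
        cand <- (nj[ok] - 1L) * nr + ni[ok]
        cand <- setdiff(cand, visited)
        if (length(cand) == 0L) break
        cur <- cand[which.min(z[cand] + stats::rnorm(length(cand), sd = 1))]
      }
      if (count >= target) break
    }
  })
  rg_like(elevation, mask)
}

# scale elevation to [-1, 1] across the configured range
scale_elev <- function(config, z) {
  lo <- config$elevation_range[1]; hi <- config$elevation_range[2]
  2 * (z - (lo + hi) / 2) / (hi - lo)
}

#' True suitability surface of the synthetic landscape
#'
#' Inverse-logit of a quadratic in scaled elevation plus a linear term in
#' distance-to-stream (km), with coefficients from the config. This is the
#' data-generating presence model the niche models should recover.
#'
#' @param config a [landscape_config()].
#' @param elevation elevation `raster_grid`.
#' @param streams binary stream `raster_grid`.
#' @return `raster_grid` of probabilities in `[0, 1]`.
#' @export
true_suitability <- function(config, elevation, streams) {
  cf <- config$suitability_coeffs
  e <- scale_elev(config, elevation$values)
  d_km <- if (any(streams$values == 1, na.rm = TRUE)) {
    distance_raster(streams)$values / 1000
  } else matrix(0, nrow(e), ncol(e))
  eta <- cf[["intercept"]] + cf[["elev"]] * e + cf[["elev2"]] * e^2 +
    cf[["dist_stream"]] * d_km
  rg_like(elevation, stats::plogis(eta))
}

# drop clustered circular patches around seed cells sampled with the given
# per-cell weights; returns a 0/1 patch-membership matrix
patch_field <- function(nr, nc, n_seeds, weights, radius_range = c(2, 4)) {
  field <- matrix(0, nr, nc)
  if (n_seeds == 0L) return(field)
  seeds <- sample.int(nr * nc, n_seeds, replace = TRUE, prob = weights)
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  for (s in seeds) {
    si <- (s - 1L) %% nr + 1L
    sj <- (s - 1L) %/% nr + 1L
    r <- sample(seq(radius_range[1], radius_range[2]), 1L)
    field[(rows - si)^2 + (cols - sj)^2 <= r^2] <- 1
  }
  field
}

#' Generate cover truth maps
#'
#' Builds the truth bundle: the true suitability surface; evergreen cover at
#' the first date sampled as Bernoulli draws of suitability within clustered
#' patches; deciduous patches completing the forest map (evergreen is a
#' subset of forest by construction); second-date evergreen cover adding new
#' cells with probability increasing in suitability and decaying
#' exponentially with distance to the first-date evergreen extent; and the
#' encroachment truth defined by the two-date overlay. No clearing is
#' simulated, so first-date evergreen is a subset of second-date evergreen.
#'
#' @param config a [landscape_config()].
#' @param elevation,streams layers from the terrain and stream generators.
#' @return A list of class `truth_bundle` with raster grids
#'   `true_suitability`, `forest_2015`, `evergreen_2015`, `forest_2021`,
#'   `evergreen_2021`, `wpe_truth`.
#' @export
generate_cover_truth <- function(config, elevation, streams) {
  rg_check_aligned(elevation, streams)
  suit <- true_suitability(config, elevation, streams)
  nr <- nrow(suit$values); nc <- ncol(suit$values)
  ncell <- nr * nc
  out <- with_seed(config$seed + 303L, {
    # many small patches: the landscape's effective sample size for the
    # environmental signal is the patch count, so patches are kept compact
    n_ev <- stats::rpois(1L, config$patch_intensity * ncell / 1000)
    pf_ev <- patch_field(nr, nc, n_ev, weights = rep(1, ncell),
                         radius_range = c(1, 3))
    p15 <- suit$values * pf_ev
    ev15 <- matrix(stats::rbinom(ncell, 1L, p15), nr, nc)

    n_dc <- stats::rpois(1L, config$deciduous_intensity * ncell / 1000)
    pf_dc <- patch_field(nr, nc, n_dc, weights = rep(1, ncell))
    decid <- matrix(stats::rbinom(ncell, 1L, 0.6 * pf_dc), nr, nc)
    f15 <- pmax(ev15, decid)

    if (any(ev15 == 1)) {
      dist_ev <- distance_raster(rg_like(elevation, ev15))$values
      p_new <- config$encroach_rate * suit$values *
        exp(-dist_ev / config$encroach_decay)
      new <- matrix(stats::rbinom(ncell, 1L, pmin(1, p_new)), nr, nc)
      ev21 <- pmax(ev15, new)
    } else ev21 <- ev15
    list(ev15 = ev15, f15 = f15, ev21 = ev21)
  })
  wpe <- out$ev21 * (1 - out$ev15)
  structure(list(
    true_suitability = suit,
    forest_2015 = rg_like(elevation, out$f15),
    evergreen_2015 = rg_like(elevation, out$ev15),
    forest_2021 = rg_like(elevation, pmax(out$f15, out$ev21)),
    evergreen_2021 = rg_like(elevation, out$ev21),
    wpe_truth = rg_like(elevation, wpe)
  ), class = "truth_bundle")
}

#' Render synthetic sensor bands from a truth bundle
#'
#' Draws HH and HV backscatter (dB), annual maximum NDVI and winter mean NDVI
#' per cell so that the decision rules of the land-cover classifier recover
#' the truth maps exactly at zero label noise: forest cells receive radar and
#' NDVI_max values strictly inside the forest decision envelope, non-forest
#' cells outside it, and winter NDVI separates evergreen (> 0.4) from
#' deciduous canopy. A nonzero `label_noise` flips that fraction of cells to
#' a different cover regime before rendering, to probe classifier robustness.
#'
#' @param truth a `truth_bundle` from [generate_cover_truth()].
#' @param config the [landscape_config()] used to build it.
#' @param year which date to render, `"2015"` or `"2021"`.
#' @param label_noise overrides `config$label_noise` when not `NULL`.
#' @return Named list of raster grids `HH`, `HV`, `NDVI_max`,
#'   `NDVI_wintermean`.
#' @export
render_sensor_bands <- function(truth, config, year = "2015",
                                label_noise = NULL) {
  year <- match.arg(year, c("2015", "2021"))
  if (is.null(label_noise)) label_noise <- config$label_noise
  forest <- truth[[paste0("forest_", year)]]$values
  ever <- truth[[paste0("evergreen_", year)]]$values
  nr <- nrow(forest); nc <- ncol(forest); ncell <- nr * nc
  regime <- forest + ever  # 0 = non-forest, 1 = deciduous forest, 2 = evergreen
  with_seed(config$seed + 404L + as.integer(year == "2021"), {
    if (label_noise > 0) {
      flip <- sample.int(ncell, round(label_noise * ncell))
      regime[flip] <- (regime[flip] + sample(1:2, length(flip),
                                             replace = TRUE)) %% 3
    }
    hh <- hv <- nmax <- nwin <- matrix(NA_real_, nr, nc)
    nf <- regime == 0
    fo <- regime >= 1
    # non-forest: HV below the forest envelope, NDVI_max below 0.7
    hv[nf] <- stats::runif(sum(nf), -30, -21)
    hh[nf] <- hv[nf] + stats::runif(sum(nf), -2, 5)
    nmax[nf] <- stats::runif(sum(nf), 0.10, 0.65)
    nwin[nf] <- stats::runif(sum(nf), 0.05, 0.35)
    # forest: sample HV, then a target HH/HV ratio consistent with all three
    # radar rules (the HH - HV bound constrains the admissible ratio)
    nfo <- sum(fo)
    hvf <- stats::runif(nfo, -18, -8)
    rlo <- pmax(0.25, 1 - 9 / abs(hvf))
    ratio <- stats::runif(nfo, rlo, 0.9)
    hv[fo] <- hvf
    hh[fo] <- hvf + (1 - ratio) * abs(hvf)
    nmax[fo] <- stats::runif(nfo, 0.75, 0.95)
    nwin[regime == 1] <- stats::runif(sum(regime == 1), 0.10, 0.38)
    nwin[regime == 2] <- stats::runif(sum(regime == 2), 0.45, 0.80)
    tmpl <- truth$forest_2015
    list(HH = rg_like(tmpl, hh), HV = rg_like(tmpl, hv),
         NDVI_max = rg_like(tmpl, nmax), NDVI_wintermean = rg_like(tmpl, nwin))
  })
}

#' Generate a complete synthetic landscape
#'
#' Convenience wrapper running terrain, streams, cover truth and both dates'
#' sensor bands from one config.
#'
#' @param config a [landscape_config()].
#' @return List with `config`, `elevation`, `streams`, `truth`, `bands_2015`,
#'   `bands_2021`.
#' @export
generate_landscape <- function(config) {
  elevation <- generate_terrain(config)
  streams <- generate_streams(config, elevation)
  truth <- generate_cover_truth(config, elevation, streams)
  list(config = config,
       elevation = elevation,
       streams = streams,
       truth = truth,
       bands_2015 = render_sensor_bands(truth, config, "2015"),
       bands_2021 = render_sensor_bands(truth, config, "2021"))
}
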