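plane_grid <- function(f, n = 9, cs = 30) {
  # f(x_east_m, y_north_m) -> elevation; row 1 is the northern edge
  z <- outer(seq_len(n), seq_len(n),
             function(i, j) f((j - 0.5) * cs, (n - i + 0.5) * cs))
  raster_grid(z, cellsize = cs)
}

test_that("slope and aspect match analytic planes", {
  # constant surface: slope 0, aspect 0 (flat convention) on interior cells
  flat <- slope_aspect(raster_grid(matrix(5, 6, 6)))
  expect_true(all(flat$slope$values[2:5, 2:5] == 0))
  expect_true(all(flat$aspect$values[2:5, 2:5] == 0))
  expect_true(all(is.na(flat$slope$values[1, ])))  # edges are nodata

  # plane rising eastward at 10 degrees: downslope faces west (270)
  east <- slope_aspect(plane_grid(function(x, y) x * tan(10 * pi / 180)))
  expect_equal(east$slope$values[5, 5], 10, tolerance = 1e-6)
  expect_equal(east$aspect$values[5, 5], 270, tolerance = 1e-6)

  # plane rising northward at 10 degrees: downslope faces south (180)
  north <- slope_aspect(plane_grid(function(x, y) y * tan(10 * pi / 180)))
  expect_equal(north$slope$values[5, 5], 10, tolerance = 1e-6)
  expect_equal(north$aspect$values[5, 5], 180, tolerance = 1e-6)

  # plane rising southward: downslope faces north; wraparound stays in [0, 360)
  south <- slope_aspect(plane_grid(function(x, y) -y * tan(5 * pi / 180)))
  a <- south$aspect$values[5, 5]
  expect_true(a >= 0 && a < 360)
  expect_equal(a %% 360, 0, tolerance = 1e-6)
})

test_that("ruggedness is the mean absolute neighbour difference", {
  expect_true(all(ruggedness(raster_grid(matrix(7, 5, 5)))$values[2:4, 2:4] == 0))
  z <- matrix(4, 3, 3); z[2, 2] <- 5
  expect_equal(ruggedness(raster_grid(z))$values[2, 2], 1.0)
  # alternating +-1 neighbours around 0: absolute form gives 1, signed gives 0
  z <- matrix(c(1, -1, 1, -1, 0, -1, 1, -1, 1), 3, 3)
  expect_equal(ruggedness(raster_grid(z))$values[2, 2], 1.0)
  expect_error(ruggedness(raster_grid(matrix(0, 2, 2))), "unsupported grid")
})

test_that("distance raster gives exact cell-centre Euclidean distances", {
  m <- matrix(0, 5, 5); m[3, 3] <- 1
  d <- distance_raster(raster_grid(m, cellsize = 30))
  expect_equal(d$values[3, 3], 0)          # source pixel itself
  expect_equal(d$values[3, 4], 30)         # 4-adjacent
  expect_equal(d$values[4, 4], 30 * sqrt(2), tolerance = 1e-9)  # diagonal
  expect_equal(d$values[1, 1], 30 * sqrt(8), tolerance = 1e-9)
  expect_error(distance_raster(raster_grid(matrix(0, 4, 4))), "empty-source")
})

test_that("distance transform equals brute force on random masks", {
  for (seed in 1:5) {
    set.seed(seed)
    nr <- sample(10:40, 1); nc <- sample(10:40, 1)
    m <- matrix(rbinom(nr * nc, 1, 0.03), nr, nc)
    if (!any(m == 1)) m[1, 1] <- 1
    g <- raster_grid(m, cellsize = 30)
    expect_equal(distance_raster(g)$values, distance_oracle(g),
                 tolerance = 1e-9)
  }
})

test_that("adding source pixels never increases distances", {
  set.seed(42)
  m <- matrix(0, 20, 20); m[sample(400, 3)] <- 1
  g1 <- raster_grid(m, cellsize = 30)
  m2 <- m; m2[sample(which(m == 0), 5)] <- 1
  g2 <- raster_grid(m2, cellsize = 30)
  expect_true(all(distance_raster(g2)$values <= distance_raster(g1)$values + 1e-12))
})

test_that("region buffering follows the distance transform", {
  m <- matrix(0, 7, 7); m[4, 4] <- 1
  g <- raster_grid(m, cellsize = 30)
  expect_equal(buffer_region(g, 0)$values, m)  # distance 0 is the identity
  plus <- buffer_region(g, 30)$values
  expect_equal(sum(plus), 5)  # 5-cell plus pattern
  expect_equal(plus[3, 4] + plus[5, 4] + plus[4, 3] + plus[4, 5], 4)
  big <- buffer_region(g, 90)$values
  expect_true(all(big >= m))  # buffered mask contains the original
  expect_error(buffer_region(g, -1), "configuration error")
})

test_that("stream masks merge as a logical OR", {
  a <- raster_grid(matrix(c(1, 0, 0, 1), 2, 2))
  b <- raster_grid(matrix(c(0, 0, 1, 1), 2, 2))
  expect_equal(merge_stream_masks(a, b)$values, matrix(c(1, 0, 1, 1), 2, 2))
})

test_that("the predictor stack is complete and co-registered", {
  cfg <- quick_config(seed = 2, w = 32, h = 32)
  elev <- generate_terrain(cfg)
  streams <- generate_streams(cfg, elev)
  stack <- build_predictors(elev, streams)
  expect_named(stack, c("elevation", "slope", "aspect", "ruggedness",
                        "dist_creek"))
  inner <- function(m) m[2:31, 2:31]
  expect_true(all(inner(stack$slope$values) >= 0 &
                  inner(stack$slope$values) <= 90))
  expect_true(all(inner(stack$aspect$values) >= 0 &
                  inner(stack$aspect$values) < 360))
  expect_true(all(stack$ruggedness$values >= 0, na.rm = TRUE))
  expect_true(all(stack$dist_creek$values >= 0))
})
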