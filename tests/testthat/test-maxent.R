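# small helper: background data.frame over a regular 1-D gradient
grad_background <- function(n = 200) data.frame(x = seq(0, 1, length.out = n))

test_that("feature expansion counts and closed forms are right", {
  bg <- data.frame(a = runif(100), b = runif(100), c = runif(100))
  sc <- feature_scaling(bg, c("a", "b"), n_knots = 5)
  f_lin <- expand_features(bg, feature_spec("l"), sc)
  expect_equal(ncol(f_lin), 2)  # linear only, 2 predictors
  sc3 <- feature_scaling(bg, c("a", "b", "c"), n_knots = 5)
  f_lqp <- expand_features(bg, feature_spec(c("l", "q", "p")), sc3)
  expect_equal(ncol(f_lqp), 3 + 3 + 3)  # 3 linear + 3 quadratic + 3 pairs
  expect_equal(attr(f_lqp, "classes"),
               rep(c("linear", "quadratic", "product"), each = 3))
  # hinge closed form: value 0.75 at knot 0.5 with max 1 -> 0.5
  scu <- feature_scaling(data.frame(u = c(0, 1)), "u", 1)
  scu$u$knots <- 0.5
  fh <- expand_features(data.frame(u = 0.75), feature_spec("h"), scu)
  expect_equal(unname(fh[1, "hinge(u,0.5)"]), 0.5)
  # threshold is a strict indicator
  ft <- expand_features(data.frame(u = c(0.4, 0.6)), feature_spec("t"), scu)
  expect_equal(unname(ft[, "thr(u,0.5)"]), c(0, 1))
  # values outside background support are clamped and counted
  fc <- expand_features(data.frame(u = 2), feature_spec("l"), scu)
  expect_equal(unname(fc[1, 1]), 1)
  expect_equal(attr(fc, "n_clamped"), 1)
})

test_that("a constant predictor yields the uniform distribution", {
  bg <- data.frame(x = rep(1, 500))
  pres <- data.frame(x = rep(1, 50))
  m <- fit_maxent(pres, bg, feature_spec("l"), "x")
  expect_equal(m$n_params, 0L)
  g <- raster_grid(matrix(1, 10, 50))
  raw <- predict_raw(m, list(x = g), full_mask(g))
  expect_true(all(abs(raw$values - 1 / 500) < 1e-12))
})

test_that("fitting recovers a known exponential density coefficient", {
  set.seed(11)
  bg <- data.frame(x = runif(2000))
  w <- exp(2 * bg$x)
  pres <- bg[sample(2000, 1000, replace = TRUE, prob = w / sum(w)), ,
             drop = FALSE]
  m <- fit_maxent(pres, bg, feature_spec("l", reg_multiplier = 1), "x")
  expect_true(m$converged)
  expect_gt(unname(m$coefficients["x"]), 1.5)
  expect_lt(unname(m$coefficients["x"]), 2.5)
})

test_that("the fitted optimum matches a fine grid search on small cases", {
  # <= 200 background cells, linear feature only: 1-D convex problem
  for (seed in c(3, 4)) {
    set.seed(seed)
    bg <- grad_background(150)
    pres <- bg[sample(150, 40, replace = TRUE,
                      prob = exp(1.3 * bg$x)), , drop = FALSE]
    m <- fit_maxent(pres, bg, feature_spec("l", reg_multiplier = 1), "x",
                    tol = 1e-8)
    sc <- feature_scaling(bg, "x", 50)
    Fb <- expand_features(bg, feature_spec("l"), sc)
    Fp <- expand_features(pres, feature_spec("l"), sc)
    obj <- function(lam) {
      eta <- Fb[, 1] * lam
      -mean(Fp[, 1]) * lam + log(sum(exp(eta))) + m$beta[1] * abs(lam)
    }
    grid <- seq(-4, 4, by = 1e-3)
    best_grid <- min(vapply(grid, obj, numeric(1)))
    expect_lte(obj(unname(m$coefficients["x"])), best_grid + 1e-4)
  }
})

test_that("stronger regularization never increases model complexity", {
  set.seed(21)
  bg <- data.frame(x = runif(800), z = runif(800))
  pres <- bg[sample(800, 200, replace = TRUE,
                    prob = exp(1.5 * bg$x - 0.8 * bg$z)), , drop = FALSE]
  ks <- vapply(c(0.3, 0.5, 0.75, 1, 3, 5), function(rm) {
    fit_maxent(pres, bg, feature_spec(c("l", "q", "h"), n_knots = 8,
                                      reg_multiplier = rm),
               c("x", "z"))$n_params
  }, integer(1))
  expect_true(all(diff(ks) <= 0))
})

test_that("raw output is normalized, rank-preserving and cloglog-bounded", {
  cfg <- quick_config(seed = 5, w = 48, h = 48)
  scape <- generate_landscape(cfg)
  mask <- full_mask(scape$elevation)
  stack <- build_predictors(scape$elevation, scape$streams)
  occ <- extract_predictors(
    filter_to_class(cast_random_points(mask, 4000, 1),
                    scape$truth$evergreen_2015),
    stack[c("elevation", "dist_creek")])
  bg <- extract_predictors(sample_background(mask, 1200, 2),
                           stack[c("elevation", "dist_creek")])
  m <- fit_maxent(occ, bg, feature_spec(c("l", "q")),
                  c("elevation", "dist_creek"))
  raw <- predict_raw(m, stack, mask, normalize = TRUE)
  expect_equal(sum(raw$values, na.rm = TRUE), 1, tolerance = 1e-9)
  suit <- predict_suitability(m, stack, mask)
  ok <- !is.na(suit$values)
  expect_true(all(suit$values[ok] >= 0 & suit$values[ok] <= 1))
  # cloglog is monotone in raw: identical orderings
  expect_equal(order(raw$values[ok]), order(suit$values[ok]))
  expect_error(predict_raw(m, stack["elevation"], mask),
               "configuration error")
})
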