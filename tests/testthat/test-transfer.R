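fit_small_model <- function(seed = 6) {
  cfg <- quick_config(seed = seed, w = 56, h = 56)
  scape <- generate_landscape(cfg)
  stack <- build_predictors(scape$elevation, scape$streams)
  mask <- full_mask(scape$elevation)
  occ <- extract_predictors(
    filter_to_class(cast_random_points(mask, 4000, 1),
                    scape$truth$evergreen_2015),
    stack[c("elevation", "dist_creek")])
  bg <- extract_predictors(sample_background(mask, 1000, 2),
                           stack[c("elevation", "dist_creek")])
  model <- fit_maxent(occ, bg, feature_spec(c("l", "q")),
                      c("elevation", "dist_creek"))
  list(model = model, stack = stack, mask = mask, scape = scape, occ = occ)
}

test_that("the truncation mask flags exactly the out-of-range cells", {
  f <- fit_small_model()
  preds <- c("elevation", "dist_creek")
  ranges <- calibration_ranges(f$stack, f$mask, preds)
  # test region identical to calibration region: everything in range
  m_id <- build_truncation_mask(f$stack, ranges, preds)
  expect_true(all(m_id$values == 1))
  # one predictor shifted above its calibration max everywhere: all masked
  shifted <- f$stack
  shifted$elevation <- rg_like(f$stack$elevation,
                               f$stack$elevation$values +
                                 diff(ranges$elevation) + 10)
  m_out <- build_truncation_mask(shifted, ranges, preds)
  expect_true(all(m_out$values == 0))
  # mixed case agrees with a brute-force per-cell range check
  mixed <- f$stack
  mixed$elevation$values <- mixed$elevation$values +
    seq(-50, 50, length.out = rg_ncell(f$stack$elevation))
  m_mix <- build_truncation_mask(mixed, ranges, preds)
  brute <- (mixed$elevation$values >= ranges$elevation[1] &
            mixed$elevation$values <= ranges$elevation[2] &
            mixed$dist_creek$values >= ranges$dist_creek[1] &
            mixed$dist_creek$values <= ranges$dist_creek[2]) * 1
  expect_equal(m_mix$values, brute)
  expect_error(build_truncation_mask(f$stack, ranges["elevation"], preds),
               "configuration error")
})

test_that("projection respects the mask and matches in-region prediction", {
  f <- fit_small_model()
  preds <- c("elevation", "dist_creek")
  ranges <- calibration_ranges(f$stack, f$mask, preds)
  mask <- build_truncation_mask(f$stack, ranges, preds)
  proj <- project_model(f$model, f$stack, mask)
  direct <- predict_suitability(f$model, f$stack, f$mask)
  expect_equal(proj$values, direct$values, tolerance = 1e-9)
  # masked cells never carry values
  mask$values[1:100] <- 0
  proj2 <- project_model(f$model, f$stack, mask)
  expect_true(all(is.na(proj2$values[1:100])))
  # fully masked region: all-nodata with a warning
  mask$values[] <- 0
  expect_warning(proj3 <- project_model(f$model, f$stack, mask), "masked")
  expect_true(all(is.na(proj3$values)))
})

test_that("final evaluation drops masked occurrences and flags skill", {
  f <- fit_small_model()
  # projection of the true suitability vs occurrences sampled from it
  truth_proj <- f$scape$truth$true_suitability
  occ <- f$occ
  ev <- final_evaluation(truth_proj, occ, reps = 200, seed = 3)
  expect_lt(ev$p_value, 0.05)
  expect_equal(ev$n_dropped_masked, 0)
  # occurrences on masked cells are excluded and counted
  holed <- truth_proj
  nr <- nrow(holed$values)
  cells <- (occ$col - 1) * nr + occ$row
  holed$values[cells[1:5]] <- NA
  ev2 <- final_evaluation(holed, occ, reps = 50, seed = 3)
  expect_equal(ev2$n_dropped_masked, 5)
  # too few usable occurrences is an error
  few <- occ[1:8, ]
  expect_error(final_evaluation(truth_proj, few, reps = 10, seed = 1),
               "insufficient-data")
})

test_that("the true suitability projection validates across seeds", {
  # occurrences sampled from the generative model should be anticipated by
  # the truncated projection of the true suitability in nearly every seed
  sig <- vapply(1:10, function(s) {
    cfg <- quick_config(seed = s, w = 96, h = 64)
    scape <- generate_landscape(cfg)
    test_mask <- rg_like(scape$elevation,
                         cbind(matrix(NA_real_, 64, 48), matrix(1, 64, 48)))
    proj <- rg_like(scape$elevation)
    keep <- !is.na(test_mask$values)
    proj$values[keep] <- scape$truth$true_suitability$values[keep]
    occ <- filter_to_class(cast_random_points(test_mask, 5000, s + 77L),
                           scape$truth$evergreen_2015)
    final_evaluation(proj, occ, reps = 200, seed = s)$p_value < 0.05
  }, logical(1))
  expect_gte(sum(sig), 9)
})

test_that("shuffled occurrences rarely pass the final evaluation", {
  f <- fit_small_model()
  truth_proj <- f$scape$truth$true_suitability
  mask <- full_mask(truth_proj)
  sig <- vapply(1:20, function(s) {
    occ_null <- cast_random_points(mask, 40, seed = 100 + s)
    final_evaluation(truth_proj, occ_null, reps = 100, seed = s)$p_value < 0.05
  }, logical(1))
  expect_lte(mean(sig), 0.15)
})
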