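test_that("candidate grid counts reproduce the closed form", {
  expect_length(feature_class_combos(), 31)
  for (V in 2:7) {
    preds <- paste0("p", seq_len(V))
    cands <- enumerate_candidates(preds)
    expect_equal(nrow(cands), count_candidates(V))
    expect_equal(nrow(cands), 31 * 6 * (2^V - 1 - V))
  }
  expect_equal(count_candidates(2), 186)
  expect_error(enumerate_candidates("only_one"), "configuration error")
  # every enumerated subset has at least two predictors
  c5 <- enumerate_candidates(paste0("p", 1:5))
  sizes <- lengths(regmatches(c5$predictors, gregexpr(",", c5$predictors))) + 1
  expect_true(all(sizes >= 2))
})

test_that("partial ROC separates perfect from random predictions", {
  set.seed(31)
  n <- 50
  suit <- raster_grid(matrix(runif(2500), 50, 50))
  mask <- full_mask(suit)
  # perfect prediction: occurrences exactly on the top-suitability cells
  top <- order(suit$values, decreasing = TRUE)[1:40]
  occ <- data.frame(row = (top - 1) %% 50 + 1, col = (top - 1) %/% 50 + 1)
  suit$values[top] <- suit$values[top] + 1  # lift occupied cells to the top
  pr <- partial_roc(suit, occ, mask, reps = 200, seed = 1)
  expect_gt(pr$mean_auc_ratio, 1.5)
  expect_lt(pr$p_value, 0.05)
  # random occurrences on random suitability: ratio ~ 1 on average and
  # non-significant in at least 90% of seeded null runs
  null_runs <- lapply(1:20, function(s) {
    set.seed(300 + s)
    occ_r <- data.frame(row = sample(50, 40, TRUE), col = sample(50, 40, TRUE))
    suit_r <- raster_grid(matrix(runif(2500), 50, 50))
    partial_roc(suit_r, occ_r, mask, reps = 200, seed = 400 + s)
  })
  ratios <- vapply(null_runs, `[[`, numeric(1), "mean_auc_ratio")
  expect_lt(abs(mean(ratios) - 1), 0.1)
  # the bootstrap p-value ignores the sampling variability of the original
  # occurrence draw, so the null rejection rate is near, not exactly at, the
  # nominal level; it must stay within the tolerated band
  expect_lte(mean(vapply(null_runs, `[[`, numeric(1), "p_value") < 0.05), 0.15)
  expect_error(partial_roc(raster_grid(matrix(0.5, 50, 50)), occ, mask),
               "degenerate-prediction")
})

test_that("the partial-AUC ratio matches an independent trapezoid oracle", {
  set.seed(7)
  for (i in 1:10) {
    thr <- seq(0, 1, length.out = 80)
    s_all <- runif(3000)
    s_occ <- rbeta(60, 3, 1.5)
    area <- vapply(thr, function(t) mean(s_all >= t), numeric(1))
    sens <- vapply(thr, function(t) mean(s_occ >= t), numeric(1))
    ours <- wpeniche:::proc_ratio(area, sens, E = 0.10)
    expect_equal(ours, proc_oracle(area, sens, E = 0.10), tolerance = 1e-9)
  }
})

test_that("omission uses the calibration E-percentile threshold", {
  set.seed(41)
  cal <- runif(200)
  # evaluation occurrences at maximum suitability: zero omission, pass
  om0 <- omission_rate(cal, rep(1, 50), E = 0.10)
  expect_equal(om0$omission, 0)
  expect_true(om0$pass)
  # evaluating on the calibration set itself sits at the E boundary
  om_self <- omission_rate(cal, cal, E = 0.10)
  expect_lte(om_self$omission, 0.10)
  expect_gte(om_self$omission, 0.05)
  # everything below threshold: omission 1, fail
  om1 <- omission_rate(cal, rep(-1, 10), E = 0.10)
  expect_equal(om1$omission, 1.0)
  expect_false(om1$pass)
  expect_error(omission_rate(numeric(0), cal), "insufficient-data")
})

test_that("AICc matches hand and oracle arithmetic", {
  # worked case: raw = (.4,.3,.2,.1), occurrences at cells 1,1,2, k = 1
  ic <- aicc(c(0.4, 0.4, 0.3), k = 1)
  expect_equal(ic$aicc, 2 - 2 * (2 * log(0.4) + log(0.3)) + 4, tolerance = 1e-12)
  # n = k + 1 is invalid
  expect_false(aicc(c(0.5, 0.5), k = 1)$valid)
  expect_equal(aicc(c(0.5, 0.5), k = 1)$aicc, Inf)
  # k = 0 with uniform raw over N cells: AICc = 2 n ln N
  N <- 64; n <- 12
  expect_equal(aicc(rep(1 / N, n), k = 0)$aicc, 2 * n * log(N),
               tolerance = 1e-12)
  # zero raw at an occurrence -> infinite AICc
  expect_equal(aicc(c(0.2, 0), k = 0)$aicc, Inf)
  expect_error(aicc(c(0.1, NA), 1), "data error")
  # random small cases against the independent oracle
  set.seed(8)
  for (i in 1:20) {
    n <- sample(5:30, 1); k <- sample(0:3, 1)
    p <- runif(n, 0.001, 0.05)
    expect_equal(aicc(p, k)$aicc, aicc_oracle(p, k), tolerance = 1e-9)
  }
})

test_that("three-stage selection is ordered with a deterministic best set", {
  res <- data.frame(
    candidate = 1:5,
    p_value = c(0.01, 0.01, 0.20, 0.01, 0.01),
    omission = c(0.05, 0.30, 0.05, 0.08, 0.01),
    aicc = c(100.0, 95.0, 90.0, 101.9, 102.1),
    k = c(3, 2, 1, 5, 2))
  rep <- select_best(res)
  # candidate 2 fails omission, 3 fails significance: never in later stages
  expect_equal(rep$n_significant, 4)
  expect_equal(rep$n_low_omission, 3)
  expect_equal(rep$min_aicc, 100.0)
  # 100.0 and 101.9 are within 2 units; 102.1 is not
  expect_equal(rep$best, c(1, 4))
  # no survivors -> empty best set with diagnostics, not an error
  res$p_value <- 0.5
  rep0 <- select_best(res)
  expect_length(rep0$best, 0)
  expect_equal(rep0$n_significant, 0)
})

test_that("the median ensemble is cellwise and bounded", {
  g <- function(v) raster_grid(matrix(v, 4, 4))
  expect_equal(median_ensemble(list(g(0.3)))$values, g(0.3)$values)
  med <- median_ensemble(list(g(0.2), g(0.5), g(0.9)))
  expect_true(all(med$values == 0.5))
  set.seed(9)
  gs <- lapply(1:5, function(i) raster_grid(matrix(runif(16), 4, 4)))
  med2 <- median_ensemble(gs)$values
  lo <- Reduce(pmin, lapply(gs, function(x) x$values))
  hi <- Reduce(pmax, lapply(gs, function(x) x$values))
  expect_true(all(med2 >= lo & med2 <= hi))
  expect_error(median_ensemble(list()), "insufficient-data")
})
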