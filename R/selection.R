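#' Candidate-model grids and ordered three-stage selection
#'
#' Enumerates the candidate grid (all non-empty feature-class combinations x
#' regularization multipliers x predictor subsets of size >= 2) and applies
#' the ordered selection used for niche-model calibration: (1) keep
#' candidates making statistically significant predictions under the partial
#' ROC test (p < 0.05), (2) keep those omitting < 10% of the evaluation
#' occurrences, (3) keep those within 2 AICc units of the minimum among
#' survivors. The best models' predictions are combined as a cellwise median.
#'
#' @name selection
NULL

PAPER_REG_MULTIPLIERS <- c(0.3, 0.5, 0.75, 1, 3, 5)

#' All feature-class combinations
#'
#' The 31 non-empty subsets of {linear, quadratic, product, threshold,
#' hinge}.
#'
#' @return List of character vectors, length 31.
#' @export
feature_class_combos <- function() {
  combos <- list()
  for (k in seq_along(MAXENT_CLASSES))
    combos <- c(combos, utils::combn(MAXENT_CLASSES, k, simplify = FALSE))
  combos
}

#' Enumerate the candidate-model grid
#'
#' Full cross product of feature-class combinations, regularization
#' multipliers and predictor subsets of size >= 2. With the standard 31
#' combinations and 6 multipliers the grid size is
#' `186 x (2^V - 1 - V)`: 4836 candidates for V = 5 predictors and 22,320
#' for V = 7.
#'
#' @param predictor_names character vector of V >= 2 predictor names.
#' @param reg_multipliers numeric vector, default {0.3, 0.5, 0.75, 1, 3, 5}.
#' @param class_combos list of feature-class subsets, default all 31.
#' @return data.frame with one row per candidate: `candidate`, `features`
#'   (letter code), `reg_multiplier`, `predictors` (comma-joined).
#' @export
enumerate_candidates <- function(predictor_names,
                                 reg_multipliers = PAPER_REG_MULTIPLIERS,
                                 class_combos = feature_class_combos()) {
  V <- length(predictor_names)
  if (V < 2L)
    stop("configuration error: need at least 2 predictors", call. = FALSE)
  subsets <- list()
  for (k in 2:V)
    subsets <- c(subsets, utils::combn(predictor_names, k, simplify = FALSE))
  grid <- expand.grid(ci = seq_along(class_combos),
                      ri = seq_along(reg_multipliers),
                      si = seq_along(subsets))
  out <- data.frame(
    candidate = seq_len(nrow(grid)),
    features = vapply(class_combos[grid$ci],
                      function(cl) paste(substr(cl, 1, 1), collapse = ""),
                      character(1)),
    reg_multiplier = reg_multipliers[grid$ri],
    predictors = vapply(subsets[grid$si], paste, character(1), collapse = ","),
    stringsAsFactors = FALSE
  )
  attr(out, "class_combos") <- class_combos[grid$ci]
  attr(out, "subsets") <- subsets[grid$si]
  out
}

#' Number of candidate models in the full grid
#'
#' Closed-form count `n_combos x n_multipliers x (2^V - 1 - V)`.
#'
#' @param n_predictors number of predictors V >= 2.
#' @param n_combos feature-class combinations (default 31).
#' @param n_multipliers regularization multipliers (default 6).
#' @return Integer count.
#' @export
count_candidates <- function(n_predictors, n_combos = 31L, n_multipliers = 6L) {
  if (n_predictors < 2L)
    stop("configuration error: need at least 2 predictors", call. = FALSE)
  as.integer(n_combos * n_multipliers *
               (2^n_predictors - 1 - n_predictors))
}

# one partial-ROC curve evaluation: sensitivities at thresholds and the
# partial-area ratio restricted to sensitivity >= 1 - E
proc_ratio <- function(area_frac, sens, E) {
  keep <- sens >= 1 - E
  if (sum(keep) < 2L) return(NA_real_)
  x <- area_frac[keep]; y <- sens[keep]
  o <- order(x)
  x <- x[o]; y <- y[o]
  pauc <- sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  pauc_null <- (max(x)^2 - min(x)^2) / 2
  if (pauc_null <= 0) return(NA_real_)
  pauc / pauc_null
}

#' Partial ROC test of a suitability prediction
#'
#' Bootstrap partial-ROC significance test: the ROC curve of sensitivity
#' (1 - omission of occurrences) against proportion of the region predicted
#' present, restricted to the high-sensitivity domain (sensitivity
#' >= 1 - E), is compared to the chance diagonal. Per replicate, a fraction
#' of the occurrences is resampled with replacement and the ratio of the
#' model partial AUC to the null partial AUC over the same domain is
#' computed; significance is the fraction of replicate ratios <= 1
#' (a bias-corrected `(1 + count) / (reps + 1)` p-value is reported
#' alongside the raw fraction).
#'
#' @param suitability `raster_grid` of model output.
#' @param test_occ `occurrence_set` of evaluation occurrences (with `col`,
#'   `row`).
#' @param region_mask binary `raster_grid` delimiting the prediction region.
#' @param E tolerated omission proportion (default 0.10).
#' @param reps bootstrap replicates (default 500).
#' @param bootstrap_frac fraction of occurrences resampled per replicate.
#' @param seed integer seed.
#' @param n_thresholds suitability thresholds spanning the value range.
#' @return List with `mean_auc_ratio`, `p_value`, `p_raw`, `n_occ`, `ratios`.
#' @export
partial_roc <- function(suitability, test_occ, region_mask, E = 0.10,
                        reps = 500L, bootstrap_frac = 0.5, seed = 1,
                        n_thresholds = 100L) {
  in_region <- !is.na(region_mask$values) & region_mask$values == 1 &
    !is.na(suitability$values)
  s_all <- suitability$values[in_region]
  if (length(unique(s_all)) < 2L)
    stop("degenerate-prediction error: constant suitability raster",
         call. = FALSE)
  nr <- nrow(suitability$values)
  cell <- (test_occ$col - 1L) * nr + test_occ$row
  s_occ <- suitability$values[cell]
  s_occ <- s_occ[!is.na(s_occ)]
  n <- length(s_occ)
  if (n < 10L)
    stop("insufficient-data error: need at least 10 test occurrences",
         call. = FALSE)
  thr <- seq(min(s_all), max(s_all), length.out = n_thresholds)
  # fraction of region predicted present at each threshold (descending in thr)
  area_frac <- vapply(thr, function(t) mean(s_all >= t), numeric(1))
  n_boot <- ceiling(bootstrap_frac * n)
  ratios <- with_seed(seed, {
    vapply(seq_len(reps), function(r) {
      sb <- s_occ[sample.int(n, n_boot, replace = TRUE)]
      sens <- vapply(thr, function(t) mean(sb >= t), numeric(1))
      proc_ratio(area_frac, sens, E)
    }, numeric(1))
  })
  ratios <- ratios[!is.na(ratios)]
  list(mean_auc_ratio = mean(ratios),
       p_raw = mean(ratios <= 1),
       p_value = (1 + sum(ratios <= 1)) / (length(ratios) + 1),
       n_occ = n, ratios = ratios)
}

#' Omission rate at a calibration-derived threshold
#'
#' The threshold is the E-percentile of suitability at the calibration
#' occurrences (modified least training presence); the omission rate is the
#' fraction of evaluation occurrences with suitability strictly below it. A
#' candidate passes the performance filter iff omission < E.
#'
#' @param suit_cal numeric suitability values at calibration occurrences.
#' @param suit_test numeric suitability values at evaluation occurrences.
#' @param E tolerated omission proportion (default 0.10).
#' @return List with `threshold`, `omission`, `pass`.
#' @export
omission_rate <- function(suit_cal, suit_test, E = 0.10) {
  if (length(suit_cal) == 0L || length(suit_test) == 0L)
    stop("insufficient-data error: empty occurrence sets", call. = FALSE)
  thr <- stats::quantile(suit_cal, probs = E, type = 1, names = FALSE)
  om <- mean(suit_test < thr)
  list(threshold = thr, omission = om, pass = om < E)
}

#' AICc of a maximum-entropy candidate
#'
#' Small-sample-corrected AIC with the likelihood evaluated from the raw
#' output normalized over the calibration region at occurrence cells and `k`
#' counted as the number of nonzero model coefficients:
#' `AICc = 2k - 2 lnL + 2k(k+1) / (n - k - 1)`. Returns `Inf` (flagged
#' invalid) when `n <= k + 1` or when any occurrence has zero raw output.
#'
#' @param raw_at_occ raw (region-normalized) output values at the n
#'   occurrence cells.
#' @param k number of nonzero model coefficients.
#' @return List with `aicc`, `loglik`, `k`, `n`, `valid`.
#' @export
aicc <- function(raw_at_occ, k) {
  if (anyNA(raw_at_occ))
    stop("data error: occurrence on nodata cell", call. = FALSE)
  n <- length(raw_at_occ)
  lnL <- sum(log(raw_at_occ))
  if (n <= k + 1 || !is.finite(lnL))
    return(list(aicc = Inf, loglik = lnL, k = k, n = n, valid = FALSE))
  list(aicc = 2 * k - 2 * lnL + 2 * k * (k + 1) / (n - k - 1),
       loglik = lnL, k = k, n = n, valid = TRUE)
}

#' Ordered three-stage best-model selection
#'
#' Applies the selection stages in order to a per-candidate results table:
#' stage 1 keeps candidates with partial-ROC p < 0.05; stage 2 keeps those
#' with omission rate < E; stage 3 keeps those within `delta_aicc_max` of the
#' minimum AICc among stage-2 survivors. Ties are ordered deterministically
#' by (AICc, k, candidate index). An empty best set is returned with stage
#' diagnostics rather than an error.
#'
#' @param results data.frame with columns `candidate`, `p_value`, `omission`,
#'   `aicc`, `k`.
#' @param alpha significance level for stage 1 (default 0.05).
#' @param E omission tolerance for stage 2 (default 0.10).
#' @param delta_aicc_max AICc window for stage 3 (default 2).
#' @return A list of class `selection_report`: the annotated table, the
#'   per-stage survivor counts, `min_aicc` and `best` (candidate ids).
#' @export
select_best <- function(results, alpha = 0.05, E = 0.10, delta_aicc_max = 2) {
  res <- results
  res$pass_proc <- !is.na(res$p_value) & res$p_value < alpha
  res$pass_omission <- res$pass_proc & !is.na(res$omission) & res$omission < E
  surv <- res[res$pass_omission & is.finite(res$aicc), , drop = FALSE]
  if (nrow(surv) > 0L) {
    min_aicc <- min(surv$aicc)
    res$delta_aicc <- ifelse(res$pass_omission, res$aicc - min_aicc, NA_real_)
    res$best <- res$pass_omission & is.finite(res$aicc) &
      (res$aicc - min_aicc) <= delta_aicc_max
    best_rows <- res[res$best, , drop = FALSE]
    best_rows <- best_rows[order(best_rows$aicc, best_rows$k,
                                 best_rows$candidate), , drop = FALSE]
    best <- best_rows$candidate
  } else {
    min_aicc <- NA_real_
    res$delta_aicc <- NA_real_
    res$best <- FALSE
    best <- integer(0)
  }
  structure(list(
    results = res,
    n_candidates = nrow(res),
    n_significant = sum(res$pass_proc),
    n_low_omission = sum(res$pass_omission),
    min_aicc = min_aicc,
    best = best
  ), class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat(sprintf(
    "selection_report: %d candidates -> %d significant -> %d low-omission -> %d best (min AICc = %.2f)\n",
    x$n_candidates, x$n_significant, x$n_low_omission, length(x$best),
    x$min_aicc))
  invisible(x)
}

#' Cellwise median of prediction rasters
#'
#' @param predictions list of co-registered `raster_grid`s (length >= 1).
#' @return `raster_grid` holding the cellwise median.
#' @export
median_ensemble <- function(predictions) {
  if (length(predictions) == 0L)
    stop("insufficient-data error: no predictions to ensemble", call. = FALSE)
  do.call(rg_check_aligned, predictions)
  vals <- vapply(predictions, function(g) as.vector(g$values),
                 numeric(rg_ncell(predictions[[1L]])))
  vals <- matrix(vals, ncol = length(predictions))
  med <- apply(vals, 1L, stats::median)
  g <- predictions[[1L]]
  rg_like(g, matrix(med, nrow(g$values), ncol(g$values)))
}
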