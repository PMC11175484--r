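#' Range-truncated model transfer
#'
#' Projects best models (or their median ensemble) onto an independent
#' region with no extrapolation permitted: any cell where a model predictor
#' falls outside the range observed over the calibration region receives no
#' prediction (nodata), and the projection is evaluated against independent
#' occurrences with the final partial-ROC test.
#'
#' @name transfer
NULL

#' Predictor ranges over the calibration region
#'
#' @param stack named list of predictor `raster_grid`s.
#' @param region_mask binary calibration-region `raster_grid`.
#' @param predictor_names predictors to summarise.
#' @return Named list of `c(min, max)` per predictor.
#' @export
calibration_ranges <- function(stack, region_mask, predictor_names) {
  rv <- stack_region_values(stack, region_mask, predictor_names)
  lapply(rv$values, range)
}

#' Build the no-extrapolation truncation mask
#'
#' A test-region cell is in-range (mask 1) iff every predictor used by the
#' model lies within its calibration [min, max]; out-of-range cells are 0 and
#' receive no prediction downstream.
#'
#' @param stack_test predictor stack over the test region.
#' @param calibration_ranges output of [calibration_ranges()].
#' @param predictor_subset predictors used by the model being transferred.
#' @param region_mask optional binary mask of the test region (cells outside
#'   it become nodata).
#' @return binary `raster_grid` of class `truncation_mask` with the ranges
#'   attached as an attribute.
#' @export
build_truncation_mask <- function(stack_test, calibration_ranges,
                                  predictor_subset, region_mask = NULL) {
  miss <- setdiff(predictor_subset, names(calibration_ranges))
  if (length(miss))
    stop("configuration error: no calibration range for: ",
         paste(miss, collapse = ", "), call. = FALSE)
  tmpl <- stack_test[[predictor_subset[1L]]]
  ok <- matrix(TRUE, nrow(tmpl$values), ncol(tmpl$values))
  for (p in predictor_subset) {
    v <- stack_test[[p]]$values
    r <- calibration_ranges[[p]]
    ok <- ok & !is.na(v) & v >= r[1L] & v <= r[2L]
  }
  out <- rg_like(tmpl, ifelse(ok, 1, 0))
  if (!is.null(region_mask)) {
    rg_check_aligned(out, region_mask)
    out$values[is.na(region_mask$values) | region_mask$values != 1] <- NA_real_
  }
  attr(out, "ranges") <- calibration_ranges[predictor_subset]
  class(out) <- c("truncation_mask", class(out))
  out
}

#' Project a model or ensemble onto a test region
#'
#' Suitability on in-range cells of the truncation mask, nodata elsewhere.
#' For a list of models the projection is the cellwise median of the member
#' projections.
#'
#' @param model a `maxent_model` or a list of them.
#' @param stack_test predictor stack over the test region.
#' @param mask binary `truncation_mask` from [build_truncation_mask()].
#' @return `raster_grid` of suitability, nodata on masked cells.
#' @export
project_model <- function(model, stack_test, mask) {
  if (!inherits(model, "maxent_model") && is.list(model)) {
    members <- lapply(model, project_model, stack_test = stack_test,
                      mask = mask)
    return(median_ensemble(members))
  }
  in_cells <- !is.na(mask$values) & mask$values == 1
  if (!any(in_cells)) {
    warning("all cells masked as extrapolative; projection is all-nodata")
    return(rg_like(mask))
  }
  region <- rg_like(mask, ifelse(in_cells, 1, NA_real_))
  predict_suitability(model, stack_test, region)
}

#' Final independent partial-ROC evaluation of a projection
#'
#' Occurrences falling on masked (nodata) cells of the projection are
#' dropped and their count reported; the remaining occurrences enter the
#' same bootstrap partial-ROC statistic used during calibration.
#'
#' @param projection truncated suitability `raster_grid` from
#'   [project_model()].
#' @param independent_occ `occurrence_set` from the test region.
#' @param E tolerated omission proportion (default 0.10).
#' @param reps bootstrap replicates (default 500).
#' @param seed integer seed.
#' @return List with `mean_auc_ratio`, `p_value`, `p_raw`, `n_occ`,
#'   `n_dropped_masked`.
#' @export
final_evaluation <- function(projection, independent_occ, E = 0.10,
                             reps = 500L, seed = 1) {
  nr <- nrow(projection$values)
  cell <- (independent_occ$col - 1L) * nr + independent_occ$row
  on_valid <- !is.na(projection$values[cell])
  n_dropped <- sum(!on_valid)
  usable <- independent_occ[on_valid, , drop = FALSE]
  if (nrow(usable) < 10L)
    stop("insufficient-data error: fewer than 10 occurrences on unmasked cells",
         call. = FALSE)
  region <- rg_like(projection,
                    ifelse(is.na(projection$values), NA_real_, 1))
  out <- partial_roc(projection, usable, region, E = E, reps = reps,
                     seed = seed)
  out$n_dropped_masked <- n_dropped
  out$ratios <- NULL
  out
}
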