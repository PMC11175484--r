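#' End-to-end experiment orchestration
#'
#' Configuration-driven runs of the two modelling experiments on a synthetic
#' landscape: the first-date evergreen distribution model (five terrain and
#' distance predictors) and the encroachment (WPE) model (seven predictors,
#' adding distance to the first-date evergreen extent and the first
#' experiment's suitability surface). Each run executes classification,
#' occurrence sampling, predictor derivation, candidate-grid calibration with
#' ordered three-stage selection, a median ensemble of best models, and
#' range-truncated transfer to a held-out region with a final partial-ROC
#' evaluation.
#'
#' @name pipeline
NULL

#' Experiment configuration
#'
#' Defaults describe a desk-scale run: a 120 x 80 cell synthetic landscape
#' split into a western calibration region and an eastern test region, a
#' reduced candidate grid (six representative feature-class combinations x
#' all six regularization multipliers x all predictor subsets, optionally
#' subsampled), 10 knots for threshold/hinge features, and fewer bootstrap
#' replicates during candidate screening than in the final evaluation. The
#' full 31-combination grid is available via `full_grid = TRUE`.
#'
#' @param landscape a [landscape_config()].
#' @param seed master seed for sampling, fitting order and evaluation.
#' @param cal_fraction fraction of grid columns forming the calibration
#'   region (the remainder is the test region).
#' @param n_cast random points cast per region before class filtering.
#' @param n_background background cells sampled from the calibration region.
#' @param feature_codes character vector of feature-class letter codes for
#'   the candidate grid (e.g. `"lq"`); ignored when `full_grid = TRUE`.
#' @param reg_multipliers regularization multipliers for the grid.
#' @param predictors predictor names for the first experiment.
#' @param n_candidates optional cap: a seeded subsample of the enumerated
#'   grid of this size is evaluated (`NULL` = evaluate all enumerated).
#' @param n_knots knots for threshold/hinge features during pipeline runs.
#' @param E tolerated omission proportion.
#' @param reps_calibration partial-ROC replicates during candidate screening.
#' @param reps_final partial-ROC replicates for the final evaluation.
#' @param full_grid use all 31 feature-class combinations.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(landscape = landscape_config(grid_width = 120,
                                                           grid_height = 80),
                              seed = 1,
                              cal_fraction = 0.5,
                              n_cast = 10000,
                              n_background = 2000,
                              feature_codes = c("l", "lq", "lqp", "t", "h",
                                                "lqpth"),
                              reg_multipliers = PAPER_REG_MULTIPLIERS,
                              predictors = c("elevation", "slope", "aspect",
                                             "ruggedness", "dist_creek"),
                              n_candidates = 40,
                              n_knots = 10,
                              E = 0.10,
                              reps_calibration = 100L,
                              reps_final = 500L,
                              full_grid = FALSE) {
  structure(list(
    landscape = landscape, seed = as.integer(seed),
    cal_fraction = cal_fraction, n_cast = n_cast,
    n_background = n_background, feature_codes = feature_codes,
    reg_multipliers = reg_multipliers, predictors = predictors,
    n_candidates = n_candidates, n_knots = n_knots, E = E,
    reps_calibration = as.integer(reps_calibration),
    reps_final = as.integer(reps_final), full_grid = full_grid
  ), class = "experiment_config")
}

# calibration / test region masks by column split
split_region_masks <- function(template, cal_fraction) {
  nc <- ncol(template$values)
  cal_cols <- seq_len(max(1L, floor(cal_fraction * nc)))
  cal <- matrix(0, nrow(template$values), nc)
  cal[, cal_cols] <- 1
  list(cal = rg_like(template, cal), test = rg_like(template, 1 - cal))
}

feature_code_to_classes <- function(code) {
  short <- c(l = "linear", q = "quadratic", p = "product", t = "threshold",
             h = "hinge")
  unname(short[strsplit(code, "")[[1L]]])
}

# build (and optionally subsample) the candidate table for a predictor set
pipeline_candidates <- function(config, predictors) {
  combos <- if (isTRUE(config$full_grid)) feature_class_combos() else
    lapply(config$feature_codes, feature_code_to_classes)
  cands <- enumerate_candidates(predictors,
                                reg_multipliers = config$reg_multipliers,
                                class_combos = combos)
  if (!is.null(config$n_candidates) && config$n_candidates < nrow(cands)) {
    keep <- with_seed(config$seed + 71L,
                      sort(sample.int(nrow(cands), config$n_candidates)))
    at_c <- attr(cands, "class_combos")[keep]
    at_s <- attr(cands, "subsets")[keep]
    cands <- cands[keep, , drop = FALSE]
    attr(cands, "class_combos") <- at_c
    attr(cands, "subsets") <- at_s
  }
  cands
}

# fit and score every candidate; returns results table + fitted models +
# calibration-region suitability maps. Each candidate is fitted twice:
# on the calibration half for the partial-ROC and omission screens, and on
# the full occurrence set for AICc and for the final (transferable) model.
evaluate_candidates <- function(cands, occ_all, occ_cal, occ_eval,
                                background, stack, cal_mask, config) {
  n <- nrow(cands)
  combos <- attr(cands, "class_combos")
  subsets <- attr(cands, "subsets")
  models <- vector("list", n)
  suits <- vector("list", n)
  res <- data.frame(candidate = cands$candidate,
                    features = cands$features,
                    reg_multiplier = cands$reg_multiplier,
                    predictors = cands$predictors,
                    p_value = NA_real_, mean_auc_ratio = NA_real_,
                    omission = NA_real_, aicc = NA_real_, k = NA_integer_)
  nr <- nrow(cal_mask$values)
  all_cells <- (occ_all$col - 1L) * nr + occ_all$row
  eval_cells <- (occ_eval$col - 1L) * nr + occ_eval$row
  cal_cells <- (occ_cal$col - 1L) * nr + occ_cal$row
  for (i in seq_len(n)) {
    spec <- feature_spec(combos[[i]], n_knots = config$n_knots,
                         reg_multiplier = cands$reg_multiplier[i])
    fit_cal <- tryCatch(
      suppressWarnings(fit_maxent(occ_cal, background, spec,
                                  predictor_names = subsets[[i]])),
      error = function(e) NULL)
    if (is.null(fit_cal)) next
    suit <- predict_suitability(fit_cal, stack, cal_mask)
    pr <- tryCatch(
      partial_roc(suit, occ_eval, cal_mask, E = config$E,
                  reps = config$reps_calibration,
                  seed = config$seed + 500L + i),
      error = function(e) NULL)
    if (!is.null(pr)) {
      res$p_value[i] <- pr$p_value
      res$mean_auc_ratio[i] <- pr$mean_auc_ratio
    }
    om <- omission_rate(suit$values[cal_cells], suit$values[eval_cells],
                        E = config$E)
    res$omission[i] <- om$omission
    # all-occurrence fit: the AICc model and the candidate's final model
    fit_all <- tryCatch(
      suppressWarnings(fit_maxent(occ_all, background, spec,
                                  predictor_names = subsets[[i]])),
      error = function(e) NULL)
    if (is.null(fit_all)) next
    models[[i]] <- fit_all
    suits[[i]] <- predict_suitability(fit_all, stack, cal_mask)
    raw <- predict_raw(fit_all, stack, cal_mask, normalize = TRUE)
    ic <- aicc(raw$values[all_cells], fit_all$n_params)
    res$aicc[i] <- ic$aicc
    res$k[i] <- fit_all$n_params
  }
  list(results = res, models = models, suitabilities = suits)
}

# shared calibrate/select/transfer/evaluate block
run_experiment_core <- function(config, stack, predictors, class_map,
                                masks, label) {
  occ_all <- filter_to_class(
    cast_random_points(masks$cal, config$n_cast, config$seed + 11L),
    class_map)
  occ_all <- extract_predictors(occ_all, stack[predictors])
  if (nrow(occ_all) < 20L)
    stop(sprintf("[%s] insufficient-data error: only %d unique occurrences",
                 label, nrow(occ_all)), call. = FALSE)
  halves <- split_half(occ_all, config$seed + 12L)
  background <- extract_predictors(
    sample_background(masks$cal, config$n_background, config$seed + 13L),
    stack[predictors])

  cands <- pipeline_candidates(config, predictors)
  ev <- evaluate_candidates(cands, occ_all, halves$cal, halves$eval,
                            background, stack, masks$cal, config)
  report <- select_best(ev$results, E = config$E)

  best_idx <- match(report$best, cands$candidate)
  best_models <- ev$models[best_idx]
  ensemble_cal <- if (length(best_idx)) {
    median_ensemble(ev$suitabilities[best_idx])
  } else NULL

  projection <- NULL; final_eval <- NULL
  occ_test <- filter_to_class(
    cast_random_points(masks$test, config$n_cast, config$seed + 21L),
    class_map)
  if (length(best_idx)) {
    members <- lapply(best_models, function(m) {
      ranges <- calibration_ranges(stack, masks$cal, m$predictor_names)
      mask <- build_truncation_mask(stack, ranges, m$predictor_names,
                                    region_mask = masks$test)
      project_model(m, stack, mask)
    })
    projection <- median_ensemble(members)
    final_eval <- tryCatch(
      final_evaluation(projection, occ_test, E = config$E,
                       reps = config$reps_final, seed = config$seed + 31L),
      error = function(e) list(error = conditionMessage(e)))
  }
  list(label = label,
       occurrences = occ_all, split = halves, background = background,
       n_occ_train = nrow(occ_all), n_occ_test = nrow(occ_test),
       candidates = cands, evaluation = ev$results, report = report,
       best_models = best_models, ensemble_cal = ensemble_cal,
       projection = projection, final_eval = final_eval,
       occ_test = occ_test)
}

#' Run the first-date evergreen distribution experiment
#'
#' Generates (or accepts) a synthetic landscape, classifies the first-date
#' forest and evergreen maps from the rendered bands, derives the
#' five-predictor stack, and runs sampling, candidate calibration, selection,
#' ensembling, truncated transfer and final evaluation.
#'
#' @param config an [experiment_config()].
#' @param scape optional pre-generated landscape from
#'   [generate_landscape()]; by default generated from `config$landscape`.
#' @return A list bundle: landscape, classified maps, predictor stack,
#'   region masks, occurrence sets, selection report, best models, median
#'   ensemble, truncated projection, final evaluation, and a manifest.
#' @export
run_forest2015 <- function(config = experiment_config(), scape = NULL) {
  if (is.null(scape)) scape <- generate_landscape(config$landscape)
  b <- scape$bands_2015
  bs <- band_stack(b$HH, b$HV, b$NDVI_max, b$NDVI_wintermean)
  forest15 <- classify_forest(bs)
  ever15 <- classify_evergreen(forest15, b$NDVI_wintermean)
  stack <- build_predictors(scape$elevation, scape$streams)
  masks <- split_region_masks(scape$elevation, config$cal_fraction)
  core <- run_experiment_core(config, stack, config$predictors, ever15,
                              masks, "forest2015")
  c(list(config = config, landscape = scape, forest_2015 = forest15,
         evergreen_2015 = ever15, stack = stack, masks = masks,
         manifest = experiment_manifest(config, core)),
    core)
}

#' Run the woody-plant-encroachment experiment
#'
#' Classifies the second-date evergreen map, overlays the two dates to
#' obtain WPE pixels, extends the predictor stack with distance to the
#' first-date evergreen extent and the first experiment's suitability
#' surface (its median best-model ensemble predicted over the full grid),
#' then runs the same calibrate/select/transfer/evaluate flow on the
#' seven-predictor grid.
#'
#' @param config an [experiment_config()]; its `predictors` field is
#'   extended with `dist_forest2015` and `suit2015`.
#' @param forest_out the bundle returned by [run_forest2015()].
#' @return A result bundle of the same shape as [run_forest2015()], plus the
#'   WPE map.
#' @export
run_wpe <- function(config, forest_out) {
  scape <- forest_out$landscape
  b21 <- scape$bands_2021
  bs21 <- band_stack(b21$HH, b21$HV, b21$NDVI_max, b21$NDVI_wintermean)
  forest21 <- classify_forest(bs21)
  ever21 <- classify_evergreen(forest21, b21$NDVI_wintermean)
  wpe <- detect_wpe(forest_out$evergreen_2015, ever21)
  if (length(forest_out$best_models) == 0L)
    stop("wpe experiment requires a non-empty best set from run_forest2015",
         call. = FALSE)
  full_mask <- rg_like(scape$elevation,
                       matrix(1, nrow(scape$elevation$values),
                              ncol(scape$elevation$values)))
  suit2015 <- median_ensemble(lapply(forest_out$best_models,
                                     predict_suitability,
                                     stack = forest_out$stack,
                                     region_mask = full_mask))
  stack <- build_predictors(scape$elevation, scape$streams,
                            evergreen_t1 = forest_out$evergreen_2015,
                            suit_t1 = suit2015)
  predictors <- unique(c(config$predictors, "dist_forest2015", "suit2015"))
  core <- run_experiment_core(config, stack, predictors, wpe,
                              forest_out$masks, "wpe")
  c(list(config = config, landscape = scape, evergreen_2021 = ever21,
         wpe_map = wpe, suit2015 = suit2015, stack = stack,
         masks = forest_out$masks,
         manifest = experiment_manifest(config, core)),
    core)
}

# plain-list run manifest for reproducibility records
experiment_manifest <- function(config, core) {
  list(
    experiment = core$label,
    seed = config$seed,
    landscape_seed = config$landscape$seed,
    grid = c(config$landscape$grid_height, config$landscape$grid_width),
    n_occ_train = core$n_occ_train,
    n_occ_test = core$n_occ_test,
    n_candidates = nrow(core$candidates),
    n_significant = core$report$n_significant,
    n_low_omission = core$report$n_low_omission,
    n_best = length(core$report$best),
    min_aicc = core$report$min_aicc
  )
}

#' Write a selection report and manifest to disk
#'
#' The per-candidate table as CSV and the summary (plus manifest) as JSON.
#'
#' @param out a bundle from [run_forest2015()] or [run_wpe()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_experiment_outputs <- function(out, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, paste0(out$label, "_candidates.csv"))
  utils::write.csv(out$report$results, csv, row.names = FALSE)
  js <- file.path(dir, paste0(out$label, "_summary.json"))
  summary <- out$manifest
  if (!is.null(out$final_eval) && is.null(out$final_eval$error)) {
    summary$final_mean_auc_ratio <- out$final_eval$mean_auc_ratio
    summary$final_p_value <- out$final_eval$p_value
  }
  jsonlite::write_json(summary, js, auto_unbox = TRUE, digits = NA)
  paths <- c(csv, js)
  for (nm in c("ensemble_cal", "projection")) {
    if (!is.null(out[[nm]])) {
      p <- file.path(dir, paste0(out$label, "_", nm, ".asc"))
      write_ascii_grid(out[[nm]], p)
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}
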