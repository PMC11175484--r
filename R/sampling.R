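#' Occurrence and background sampling
#'
#' Random point casting over a region, filtering to target-class pixels with
#' per-pixel deduplication (producing "unique occurrence points"), random
#' 50/50 calibration/evaluation splits, and uniform background samples for
#' presence-background modelling.
#'
#' @name sampling
NULL

occurrence_set <- function(df, region = NA_character_) {
  rownames(df) <- NULL
  structure(df, class = c("occurrence_set", "data.frame"), region = region)
}

region_cells <- function(region_mask) {
  which(!is.na(region_mask$values) & region_mask$values == 1)
}

cells_to_points <- function(grid, cells) {
  nr <- nrow(grid$values)
  row <- (cells - 1L) %% nr + 1L
  col <- (cells - 1L) %/% nr + 1L
  xy <- rg_cell_xy(grid, col, row)
  data.frame(col = col, row = row, x = xy[, "x"], y = xy[, "y"])
}

#' Cast random points across a region
#'
#' Samples `n` cells uniformly (with replacement) from the region mask and
#' places each point at the cell centre.
#'
#' @param region_mask binary `raster_grid`; cells equal to 1 are eligible.
#' @param n number of points.
#' @param seed integer seed; draws are reproducible.
#' @return data.frame with columns `col`, `row`, `x`, `y`.
#' @export
cast_random_points <- function(region_mask, n, seed) {
  cells <- region_cells(region_mask)
  if (length(cells) == 0L)
    stop("empty-source error: region mask has no cells", call. = FALSE)
  if (n == 0L) return(cells_to_points(region_mask, integer(0)))
  picked <- with_seed(seed, sample(cells, n, replace = TRUE))
  cells_to_points(region_mask, picked)
}

#' Filter points to a target class and deduplicate
#'
#' Retains points whose pixel holds class value 1 and collapses them to
#' unique pixels, mirroring the construction of unique occurrence points from
#' random casts over a cover map.
#'
#' @param points data.frame from [cast_random_points()].
#' @param class_map binary `raster_grid` (e.g. an evergreen or WPE map).
#' @return An `occurrence_set` (data.frame of unique pixels).
#' @export
filter_to_class <- function(points, class_map) {
  nr <- nrow(class_map$values)
  cell <- (points$col - 1L) * nr + points$row
  keep <- !is.na(class_map$values[cell]) & class_map$values[cell] == 1
  kept <- points[keep, , drop = FALSE]
  kept <- kept[!duplicated(cell[keep]), , drop = FALSE]
  occurrence_set(kept)
}

#' Random half split of an occurrence set
#'
#' Disjoint random halves (sizes differing by at most one) for model
#' calibration and internal evaluation.
#'
#' @param occ an `occurrence_set`.
#' @param seed integer seed.
#' @return List with `cal` and `eval` occurrence sets.
#' @export
split_half <- function(occ, seed) {
  n <- nrow(occ)
  if (n < 2L)
    stop("insufficient-data error: need at least 2 occurrences to split",
         call. = FALSE)
  idx <- with_seed(seed, sample.int(n))
  half <- ceiling(n / 2)
  list(cal = occurrence_set(occ[sort(idx[seq_len(half)]), , drop = FALSE]),
       eval = occurrence_set(occ[sort(idx[-seq_len(half)]), , drop = FALSE]))
}

#' Sample background cells
#'
#' Uniform sample of distinct region cells (all cells if the region holds
#' fewer than `n`). Background may include presence cells, per the usual
#' presence-background convention.
#'
#' @param region_mask binary `raster_grid`.
#' @param n_background target number of background cells (default 10000).
#' @param seed integer seed.
#' @return An `occurrence_set` of background cells.
#' @export
sample_background <- function(region_mask, n_background = 10000, seed = 1) {
  cells <- region_cells(region_mask)
  if (length(cells) == 0L)
    stop("empty-source error: region mask has no cells", call. = FALSE)
  picked <- if (n_background >= length(cells)) cells else
    with_seed(seed, sample(cells, n_background))
  occurrence_set(cells_to_points(region_mask, sort(picked)))
}

#' Extract predictor values at points
#'
#' Appends one column per predictor layer; points falling on nodata cells of
#' any predictor are dropped (their count is recorded in the
#' `n_dropped_nodata` attribute).
#'
#' @param points data.frame or `occurrence_set` with `col`, `row`.
#' @param stack named list of co-registered predictor `raster_grid`s.
#' @return The points with predictor columns appended.
#' @export
extract_predictors <- function(points, stack) {
  nr <- nrow(stack[[1L]]$values)
  cell <- (points$col - 1L) * nr + points$row
  vals <- matrix(NA_real_, length(cell), length(stack),
                 dimnames = list(NULL, names(stack)))
  for (i in seq_along(stack)) vals[, i] <- stack[[i]]$values[cell]
  ok <- stats::complete.cases(vals)
  out <- cbind(points[ok, , drop = FALSE], as.data.frame(vals[ok, , drop = FALSE]))
  out <- occurrence_set(out, region = attr(points, "region"))
  attr(out, "n_dropped_nodata") <- sum(!ok)
  out
}
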