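#' Rule-based land-cover classification
#'
#' Knowledge-based decision rules mapping L-band radar backscatter and NDVI
#' summary layers to annual forest and evergreen-forest maps, and the
#' two-date overlay that defines woody-plant-encroachment (WPE) pixels.
#'
#' @name landcover
NULL

#' Assemble a co-registered band stack
#'
#' Computes the derived radar bands (HH - HV difference and HH/HV ratio, both
#' on the dB-scale values as supplied) and validates co-registration. The
#' derived bands are always computed here, never supplied.
#'
#' @param HH,HV radar backscatter raster grids (dB).
#' @param NDVI_max annual maximum NDVI `raster_grid` (unitless, `[-1, 1]`).
#' @param NDVI_wintermean winter (Dec-Feb) mean NDVI `raster_grid`.
#' @return A list of class `band_stack`.
#' @export
band_stack <- function(HH, HV, NDVI_max, NDVI_wintermean) {
  rg_check_aligned(HH, HV, NDVI_max, NDVI_wintermean)
  structure(list(
    HH = HH, HV = HV,
    HH_minus_HV = rg_like(HH, HH$values - HV$values),
    HH_over_HV = rg_like(HH, HH$values / HV$values),
    NDVI_max = NDVI_max, NDVI_wintermean = NDVI_wintermean
  ), class = "band_stack")
}

#' Classify forest pixels
#'
#' A pixel is forest iff all four decision rules hold:
#' `-19 <= HV <= -7.5` dB, `0 <= HH - HV <= 9.5` dB,
#' `0.2 <= HH/HV <= 0.95` (ratio of the dB values), and `NDVI_max > 0.7`
#' (strict). The closed ranges are inclusive at their printed bounds; the
#' NDVI threshold is strict. Nodata in any input propagates: a pixel is
#' classified only when all bands are valid.
#'
#' @param stack a [band_stack()].
#' @return binary `raster_grid` (1 = forest), `NA` where any band is nodata.
#' @export
classify_forest <- function(stack) {
  stopifnot(inherits(stack, "band_stack"))
  hv <- stack$HV$values
  d <- stack$HH_minus_HV$values
  r <- stack$HH_over_HV$values
  nmax <- stack$NDVI_max$values
  out <- as.numeric(hv >= -19 & hv <= -7.5 &
                    d >= 0 & d <= 9.5 &
                    r >= 0.2 & r <= 0.95 &
                    nmax > 0.7)
  out <- matrix(out, nrow(hv), ncol(hv))
  if (all(is.na(out)))
    warning("all pixels are nodata; returning an empty map")
  rg_like(stack$HV, out)
}

#' Classify evergreen forest pixels
#'
#' Within the forest map, evergreen pixels are those whose winter mean NDVI
#' strictly exceeds 0.4 (evergreen canopy stays green through December to
#' February; deciduous canopy does not). Evergreen is a subset of forest by
#' construction.
#'
#' @param forest binary forest `raster_grid` from [classify_forest()].
#' @param NDVI_wintermean winter mean NDVI `raster_grid`.
#' @return binary `raster_grid` (1 = evergreen forest).
#' @export
classify_evergreen <- function(forest, NDVI_wintermean) {
  rg_check_aligned(forest, NDVI_wintermean)
  out <- as.numeric(forest$values == 1 & NDVI_wintermean$values > 0.4)
  rg_like(forest, matrix(out, nrow(forest$values), ncol(forest$values)))
}

#' Detect woody plant encroachment between two dates
#'
#' Overlay of two evergreen maps: a pixel is WPE iff it held no evergreen
#' forest at the first date and holds evergreen forest at the second.
#' Persistent forest and forest loss are both 0. Nodata in either input
#' propagates.
#'
#' @param evergreen_t1,evergreen_t2 co-registered binary evergreen maps for
#'   the earlier and later date.
#' @return binary `raster_grid` (1 = encroachment pixel).
#' @export
detect_wpe <- function(evergreen_t1, evergreen_t2) {
  rg_check_aligned(evergreen_t1, evergreen_t2)
  out <- as.numeric(evergreen_t1$values == 0 & evergreen_t2$values == 1)
  rg_like(evergreen_t1,
          matrix(out, nrow(evergreen_t1$values), ncol(evergreen_t1$values)))
}

#' Class area and fraction within a region
#'
#' Counts positive map cells inside the region mask on the equal-area grid.
#'
#' @param map binary `raster_grid`.
#' @param region_mask binary `raster_grid` defining the region.
#' @return List with `area_km2` and `fraction` (of region cells).
#' @export
class_area <- function(map, region_mask) {
  rg_check_aligned(map, region_mask)
  in_region <- !is.na(region_mask$values) & region_mask$values == 1
  n_region <- sum(in_region)
  if (n_region == 0L)
    stop("undefined-fraction error: region mask is empty", call. = FALSE)
  n_pos <- sum(map$values == 1 & in_region, na.rm = TRUE)
  list(area_km2 = n_pos * rg_cell_area_m2(map) / 1e6,
       fraction = n_pos / n_region)
}
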