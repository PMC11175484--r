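#' Single-band georeferenced raster grid
#'
#' Minimal carrier for all spatial layers in the package: a numeric matrix
#' (row 1 = northernmost row) plus an affine grid origin and a square cell
#' size in projected metres. Missing data are `NA` in the matrix.
#'
#' @param values numeric matrix; rows run north to south.
#' @param xmin,ymin projected coordinates (m) of the lower-left grid corner.
#' @param cellsize cell edge length in metres (square cells only).
#' @return An object of class `raster_grid`.
#' @examples
#' g <- raster_grid(matrix(1:12, 3, 4), cellsize = 30)
#' dim(g$values)
#' @export
raster_grid <- function(values, xmin = 0, ymin = 0, cellsize = 30) {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.numeric(cellsize) || length(cellsize) != 1L || cellsize <= 0)
    stop("unsupported grid: cellsize must be a positive scalar", call. = FALSE)
  structure(
    list(values = values, xmin = as.numeric(xmin), ymin = as.numeric(ymin),
         cellsize = as.numeric(cellsize)),
    class = "raster_grid"
  )
}

#' @export
print.raster_grid <- function(x, ...) {
  v <- x$values
  cat(sprintf("raster_grid: %d rows x %d cols, cell %g m, origin (%g, %g)\n",
              nrow(v), ncol(v), x$cellsize, x$xmin, x$ymin))
  cat(sprintf("  values: [%g, %g], %d NA\n",
              suppressWarnings(min(v, na.rm = TRUE)),
              suppressWarnings(max(v, na.rm = TRUE)), sum(is.na(v))))
  invisible(x)
}

#' @export
as.matrix.raster_grid <- function(x, ...) x$values

is_raster_grid <- function(x) inherits(x, "raster_grid")

#' Construct a grid with the same georeferencing as a template
#'
#' @param template a `raster_grid` supplying shape, origin and cell size.
#' @param values optional matrix of the same shape; defaults to all-`NA`.
#' @return A `raster_grid`.
#' @export
rg_like <- function(template, values = NULL) {
  if (is.null(values))
    values <- matrix(NA_real_, nrow(template$values), ncol(template$values))
  raster_grid(values, template$xmin, template$ymin, template$cellsize)
}

#' Check that raster grids are co-registered
#'
#' All layers entering a classification, overlay or extraction must share
#' shape, origin and cell size. Stops with an alignment error otherwise.
#'
#' @param ... `raster_grid` objects.
#' @return Invisibly `TRUE`.
#' @export
rg_check_aligned <- function(...) {
  gs <- list(...)
  ref <- gs[[1L]]
  for (g in gs) {
    if (!is_raster_grid(g)) stop("alignment error: not a raster_grid", call. = FALSE)
    if (!identical(dim(g$values), dim(ref$values)) ||
        !isTRUE(all.equal(c(g$xmin, g$ymin, g$cellsize),
                          c(ref$xmin, ref$ymin, ref$cellsize))))
      stop("alignment error: grids are not co-registered", call. = FALSE)
  }
  invisible(TRUE)
}

#' Projected coordinates of cell centres
#'
#' @param grid a `raster_grid`.
#' @param col,row 1-based column and row indices (row 1 is the north edge).
#' @return A two-column matrix of x, y centre coordinates in metres.
#' @export
rg_cell_xy <- function(grid, col, row) {
  nr <- nrow(grid$values)
  cbind(x = grid$xmin + (col - 0.5) * grid$cellsize,
        y = grid$ymin + (nr - row + 0.5) * grid$cellsize)
}

#' Read / write ESRI ASCII grid files
#'
#' Plain-text single-band raster interchange (NCOLS/NROWS/XLLCORNER/
#' YLLCORNER/CELLSIZE/NODATA_VALUE header followed by rows north to south).
#'
#' @param path file path.
#' @param grid a `raster_grid`.
#' @param nodata value written for `NA` cells (default -9999).
#' @return `read_ascii_grid` returns a `raster_grid`; `write_ascii_grid`
#'   returns `path` invisibly.
#' @export
write_ascii_grid <- function(grid, path, nodata = -9999) {
  v <- grid$values
  v[is.na(v)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("NCOLS %d", ncol(v)),
    sprintf("NROWS %d", nrow(v)),
    sprintf("XLLCORNER %.10g", grid$xmin),
    sprintf("YLLCORNER %.10g", grid$ymin),
    sprintf("CELLSIZE %.10g", grid$cellsize),
    sprintf("NODATA_VALUE %.10g", nodata)
  ), con)
  utils::write.table(v, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path) {
  hdr <- readLines(path, n = 6L)
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  key <- toupper(kv[, 1L]); val <- as.numeric(kv[, 2L])
  names(val) <- key
  v <- as.matrix(utils::read.table(path, skip = 6L))
  dimnames(v) <- NULL
  stopifnot(nrow(v) == val[["NROWS"]], ncol(v) == val[["NCOLS"]])
  v[v == val[["NODATA_VALUE"]]] <- NA_real_
  raster_grid(v, val[["XLLCORNER"]], val[["YLLCORNER"]], val[["CELLSIZE"]])
}

#' Cell count and area helpers
#'
#' @param grid a `raster_grid`.
#' @return `rg_ncell` returns the number of cells; `rg_cell_area_m2` the area
#'   of one cell in square metres.
#' @export
rg_ncell <- function(grid) length(grid$values)

#' @rdname rg_ncell
#' @export
rg_cell_area_m2 <- function(grid) grid$cellsize^2
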