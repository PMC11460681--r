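#' Regular lon/lat raster grid
#'
#' A named covariate on a regular longitude/latitude cell grid. Cell `(i, j)`
#' (row `i` counted from the southern edge, column `j` from the western edge)
#' covers the half-open box
#' `[lon0 + (j-1) * cell_size, lon0 + j * cell_size) x
#'  [lat0 + (i-1) * cell_size, lat0 + i * cell_size)`,
#' and its centroid is the box center. Every stage of the pipeline shares
#' this convention, so a point on a cell boundary belongs to exactly one
#' cell. Missing values are `NA`.
#'
#' @param name covariate identifier.
#' @param origin numeric length-2, `(lon0, lat0)` of the lower-left corner.
#' @param cell_size cell edge in degrees (> 0).
#' @param values numeric matrix, `n_rows x n_cols`, row 1 = southernmost row.
#' @return object of class `raster_grid`.
#' @export
raster_grid <- function(name, origin, cell_size, values) {
  stopifnot(is.character(name), length(origin) == 2, cell_size > 0,
            is.matrix(values))
  structure(
    list(name = name, origin = as.numeric(origin), cell_size = cell_size,
         n_rows = nrow(values), n_cols = ncol(values), values = values),
    class = "raster_grid"
  )
}

#' @export
print.raster_grid <- function(x, ...) {
  cat(sprintf("<raster_grid '%s'> %d x %d cells, %.4g deg, origin (%g, %g)\n",
              x$name, x$n_rows, x$n_cols, x$cell_size,
              x$origin[1], x$origin[2]))
  invisible(x)
}

#' Cell id containing a lon/lat point
#'
#' Half-open membership: a point on the shared edge of two cells belongs to
#' the cell whose lower/left edge it lies on. Points outside the grid extent
#' get `NA`.
#'
#' @param grid a [raster_grid].
#' @param lon,lat coordinates in degrees (vectorized).
#' @return integer cell ids (`(i-1) * n_cols + j`), `NA` outside the extent.
#' @export
cell_from_lonlat <- function(grid, lon, lat) {
  j <- floor((lon - grid$origin[1]) / grid$cell_size) + 1
  i <- floor((lat - grid$origin[2]) / grid$cell_size) + 1
  ok <- i >= 1 & i <= grid$n_rows & j >= 1 & j <= grid$n_cols
  id <- ifelse(ok, (i - 1) * grid$n_cols + j, NA_integer_)
  as.integer(id)
}

#' Cell centroids for cell ids
#'
#' @param grid a [raster_grid].
#' @param cell_id integer cell ids.
#' @return data.frame with `cell_id`, `lon`, `lat` (centroid coordinates).
#' @export
cell_centroid <- function(grid, cell_id) {
  i <- (cell_id - 1L) %/% grid$n_cols + 1L
  j <- (cell_id - 1L) %% grid$n_cols + 1L
  data.frame(
    cell_id = cell_id,
    lon = grid$origin[1] + (j - 0.5) * grid$cell_size,
    lat = grid$origin[2] + (i - 0.5) * grid$cell_size
  )
}

#' Grid values at cell ids
#'
#' @param grid a [raster_grid].
#' @param cell_id integer cell ids (NA propagates).
#' @return numeric vector of cell values.
#' @export
cell_value <- function(grid, cell_id) {
  out <- rep(NA_real_, length(cell_id))
  ok <- !is.na(cell_id)
  id <- cell_id[ok]
  i <- (id - 1L) %/% grid$n_cols + 1L
  j <- (id - 1L) %% grid$n_cols + 1L
  out[ok] <- grid$values[cbind(i, j)]
  out
}

# row/col <-> id helpers (internal)
cell_ij <- function(grid, cell_id) {
  cbind(i = (cell_id - 1L) %/% grid$n_cols + 1L,
        j = (cell_id - 1L) %% grid$n_cols + 1L)
}

n_cells <- function(grid) grid$n_rows * grid$n_cols
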