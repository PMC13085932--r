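# Single home of the pixel/coordinate convention used across the package.
#
# Pixel-center registration, 1-based row/col indices. `row` counts down from
# the top edge, `col` counts right from the left edge. `geo` is a list with
# x_origin / y_origin (coordinates of the TOP-LEFT CORNER of pixel [1,1]),
# pixel (square pixel size in map units, 10 m after harmonization) and crs
# (a free-form CRS string, e.g. "EPSG:32615").

#' Georeferencing metadata
#'
#' Builds the small georeferencing record attached to every raster object in
#' the package: top-left corner origin, square pixel size and a CRS string.
#' The package uses pixel-center registration with 1-based row/column
#' indices; `pixel_to_coord()` and `coord_to_pixel()` are exact inverses on
#' pixel centers.
#'
#' @param x_origin,y_origin Map coordinates of the top-left corner of the
#'   grid (not of the first pixel center).
#' @param pixel Square pixel size in map units (metres for projected CRS).
#' @param crs CRS identifier string (e.g. `"EPSG:32615"`). Compared verbatim;
#'   the package performs no reprojection.
#' @return A list of class `"soymapr_geo"`.
#' @export
#' @examples
#' g <- geo_meta(500000, 4500000, 10)
#' pixel_to_coord(g, row = 1, col = 1)  # centre of the top-left pixel
geo_meta <- function(x_origin = 0, y_origin = 0, pixel = 10, crs = "EPSG:32615") {
  stopifnot(is.numeric(x_origin), is.numeric(y_origin), pixel > 0)
  structure(list(x_origin = x_origin, y_origin = y_origin,
                 pixel = pixel, crs = crs),
            class = "soymapr_geo")
}

#' Convert between pixel indices and map coordinates
#'
#' @param geo A [geo_meta()] record.
#' @param row,col 1-based pixel indices (vectors allowed).
#' @param x,y Map coordinates in the CRS of `geo`.
#' @return `pixel_to_coord()` returns a tibble with columns `x`, `y` (pixel
#'   centers); `coord_to_pixel()` returns a tibble with integer columns
#'   `row`, `col` of the pixel containing the point.
#' @export
pixel_to_coord <- function(geo, row, col) {
  tibble::tibble(
    x = geo$x_origin + (col - 0.5) * geo$pixel,
    y = geo$y_origin - (row - 0.5) * geo$pixel
  )
}

#' @rdname pixel_to_coord
#' @export
coord_to_pixel <- function(geo, x, y) {
  tibble::tibble(
    row = as.integer(floor((geo$y_origin - y) / geo$pixel) + 1L),
    col = as.integer(floor((x - geo$x_origin) / geo$pixel) + 1L)
  )
}

# TRUE for points whose containing pixel lies on an nrow x ncol grid.
in_extent <- function(geo, nrow, ncol, x, y) {
  px <- coord_to_pixel(geo, x, y)
  px$row >= 1L & px$row <= nrow & px$col >= 1L & px$col <= ncol
}

same_geo <- function(a, b, tol = 1e-6) {
  abs(a$x_origin - b$x_origin) < tol && abs(a$y_origin - b$y_origin) < tol &&
    abs(a$pixel - b$pixel) < tol && identical(a$crs, b$crs)
}
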