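# In-memory containers for dated multiband reflectance imagery.

#' Sentinel-2 band vocabulary
#'
#' The ten surface-reflectance bands the package recognises, in canonical
#' order: blue (B2), green (B3), red (B4), three red-edge bands (B5 RE1,
#' B6 RE2, B7 RE3), NIR (B8), narrow NIR (B8A) and two shortwave-infrared
#' bands (B11 SWIR1, B12 SWIR2).
#'
#' @format A character vector of length 10.
#' @export
S2_BANDS <- c("B2", "B3", "B4", "B5", "B6", "B7", "B8", "B8A", "B11", "B12")

#' Construct a reflectance stack
#'
#' A reflectance stack is the package's container for a dated multiband
#' raster cube: a 4-d numeric array indexed `[row, col, band, date]` holding
#' surface reflectance (unitless, nominally in `[0, 1]`), with `NA` marking
#' nodata (clouds, gaps). Dates must be strictly increasing and the band set
#' must be a subset of [S2_BANDS].
#'
#' @param values Numeric 4-d array `[row, col, band, date]`; `NA` = nodata.
#' @param dates `Date` vector, one per time slice, strictly increasing.
#' @param bands Character vector of band names, subset of [S2_BANDS].
#' @param geo A [geo_meta()] record.
#' @return An object of class `"reflectance_stack"`.
#' @export
reflectance_stack <- function(values, dates, bands, geo = geo_meta()) {
  dates <- as.Date(dates)
  stopifnot(is.array(values), length(dim(values)) == 4)
  if (length(bands) != dim(values)[3] || length(dates) != dim(values)[4])
    stop("dim(values) does not match bands/dates", call. = FALSE)
  bad <- setdiff(bands, S2_BANDS)
  if (length(bad))
    stop("unknown band name(s): ", paste(bad, collapse = ", "), call. = FALSE)
  if (length(dates) > 1 && any(diff(as.numeric(dates)) <= 0))
    stop("dates must be strictly increasing", call. = FALSE)
  values[!is.finite(values)] <- NA_real_
  dimnames(values) <- list(NULL, NULL, bands, as.character(dates))
  structure(list(values = values, dates = dates, bands = bands, geo = geo),
            class = "reflectance_stack")
}

#' @export
print.reflectance_stack <- function(x, ...) {
  d <- dim(x$values)
  cat("<reflectance_stack> ", d[1], "x", d[2], " px, ",
      d[3], " bands (", paste(x$bands, collapse = ", "), "), ",
      d[4], " dates ", as.character(min(x$dates)), "..",
      as.character(max(x$dates)), "\n", sep = "")
  cat("  nodata: ", sum(is.na(x$values)), " of ", length(x$values),
      " cells; pixel ", x$geo$pixel, " m, ", x$geo$crs, "\n", sep = "")
  invisible(x)
}

#' @export
dim.reflectance_stack <- function(x) dim(x$values)

# Shared band-slice accessor for stacks and composite series: returns the
# [row, col, time] array for one band, erroring with the band name if absent.
band_slab <- function(obj, band) {
  i <- match(band, obj$bands)
  if (is.na(i)) stop("band not present in object: ", band, call. = FALSE)
  obj$values[, , i, , drop = FALSE][, , 1, , drop = TRUE]
}
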