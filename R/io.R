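# Raster and sample-table input/output.
#
# Rasters are written as baseline TIFF (one file per band and date, or
# multi-page for multiband composites) with a JSON sidecar (<file>.aux.json)
# carrying georeferencing, band names and the value scaling. TIFF payloads
# are stored as 32-bit [0,1]-scaled integers: values are affinely mapped
# from [lo, hi] (recorded in the sidecar) onto [0, NODATA_SENTINEL) and
# nodata is stored as the sentinel, so round-trips are exact to ~2e-10 of
# the value range. Classification maps use exact 8-bit 0/1/255 coding.

NODATA_SENTINEL <- 1.0
SCALE_TOP <- 0.9  # valid data occupies [0, SCALE_TOP]; sentinel sits above

#' Write / read a single raster (matrix or band-page array)
#'
#' `write_raster()` stores a numeric matrix, or a 3-d array `[row, col, page]`
#' as a multi-page TIFF, together with a JSON sidecar holding the
#' georeferencing ([geo_meta()]), page names and value scaling. `NA` cells
#' round-trip as `NA`. `read_raster()` reverses it.
#'
#' @param x Numeric matrix or 3-d array; `NA` = nodata.
#' @param path Output TIFF path; the sidecar is written at `<path>.aux.json`.
#' @param geo A [geo_meta()] record.
#' @param pages Optional character names for the third dimension (e.g. bands).
#' @return `write_raster()` returns `path` invisibly; `read_raster()` returns
#'   a list with `values` (3-d array), `pages`, and `geo`.
#' @export
write_raster <- function(x, path, geo = geo_meta(), pages = NULL) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  stopifnot(length(dim(x)) == 3)
  fin <- x[is.finite(x)]
  rng <- if (length(fin)) range(fin) else c(0, 1)
  if (rng[1] == rng[2]) rng[2] <- rng[1] + 1
  enc <- (x - rng[1]) / (rng[2] - rng[1]) * SCALE_TOP
  enc[!is.finite(enc)] <- NODATA_SENTINEL
  pgs <- lapply(seq_len(dim(x)[3]), function(i) enc[, , i])
  tiff::writeTIFF(pgs, path, bits.per.sample = 32L, compression = "none")
  meta <- list(
    nrow = dim(x)[1], ncol = dim(x)[2], n_pages = dim(x)[3],
    pages = pages, lo = rng[1], hi = rng[2], scale_top = SCALE_TOP,
    nodata_sentinel = NODATA_SENTINEL, encoding = "scaled32",
    x_origin = geo$x_origin, y_origin = geo$y_origin,
    pixel = geo$pixel, crs = geo$crs
  )
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_raster
#' @export
read_raster <- function(path) {
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  pgs <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pgs)) pgs <- list(pgs)
  dec <- lapply(pgs, function(p) {
    if (identical(meta$encoding, "byte")) {
      v <- round(p * 255)
      v[v == 255] <- NA_real_
      v
    } else {
      v <- p / meta$scale_top * (meta$hi - meta$lo) + meta$lo
      v[p >= meta$nodata_sentinel - 1e-9] <- NA_real_
      v
    }
  })
  values <- array(unlist(dec), c(dim(dec[[1]]), length(dec)))
  list(values = values, pages = meta$pages,
       geo = geo_meta(meta$x_origin, meta$y_origin, meta$pixel, meta$crs))
}

sidecar_path <- function(path) paste0(path, ".aux.json")

#' Read a reflectance stack from band files
#'
#' The manifest is either a data frame with columns `date`, `band`, `path`
#' (one single-band raster file per row) or the path of a YAML config listing
#' the same (top-level key `dates:`, each with `date:` and a `bands:` map of
#' band name to file). All files must share the CRS of the first; bands on a
#' coarser grid (e.g. 20 m red-edge/SWIR bands against a 10 m target grid)
#' are upsampled on read.
#'
#' @param manifest Data frame `(date, band, path)` or YAML config path.
#' @param resample Kernel for coarse-band upsampling: `"nearest"` (default;
#'   preserves the reflectance distribution, hence class statistics) or
#'   `"bilinear"`.
#' @return A [reflectance_stack()].
#' @export
read_stack <- function(manifest, resample = c("nearest", "bilinear")) {
  resample <- match.arg(resample)
  if (is.character(manifest) && length(manifest) == 1) {
    cfg <- yaml::read_yaml(manifest)
    base <- dirname(manifest)
    manifest <- purrr::map_dfr(cfg$dates, function(d) {
      tibble::tibble(date = d$date, band = names(d$bands),
                     path = file.path(base, unlist(d$bands, use.names = FALSE)))
    })
  }
  manifest <- tibble::as_tibble(manifest)
  stopifnot(all(c("date", "band", "path") %in% names(manifest)))
  bad <- setdiff(unique(manifest$band), S2_BANDS)
  if (length(bad))
    stop("unknown band name(s) in manifest: ", paste(bad, collapse = ", "),
         call. = FALSE)
  miss <- manifest$path[!file.exists(manifest$path)]
  if (length(miss))
    stop("missing raster file(s): ", paste(miss, collapse = ", "), call. = FALSE)
  manifest$date <- as.Date(manifest$date)
  dates <- sort(unique(manifest$date))
  bands <- S2_BANDS[S2_BANDS %in% unique(manifest$band)]

  rasters <- lapply(manifest$path, read_raster)
  geo0 <- rasters[[1]]$geo
  for (r in rasters)
    if (!identical(r$geo$crs, geo0$crs))
      stop("mismatched CRS across band files (", r$geo$crs, " vs ",
           geo0$crs, "); reprojection is not supported", call. = FALSE)
  # target grid = finest grid seen
  dims <- vapply(rasters, function(r) dim(r$values)[1:2], integer(2))
  tgt <- c(max(dims[1, ]), max(dims[2, ]))
  fine <- which(dims[1, ] == tgt[1])[1]
  geo <- rasters[[fine]]$geo

  values <- array(NA_real_, c(tgt, length(bands), length(dates)))
  for (i in seq_len(nrow(manifest))) {
    m <- rasters[[i]]$values[, , 1]
    if (!all(dim(m) == tgt)) m <- upsample(m, tgt, resample)
    bi <- match(manifest$band[i], bands)
    di <- match(manifest$date[i], dates)
    values[, , bi, di] <- m
  }
  reflectance_stack(values, dates, bands, geo)
}

#' Write a reflectance stack as per-date, per-band rasters plus a YAML config
#'
#' @param stack A [reflectance_stack()].
#' @param dir Output directory (created if needed).
#' @param config Name of the YAML manifest written inside `dir`.
#' @return The config path, invisibly.
#' @export
write_stack <- function(stack, dir, config = "stack.yaml") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dates <- lapply(seq_along(stack$dates), function(di) {
    d <- stack$dates[di]
    files <- lapply(seq_along(stack$bands), function(bi) {
      fn <- sprintf("%s_%s.tif", format(d, "%Y%m%d"), stack$bands[bi])
      write_raster(stack$values[, , bi, di], file.path(dir, fn),
                   geo = stack$geo)
      fn
    })
    list(date = as.character(d),
         bands = stats::setNames(files, stack$bands))
  })
  path <- file.path(dir, config)
  yaml::write_yaml(list(dates = dates), path)
  invisible(path)
}

# Integer/real-factor upsampling of matrix m to target dims.
upsample <- function(m, tgt, method = c("nearest", "bilinear")) {
  method <- match.arg(method)
  fr <- tgt[1] / nrow(m); fc <- tgt[2] / ncol(m)
  if (method == "nearest") {
    ri <- pmin(nrow(m), ceiling((seq_len(tgt[1]) - 0.5) / fr))
    ci <- pmin(ncol(m), ceiling((seq_len(tgt[2]) - 0.5) / fc))
    m[ri, ci, drop = FALSE]
  } else {
    # bilinear on pixel centers, clamped at edges
    src_r <- (seq_len(tgt[1]) - 0.5) / fr + 0.5
    src_c <- (seq_len(tgt[2]) - 0.5) / fc + 0.5
    r0 <- pmin(pmax(floor(src_r), 1), nrow(m)); r1 <- pmin(r0 + 1, nrow(m))
    c0 <- pmin(pmax(floor(src_c), 1), ncol(m)); c1 <- pmin(c0 + 1, ncol(m))
    wr <- pmin(pmax(src_r - r0, 0), 1); wc <- pmin(pmax(src_c - c0, 0), 1)
    top <- m[r0, c0, drop = FALSE] * outer(1 - wr, 1 - wc) +
      m[r0, c1, drop = FALSE] * outer(1 - wr, wc)
    bot <- m[r1, c0, drop = FALSE] * outer(wr, 1 - wc) +
      m[r1, c1, drop = FALSE] * outer(wr, wc)
    top + bot
  }
}

#' Read / write labeled sample points
#'
#' Samples are tabular points `(x, y, label[, role])` in the CRS of the
#' stack they accompany. CSV and GeoJSON (Point features with `label`/`role`
#' properties) are supported, chosen by file extension. Points outside the
#' extent of `stack` (when given) are dropped with a warning, not an error.
#'
#' @param path CSV or GeoJSON file.
#' @param stack Optional [reflectance_stack()] (or any object with `$geo` and
#'   raster `$values`) used to filter points to the image extent.
#' @return A tibble with columns `x`, `y`, `label`, `role`.
#' @export
read_samples <- function(path, stack = NULL) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("geojson", "json")) {
    gj <- jsonlite::read_json(path)
    pts <- purrr::map_dfr(gj$features, function(f) {
      tibble::tibble(
        x = as.numeric(f$geometry$coordinates[[1]]),
        y = as.numeric(f$geometry$coordinates[[2]]),
        label = as.character(f$properties$label %||% NA_character_),
        role = as.character(f$properties$role %||% "unassigned")
      )
    })
    if (nrow(pts) == 0)
      pts <- tibble::tibble(x = double(), y = double(),
                            label = character(), role = character())
  } else {
    pts <- readr::read_csv(path, show_col_types = FALSE,
                           col_types = readr::cols())
    pts <- tibble::as_tibble(pts)
    if (!"role" %in% names(pts)) pts$role <- "unassigned"
    pts <- pts[, c("x", "y", "label", "role")]
  }
  if (!is.null(stack) && nrow(pts)) {
    d <- dim(stack$values)
    keep <- in_extent(stack$geo, d[1], d[2], pts$x, pts$y)
    if (any(!keep))
      warning(sum(!keep), " sample point(s) outside the stack extent dropped",
              call. = FALSE)
    pts <- pts[keep, ]
  }
  pts
}

#' @rdname read_samples
#' @param samples Tibble with columns `x`, `y`, `label` and optionally `role`.
#' @export
write_samples <- function(samples, path) {
  if (!"role" %in% names(samples)) samples$role <- "unassigned"
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("geojson", "json")) {
    feats <- purrr::pmap(samples[, c("x", "y", "label", "role")],
      function(x, y, label, role) {
        list(type = "Feature",
             geometry = list(type = "Point", coordinates = c(x, y)),
             properties = list(label = label, role = role))
      })
    jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                         path, auto_unbox = TRUE, digits = NA)
  } else {
    readr::write_csv(samples[, c("x", "y", "label", "role")], path)
  }
  invisible(path)
}

#' Write / read a classified map as a byte raster
#'
#' Single-band 8-bit coding: 1 = target class, 0 = other, 255 = nodata.
#'
#' @param map A `classified_map` (see [classify()]) or 0/1/`NA` matrix.
#' @param path Output TIFF path.
#' @return `write_map()` returns `path` invisibly; `read_map()` a
#'   `classified_map`.
#' @export
write_map <- function(map, path) {
  geo <- attr(map, "geo") %||% geo_meta()
  m <- unclass(map)
  attributes(m) <- list(dim = dim(m))
  enc <- m
  enc[is.na(enc)] <- 255
  tiff::writeTIFF(enc / 255, path, bits.per.sample = 8L, compression = "none")
  meta <- list(nrow = nrow(m), ncol = ncol(m), n_pages = 1L,
               encoding = "byte", x_origin = geo$x_origin,
               y_origin = geo$y_origin, pixel = geo$pixel, crs = geo$crs)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_map
#' @export
read_map <- function(path) {
  r <- read_raster(path)
  m <- r$values[, , 1]
  mi <- matrix(as.integer(round(m)), nrow(m), ncol(m))
  new_classified_map(mi, geo = r$geo, threshold = NA_real_)
}

#' Write a tibble/data frame as CSV
#'
#' Thin convenience wrapper kept for symmetry with the raster writers.
#' @param rows A data frame.
#' @param path Output CSV path.
#' @export
write_table <- function(rows, path) {
  readr::write_csv(tibble::as_tibble(rows), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
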