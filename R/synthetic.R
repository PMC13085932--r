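# Synthetic labeled multiband scenes emulating soybean/corn canopy
# phenology, so every pipeline stage is testable without downloads.

#' Double-logistic phenology curve
#'
#' The standard remote-sensing growth-curve form: reflectance rises along a
#' logistic green-up centred at `green_doy` and falls along a logistic
#' senescence centred at `sen_doy`,
#' `base + amp * (plogis(green_rate * (doy - green_doy)) -
#' plogis(sen_rate * (doy - sen_doy)))`.
#' Negative `amp` models bands that *dip* during the green season (visible
#' and SWIR bands).
#'
#' @param doy Day of year (numeric vector).
#' @param base Off-season reflectance.
#' @param amp Seasonal amplitude (signed).
#' @param green_doy,green_rate Green-up inflection DOY and rate (1/day).
#' @param sen_doy,sen_rate Senescence inflection DOY and rate (1/day).
#' @return Reflectance values.
#' @export
dl_curve <- function(doy, base, amp, green_doy, green_rate,
                     sen_doy, sen_rate) {
  base + amp * (stats::plogis(green_rate * (doy - green_doy)) -
                  stats::plogis(sen_rate * (doy - sen_doy)))
}

#' Default per-class, per-band phenology preset
#'
#' A "U1-like" humid-continental corn-belt preset over a DOY 120-300
#' season. The curves encode the qualitative mid-season divergence that
#' makes soybean separable from corn around DOY 220-260 (soybean
#' pod-filling vs. corn silking-to-milk):
#'
#' * soybean loses canopy water early: its SWIR bands (B11/B12) senesce
#'   around DOY 230, so SWIR reflectance *rises* through the window while
#'   corn's stays low and stable (corn senescence ~DOY 270);
#' * soybean chlorophyll/structure bands (red-edge, NIR) begin declining
#'   around DOY 255, so red-edge reflectance drops below corn's inside the
#'   window;
#' * corn carries a higher NIR/red-edge amplitude throughout mid-season;
#' * the `other` class (early-season small grains/grass) is senesced by
#'   DOY 200 and sits well below both crops.
#'
#' @return A tibble: `class`, `band`, `base`, `amp`, `green_doy`,
#'   `green_rate`, `sen_doy`, `sen_rate`.
#' @export
default_phenology <- function() {
  row <- function(class, band, base, amp, g, s, ks = 0.15)
    tibble::tibble(class = class, band = band, base = base, amp = amp,
                   green_doy = g, green_rate = 0.10,
                   sen_doy = s, sen_rate = ks)
  dplyr::bind_rows(
    # soybean: canopy water drops early in pod-fill (SWIR recovers sharply
    # around DOY 222), chlorophyll/structure hold until ~DOY 268
    row("soybean", "B2",  0.080, -0.040, 160, 268),
    row("soybean", "B3",  0.095, -0.045, 160, 268),
    row("soybean", "B4",  0.100, -0.060, 160, 268),
    row("soybean", "B5",  0.110,  0.080, 160, 268),
    row("soybean", "B6",  0.080,  0.220, 160, 268),
    row("soybean", "B7",  0.085,  0.250, 160, 268),
    row("soybean", "B8",  0.100,  0.280, 160, 268),
    row("soybean", "B8A", 0.105,  0.290, 160, 268),
    row("soybean", "B11", 0.300, -0.200, 160, 222, 0.18),
    row("soybean", "B12", 0.280, -0.180, 160, 222, 0.18),
    # corn: green and water-rich through the window (stable low SWIR, high
    # NIR/red-edge), then senesces shortly after soybean (~DOY 272)
    row("corn", "B2",  0.075, -0.040, 155, 272),
    row("corn", "B3",  0.090, -0.040, 155, 272),
    row("corn", "B4",  0.095, -0.060, 155, 272),
    row("corn", "B5",  0.105,  0.090, 155, 272),
    row("corn", "B6",  0.080,  0.270, 155, 272),
    row("corn", "B7",  0.085,  0.300, 155, 272),
    row("corn", "B8",  0.100,  0.340, 155, 272),
    row("corn", "B8A", 0.105,  0.350, 155, 272),
    row("corn", "B11", 0.240, -0.145, 155, 272),
    row("corn", "B12", 0.220, -0.135, 155, 272),
    # other: early small grains / grass, senesced by DOY 200
    row("other", "B2",  0.085, -0.030, 130, 200, 0.10),
    row("other", "B3",  0.100, -0.030, 130, 200, 0.10),
    row("other", "B4",  0.110, -0.040, 130, 200, 0.10),
    row("other", "B5",  0.115,  0.050, 130, 200, 0.10),
    row("other", "B6",  0.100,  0.150, 130, 200, 0.10),
    row("other", "B7",  0.105,  0.160, 130, 200, 0.10),
    row("other", "B8",  0.110,  0.180, 130, 200, 0.10),
    row("other", "B8A", 0.112,  0.180, 130, 200, 0.10),
    row("other", "B11", 0.300, -0.120, 130, 200, 0.10),
    row("other", "B12", 0.280, -0.110, 130, 200, 0.10)
  )
}

#' Configure a synthetic labeled scene
#'
#' @param grid Integer `c(nrow, ncol)` pixel grid (10 m pixels). The
#'   default 80 x 80 comfortably hosts the default sampling intensity under
#'   the 30 m minimum point spacing.
#' @param classes Named numeric vector of class proportions; must sum to 1.
#' @param season Integer `c(first, last)` DOY of the acquisition season.
#' @param step_days Days between acquisitions (revisit interval).
#' @param year Calendar year used to date the acquisitions.
#' @param field_px Integer `c(min, max)` field edge lengths in pixels; the
#'   scene is a jittered rectangular tessellation of single-class fields.
#' @param phenology Per-class per-band curve table, see
#'   [default_phenology()].
#' @param noise_sd Additive Gaussian noise s.d. per band observation
#'   (reflectance units).
#' @param cloud_prob Per-date, per-pixel probability of a cloud gap
#'   (masked observation).
#' @param divergence Integer `c(first, last)` DOY of the designed
#'   soybean/corn divergence window.
#' @param n_per_class Sample points drawn per class.
#' @param min_distance Minimum distance between sample points (m).
#' @param seed Integer seed making the scene fully deterministic.
#' @param geo A [geo_meta()] record for the scene grid.
#' @return A list of class `"scene_config"`.
#' @export
scene_config <- function(grid = c(80, 80),
                         classes = c(soybean = 0.4, corn = 0.4, other = 0.2),
                         season = c(120, 300), step_days = 5, year = 2021,
                         field_px = c(8, 14),
                         phenology = default_phenology(),
                         noise_sd = 0.01, cloud_prob = 0.05,
                         divergence = c(220, 260),
                         n_per_class = 80, min_distance = 30,
                         seed = 1, geo = geo_meta(500000, 4500000, 10)) {
  if (abs(sum(classes) - 1) > 1e-8)
    stop("class proportions must sum to 1", call. = FALSE)
  stopifnot(noise_sd >= 0, cloud_prob >= 0, cloud_prob < 1,
            length(grid) == 2, length(season) == 2,
            divergence[1] >= season[1], divergence[2] <= season[2])
  need <- setdiff(names(classes), unique(phenology$class))
  if (length(need))
    stop("phenology table lacks class(es): ", paste(need, collapse = ", "),
         call. = FALSE)
  structure(list(grid = as.integer(grid), classes = classes,
                 season = season, step_days = step_days, year = year,
                 field_px = as.integer(field_px), phenology = phenology,
                 noise_sd = noise_sd, cloud_prob = cloud_prob,
                 divergence = divergence, n_per_class = n_per_class,
                 min_distance = min_distance, seed = seed, geo = geo),
            class = "scene_config")
}

#' Generate a labeled synthetic scene
#'
#' Builds a field mosaic, assigns each field a crop class matching the
#' configured proportions (largest-remainder rounding, so every class with
#' nonzero share is present), evaluates each class's per-band
#' double-logistic curve at each acquisition date, adds independent
#' Gaussian noise, clips to `[0, 1]`, masks cloud gaps, and draws labeled
#' sample points from the truth raster. Bit-identical for a given seed.
#'
#' @param cfg A [scene_config()].
#' @return A list of class `"labeled_scene"`: `stack`
#'   ([reflectance_stack()]), `truth` (character matrix of class labels),
#'   `samples` (tibble `x, y, label, role`), `config`.
#' @export
generate_scene <- function(cfg) {
  stopifnot(inherits(cfg, "scene_config"))
  withr::with_seed(cfg$seed, {
    truth <- field_mosaic(cfg$grid, cfg$field_px, cfg$classes)
    doys <- seq(cfg$season[1], cfg$season[2], by = cfg$step_days)
    dates <- as.Date(doys - 1, origin = paste0(cfg$year, "-01-01"))
    bands <- S2_BANDS
    d <- c(cfg$grid, length(bands), length(dates))
    values <- array(NA_real_, d)
    ph <- cfg$phenology
    cls_idx <- match(truth, names(cfg$classes))  # integer matrix layout
    for (bi in seq_along(bands)) {
      pb <- ph[ph$band == bands[bi], ]
      for (di in seq_along(doys)) {
        mu_by_class <- vapply(names(cfg$classes), function(cl) {
          r <- pb[pb$class == cl, ]
          dl_curve(doys[di], r$base, r$amp, r$green_doy, r$green_rate,
                   r$sen_doy, r$sen_rate)
        }, numeric(1))
        slice <- mu_by_class[cls_idx]
        if (cfg$noise_sd > 0)
          slice <- slice + stats::rnorm(length(slice), 0, cfg$noise_sd)
        values[, , bi, di] <- pmin(pmax(slice, 0), 1)
      }
    }
    if (cfg$cloud_prob > 0) {
      for (di in seq_along(doys)) {
        gap <- stats::runif(prod(cfg$grid)) < cfg$cloud_prob
        if (any(gap)) {
          sl <- values[, , , di]
          sl[array(gap, c(cfg$grid, length(bands)))] <- NA_real_
          values[, , , di] <- sl
        }
      }
    }
    stack <- reflectance_stack(values, dates, bands, cfg$geo)
    scene <- structure(list(stack = stack, truth = truth, samples = NULL,
                            config = cfg),
                       class = "labeled_scene")
    scene$samples <- sample_truth(scene, n_per_class = cfg$n_per_class,
                                  min_distance = cfg$min_distance,
                                  seed = NULL)  # inside the scene's RNG scope
    scene
  })
}

# Jittered rectangular tessellation with largest-remainder class counts.
field_mosaic <- function(grid, field_px, classes) {
  cuts <- function(n) {
    b <- 0L
    while (utils::tail(b, 1) < n) {
      b <- c(b, min(n, utils::tail(b, 1) +
                      sample(seq(field_px[1], field_px[2]), 1)))
    }
    b
  }
  rb <- cuts(grid[1]); cb <- cuts(grid[2])
  nf <- (length(rb) - 1L) * (length(cb) - 1L)
  share <- classes * nf
  cnt <- floor(share)
  rem <- nf - sum(cnt)
  if (rem > 0) {
    o <- order(share - cnt, decreasing = TRUE)
    cnt[o[seq_len(rem)]] <- cnt[o[seq_len(rem)]] + 1
  }
  labels <- sample(rep(names(classes), times = cnt))
  truth <- matrix(NA_character_, grid[1], grid[2])
  f <- 0L
  for (i in seq_len(length(rb) - 1L)) {
    for (j in seq_len(length(cb) - 1L)) {
      f <- f + 1L
      truth[(rb[i] + 1L):rb[i + 1L], (cb[j] + 1L):cb[j + 1L]] <- labels[f]
    }
  }
  truth
}

#' Draw labeled sample points from a scene's truth raster
#'
#' Stratified random pixel-center points per class, honouring a minimum
#' inter-point distance by greedy rejection. Labels are read off the truth
#' raster, so every sample label matches the truth at its location.
#'
#' @param scene A `labeled_scene`.
#' @param n_per_class Points per class.
#' @param min_distance Minimum distance between points, in map units.
#' @param seed Seed (`NULL` to use the ambient RNG state).
#' @param classes Classes to sample (default: all in the truth raster).
#' @return Tibble `x`, `y`, `label`, `role = "unassigned"`.
#' @export
sample_truth <- function(scene, n_per_class = 80, min_distance = 30,
                         seed = NULL, classes = NULL) {
  run <- function() {
    truth <- scene$truth
    geo <- scene$stack$geo
    if (is.null(classes)) classes <- sort(unique(as.vector(truth)))
    if (n_per_class == 0)
      return(tibble::tibble(x = double(), y = double(),
                            label = character(), role = character()))
    kx <- numeric(0); ky <- numeric(0)
    out <- list()
    for (cl in classes) {
      idx <- which(truth == cl)
      idx <- idx[sample.int(length(idx))]
      got <- 0L
      for (i in idx) {
        if (got == n_per_class) break
        rc <- arrayInd(i, dim(truth))
        p <- pixel_to_coord(geo, rc[1], rc[2])
        if (!length(kx) ||
            min((kx - p$x)^2 + (ky - p$y)^2) >= min_distance^2) {
          kx <- c(kx, p$x); ky <- c(ky, p$y)
          got <- got + 1L
          out[[length(out) + 1L]] <- tibble::tibble(
            x = p$x, y = p$y, label = cl, role = "unassigned")
        }
      }
      if (got < n_per_class)
        stop("class '", cl, "': only ", got, " of ", n_per_class,
             " points satisfiable under min_distance = ", min_distance,
             call. = FALSE)
    }
    dplyr::bind_rows(out)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' @export
print.labeled_scene <- function(x, ...) {
  cat("<labeled_scene> ", nrow(x$truth), "x", ncol(x$truth), " px, classes: ",
      paste(names(x$config$classes), collapse = ", "), "; ",
      nrow(x$samples), " samples, seed ", x$config$seed, "\n", sep = "")
  print(x$stack)
  invisible(x)
}
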