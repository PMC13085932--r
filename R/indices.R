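# Vegetation-index formulary: named band-arithmetic expressions over the
# Sentinel-2 band symbols of `S2_BANDS`, evaluated per pixel with mask
# propagation (any non-finite result, e.g. a zero denominator, masks the
# pixel rather than raising).

#' Sign-preserving cube root
#'
#' `cbrt(-8) == -2`. Used by the cube-root form of the soybean
#' identification index so that negative products (water, bare soil, where
#' EVI can go negative) map to strongly negative index values instead of
#' `NaN`.
#'
#' @param x Numeric.
#' @return Numeric of the same shape.
#' @export
cbrt <- function(x) sign(x) * abs(x)^(1 / 3)

#' Enhanced Vegetation Index
#'
#' `EVI = G * (NIR - Red) / (NIR + C1 * Red - C2 * Blue + L)` with the
#' standard coefficients `G = 2.5`, `C1 = 6`, `C2 = 7.5`, `L = 1`. A zero
#' denominator yields `NA` (masked), not an error.
#'
#' @param nir,red,blue Surface reflectance (B8, B4, B2).
#' @return EVI values, `NA` at singularities.
#' @export
#' @examples
#' evi(0.5, 0.1, 0.05)  # 1.0 / 1.725 = 0.5797
evi <- function(nir, red, blue) {
  den <- nir + 6 * red - 7.5 * blue + 1
  out <- 2.5 * (nir - red) / den
  out[!is.finite(out)] <- NA_real_
  out
}

#' Green Chlorophyll Vegetation Index
#'
#' `GCVI = NIR / Green - 1`.
#' @param nir,green Surface reflectance (B8, B3).
#' @return GCVI values, `NA` at singularities.
#' @export
gcvi <- function(nir, green) {
  out <- nir / green - 1
  out[!is.finite(out)] <- NA_real_
  out
}

#' Soybean identification index (NSII)
#'
#' Composite of the second red-edge band (RE2, B6), the first
#' shortwave-infrared band (SWIR1, B11) and EVI, evaluated inside the
#' optimal soybean/corn divergence window. Two renderings are provided:
#'
#' * `"cube_root"` (default): sign-preserving cube root of the triple
#'   product, `cbrt(RE2 * SWIR1 * EVI)` — a geometric-mean-style index that
#'   stays on a reflectance-like scale;
#' * `"product"`: `RE2 * SWIR1 * EVI^3`.
#'
#' For positive inputs both are strictly monotone transformations of each
#' other's ordering along each argument, so threshold classification is
#' invariant to the choice (at correspondingly transformed thresholds).
#' Higher values indicate higher likelihood of soybean.
#'
#' @param re2,swir1 Surface reflectance (B6, B11).
#' @param evi EVI values (see [evi()]).
#' @param form `"cube_root"` or `"product"`.
#' @return Index values.
#' @export
#' @examples
#' nsii(0.30, 0.22, 0.60)  # cbrt(0.0396) = 0.3409
nsii <- function(re2, swir1, evi, form = c("cube_root", "product")) {
  form <- match.arg(form)
  if (form == "cube_root") cbrt(re2 * swir1 * evi) else re2 * swir1 * evi^3
}

#' The vegetation-index registry
#'
#' A tibble of named band-arithmetic feature definitions: the full 35-index
#' formulary (normalized-difference, ratio, soil-adjusted, red-edge and
#' composite soybean indices) plus the `GCVI` sub-feature and the soybean
#' identification index `NSII`. Each entry records:
#'
#' * `name`, `formula` — an arithmetic expression over band symbols
#'   (`B2`..`B12`), scalar constants and previously defined features
#'   (`EVI`, `GCVI`, `NDVI` may appear inside composites);
#' * `fidelity` — `"as_printed"` where the circulating printed form is
#'   well defined, `"canonical_corrected"` where that form is degenerate or
#'   inconsistent with the index's source publication (e.g. `WDRVI`,
#'   `MSRre`, `MSRren`, `RDVI`, `MSAVI` without its square root) and the
#'   canonical published form is stored instead;
#' * `bounded_pm1` — `TRUE` for normalized-difference-type indices bounded
#'   in `[-1, 1]` for nonnegative band inputs;
#' * `required_bands` — list-column of band symbols the formula needs after
#'   resolving sub-features.
#'
#' @param nsii_form Rendering of `NSII`, see [nsii()].
#' @return A tibble with one row per feature definition.
#' @export
#' @examples
#' reg <- index_registry()
#' reg$formula[reg$name == "NDVI"]
index_registry <- function(nsii_form = c("cube_root", "product")) {
  nsii_form <- match.arg(nsii_form)
  def <- function(name, formula, fidelity = "as_printed", bounded = FALSE)
    tibble::tibble(name = name, formula = formula, fidelity = fidelity,
                   bounded_pm1 = bounded)
  reg <- dplyr::bind_rows(
    def("NDVI",      "(B8 - B4) / (B8 + B4)", bounded = TRUE),
    def("NDre1",     "(B6 - B5) / (B6 + B5)", bounded = TRUE),
    def("NDre2",     "(B7 - B5) / (B7 + B5)", bounded = TRUE),
    def("LSWI",      "(B8 - B11) / (B8 + B11)", bounded = TRUE),
    def("SAVI",      "1.5 * (B8 - B4) / (B8 + B4 + 0.5)"),
    def("NDWI",      "(B3 - B8) / (B3 + B8)", bounded = TRUE),
    def("PSRI",      "(B4 - B3) / B6"),
    def("NDVIre1",   "(B8 - B5) / (B8 + B5)", bounded = TRUE),
    def("NDVIre2",   "(B8 - B6) / (B8 + B6)", bounded = TRUE),
    def("IRECI",     "(B8 - B4) / (B5 / B6)"),
    def("CIre",      "(B8 / B5) - 1"),
    def("RVI",       "B8 / B4"),
    def("WDRVI",     "(0.1 * B8 - B4) / (0.1 * B8 + B4)",
        fidelity = "canonical_corrected", bounded = TRUE),
    def("NLI",       "(B8 * B8 - B4) / (B8 * B8 + B4)", bounded = TRUE),
    def("MNLI",      "((B8 * B8 - B4) * 1.5) / (B8 * B8 + B4 + 0.5)"),
    def("OSAVI",     "(B8 - B4) / (B8 + B4 + 0.16)"),
    def("EVI",       "2.5 * (B8 - B4) / (B8 + 6 * B4 - 7.5 * B2 + 1)"),
    def("DVI",       "B8 - B4"),
    def("BSI",       "((B11 + B4) - (B8 + B2)) / ((B11 + B4) + (B8 + B2))",
        bounded = TRUE),
    def("WRI",       "((B8 - B3) / (B8 + B3)) * (B2 / (B3 + B4))",
        fidelity = "canonical_corrected"),
    def("RVI_green", "B8 / B3"),
    def("SR_red_green", "B4 / B3"),
    def("VARI_green", "(B3 - B4) / (B3 + B4 - B2)"),
    def("TVI",       "0.5 * (120 * (B8 - B3) - 200 * (B4 - B3))",
        fidelity = "canonical_corrected"),
    def("MTCI",      "(B6 - B5) / (B5 - B4)"),
    def("MNDVI",     "(B3 - B11) / (B3 + B11)", bounded = TRUE),
    def("MSAVI",     "(2 * B8 + 1 - sqrt((2 * B8 + 1)^2 - 8 * (B8 - B4))) / 2",
        fidelity = "canonical_corrected"),
    def("MSRre",     "((B8 / B5) - 1) / sqrt((B8 / B5) + 1)",
        fidelity = "canonical_corrected"),
    def("MSRren",    "((B8A / B5) - 1) / sqrt((B8A / B5) + 1)",
        fidelity = "canonical_corrected"),
    def("RDVI",      "(B8 - B4) / sqrt(B8 + B4)",
        fidelity = "canonical_corrected"),
    def("SR",        "B8 / B4"),
    def("REP",       "705 + 35 * ((0.5 * (B4 + B7) - B5) / (B6 - B5))"),
    def("NBR",       "(B8 - B12) / (B8 + B12)", bounded = TRUE),
    def("GWCCI",     "B11 * (B8 - B4) / (B8 + B4)"),
    def("GCVI",      "(B8 / B3) - 1"),
    def("SMCI",      "(B11 + B8 + B8A + B7 + B6) * EVI * GCVI"),
    def("NSII",
        if (nsii_form == "cube_root") "cbrt(B6 * B11 * EVI)"
        else "B6 * B11 * EVI^3")
  )
  reg$required_bands <- lapply(reg$formula, required_bands, registry = reg)
  reg
}

# Band symbols a formula needs, resolving named sub-features recursively.
required_bands <- function(formula, registry, seen = character()) {
  vars <- all.vars(str2lang(formula))
  bands <- intersect(vars, S2_BANDS)
  subs <- setdiff(vars, c(S2_BANDS, seen))
  for (s in subs) {
    i <- match(s, registry$name)
    if (is.na(i))
      stop("formula references unknown feature or band: ", s, call. = FALSE)
    bands <- union(bands,
                   required_bands(registry$formula[i], registry,
                                  seen = c(seen, s)))
  }
  sort(bands)
}

#' Define a custom band-arithmetic feature
#'
#' @param name Feature name.
#' @param formula Arithmetic expression string over band symbols
#'   ([S2_BANDS]), scalar constants, `sqrt`/`cbrt`, and names already in
#'   `registry`.
#' @param registry Registry the formula may reference (default
#'   [index_registry()]).
#' @return A one-row registry tibble.
#' @export
feature_definition <- function(name, formula, registry = index_registry()) {
  tibble::tibble(name = name, formula = formula, fidelity = "user",
                 bounded_pm1 = FALSE,
                 required_bands = list(required_bands(formula, registry)))
}

#' Evaluate a feature over a composite series or reflectance stack
#'
#' Evaluates a registry feature (by name), a formula string, or a
#' [feature_definition()] row per pixel and time slice. Pixels where any
#' required band is masked, or where evaluation is singular (division by
#' zero, negative square root), come out masked.
#'
#' @param series A `composite_series` (or a [reflectance_stack()], in which
#'   case dates play the role of periods).
#' @param feature Registry name, formula string, or one-row definition tibble.
#' @param periods Optional integer vector of period indices to evaluate
#'   (default: all).
#' @param registry Feature registry, see [index_registry()].
#' @return A `feature_raster`: list with `values` (`[row, col, period]`
#'   array), `name`, `periods` (tibble), `geo`.
#' @export
#' @examples
#' # NDVI over a 1x1 scene with B8 = B4 is 0 everywhere
compute_feature <- function(series, feature, periods = NULL,
                            registry = index_registry()) {
  if (is.data.frame(feature)) {
    name <- feature$name[1]; formula <- feature$formula[1]
    registry <- dplyr::bind_rows(registry, feature)
  } else if (feature %in% registry$name) {
    name <- feature; formula <- registry$formula[match(feature, registry$name)]
  } else if (feature %in% S2_BANDS || grepl("[-+*/() ]", feature)) {
    name <- feature; formula <- feature
  } else {
    stop("unknown feature: ", feature, call. = FALSE)
  }
  ptab <- series_periods(series)
  if (is.null(periods)) periods <- seq_len(nrow(ptab))
  need <- required_bands(formula, registry)
  missing_bands <- setdiff(need, series$bands)
  if (length(missing_bands))
    stop("required band(s) missing from series: ",
         paste(missing_bands, collapse = ", "), call. = FALSE)

  d <- dim(series$values)
  out <- array(NA_real_, c(d[1], d[2], length(periods)))
  for (k in seq_along(periods)) {
    p <- periods[k]
    env <- new.env(parent = baseenv())
    assign("cbrt", cbrt, envir = env)
    for (b in need)
      assign(b, series$values[, , match(b, series$bands), p], envir = env)
    v <- eval_feature_formula(formula, env, registry)
    v[!is.finite(v)] <- NA_real_
    out[, , k] <- v
  }
  structure(list(values = out, name = name, periods = ptab[periods, ],
                 geo = series$geo),
            class = "feature_raster")
}

# Recursive evaluation: resolve sub-feature names into the environment first.
eval_feature_formula <- function(formula, env, registry, seen = character()) {
  expr <- str2lang(formula)
  vars <- setdiff(all.vars(expr), c(ls(env), seen))
  for (s in vars) {
    i <- match(s, registry$name)
    if (is.na(i))
      stop("formula references unknown feature or band: ", s, call. = FALSE)
    assign(s,
           eval_feature_formula(registry$formula[i], env, registry,
                                seen = c(seen, s)),
           envir = env)
  }
  eval(expr, env)
}

series_periods <- function(series) {
  if (inherits(series, "reflectance_stack"))
    tibble::tibble(period = seq_along(series$dates), start = series$dates,
                   end = series$dates, midpoint = series$dates,
                   mid_doy = as.numeric(format(series$dates, "%j")))
  else series$periods
}

#' Reduce a feature raster over a set of periods
#'
#' Collapses the period dimension (e.g. to the mean feature value inside the
#' optimal time window, the form in which composite soybean indices are
#' thresholded).
#'
#' @param fr A `feature_raster` from [compute_feature()].
#' @param window A `time_window` (see [select_optimal_window()]) or integer
#'   period indices; default all periods.
#' @param fun Reduction: `"mean"` or `"median"`.
#' @param na.rm Drop masked periods per pixel before reducing.
#' @return A `feature_raster` with a single period layer.
#' @export
reduce_periods <- function(fr, window = NULL, fun = c("mean", "median"),
                           na.rm = TRUE) {
  fun <- match.arg(fun)
  idx <- window_indices(window, fr$periods)
  m <- matrix(fr$values[, , idx, drop = FALSE],
              nrow = prod(dim(fr$values)[1:2]), ncol = length(idx))
  v <- if (fun == "mean") {
    k <- rowSums(!is.na(m))
    s <- rowSums(m, na.rm = na.rm)
    ifelse(k == 0, NA_real_, s / k)
  } else row_median(m)
  structure(list(values = array(v, c(dim(fr$values)[1:2], 1L)),
                 name = fr$name, periods = fr$periods[idx[1], ],
                 geo = fr$geo),
            class = "feature_raster")
}

# Accepts a time_window object, integer indices, or NULL (all), and returns
# row indices into the `periods` tibble.
window_indices <- function(window, periods) {
  if (is.null(window)) return(seq_len(nrow(periods)))
  if (inherits(window, "time_window"))
    return(which(periods$period >= window$start_period &
                   periods$period <= window$end_period))
  as.integer(window)
}

#' @export
print.feature_raster <- function(x, ...) {
  d <- dim(x$values)
  cat("<feature_raster> ", x$name, ": ", d[1], "x", d[2], " px, ",
      d[3], " period(s)\n", sep = "")
  invisible(x)
}
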