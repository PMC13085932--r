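# End-to-end mapping: feature -> window -> threshold -> map -> metrics.

#' Map soybean from a composite series with an automatic threshold
#'
#' Runs the full classification stage: computes the chosen feature per
#' period, finds (or accepts) the optimal time window, averages the feature
#' inside the window, thins and splits the samples, fits the automatic
#' threshold on the 70% threshold set, classifies the scene, and scores the
#' map on the held-out 30% validation set.
#'
#' @param series A `composite_series` (see [median_composite()],
#'   [fill_gaps_linear()]).
#' @param samples Labeled sample tibble `(x, y, label)`.
#' @param feature Registry feature to threshold (default `"NSII"`).
#' @param window A `time_window`, integer period indices, or `NULL` to
#'   select the window automatically from the feature's separability matrix
#'   (windows of `min_len`..`max_len` periods).
#' @param class_pair Classes used for window selection.
#' @param positive Target class label (default `"soybean"`).
#' @param ratio,min_distance,seed Passed to [split_samples()].
#' @param direction_mode Passed to [iterative_threshold()].
#' @param min_len,max_len Window length bounds (periods) for automatic
#'   selection.
#' @param registry Feature registry.
#' @return A list of class `"soy_map_result"`: `feature`, `window`,
#'   `threshold` ([iterative_threshold()] result), `map`
#'   (`classified_map`), `metrics` (validation [metrics()] report),
#'   `split` (the role-assigned samples).
#' @export
map_soybean <- function(series, samples, feature = "NSII", window = NULL,
                        class_pair = c("soybean", "corn"),
                        positive = "soybean",
                        ratio = 0.7, min_distance = 30, seed = 1,
                        direction_mode = "consistent",
                        min_len = 3L, max_len = 5L,
                        registry = index_registry()) {
  if (is.null(window)) {
    sep <- separability_matrix(series, samples, features = feature,
                               class_pair = class_pair, registry = registry)
    window <- select_optimal_window(sep, min_len = min_len,
                                    max_len = max_len)
  }
  fr <- compute_feature(series, feature, registry = registry)
  fw <- reduce_periods(fr, window, fun = "mean")

  split <- split_samples(samples, ratio = ratio, seed = seed,
                         min_distance = min_distance)
  thr_set <- split[split$role == "threshold", ]
  val_set <- split[split$role == "validation", ]
  px <- coord_to_pixel(series$geo, thr_set$x, thr_set$y)
  v <- fw$values[, , 1][cbind(px$row, px$col)]
  thr <- iterative_threshold(v, thr_set$label == positive,
                             direction_mode = direction_mode)
  map <- classify(fw, thr$threshold)
  res <- evaluate_map(map, val_set, positive = positive)
  structure(list(feature = feature, window = window, threshold = thr,
                 map = map, metrics = res, split = split),
            class = "soy_map_result")
}

#' @export
print.soy_map_result <- function(x, ...) {
  cat("<soy_map_result> feature ", x$feature, ", window periods ",
      x$window$start_period, "..", x$window$end_period,
      " (DOY ", x$window$start_doy, "-", x$window$end_doy, ")\n", sep = "")
  cat("  threshold ", format(x$threshold$threshold),
      " (fit F1 ", round(x$threshold$f1, 3), ")\n", sep = "")
  m <- x$metrics
  cat("  validation: OA ", round(m$oa, 3), ", P ", round(m$precision, 3),
      ", R ", round(m$recall, 3), ", F1 ", round(m$f1, 3), "\n", sep = "")
  invisible(x)
}
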