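# broom-style tidiers for the package's fitted/result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a threshold search result
#'
#' @param x A `threshold_result` from [iterative_threshold()].
#' @param ... Unused.
#' @return The iteration trace: one row per evaluated threshold with
#'   `iter`, `threshold`, `precision`, `recall`, `f1`, `accepted`.
#' @method tidy threshold_result
#' @export
tidy.threshold_result <- function(x, ...) x$trace

#' @rdname tidy.threshold_result
#' @return For `glance()`: a one-row summary with the final threshold,
#'   its precision/recall/F1, iteration count, convergence and mode.
#' @method glance threshold_result
#' @export
glance.threshold_result <- function(x, ...) {
  tibble::tibble(threshold = x$threshold, f1 = x$f1,
                 precision = x$precision, recall = x$recall,
                 iterations = x$iterations, converged = x$converged,
                 degenerate = x$degenerate,
                 direction_mode = x$direction_mode)
}

#' Tidy a separability matrix
#'
#' @param x A [separability_matrix()].
#' @param ... Unused.
#' @return A plain tibble (`feature`, `period`, `start`, `end`, `mid_doy`,
#'   `jm`) with a `class_a`/`class_b` column pair identifying the contrast.
#' @method tidy separability_matrix
#' @export
tidy.separability_matrix <- function(x, ...) {
  cp <- attr(x, "class_pair")
  out <- tibble::as_tibble(x)
  out$class_a <- cp[1]
  out$class_b <- cp[2]
  out
}

#' Glance at an end-to-end mapping result
#'
#' @param x A `soy_map_result` from [map_soybean()].
#' @param ... Unused.
#' @return One-row tibble: feature, window bounds (periods and DOY), window
#'   mean J-M, threshold, and validation OA/precision/recall/F1.
#' @method glance soy_map_result
#' @export
glance.soy_map_result <- function(x, ...) {
  m <- x$metrics
  tibble::tibble(feature = x$feature,
                 start_period = x$window$start_period,
                 end_period = x$window$end_period,
                 start_doy = x$window$start_doy, end_doy = x$window$end_doy,
                 window_mean_jm = x$window$mean_jm,
                 threshold = x$threshold$threshold,
                 oa = m$oa, precision = m$precision, recall = m$recall,
                 f1 = m$f1)
}
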