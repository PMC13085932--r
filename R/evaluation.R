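# Confusion-matrix accuracy assessment: OA, precision, recall, F1.

#' Confusion counts for a binary classification
#'
#' Tallies the standard 2x2 confusion counts between predicted and
#' reference labels. Pairs where either side is `NA` (nodata pixels) are
#' excluded and counted in `n_excluded`.
#'
#' @param pred Predicted labels: logical, 0/1, a `classified_map`, or
#'   character with `positive`.
#' @param ref Reference labels, same conventions and length as `pred`.
#' @param positive Label counted as the target class for character input.
#' @return One-row tibble of class `"confusion_counts"`: `tp`, `fp`, `fn`,
#'   `tn`, `n_excluded`.
#' @export
#' @examples
#' confusion(c(1, 1, 0, 0), c(1, 0, 0, 0))  # tp 1, fp 1, tn 2
confusion <- function(pred, ref, positive = NULL) {
  if (inherits(pred, "classified_map")) pred <- as.vector(unclass(pred))
  if (inherits(ref, "classified_map")) ref <- as.vector(unclass(ref))
  p <- as_binary_labels(pred, positive)
  r <- as_binary_labels(ref, positive)
  if (length(p) != length(r))
    stop("pred and ref must have the same length", call. = FALSE)
  ok <- !is.na(p) & !is.na(r)
  out <- tibble::tibble(
    tp = sum(p[ok] & r[ok]), fp = sum(p[ok] & !r[ok]),
    fn = sum(!p[ok] & r[ok]), tn = sum(!p[ok] & !r[ok]),
    n_excluded = sum(!ok)
  )
  class(out) <- c("confusion_counts", class(out))
  out
}

#' Accuracy metrics from confusion counts
#'
#' Overall accuracy `OA = (tp + tn) / total`, precision `P = tp / (tp +
#' fp)` (fraction of predicted target pixels that are truly target), recall
#' `R = tp / (tp + fn)` (fraction of true target pixels recovered), and the
#' F1 score `2PR / (P + R)`, the harmonic mean of precision and recall. A
#' zero denominator yields the defined value 0 and sets `degenerate`, so
#' extreme thresholds never crash the iterative search.
#'
#' @param counts A [confusion()] row, or anything coercible (list/tibble
#'   with `tp`, `fp`, `fn`, `tn`).
#' @return One-row tibble of class `"metrics_report"`: `oa`, `precision`,
#'   `recall`, `f1`, the four counts, `n_excluded`, `degenerate`.
#' @export
#' @examples
#' metrics(tibble::tibble(tp = 8, fp = 2, fn = 2, tn = 88))  # P = R = 0.8
metrics <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn; tn <- counts$tn
  total <- tp + fp + fn + tn
  if (total == 0) stop("no evaluated samples", call. = FALSE)
  safe_div <- function(num, den) if (den == 0) 0 else num / den
  p <- safe_div(tp, tp + fp)
  r <- safe_div(tp, tp + fn)
  f1 <- safe_div(2 * p * r, p + r)
  out <- tibble::tibble(
    oa = (tp + tn) / total, precision = p, recall = r, f1 = f1,
    tp = tp, fp = fp, fn = fn, tn = tn,
    n_excluded = if ("n_excluded" %in% names(counts)) counts$n_excluded else 0L,
    degenerate = (tp + fp) == 0 || (tp + fn) == 0 || (p + r) == 0
  )
  class(out) <- c("metrics_report", class(out))
  out
}

#' Evaluate a classified map against labeled sample points
#'
#' Looks up the map prediction at each sample location and computes the
#' accuracy metrics. Samples falling on nodata pixels are excluded and
#' counted.
#'
#' @param map A `classified_map` (see [classify()]).
#' @param samples Tibble `(x, y, label, ...)`; typically the `"validation"`
#'   role of [split_samples()].
#' @param positive Label counted as the target class (default
#'   `"soybean"`).
#' @return A [metrics()] report.
#' @export
evaluate_map <- function(map, samples, positive = "soybean") {
  geo <- attr(map, "geo") %||% geo_meta()
  px <- coord_to_pixel(geo, samples$x, samples$y)
  m <- unclass(map)
  pred <- m[cbind(px$row, px$col)]
  metrics(confusion(pred, samples$label == positive))
}
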