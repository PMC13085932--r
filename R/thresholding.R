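# Automatic threshold determination: distance-thinned stratified sample
# split, precision/recall-guided bisection with F1-improvement stopping, a
# grid-search oracle, and map classification.

#' Thin and split labeled samples for threshold fitting and validation
#'
#' First applies greedy distance thinning (a point is kept iff it lies at
#' least `min_distance` from every already-kept point, visiting points in a
#' seeded random order) to curb spatial autocorrelation, then splits each
#' class 70/30 (by `ratio`) into a threshold-fitting set and a validation
#' set. Deterministic given `seed`.
#'
#' @param samples Tibble `(x, y, label, ...)`.
#' @param ratio Fraction per class assigned the `"threshold"` role.
#' @param seed Integer seed controlling thinning order and split.
#' @param min_distance Minimum distance between kept points, in map units
#'   (default 30 m = 3 pixels at 10 m).
#' @return The kept samples with `role` set to `"threshold"` or
#'   `"validation"`; the number of thinned-out points is in the
#'   `n_thinned` attribute.
#' @export
split_samples <- function(samples, ratio = 0.7, seed = NULL,
                          min_distance = 30) {
  stopifnot(nrow(samples) >= 1, ratio > 0, ratio < 1)
  run <- function() {
    ord <- sample.int(nrow(samples))
    kept <- thin_points(samples$x[ord], samples$y[ord], min_distance)
    keep_idx <- ord[kept]
    out <- samples[keep_idx, ]
    lost <- setdiff(unique(samples$label), unique(out$label))
    if (length(lost))
      stop("distance thinning removed every sample of class: ",
           paste(lost, collapse = ", "), call. = FALSE)
    out$role <- "validation"
    for (cl in unique(out$label)) {
      i <- which(out$label == cl)
      n_thr <- round(ratio * length(i))
      pick <- sample(i, n_thr)
      out$role[pick] <- "threshold"
    }
    attr(out, "n_thinned") <- nrow(samples) - nrow(out)
    out
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

# Greedy sequential thinning; returns logical keep-vector in input order.
thin_points <- function(x, y, min_distance) {
  n <- length(x)
  keep <- logical(n)
  kx <- numeric(0); ky <- numeric(0)
  for (i in seq_len(n)) {
    if (!length(kx) ||
        min((kx - x[i])^2 + (ky - y[i])^2) >= min_distance^2) {
      keep[i] <- TRUE
      kx <- c(kx, x[i]); ky <- c(ky, y[i])
    }
  }
  keep
}

#' Automatic threshold search by precision/recall-guided bisection
#'
#' Starting from the midpoint of the value range, repeatedly halves the
#' search interval: at the current threshold `T` it computes precision,
#' recall and F1 of the rule `value >= T` against the labels, moves `T`
#' towards the half-interval indicated by the precision/recall comparison,
#' and accepts the move unless F1 strictly worsens. An F1 tie continues in
#' the indicated direction (on clustered values consecutive midpoints often
#' fall in the same inter-class gap); a strict worsening is treated as an
#' overshoot and the step is halved towards the current threshold rather
#' than terminating, so a too-large first jump cannot strand the search.
#' The search stops when no resolvable step improves F1, when the interval
#' collapses below `tol` times the initial range, or at `max_iter`, and
#' returns the best-F1 threshold seen.
#'
#' Two direction conventions are provided. For a `>=` rule, precision rises
#' and recall falls as `T` increases, so precision exceeding recall means
#' the threshold is too *high*; `"consistent"` (default) therefore moves
#' `T` down when `P > R`. `"as_printed"` preserves the opposite, commonly
#' printed convention (`P > R` moves `T` up); the F1-acceptance rule
#' partially self-corrects either mode. Exact `P == R` ties probe one
#' F1-improving move in each direction before stopping.
#'
#' @param values Numeric feature values, one per sample.
#' @param labels Binary labels: logical, 0/1, or character with `positive`
#'   naming the target class.
#' @param positive Label value counted as the target class (required for
#'   character labels).
#' @param direction_mode `"consistent"` or `"as_printed"`.
#' @param tol Relative interval tolerance (default `1e-6` of the range).
#' @param max_iter Iteration cap (default 60).
#' @return An object of class `"threshold_result"`: `threshold`, `f1`,
#'   `precision`, `recall`, `trace` (tibble with one row per evaluated
#'   threshold), `direction_mode`, `converged`, `degenerate`, `t_range`.
#' @export
#' @examples
#' r <- iterative_threshold(c(0.8, 0.9, 0.1, 0.2), c(1, 1, 0, 0))
#' r$f1  # 1: separable classes
iterative_threshold <- function(values, labels, positive = NULL,
                                direction_mode = c("consistent", "as_printed"),
                                tol = 1e-6, max_iter = 60L) {
  direction_mode <- match.arg(direction_mode)
  pos <- as_binary_labels(labels, positive)
  ok <- is.finite(values) & !is.na(pos)
  values <- values[ok]; pos <- pos[ok]
  if (length(unique(pos)) < 2)
    stop("both classes must be present in labels", call. = FALSE)

  lo0 <- min(values); hi0 <- max(values)
  eval_t <- function(t) prf_at(values, pos, t)
  if (lo0 == hi0) {
    m <- eval_t(lo0)
    return(new_threshold_result(
      threshold = lo0, m = m,
      trace = trace_row(1L, lo0, m, TRUE),
      direction_mode = direction_mode, converged = TRUE,
      degenerate = TRUE, t_range = c(lo0, hi0)))
  }

  lo <- lo0; hi <- hi0
  t_cur <- (lo + hi) / 2
  m_cur <- eval_t(t_cur)
  trace <- trace_row(1L, t_cur, m_cur, TRUE)
  best_t <- t_cur; best_m <- m_cur
  converged <- FALSE
  iter <- 1L
  accept <- function(cand_t, m_new, move_down) {
    if (move_down) hi <<- t_cur else lo <<- t_cur
    t_cur <<- cand_t; m_cur <<- m_new
    trace <<- rbind(trace, trace_row(iter, cand_t, m_new, TRUE))
    if (m_new$f1 > best_m$f1) { best_t <<- cand_t; best_m <<- m_new }
  }
  while (iter < max_iter) {
    if ((hi - lo) < tol * (hi0 - lo0)) { converged <- TRUE; break }
    p <- m_cur$precision; r <- m_cur$recall
    t_down <- (lo + t_cur) / 2
    t_up <- (t_cur + hi) / 2
    if (p == r) {
      # balanced: probe both half-intervals, take an improving one if any
      md <- eval_t(t_down); mu <- eval_t(t_up)
      iter <- iter + 1L
      if (md$f1 >= mu$f1 && md$f1 > m_cur$f1) {
        accept(t_down, md, TRUE)
      } else if (mu$f1 > m_cur$f1) {
        accept(t_up, mu, FALSE)
      } else {
        trace <- rbind(trace, trace_row(iter, t_down, md, FALSE))
        converged <- TRUE
        break
      }
    } else {
      move_down <- if (direction_mode == "consistent") p > r else p < r
      cand_t <- if (move_down) t_down else t_up
      m_new <- eval_t(cand_t)
      iter <- iter + 1L
      if (m_new$f1 >= m_cur$f1) {
        # F1 plateaus between consecutive midpoints are common on clustered
        # values; a tie keeps the direction the P/R comparison indicates.
        accept(cand_t, m_new, move_down)
      } else {
        # the half-interval midpoint worsened F1: either an overshoot past
        # the optimum or a misleading P/R hint (e.g. weakly discriminative
        # features, where precision barely moves with T). Shrink the
        # indicated half so the next directed step is smaller, and give the
        # opposite half-interval one probe; the interval tolerance bounds
        # the refinement.
        trace <- rbind(trace, trace_row(iter, cand_t, m_new, FALSE))
        if (move_down) lo <- cand_t else hi <- cand_t
        if (iter < max_iter) {
          t_opp <- if (move_down) t_up else t_down
          m_opp <- eval_t(t_opp)
          iter <- iter + 1L
          if (m_opp$f1 > m_cur$f1) {
            accept(t_opp, m_opp, !move_down)
          } else {
            trace <- rbind(trace, trace_row(iter, t_opp, m_opp, FALSE))
          }
        }
      }
    }
  }
  new_threshold_result(best_t, best_m, trace, direction_mode, converged,
                       degenerate = FALSE, t_range = c(lo0, hi0))
}

trace_row <- function(iter, t, m, accepted) {
  tibble::tibble(iter = iter, threshold = t, precision = m$precision,
                 recall = m$recall, f1 = m$f1, accepted = accepted)
}

new_threshold_result <- function(threshold, m, trace, direction_mode,
                                 converged, degenerate, t_range) {
  structure(list(threshold = threshold, f1 = m$f1,
                 precision = m$precision, recall = m$recall,
                 trace = trace, direction_mode = direction_mode,
                 converged = converged, degenerate = degenerate,
                 t_range = t_range, iterations = max(trace$iter)),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat("<threshold_result> T = ", format(x$threshold), ", F1 = ",
      round(x$f1, 4), " (P = ", round(x$precision, 4), ", R = ",
      round(x$recall, 4), "), ", x$iterations, " iterations, mode ",
      x$direction_mode, if (x$degenerate) ", degenerate" else "",
      "\n", sep = "")
  invisible(x)
}

#' Exhaustive grid oracle for the F1-optimal threshold
#'
#' Evaluates F1 of the rule `value >= T` at `n_cuts` evenly spaced cuts
#' across the value range plus all midpoints between sorted unique values
#' (and the minimum itself, so the classify-everything cut is reachable),
#' returning the argmax (ties resolved to the lowest threshold). Used as an
#' independent reference for [iterative_threshold()].
#'
#' @inheritParams iterative_threshold
#' @param n_cuts Number of evenly spaced cuts (default 1000).
#' @return One-row tibble: `threshold`, `f1`.
#' @export
grid_threshold_oracle <- function(values, labels, positive = NULL,
                                  n_cuts = 1000L) {
  pos <- as_binary_labels(labels, positive)
  ok <- is.finite(values) & !is.na(pos)
  values <- values[ok]; pos <- pos[ok]
  if (length(unique(pos)) < 2)
    stop("both classes must be present in labels", call. = FALSE)
  u <- sort(unique(values))
  cuts <- sort(unique(c(seq(min(values), max(values), length.out = n_cuts),
                        if (length(u) > 1) (u[-1] + u[-length(u)]) / 2,
                        u[1])))
  f1s <- vapply(cuts, function(t) prf_at(values, pos, t)$f1, numeric(1))
  i <- which(f1s == max(f1s))[1]  # cuts sorted ascending -> lowest T wins
  tibble::tibble(threshold = cuts[i], f1 = f1s[i])
}

#' Classify a feature raster by threshold
#'
#' Pixels with `value >= threshold` become the target class (1), other
#' unmasked pixels 0, masked pixels stay `NA`.
#'
#' @param feature A `feature_raster` with a single period layer (see
#'   [reduce_periods()]), or a numeric matrix/vector.
#' @param threshold Finite scalar threshold.
#' @return A `classified_map` (integer matrix with `geo` and `threshold`
#'   attributes) for raster input, or an integer vector for vector input.
#' @export
classify <- function(feature, threshold) {
  stopifnot(is.finite(threshold))
  if (inherits(feature, "feature_raster")) {
    v <- feature$values
    if (length(dim(v)) == 3) {
      stopifnot(dim(v)[3] == 1)
      v <- v[, , 1]
    }
    new_classified_map(ifelse(is.na(v), NA_integer_,
                              as.integer(v >= threshold)),
                       geo = feature$geo, threshold = threshold)
  } else if (is.matrix(feature)) {
    new_classified_map(ifelse(is.na(feature), NA_integer_,
                              as.integer(feature >= threshold)),
                       geo = NULL, threshold = threshold)
  } else {
    ifelse(is.na(feature), NA_integer_, as.integer(feature >= threshold))
  }
}

new_classified_map <- function(m, geo = NULL, threshold = NA_real_) {
  structure(m, class = "classified_map", geo = geo, threshold = threshold)
}

#' @export
print.classified_map <- function(x, ...) {
  tab <- table(factor(unclass(x), levels = c(0, 1)), useNA = "always")
  cat("<classified_map> ", nrow(x), "x", ncol(x), " px: ",
      tab[["1"]], " target, ", tab[["0"]], " other, ",
      sum(is.na(unclass(x))), " nodata; threshold ",
      format(attr(x, "threshold")), "\n", sep = "")
  invisible(x)
}

# Plain-arithmetic precision/recall/F1 of the rule `values >= t`: the hot
# path of both threshold searches (same conventions as metrics()).
prf_at <- function(values, pos, t) {
  pred <- values >= t
  tp <- sum(pred & pos)
  p <- if (tp + sum(pred & !pos) == 0) 0 else tp / sum(pred)
  r <- if (sum(pos) == 0) 0 else tp / sum(pos)
  list(precision = p, recall = r,
       f1 = if (p + r == 0) 0 else 2 * p * r / (p + r))
}

# Coerce labels to logical target indicator.
as_binary_labels <- function(labels, positive = NULL) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels) && all(labels %in% c(0, 1, NA))) return(labels == 1)
  if (is.null(positive))
    stop("`positive` must name the target class for non-binary labels",
         call. = FALSE)
  as.character(labels) == positive
}
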