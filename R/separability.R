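# Jeffries-Matusita class separability, optimal time-window selection and
# the combinatorial composite-index search.

#' Per-class sample statistics
#'
#' Computes, for each class, the sample mean vector and the unbiased
#' (n - 1 denominator) covariance matrix of the feature columns — the
#' ingredients of the Gaussian Bhattacharyya/Jeffries-Matusita statistics.
#'
#' @param data Data frame with one row per sample: one label column and one
#'   or more numeric feature columns.
#' @param label Name of the label column (default `"label"`).
#' @return A tibble with one row per class: `class`, `n`, `mu` (list of
#'   named mean vectors), `sigma` (list of covariance matrices), and
#'   `degenerate` (`TRUE` when the covariance is singular, e.g. constant
#'   samples).
#' @export
#' @examples
#' d <- data.frame(label = c("a", "a"), x = c(0, 1))
#' class_stats(d)  # mu 0.5, sigma 0.5
class_stats <- function(data, label = "label") {
  data <- as.data.frame(data)
  stopifnot(label %in% names(data))
  feat <- setdiff(names(data)[vapply(data, is.numeric, logical(1))], label)
  if (!length(feat)) stop("no numeric feature columns", call. = FALSE)
  cls <- unique(as.character(data[[label]]))
  rows <- lapply(cls, function(cl) {
    x <- as.matrix(data[data[[label]] == cl, feat, drop = FALSE])
    x <- x[stats::complete.cases(x), , drop = FALSE]
    if (nrow(x) < 2)
      stop("class '", cl, "' has fewer than 2 complete samples", call. = FALSE)
    mu <- colMeans(x)
    sg <- stats::cov(x)
    tibble::tibble(class = cl, n = nrow(x), mu = list(mu),
                   sigma = list(sg),
                   degenerate = det(as.matrix(sg)) <= 0)
  })
  dplyr::bind_rows(rows)
}

# Accepts a list(mu=, sigma=), or a one-row slice of class_stats() output,
# and returns list(mu = numeric vector, sigma = matrix).
as_class_stats <- function(a) {
  if (is.data.frame(a)) a <- list(mu = a$mu[[1]], sigma = a$sigma[[1]])
  mu <- as.numeric(a$mu)
  sigma <- a$sigma
  if (!is.matrix(sigma)) sigma <- diag(as.numeric(sigma), nrow = length(mu))
  stopifnot(nrow(sigma) == length(mu), ncol(sigma) == length(mu))
  list(mu = mu, sigma = sigma)
}

#' Bhattacharyya distance between two Gaussian class distributions
#'
#' \deqn{B = \frac18 (\mu_j-\mu_k)^T \left[\frac{\Sigma_j+\Sigma_k}{2}\right]^{-1}
#'   (\mu_j-\mu_k) + \frac12 \ln \frac{\left|\frac{\Sigma_j+\Sigma_k}{2}\right|}
#'   {\sqrt{|\Sigma_j||\Sigma_k|}}}
#'
#' `B >= 0`, with `B = 0` exactly when mean and covariance coincide. A small
#' ridge is added to every covariance diagonal before inversion so that
#' degenerate (constant-sample) classes behave continuously: two identical
#' constant classes give `B = 0`, constant-but-different classes saturate.
#'
#' @param a,b Class statistics: a `list(mu =, sigma =)` (scalar `sigma` is
#'   taken as a variance in 1-D) or a one-row slice of [class_stats()]
#'   output.
#' @param ridge Diagonal regularization added to each covariance
#'   (default `1e-10`).
#' @return Nonnegative scalar.
#' @export
#' @examples
#' bhattacharyya(list(mu = 0, sigma = 1), list(mu = 1, sigma = 1))  # 0.125
bhattacharyya <- function(a, b, ridge = 1e-10) {
  a <- as_class_stats(a); b <- as_class_stats(b)
  stopifnot(length(a$mu) == length(b$mu))
  p <- length(a$mu)
  sa <- a$sigma + diag(ridge, p)
  sb <- b$sigma + diag(ridge, p)
  sp <- (sa + sb) / 2
  ld <- function(m) {
    d <- determinant(m, logarithm = TRUE)
    if (d$sign <= 0) stop("covariance not positive definite", call. = FALSE)
    as.numeric(d$modulus)
  }
  d <- a$mu - b$mu
  mahal <- tryCatch(drop(crossprod(d, solve(sp, d))),
                    error = function(e)
                      stop("pooled covariance is singular", call. = FALSE))
  as.numeric(mahal / 8 + 0.5 * (ld(sp) - 0.5 * (ld(sa) + ld(sb))))
}

#' Jeffries-Matusita distance
#'
#' `JM = 2 * (1 - exp(-B))` with `B` the Gaussian Bhattacharyya distance:
#' a separability statistic in `[0, 2]`, 0 for identical class
#' distributions, saturating towards 2 as classes become perfectly
#' separable.
#'
#' @inheritParams bhattacharyya
#' @return Scalar in `[0, 2]`.
#' @export
#' @examples
#' jm_distance(list(mu = 0, sigma = 1), list(mu = 1, sigma = 1))  # 0.2350
jm_distance <- function(a, b, ridge = 1e-10) {
  jm_from_bhattacharyya(bhattacharyya(a, b, ridge = ridge))
}

#' @rdname jm_distance
#' @param B Bhattacharyya distance(s).
#' @export
jm_from_bhattacharyya <- function(B) 2 * (1 - exp(-B))

#' Feature-by-period separability matrix
#'
#' For every feature and compositing period, computes the univariate
#' Jeffries-Matusita distance between the two classes of `class_pair` from
#' the feature values at the labeled sample pixels. Cells where either class
#' has fewer than two finite values (or the statistics degenerate) are
#' masked (`NA`) and counted.
#'
#' @param series A `composite_series` (see [median_composite()]).
#' @param samples Tibble `(x, y, label, ...)` in the series CRS.
#' @param features Character vector of registry feature names and/or band
#'   symbols (e.g. `c("B6", "B11", "EVI", "NSII")`).
#' @param class_pair Length-2 character: the two labels to separate.
#' @param registry Feature registry, see [index_registry()].
#' @return A tibble of class `"separability_matrix"` with columns `feature`,
#'   `period`, `start`, `end`, `mid_doy`, `jm`; the class pair is stored in
#'   the `class_pair` attribute.
#' @export
separability_matrix <- function(series, samples,
                                features = c("B6", "B11", "EVI", "NSII"),
                                class_pair = c("soybean", "corn"),
                                registry = index_registry()) {
  stopifnot(length(class_pair) == 2)
  samples <- samples[samples$label %in% class_pair, ]
  if (!all(class_pair %in% samples$label))
    stop("samples must contain both classes: ",
         paste(class_pair, collapse = ", "), call. = FALSE)
  px <- coord_to_pixel(series$geo, samples$x, samples$y)
  ptab <- series_periods(series)
  masked <- 0L
  rows <- purrr::map_dfr(features, function(f) {
    fr <- compute_feature(series, f, registry = registry)
    purrr::map_dfr(seq_len(nrow(ptab)), function(p) {
      v <- fr$values[, , p][cbind(px$row, px$col)]
      jm <- jm_cell(v, samples$label, class_pair)
      if (is.na(jm)) masked <<- masked + 1L
      tibble::tibble(feature = f, period = ptab$period[p],
                     start = ptab$start[p], end = ptab$end[p],
                     mid_doy = ptab$mid_doy[p], jm = jm)
    })
  })
  if (masked > 0)
    message(masked, " separability cell(s) masked (degenerate statistics)")
  rows$feature <- factor(rows$feature, levels = features)
  structure(rows, class = c("separability_matrix", class(rows)),
            class_pair = class_pair, n_masked = masked)
}

# Univariate JM for one feature/period cell; NA on degeneracy.
jm_cell <- function(v, labels, class_pair) {
  va <- v[labels == class_pair[1]]; va <- va[is.finite(va)]
  vb <- v[labels == class_pair[2]]; vb <- vb[is.finite(vb)]
  if (length(va) < 2 || length(vb) < 2) return(NA_real_)
  tryCatch(
    jm_distance(list(mu = mean(va), sigma = stats::var(va)),
                list(mu = mean(vb), sigma = stats::var(vb))),
    error = function(e) NA_real_
  )
}

#' Select the optimal contiguous time window
#'
#' Scans every contiguous run of periods (length between `min_len` and
#' `max_len`) and returns the one maximizing the mean Jeffries-Matusita
#' distance over the chosen features — the phenological window where the
#' crops are most separable. Ties are broken by earliest start, then
#' shortest length.
#'
#' @param sep A [separability_matrix()].
#' @param features Subset of features to average over (default: all in
#'   `sep`).
#' @param min_len,max_len Window length bounds in periods.
#' @return A list of class `"time_window"`: `start_period`, `end_period`
#'   (inclusive period indices), `start`, `end` (dates), `start_doy`,
#'   `end_doy`, `mean_jm`, `features`.
#' @export
select_optimal_window <- function(sep, features = NULL,
                                  min_len = 1L, max_len = NULL) {
  if (!is.null(features)) sep <- sep[sep$feature %in% features, ]
  if (nrow(sep) == 0) stop("empty separability matrix", call. = FALSE)
  wide <- tidyr::pivot_wider(
    tibble::as_tibble(sep)[, c("feature", "period", "jm")],
    names_from = "period", values_from = "jm")
  m <- as.matrix(wide[, -1, drop = FALSE])
  periods <- as.integer(colnames(m))
  np <- length(periods)
  if (all(is.na(m))) stop("all separability cells are masked", call. = FALSE)
  if (is.null(max_len)) max_len <- np
  min_len <- max(1L, as.integer(min_len))
  max_len <- min(np, as.integer(max_len))

  best <- NULL
  for (s in seq_len(np)) {
    if (s + min_len - 1L > np) next
    for (e in seq(s + min_len - 1L, min(np, s + max_len - 1L))) {
      cells <- m[, s:e]
      if (all(is.na(cells))) next
      score <- mean(cells, na.rm = TRUE)
      better <- is.null(best) || score > best$score + 1e-12 ||
        (abs(score - best$score) <= 1e-12 &&
           (s < best$s || (s == best$s && e - s < best$e - best$s)))
      if (better) best <- list(s = s, e = e, score = score)
    }
  }
  ptab <- unique(tibble::as_tibble(sep)[, c("period", "start", "end", "mid_doy")])
  ptab <- ptab[order(ptab$period), ]
  pi_s <- match(periods[best$s], ptab$period)
  pi_e <- match(periods[best$e], ptab$period)
  structure(list(
    start_period = periods[best$s], end_period = periods[best$e],
    start = ptab$start[pi_s], end = ptab$end[pi_e],
    start_doy = as.numeric(format(ptab$start[pi_s], "%j")),
    end_doy = as.numeric(format(ptab$end[pi_e], "%j")),
    mean_jm = best$score,
    features = as.character(unique(sep$feature))
  ), class = "time_window")
}

#' @export
print.time_window <- function(x, ...) {
  cat("<time_window> periods ", x$start_period, "..", x$end_period,
      " (", as.character(x$start), " .. ", as.character(x$end),
      ", DOY ", x$start_doy, "-", x$end_doy, "), mean J-M ",
      round(x$mean_jm, 3), "\n", sep = "")
  invisible(x)
}

#' Combinatorial search for the best composite index
#'
#' Enumerates arithmetic combinations of the selected base features — every
#' expression using each base feature exactly once, combined with the
#' operators in `ops`, optionally wrapped in a reciprocal or cube-root
#' transform — and ranks them by the mean univariate Jeffries-Matusita
#' distance between the class pair inside the time window. Algebraically
#' identical templates (e.g. `a*b` vs `b*a`) are deduplicated by numeric
#' fingerprint on fixed probe points; candidates that are singular on all
#' samples are dropped.
#'
#' @param series A `composite_series`.
#' @param samples Labeled sample tibble `(x, y, label)`.
#' @param window A `time_window` or integer period indices to score within.
#' @param base_features Named character vector mapping display names to
#'   registry features/bands, e.g.
#'   `c(RE2 = "B6", SWIR1 = "B11", EVI = "EVI")`. 2 or 3 features.
#' @param class_pair Length-2 character labels.
#' @param ops Binary operators to combine with (subset of `+ - * /`).
#' @param outer Outer transforms applied to each combination: subset of
#'   `"identity"`, `"cbrt"`, `"reciprocal"`.
#' @param registry Feature registry.
#' @return Tibble of class `"index_search"`: `rank`, `expression`,
#'   `mean_jm`, `n_periods`, sorted by descending `mean_jm` (ties broken by
#'   expression string, so the ordering is deterministic).
#' @export
search_index_combinations <- function(series, samples, window,
                                      base_features = c(RE2 = "B6",
                                                        SWIR1 = "B11",
                                                        EVI = "EVI"),
                                      class_pair = c("soybean", "corn"),
                                      ops = c("+", "-", "*", "/"),
                                      outer = c("identity", "cbrt",
                                                "reciprocal"),
                                      registry = index_registry()) {
  stopifnot(length(base_features) %in% 2:3)
  ops <- match.arg(ops, c("+", "-", "*", "/"), several.ok = TRUE)
  outer <- match.arg(outer, c("identity", "cbrt", "reciprocal"),
                     several.ok = TRUE)
  nm <- names(base_features)
  if (is.null(nm) || any(nm == "")) nm <- unname(base_features)

  samples <- samples[samples$label %in% class_pair, ]
  px <- coord_to_pixel(series$geo, samples$x, samples$y)
  idx <- window_indices(window, series_periods(series))
  # per-sample, per-period value matrix for each base feature
  vals <- lapply(seq_along(base_features), function(i) {
    fr <- compute_feature(series, unname(base_features[i]),
                          periods = idx, registry = registry)
    sapply(seq_along(idx), function(k)
      fr$values[, , k][cbind(px$row, px$col)])
  })
  names(vals) <- nm

  templates <- enumerate_templates(nm, ops)
  cand <- unlist(lapply(templates, function(tpl)
    vapply(outer, function(o) switch(o,
      identity   = tpl,
      cbrt       = paste0("cbrt(", tpl, ")"),
      reciprocal = paste0("1 / (", tpl, ")")), character(1))))
  cand <- dedup_expressions(cand, nm)

  scores <- vapply(cand, function(ex) {
    f <- function(k) {
      env <- list2env(stats::setNames(
        lapply(vals, function(v) v[, k]), nm), parent = baseenv())
      assign("cbrt", cbrt, envir = env)
      v <- eval(str2lang(ex), env)
      v[!is.finite(v)] <- NA_real_
      v
    }
    jms <- vapply(seq_along(idx), function(k)
      jm_cell(f(k), samples$label, class_pair), numeric(1))
    if (all(is.na(jms))) NA_real_ else mean(jms, na.rm = TRUE)
  }, numeric(1))

  keep <- !is.na(scores)
  if (any(!keep))
    message(sum(!keep), " candidate expression(s) dropped (singular on all samples)")
  out <- tibble::tibble(expression = cand[keep], mean_jm = scores[keep],
                        n_periods = length(idx))
  out <- out[order(-out$mean_jm, out$expression), ]
  out$rank <- seq_len(nrow(out))
  out <- out[, c("rank", "expression", "mean_jm", "n_periods")]
  structure(out, class = c("index_search", class(out)),
            class_pair = class_pair)
}

# All parenthesized binary-operator expressions using each variable once.
enumerate_templates <- function(vars, ops) {
  if (length(vars) == 2) {
    combos <- expand.grid(a = vars, b = vars, op = ops,
                          stringsAsFactors = FALSE)
    combos <- combos[combos$a != combos$b, ]
    return(sprintf("%s %s %s", combos$a, combos$op, combos$b))
  }
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  out <- character(0)
  for (p in perms) {
    v <- vars[p]
    for (o1 in ops) for (o2 in ops) {
      out <- c(out,
               sprintf("(%s %s %s) %s %s", v[1], o1, v[2], o2, v[3]),
               sprintf("%s %s (%s %s %s)", v[1], o1, v[2], o2, v[3]))
    }
  }
  unique(out)
}

# Numeric-fingerprint deduplication on fixed positive probe points; keeps
# the first (shortest, then lexicographically first) representative.
dedup_expressions <- function(exprs, vars) {
  probes <- matrix(c(0.31, 0.17, 0.53,
                     0.72, 0.41, 0.11,
                     0.13, 0.87, 0.29,
                     0.55, 0.23, 0.67,
                     0.91, 0.37, 0.47), ncol = 3, byrow = TRUE)
  fp <- vapply(exprs, function(ex) {
    v <- vapply(seq_len(nrow(probes)), function(i) {
      env <- list2env(stats::setNames(as.list(probes[i, seq_along(vars)]),
                                      vars), parent = baseenv())
      assign("cbrt", cbrt, envir = env)
      out <- tryCatch(eval(str2lang(ex), env), error = function(e) NaN)
      if (!is.finite(out)) NaN else out
    }, numeric(1))
    paste(signif(v, 10), collapse = "|")
  }, character(1))
  o <- order(nchar(exprs), exprs)
  exprs_sorted <- exprs[o]; fp_sorted <- fp[o]
  exprs_sorted[!duplicated(fp_sorted)]
}
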