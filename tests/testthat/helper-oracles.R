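# Independent reference implementations used as test oracles. These are
# deliberately written as plain scalar arithmetic / explicit loops, separate
# from the package's vectorised or expression-parsing code paths.

# Scalar per-pixel index formulas, one hand-written function per registry
# entry. b is a named list of band values.
oracle_index_funs <- list(
  NDVI = function(b) (b$B8 - b$B4) / (b$B8 + b$B4),
  NDre1 = function(b) (b$B6 - b$B5) / (b$B6 + b$B5),
  NDre2 = function(b) (b$B7 - b$B5) / (b$B7 + b$B5),
  LSWI = function(b) (b$B8 - b$B11) / (b$B8 + b$B11),
  SAVI = function(b) 1.5 * (b$B8 - b$B4) / (b$B8 + b$B4 + 0.5),
  NDWI = function(b) (b$B3 - b$B8) / (b$B3 + b$B8),
  PSRI = function(b) (b$B4 - b$B3) / b$B6,
  NDVIre1 = function(b) (b$B8 - b$B5) / (b$B8 + b$B5),
  NDVIre2 = function(b) (b$B8 - b$B6) / (b$B8 + b$B6),
  IRECI = function(b) (b$B8 - b$B4) / (b$B5 / b$B6),
  CIre = function(b) b$B8 / b$B5 - 1,
  RVI = function(b) b$B8 / b$B4,
  WDRVI = function(b) (0.1 * b$B8 - b$B4) / (0.1 * b$B8 + b$B4),
  NLI = function(b) (b$B8^2 - b$B4) / (b$B8^2 + b$B4),
  MNLI = function(b) (b$B8^2 - b$B4) * 1.5 / (b$B8^2 + b$B4 + 0.5),
  OSAVI = function(b) (b$B8 - b$B4) / (b$B8 + b$B4 + 0.16),
  EVI = function(b) 2.5 * (b$B8 - b$B4) / (b$B8 + 6 * b$B4 - 7.5 * b$B2 + 1),
  DVI = function(b) b$B8 - b$B4,
  BSI = function(b) ((b$B11 + b$B4) - (b$B8 + b$B2)) /
    ((b$B11 + b$B4) + (b$B8 + b$B2)),
  WRI = function(b) ((b$B8 - b$B3) / (b$B8 + b$B3)) * (b$B2 / (b$B3 + b$B4)),
  RVI_green = function(b) b$B8 / b$B3,
  SR_red_green = function(b) b$B4 / b$B3,
  VARI_green = function(b) (b$B3 - b$B4) / (b$B3 + b$B4 - b$B2),
  TVI = function(b) 0.5 * (120 * (b$B8 - b$B3) - 200 * (b$B4 - b$B3)),
  MTCI = function(b) (b$B6 - b$B5) / (b$B5 - b$B4),
  MNDVI = function(b) (b$B3 - b$B11) / (b$B3 + b$B11),
  MSAVI = function(b) (2 * b$B8 + 1 - sqrt((2 * b$B8 + 1)^2 -
                                             8 * (b$B8 - b$B4))) / 2,
  MSRre = function(b) (b$B8 / b$B5 - 1) / sqrt(b$B8 / b$B5 + 1),
  MSRren = function(b) (b$B8A / b$B5 - 1) / sqrt(b$B8A / b$B5 + 1),
  RDVI = function(b) (b$B8 - b$B4) / sqrt(b$B8 + b$B4),
  SR = function(b) b$B8 / b$B4,
  REP = function(b) 705 + 35 * (0.5 * (b$B4 + b$B7) - b$B5) / (b$B6 - b$B5),
  NBR = function(b) (b$B8 - b$B12) / (b$B8 + b$B12),
  GWCCI = function(b) b$B11 * (b$B8 - b$B4) / (b$B8 + b$B4),
  GCVI = function(b) b$B8 / b$B3 - 1,
  SMCI = function(b) {
    evi_v <- 2.5 * (b$B8 - b$B4) / (b$B8 + 6 * b$B4 - 7.5 * b$B2 + 1)
    gcvi_v <- b$B8 / b$B3 - 1
    (b$B11 + b$B8 + b$B8A + b$B7 + b$B6) * evi_v * gcvi_v
  },
  NSII = function(b) {
    evi_v <- 2.5 * (b$B8 - b$B4) / (b$B8 + 6 * b$B4 - 7.5 * b$B2 + 1)
    p <- b$B6 * b$B11 * evi_v
    sign(p) * abs(p)^(1 / 3)
  }
)

# Sort-based median with the even-count midpoint convention.
oracle_median <- function(x) {
  x <- sort(unname(x[!is.na(x)]))
  n <- length(x)
  if (n == 0) return(NA_real_)
  if (n %% 2 == 1) x[(n + 1) / 2] else (x[n / 2] + x[n / 2 + 1]) / 2
}

# Piecewise-linear interpolation with nearest-valid edge extension,
# written as explicit interval arithmetic.
oracle_fill <- function(x, y) {
  ok <- which(!is.na(y))
  if (length(ok) == 0) return(y)
  out <- y
  for (i in seq_along(y)) {
    if (!is.na(y[i])) next
    lower <- ok[ok < i]; upper <- ok[ok > i]
    if (!length(lower)) {
      out[i] <- y[upper[1]]
    } else if (!length(upper)) {
      out[i] <- y[lower[length(lower)]]
    } else {
      i0 <- lower[length(lower)]; i1 <- upper[1]
      w <- (x[i] - x[i0]) / (x[i1] - x[i0])
      out[i] <- y[i0] * (1 - w) + y[i1] * w
    }
  }
  out
}

# Closed-form 1-D Gaussian Bhattacharyya distance.
oracle_bhattacharyya_1d <- function(mu1, var1, mu2, var2) {
  vbar <- (var1 + var2) / 2
  (mu1 - mu2)^2 / (8 * vbar) + 0.5 * log(vbar / sqrt(var1 * var2))
}

# Four-branch loop confusion counting.
oracle_confusion <- function(pred, ref) {
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_along(pred)) {
    if (is.na(pred[i]) || is.na(ref[i])) next
    if (pred[i] && ref[i]) tp <- tp + 1L
    else if (pred[i] && !ref[i]) fp <- fp + 1L
    else if (!pred[i] && ref[i]) fn <- fn + 1L
    else tn <- tn + 1L
  }
  list(tp = tp, fp = fp, fn = fn, tn = tn)
}

# Textbook mean/covariance by explicit sums (n - 1 denominator).
oracle_cov <- function(x) {
  n <- nrow(x)
  mu <- colSums(x) / n
  s <- matrix(0, ncol(x), ncol(x))
  for (i in seq_len(n)) s <- s + tcrossprod(x[i, ] - mu)
  list(mu = mu, sigma = s / (n - 1))
}

random_pixel_bands <- function() {
  as.list(stats::setNames(runif(length(S2_BANDS), 0.01, 0.6), S2_BANDS))
}
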