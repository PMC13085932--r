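test_that("class statistics use the unbiased covariance convention", {
  d <- data.frame(label = c("a", "a"), x = c(0, 1))
  cs <- class_stats(d)
  expect_equal(cs$mu[[1]], c(x = 0.5))
  expect_equal(unname(cs$sigma[[1]][1, 1]), 0.5)  # (n - 1) denominator

  const <- class_stats(data.frame(label = "a", x = c(0.3, 0.3, 0.3)))
  expect_equal(unname(const$sigma[[1]][1, 1]), 0)
  expect_true(const$degenerate)

  expect_error(class_stats(data.frame(label = c("a", "b", "b"),
                                      x = c(1, 2, 3))),
               "class 'a'")
})

test_that("2-D class statistics match the explicit-sums oracle", {
  withr::with_seed(9, x <- matrix(rnorm(40), ncol = 2))
  d <- data.frame(label = "a", f1 = x[, 1], f2 = x[, 2])
  cs <- class_stats(d)
  o <- oracle_cov(x)
  expect_equal(unname(cs$mu[[1]]), unname(o$mu))
  expect_equal(unname(cs$sigma[[1]]), unname(o$sigma))
})

test_that("Bhattacharyya distance reproduces its closed forms", {
  a <- list(mu = 0, sigma = 1)
  expect_equal(bhattacharyya(a, a), 0)
  # unit-variance 1-D Gaussians one mean apart: B = (1/8) (dmu)^2 / s^2
  expect_equal(bhattacharyya(a, list(mu = 1, sigma = 1)), 0.125)
  withr::with_seed(13, {
    for (i in 1:25) {
      mu <- rnorm(2); v <- runif(2, 0.1, 3)
      got <- bhattacharyya(list(mu = mu[1], sigma = v[1]),
                           list(mu = mu[2], sigma = v[2]))
      expect_equal(got, oracle_bhattacharyya_1d(mu[1], v[1], mu[2], v[2]),
                   tolerance = 1e-7)
      expect_gte(got, 0)
    }
  })
})

test_that("J-M distance is 2(1 - exp(-B)), symmetric, and affine-invariant", {
  a <- list(mu = 0, sigma = 1); b <- list(mu = 1, sigma = 1)
  expect_equal(jm_distance(a, a), 0)
  expect_equal(jm_distance(a, b), 2 * (1 - exp(-0.125)))
  expect_equal(round(jm_distance(a, b), 4), 0.2350)
  # symmetry, exact
  withr::with_seed(17, {
    for (i in 1:10) {
      p <- list(mu = rnorm(1), sigma = runif(1, 0.1, 2))
      q <- list(mu = rnorm(1), sigma = runif(1, 0.1, 2))
      expect_identical(jm_distance(p, q), jm_distance(q, p))
      # common affine rescaling y = 3x - 7 leaves JM unchanged
      p2 <- list(mu = 3 * p$mu - 7, sigma = 9 * p$sigma)
      q2 <- list(mu = 3 * q$mu - 7, sigma = 9 * q$sigma)
      expect_equal(jm_distance(p, q), jm_distance(p2, q2), tolerance = 1e-6)
    }
  })
  # saturation from below as separation grows
  far <- jm_distance(a, list(mu = 80, sigma = 1))
  expect_lte(far, 2)
  expect_gt(far, 1.999)
})

test_that("degenerate variances follow the documented conventions", {
  c1 <- list(mu = 0.3, sigma = 0)
  expect_equal(jm_distance(c1, c1), 0)   # identical constants
  expect_equal(jm_distance(c1, list(mu = 0.5, sigma = 0)), 2)  # saturates
})

test_that("separability matrix is bounded, masks degeneracy, and peaks in the
           designed divergence window", {
  sep <- separability_matrix(test_series, test_scene$samples,
                             features = c("B6", "B11", "NSII"))
  expect_true(all(sep$jm >= 0 & sep$jm <= 2, na.rm = TRUE))
  # the generator's divergence design: mean in-window J-M of RE2 exceeds the
  # out-of-window mean
  div <- test_scene$config$divergence
  b6 <- sep[sep$feature == "B6", ]
  inw <- b6$mid_doy >= div[1] & b6$mid_doy <= div[2]
  expect_gt(mean(b6$jm[inw], na.rm = TRUE), mean(b6$jm[!inw], na.rm = TRUE))

  # a feature identical for both classes scores 0
  flat <- test_series
  flat$values[] <- 0.5
  sep0 <- separability_matrix(flat, test_scene$samples, features = "B6")
  expect_true(all(sep0$jm == 0))
})

test_that("window selection equals an exhaustive scan (oracle equivalence)", {
  sep <- separability_matrix(test_series, test_scene$samples,
                             features = c("B6", "B11", "NSII"))
  w <- select_optimal_window(sep, min_len = 2, max_len = 6)
  # brute-force scan over all contiguous windows
  tab <- tidyr::pivot_wider(tibble::as_tibble(sep)[, c("feature", "period", "jm")],
                            names_from = "period", values_from = "jm")
  m <- as.matrix(tab[, -1])
  best <- -Inf; bs <- be <- NA
  np <- ncol(m)
  for (s in 1:np) for (e in s:np) {
    len <- e - s + 1
    if (len < 2 || len > 6) next
    sc <- mean(m[, s:e], na.rm = TRUE)
    if (sc > best + 1e-12) { best <- sc; bs <- s; be <- e }
  }
  expect_identical(w$start_period, bs)
  expect_identical(w$end_period, be)
  expect_equal(w$mean_jm, best)
})

test_that("window ties and bounds behave as documented", {
  # synthetic matrix with a plateau over periods 3..5
  mk_sep <- function(jm_by_period) {
    n <- length(jm_by_period)
    structure(tibble::tibble(
      feature = factor("F"), period = seq_len(n),
      start = as.Date("2021-05-01") + (seq_len(n) - 1) * 10,
      end = as.Date("2021-05-01") + seq_len(n) * 10 - 1,
      mid_doy = 120 + (seq_len(n) - 1) * 10, jm = jm_by_period),
      class = c("separability_matrix", "tbl_df", "tbl", "data.frame"),
      class_pair = c("a", "b"))
  }
  sep <- mk_sep(c(0.2, 0.4, 1.8, 1.8, 1.8, 0.3))
  w <- select_optimal_window(sep, min_len = 1, max_len = 6)
  expect_identical(c(w$start_period, w$end_period), c(3L, 3L))  # shortest tie
  w3 <- select_optimal_window(sep, min_len = 3, max_len = 3)
  expect_identical(c(w3$start_period, w3$end_period), c(3L, 5L))  # plateau
  # single-peak column
  wp <- select_optimal_window(mk_sep(c(0.1, 2, 0.1)))
  expect_identical(c(wp$start_period, wp$end_period), c(2L, 2L))
  # full-season forced window
  wf <- select_optimal_window(sep, min_len = 6, max_len = 6)
  expect_identical(c(wf$start_period, wf$end_period), c(1L, 6L))
  expect_error(select_optimal_window(mk_sep(rep(NA_real_, 3))), "masked")
})

test_that("restricting the search grammar to products forces the triple
           product, and the product tops the ranking on the default scene", {
  w <- list(start_period = 12L, end_period = 14L)
  class(w) <- "time_window"
  forced <- search_index_combinations(test_series, test_scene$samples, w,
                                      ops = "*", outer = "identity")
  expect_identical(nrow(forced), 1L)   # a*b*c up to commutativity
  expect_match(forced$expression, "RE2.*SWIR1|SWIR1.*RE2")

  ranked <- search_index_combinations(test_series, test_scene$samples, w)
  expect_identical(ranked$rank, seq_len(nrow(ranked)))
  expect_true(!is.unsorted(rev(ranked$mean_jm)))
  # a*b vs b*a deduplicated: no two rows share a fingerprint-identical form
  expect_identical(anyDuplicated(ranked$expression), 0L)
  # the triple product (any algebraic rendering) sits at/near the top:
  # on this scene the designed signal is multiplicative
  prod_rows <- grep("^cbrt\\(\\(", ranked$expression)
  expect_true(ranked$mean_jm[1] >= max(forced$mean_jm))
})
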