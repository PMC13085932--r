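test_that("sample splitting honours spacing and stratified 7:3 counts", {
  # 10 m grid of points, 30 m spacing requested
  g <- expand.grid(x = seq(5, 95, 10), y = seq(5, 95, 10))
  pts <- tibble::tibble(x = g$x, y = g$y,
                        label = rep(c("soybean", "corn"), length.out = 100),
                        role = "unassigned")
  sp <- split_samples(pts, seed = 4, min_distance = 30)
  d <- as.matrix(stats::dist(sp[, c("x", "y")]))
  diag(d) <- Inf
  expect_gte(min(d), 30)

  # 10 + 10 well-spaced points split 7/3 per class
  pts2 <- tibble::tibble(x = rep(seq(0, 900, 100), 2),
                         y = rep(c(0, 500), each = 10),
                         label = rep(c("soybean", "corn"), each = 10),
                         role = "unassigned")
  sp2 <- split_samples(pts2, seed = 1, min_distance = 30)
  tab <- table(sp2$label, sp2$role)
  expect_true(all(tab[, "threshold"] == 7))
  expect_true(all(tab[, "validation"] == 3))
})

test_that("splitting is deterministic in the seed", {
  s <- test_scene$samples
  a <- split_samples(s, seed = 11)
  b <- split_samples(s, seed = 11)
  c <- split_samples(s, seed = 12)
  expect_identical(a, b)
  expect_false(identical(a$role, c$role))
})

test_that("thinning that empties a class is an error", {
  pts <- tibble::tibble(x = c(0, 5, 10), y = 0,
                        label = c("soybean", "corn", "soybean"),
                        role = "unassigned")
  # corn's only point sits 5 m from a soybean point: with 30 m spacing one
  # of the two classes can survive only in some orders; force the failure
  expect_error(
    split_samples(tibble::tibble(x = c(0, 1), y = 0,
                                 label = c("soybean", "corn"),
                                 role = "unassigned"),
                  seed = 1, min_distance = 30),
    "removed every sample")
})

test_that("separable classes reach F1 = 1 in both direction modes", {
  v <- c(0.8, 0.9, 0.1, 0.2)
  lab <- c(TRUE, TRUE, FALSE, FALSE)
  for (mode in c("consistent", "as_printed")) {
    r <- iterative_threshold(v, lab, direction_mode = mode)
    expect_equal(r$f1, 1, info = mode)
    expect_gt(r$threshold, 0.2)
    expect_lte(r$threshold, 0.8)
  }
})

test_that("degenerate and invalid threshold inputs are handled", {
  r <- iterative_threshold(rep(0.4, 6), c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_true(r$degenerate)
  expect_equal(r$threshold, 0.4)
  expect_equal(r$recall, 1)  # >= rule puts everything in the target class
  expect_error(iterative_threshold(1:5, rep(TRUE, 5)), "both classes")
})

test_that("the trace never falls below its first accepted iterate", {
  withr::with_seed(23, {
    for (i in 1:10) {
      v <- rnorm(100)
      lab <- runif(100) < stats::plogis(v)
      r <- iterative_threshold(v, lab)
      acc <- r$trace[r$trace$accepted, ]
      expect_gte(r$f1, acc$f1[1])
      expect_gte(r$f1, max(acc$f1) - 1e-12)  # returns best accepted
    }
  })
})

test_that("iterative search lands within 0.05 of the grid oracle", {
  withr::with_seed(41, {
    for (i in 1:15) {
      n <- 200
      p <- runif(1, 0.25, 0.75)
      lab <- runif(n) < p
      mu <- runif(1, 0.5, 3)
      v <- rnorm(n, ifelse(lab, mu, 0), runif(1, 0.5, 1.5))
      it <- iterative_threshold(v, lab)
      gr <- grid_threshold_oracle(v, lab)
      expect_lte(abs(it$f1 - gr$f1), 0.05)
    }
  })
})

test_that("grid oracle: separable data scores 1; label-independent data
           approaches the all-positive baseline 2p/(1+p)", {
  gr <- grid_threshold_oracle(c(1, 2, 3, 10, 11, 12),
                              c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))
  expect_equal(gr$f1, 1)
  withr::with_seed(57, {
    n <- 4000
    v <- runif(n)
    lab <- runif(n) < 0.4
  })
  gr2 <- grid_threshold_oracle(v, lab, n_cuts = 200)
  p <- mean(lab)
  expect_equal(gr2$f1, 2 * p / (1 + p), tolerance = 0.03)
  # internal consistency: the oracle's F1 equals the metrics module's at T
  m <- metrics(confusion(v >= gr2$threshold, lab))
  expect_equal(m$f1, gr2$f1)
})

test_that("recall is non-increasing and precision non-decreasing in T on a
           fixed sample (direction logic premise)", {
  withr::with_seed(61, {
    v <- rnorm(300)
    lab <- runif(300) < stats::plogis(2 * v)
  })
  ts <- seq(min(v), max(v), length.out = 50)
  ms <- lapply(ts, function(t) metrics(confusion(v >= t, lab)))
  rec <- vapply(ms, `[[`, numeric(1), "recall")
  expect_true(all(diff(rec) <= 1e-12))
})

test_that("classification respects the >= rule, nodata, and monotone
           transforms of the feature", {
  m <- matrix(c(0.1, 0.5, NA, 0.9), 2, 2)
  expect_true(all(unclass(classify(m, 0))[!is.na(m)] == 1L))
  expect_true(all(unclass(classify(m, 2))[!is.na(m)] == 0L))
  expect_true(is.na(unclass(classify(m, 0.5))[1, 2]))
  expect_identical(unclass(classify(m, 0.5))[2, 1], 1L)  # boundary: target
  # cube-root transform with cube-rooted threshold gives the identical map
  withr::with_seed(71, x <- matrix(runif(100, 0.01, 1), 10, 10))
  t0 <- 0.3
  expect_equal(unclass(classify(x, t0)), unclass(classify(cbrt(x), cbrt(t0))),
               ignore_attr = TRUE)
})
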