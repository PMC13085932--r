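test_that("EVI matches direct arithmetic and masks its singularity", {
  expect_equal(evi(0.5, 0.5, 0.1), 0)              # zero numerator
  expect_equal(evi(0.5, 0.1, 0.05), 1.0 / 1.725)   # 0.5797
  # denominator NIR + 6 Red - 7.5 Blue + 1 = 0
  expect_true(is.na(evi(0.5, 0.1, (0.5 + 0.6 + 1) / 7.5)))
})

test_that("NSII follows the cube-root convention with a product variant", {
  expect_equal(nsii(1, 1, 1), 1)
  expect_equal(nsii(0.4, 0.2, 0), 0)
  expect_equal(nsii(0.30, 0.22, 0.60), (0.30 * 0.22 * 0.60)^(1 / 3))
  expect_equal(round(nsii(0.30, 0.22, 0.60), 4), 0.3409)
  expect_equal(nsii(0.30, 0.22, 0.60, form = "product"),
               0.30 * 0.22 * 0.60^3)
  # sign-preserving for negative EVI (water/soil pixels)
  expect_lt(nsii(0.3, 0.2, -0.5), 0)
})

test_that("registry lookups return the expected formulas and tags", {
  reg <- index_registry()
  expect_identical(reg$formula[reg$name == "NDVI"], "(B8 - B4) / (B8 + B4)")
  expect_identical(reg$formula[reg$name == "LSWI"], "(B8 - B11) / (B8 + B11)")
  expect_setequal(reg$required_bands[reg$name == "SMCI"][[1]],
                  c("B2", "B3", "B4", "B6", "B7", "B8", "B8A", "B11"))
  # degenerate printed forms are stored canonically and flagged
  expect_identical(unique(reg$fidelity[reg$name %in%
    c("WDRVI", "MSRre", "MSRren", "RDVI", "MSAVI")]), "canonical_corrected")
  expect_error(compute_feature(test_series, "NOPE"), "unknown feature")
})

test_that("compute_feature agrees with the scalar per-pixel oracle", {
  # random-pixel composite covering all ten bands, one period
  withr::with_seed(101, {
    d <- c(6, 6, length(S2_BANDS), 2)
    vals <- array(runif(prod(d), 0.01, 0.6), d)
  })
  st <- reflectance_stack(vals, as.Date("2021-08-01") + c(0, 5), S2_BANDS)
  cs <- median_composite(st, c("2021-08-01", "2021-08-10"))
  reg <- index_registry()
  for (nm in reg$name) {
    fr <- compute_feature(cs, nm, registry = reg)
    oracle <- oracle_index_funs[[nm]]
    expect_false(is.null(oracle), info = nm)
    for (k in c(1L, 17L, 36L)) {
      ij <- arrayInd(k, c(6, 6))
      b <- as.list(stats::setNames(cs$values[ij[1], ij[2], , 1], S2_BANDS))
      expect_equal(fr$values[ij[1], ij[2], 1], oracle(b),
                   tolerance = 1e-12, info = nm)
    }
  }
})

test_that("GWCCI and SMCI compose sub-features correctly", {
  # constructed pixel: B11 = 0.2 and NDVI = 0.5 (B8 = 0.3, B4 = 0.1)
  d <- array(0, c(1, 1, length(S2_BANDS), 1))
  b <- stats::setNames(seq_along(S2_BANDS), S2_BANDS)
  d[1, 1, b["B8"], 1] <- 0.3; d[1, 1, b["B4"], 1] <- 0.1
  d[1, 1, b["B11"], 1] <- 0.2; d[1, 1, b["B2"], 1] <- 0.04
  d[1, 1, b["B3"], 1] <- 0.06; d[1, 1, b["B6"], 1] <- 0.25
  d[1, 1, b["B7"], 1] <- 0.28; d[1, 1, b["B8A"], 1] <- 0.31
  st <- reflectance_stack(d, as.Date("2021-08-01"), S2_BANDS)
  gw <- compute_feature(st, "GWCCI")
  expect_equal(gw$values[1, 1, 1], 0.2 * 0.5)  # B11 x NDVI = 0.10
  sm <- compute_feature(st, "SMCI")
  evi_v <- evi(0.3, 0.1, 0.04)
  gcvi_v <- gcvi(0.3, 0.06)
  expect_equal(sm$values[1, 1, 1],
               (0.2 + 0.3 + 0.31 + 0.28 + 0.25) * evi_v * gcvi_v)
})

test_that("normalized-difference indices stay within [-1, 1]", {
  reg <- index_registry()
  nd <- reg$name[reg$bounded_pm1]
  expect_gt(length(nd), 8)
  withr::with_seed(55, {
    d <- c(8, 8, length(S2_BANDS), 1)
    vals <- array(runif(prod(d), 0, 1), d)
  })
  st <- reflectance_stack(vals, as.Date("2021-08-01"), S2_BANDS)
  for (nm in nd) {
    v <- compute_feature(st, nm)$values
    expect_true(all(abs(v) <= 1 + 1e-12, na.rm = TRUE), info = nm)
  }
})

test_that("mask propagates from any required band and from singularities", {
  d <- array(0.3, c(2, 2, length(S2_BANDS), 1))
  d[1, 1, match("B4", S2_BANDS), 1] <- NA
  st <- reflectance_stack(d, as.Date("2021-08-01"), S2_BANDS)
  v <- compute_feature(st, "NDVI")$values
  expect_true(is.na(v[1, 1, 1]))
  expect_false(anyNA(v[2, , 1]))
  # NDVI on a NIR = Red image is 0 everywhere, except B8 = B4 = 0 pixels
  d2 <- array(0.3, c(1, 2, length(S2_BANDS), 1))
  d2[1, 2, , 1] <- 0  # 0/0 singularity
  st2 <- reflectance_stack(d2, as.Date("2021-08-01"), S2_BANDS)
  v2 <- compute_feature(st2, "NDVI")$values
  expect_equal(v2[1, 1, 1], 0)
  expect_true(is.na(v2[1, 2, 1]))
  expect_error(compute_feature(make_stack(bands = "B4"), "NDVI"),
               "missing.*B8")
})

test_that("cube-root NSII is monotone in each argument, so thresholding is
           invariant to the cube-root vs raw-product rendering", {
  withr::with_seed(77, {
    re2 <- runif(200, 0.01, 0.5)
    sw <- runif(200, 0.01, 0.5)
    ev <- runif(200, 0.01, 1)
  })
  # monotone in each argument with the other two positive and fixed
  o <- order(re2)
  expect_true(all(diff(nsii(re2[o], 0.2, 0.5)) > 0))
  expect_true(all(diff(nsii(0.2, sw[sort.list(sw)], 0.5)) > 0))
  # the cube root is a monotone transform of the raw triple product, so the
  # two carry the same pixel ordering (the EVI-cubed variant re-weights EVI
  # and is a genuinely different index)
  expect_identical(order(nsii(re2, sw, ev)), order(re2 * sw * ev))
})
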