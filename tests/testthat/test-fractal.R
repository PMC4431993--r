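test_that("log-log fitting is exact on lines and rejects degenerate input", {
  x <- log(2^(1:6))
  pts <- cbind(log_scale = x, log_stat = -2 * x + 1)
  f <- fitLogLog(pts)
  expect_equal(f$slope, -2, tolerance = 1e-12)
  expect_equal(f$intercept, 1, tolerance = 1e-12)
  expect_equal(f$rSquared, 1, tolerance = 1e-12)

  expect_error(fitLogLog(pts[1:3, ]), "at least 4")
  dup <- pts
  dup[2, 1] <- dup[1, 1]
  expect_error(fitLogLog(dup, c(1, 6)), "duplicated")
})

test_that("auto range drops the top octave and zero statistics", {
  # scaling linear over five octaves, then the statistic dies to zero:
  # the zero points and the largest surviving octave are excluded
  scales <- 2^(1:8)
  stat <- c(scales[1:5]^-2, 0, 0, 0)
  pts <- cbind(log_scale = log(scales),
               log_stat = ifelse(stat > 0, log(stat), -Inf))
  f <- fitLogLog(pts, "auto")
  expect_equal(f$slope, -2, tolerance = 1e-9)
  expect_identical(f$used, 1:4)   # octave 2^5 is the largest usable scale
})

test_that("smooth surfaces are two-dimensional", {
  flat <- makeFixture("plane", 64, h0 = 3)
  for (m in c("cube_counting", "triangulation", "variation")) {
    e <- fractalDimension(flat, m)
    expect_identical(e@Df, 2)
    expect_match(e@warn, "degenerate")
  }
  expect_error(fractalDimension(flat, "variance"), "degenerate")
  expect_error(fractalDimension(flat, "structure_function"), "degenerate")

  ramp <- makeFixture("plane", 256, h0 = 0, slope = 0.5)
  expect_equal(fractalDimension(ramp, "triangulation")@Df, 2,
               tolerance = 1e-9)
  expect_equal(fractalDimension(ramp, "structure_function")@Df, 2,
               tolerance = 1e-6)
  # within-box variance of a ramp is g^2 (l^2 - 1) / 12, so the slope
  # carries a small discrete correction at the finest octaves
  expect_equal(fractalDimension(ramp, "variance")@Df, 2, tolerance = 0.06)
})

test_that("white noise drives increment-based estimators towards 3", {
  wn <- randomMap(256, seed = 31, mean = 0, sd = 5)
  expect_gte(fractalDimension(wn, "variance")@Df, 2.8)
  expect_gte(fractalDimension(wn, "structure_function")@Df, 2.8)
})

test_that("height rescaling leaves scale-free estimators untouched", {
  hm <- generateFbmSurface(sceneSpec(sizePx = 256, hurst = 0.4, seed = 17))
  big <- hm
  big@heights <- big@heights * 1000
  for (m in c("cube_counting", "triangulation", "variance",
              "structure_function", "variation")) {
    expect_equal(fractalDimension(big, m)@Df, fractalDimension(hm, m)@Df,
                 tolerance = 1e-9)
  }
  # the power spectrum shifts only its intercept
  e1 <- fractalDimension(hm, "power_spectrum")
  e2 <- fractalDimension(big, "power_spectrum")
  expect_equal(e2@Df, e1@Df, tolerance = 1e-9)
  expect_gt(e2@intercept, e1@intercept)
})

test_that("estimates decrease in the Hurst exponent for all six methods", {
  methods <- c("variance", "cube_counting", "triangulation",
               "power_spectrum", "structure_function", "variation")
  dfs <- sapply(c(0.2, 0.5, 0.8), function(H) {
    rowMeans(sapply(1:3, function(s) {
      hm <- generateFbmSurface(sceneSpec(sizePx = 256, hurst = H, seed = s))
      vapply(methods, function(m) fractalDimension(hm, m)@Df, numeric(1))
    }))
  })
  for (i in seq_along(methods)) {
    expect_gt(dfs[i, 1], dfs[i, 2])
    expect_gt(dfs[i, 2], dfs[i, 3])
  }
})

test_that("out-of-range estimates are flagged, never clamped", {
  # a surface with spectral decay steeper than any self-affine law
  # (P ~ f^-6) pushes the power spectrum estimator below 2
  set.seed(2)
  n <- 128
  k <- c(0:(n / 2), -(n / 2 - 1):-1)
  amp <- outer(k^2, k^2, "+")^(-1.5)
  amp[1, 1] <- 0
  z <- Re(fft(amp * complex(real = matrix(rnorm(n^2), n, n),
                            imaginary = matrix(rnorm(n^2), n, n)),
              inverse = TRUE))
  e <- fractalDimension(HeightMap(z * (10 / sd(z)), 2), "power_spectrum")
  expect_lt(e@Df, 2)
  expect_match(e@warn, "outside")
})

test_that("spline resampling is exact on linear fields and mild on fBm", {
  hm <- randomMap(32, seed = 5)
  expect_identical(bsplineResample(hm, 1), hm)

  ramp <- makeFixture("plane", 32, h0 = 2, slope = 0.25)
  up <- bsplineResample(ramp, 2)
  expect_equal(dim(up), c(64, 64))
  expect_equal(unname(pixelSize(up)), c(0.5, 0.5))
  # interior of the upsampled ramp is still the same linear field
  zi <- heights(up)[5:60, 5:60]
  expect_equal(max(abs(diff(t(zi))) - 0.125), 0, tolerance = 1e-9)

  # resampling shifts estimates only mildly (smoothing below the original
  # pixel scale)
  shift <- rowMeans(sapply(1:5, function(s) {
    hm <- generateFbmSurface(sceneSpec(sizePx = 128, hurst = 0.5, seed = s))
    vapply(c("variance", "triangulation", "structure_function"), function(m)
      fractalDimension(hm, m, bsplineFactor = 2)@Df -
        fractalDimension(hm, m)@Df, numeric(1))
  }))
  expect_lt(max(abs(shift)), 0.35)
})

test_that("non-square pixels and tiny maps are rejected", {
  bad <- HeightMap(matrix(rnorm(512), 16, 32), c(1, 2))
  expect_error(fractalDimension(bad, "variance"), "square pixels")
  tiny <- randomMap(8, seed = 1)
  expect_error(fractalDimension(tiny, "variance"), "at least 16")
})
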