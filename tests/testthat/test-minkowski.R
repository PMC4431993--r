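test_that("step fixture has exact half-plane functionals", {
  st <- makeFixture("step", 512, h0 = 0, h1 = 100)
  mk <- minkowskiCurves(st, 256)
  i50 <- which.min(abs(mk@thresholds - 50))
  expect_equal(mk@V[i50], 0.5)
  expect_equal(mk@S[i50], 512 / 512^2)   # one column of boundary pairs
  expect_identical(mk@chi[i50], 0)       # one white vs one black half-plane

  lm <- connectivityLandmarks(mk)
  expect_false(lm$chiDefined)
  expect_true(is.na(lm$chiMin))
})

test_that("disk fields count their components exactly", {
  n <- 256
  dk <- makeFixture("disk_field", n, k = 5, r = 10, h0 = 0, h1 = 100)
  mk <- minkowskiCurves(dk, 101)
  i50 <- which.min(abs(mk@thresholds - 50))
  area <- sum(heights(dk) == 100)
  expect_equal(mk@V[i50], area / n^2)
  expect_identical(unname(mk@counts[i50, "c_white"]), 5L)
  expect_identical(unname(mk@counts[i50, "c_black"]), 1L)
  expect_equal(mk@chi[i50], 4 / n^2)
  expect_gt(connectivityLandmarks(mk)$chiMax, 0)
  expect_lt(connectivityLandmarks(mk)$chiMax, 100)

  # inverted: pits in a plateau flip the sign (complement duality away
  # from the border)
  pit <- makeFixture("disk_field", n, k = 5, r = 10, h0 = 100, h1 = 0)
  mkp <- minkowskiCurves(pit, 101)
  expect_equal(mkp@chi[i50], -4 / n^2)
})

test_that("checkerboard is one diagonal net against isolated black pixels", {
  n <- 32
  cb <- makeFixture("checkerboard", n, h0 = 0, h1 = 10)
  o <- minkowskiOracle(heights(cb), 5)
  expect_equal(o$cWhite, 1L)              # 8-connected white net
  expect_equal(o$cBlack, n^2 / 2, ignore_attr = TRUE)
  mk <- minkowskiCurves(cb, 11)
  i <- which.min(abs(mk@thresholds - 5))
  expect_equal(mk@chi[i], (1 - n^2 / 2) / n^2)
})

test_that("curves match the flood-fill oracle on random binary images", {
  for (s in 1:15) {
    set.seed(s)
    z <- matrix(rbinom(32 * 32, 1, runif(1, 0.2, 0.8)) * 100, 32, 32)
    if (min(z) == max(z)) z[1, 1] <- 50
    hm <- HeightMap(z, 1)
    mk <- minkowskiCurves(hm, 5)
    for (i in seq_along(mk@thresholds)) {
      o <- minkowskiOracle(z, mk@thresholds[i])
      expect_identical(unname(mk@counts[i, ]),
                       c(o$nWhite, o$nPairs, o$cWhite, o$cBlack))
    }
  }
})

test_that("volume curves are monotone with exact endpoints", {
  for (s in 1:8) {
    hm <- randomMap(48, seed = s)
    mk <- minkowskiCurves(hm, 64)
    expect_identical(mk@V[1], 1)                      # all heights >= Zmin
    expect_true(all(diff(mk@V) <= 0))
    expect_equal(mean(heights(hm) >= max(heights(hm)) + 1e-9), 0)
    expect_identical(mk@S[1], 0)
    # at the top threshold only the isolated maxima remain white
    expect_lte(mk@S[length(mk@S)], 8 / mk@nPixels)
    expect_lte(abs(mk@chi[1]), 1 / mk@nPixels)
    expect_lte(abs(mk@chi[length(mk@chi)]), 2 / mk@nPixels)
  }
})

test_that("constant surfaces give the documented degenerate curves", {
  mk <- minkowskiCurves(HeightMap(matrix(4, 16, 16), 1), 8)
  expect_true(all(mk@V == 1))
  expect_true(all(mk@S == 0))
  expect_true(all(mk@chi == 1 / 256))
})

test_that("landmarks locate the V = 0.5 crossing of symmetric surfaces", {
  hm <- randomMap(256, seed = 12, mean = 40, sd = 8)
  mk <- minkowskiCurves(hm, 256)
  lm <- connectivityLandmarks(mk)
  step <- diff(mk@thresholds)[1]
  expect_lt(abs(lm$vHalf - mean(heights(hm))), 2 * step)
  expect_true(lm$chiDefined)
})

test_that("point-symmetric volume curves score 1, skewed scenes score lower", {
  ramp <- makeFixture("plane", 128, h0 = 0, slope = 1)
  expect_gte(volumeSymmetryScore(minkowskiCurves(ramp, 256)), 0.98)

  gauss <- randomMap(256, seed = 5, mean = 50, sd = 10)
  expect_gte(volumeSymmetryScore(minkowskiCurves(gauss, 256)), 0.95)

  # heavy one-sided deposition skews V against the bare background
  bare <- generateFbmSurface(sceneSpec(seed = 2))
  heavy <- depositParticles(bare, particleFieldSpec(count = 120,
                                                    radiusMean = 80,
                                                    radiusSd = 20,
                                                    heightScale = 0.8),
                            seed = 2)
  expect_lt(volumeSymmetryScore(minkowskiCurves(heavy, 128)),
            volumeSymmetryScore(minkowskiCurves(bare, 128)))
})
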