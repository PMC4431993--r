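test_that("fBm synthesis enforces normalization and determinism", {
  spec <- sceneSpec(sizePx = 256, hurst = 0.5, rmsTarget = 10, seed = 1)
  hm <- generateFbmSurface(spec)
  z <- heights(hm)
  expect_equal(sqrt(mean((z - mean(z))^2)), 10, tolerance = 1e-12)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_identical(z, heights(generateFbmSurface(spec)))
  hm2 <- generateFbmSurface(sceneSpec(sizePx = 256, hurst = 0.5,
                                      rmsTarget = 10, seed = 2))
  expect_gt(max(abs(z - heights(hm2))), 1)
})

test_that("scene parameters are validated", {
  expect_error(sceneSpec(hurst = 1.2), "hurst")
  expect_error(sceneSpec(sizePx = 100), "power of two")
  expect_error(particleFieldSpec(heightScale = 0), "heightScale")
})

test_that("generated backgrounds carry the target fractal dimension", {
  # D = 3 - H ground truth, triangulation estimator (full-strength check
  # over 10 seeds lives in the acceptance suite)
  df <- mean(sapply(1:3, function(s) {
    hm <- generateFbmSurface(sceneSpec(sizePx = 512, hurst = 0.5,
                                       rmsTarget = 10, seed = s))
    fractalDimension(hm, "triangulation")@Df
  }))
  expect_lt(abs(df - 2.5), 0.15)
})

test_that("particle deposition is a pointwise maximum", {
  base <- generateFbmSurface(sceneSpec(sizePx = 128, seed = 4))
  expect_identical(
    heights(depositParticles(base, particleFieldSpec(count = 0), seed = 1)),
    heights(base))
  dep <- depositParticles(base, particleFieldSpec(count = 40), seed = 1)
  expect_true(all(heights(dep) >= heights(base)))
  # sub-seeded draws: growing the count never perturbs earlier particles
  dep20 <- depositParticles(base, particleFieldSpec(count = 20), seed = 1)
  expect_true(all(heights(dep) - heights(dep20) >= -1e-12))
  touched20 <- heights(dep20) > heights(base)
  expect_true(all((heights(dep) >= heights(dep20))[touched20]))
})

test_that("a single cap on a plane has closed-form geometry", {
  base <- HeightMap(matrix(0, 512, 512), 1)
  pf <- particleFieldSpec(count = 1, radiusMean = 50, radiusSd = 0,
                          heightScale = 0.6)
  dep <- depositParticles(base, pf, seed = 3)
  z <- heights(dep)
  expect_equal(max(z), 30, tolerance = 0.05)      # apex = 0.6 * 50
  r <- roughnessReport(dep)
  # Rmph = apex - Zbar up to the sub-pixel apex sampling offset
  expect_equal(r@values[["Rmph"]], 30 - r@values[["Zbar"]], tolerance = 1e-3)
  expect_gt(r@values[["Rmph"]], 29)
  # the cap's footprint radius is respected
  expect_equal(sum(z > 0), sum(z > 0 & z <= 30))
  expect_lt(sum(z > 0), pi * 51^2)
})

test_that("deposition raises mean and rms height of zero-referenced scenes", {
  for (s in 1:3) {
    bare <- generateFbmSurface(sceneSpec(seed = s, sizePx = 256))
    dep <- depositParticles(bare, particleFieldSpec(count = 15), seed = s)
    rb <- roughnessReport(zeroRef(bare))
    rd <- roughnessReport(zeroRef(dep))
    expect_gt(rd@values[["Zbar"]], rb@values[["Zbar"]])
    expect_gt(rd@values[["Rq"]], rb@values[["Rq"]])
  }
})

test_that("fixtures have their defining exact properties", {
  pl <- makeFixture("plane", 64, h0 = 5)
  r <- roughnessReport(pl)
  expect_identical(r@values[["Rq"]], 0)
  expect_identical(r@values[["Ra"]], 0)
  expect_identical(r@values[["Zbar"]], 5)

  st <- makeFixture("step", 512, h0 = 0, h1 = 100)
  mk <- minkowskiCurves(st, 256)
  expect_equal(mk@V[which.min(abs(mk@thresholds - 50))], 0.5)

  dk <- makeFixture("disk_field", 256, k = 3, r = 10, h0 = 0, h1 = 100)
  for (th in c(10, 50, 90))
    expect_identical(countComponents(heights(dk) >= th, 8), 3L)
  expect_error(makeFixture("disk_field", 64, k = 9, r = 15), "disjoint")

  cb <- makeFixture("checkerboard", 16, h0 = 0, h1 = 1)
  expect_identical(sum(heights(cb)), 128)
})

test_that("scene specs serialize to key=value files and back", {
  spec <- sceneSpec(sizePx = 128, pixelSize = 3.5, hurst = 0.62,
                    rmsTarget = 12.5, seed = 42,
                    particles = particleFieldSpec(count = 17, placement = "clustered"))
  f <- withr::local_tempfile(fileext = ".cfg")
  writeSceneSpec(spec, f)
  back <- readSceneSpec(f)
  expect_equal(back@hurst, spec@hurst)
  expect_equal(back@rmsTarget, spec@rmsTarget)
  expect_identical(back@seed, spec@seed)
  expect_identical(back@particles@count, 17L)
  expect_identical(back@particles@placement, "clustered")
  expect_identical(heights(generateScene(back)), heights(generateScene(spec)))
})

test_that("default particle scenes keep the height PDF unimodal", {
  # mean, median and mode agree within the unimodality tolerance and the
  # smoothed density is single-peaked in at least 8 of 10 seeds
  hits <- 0
  for (s in 1:10) {
    dep <- zeroRef(generateScene(sceneSpec(particles = particleFieldSpec(),
                                           seed = s)))
    u <- unimodalityCheck(heightPDF(dep), roughnessReport(dep))
    hits <- hits + u$unimodal
  }
  expect_gte(hits, 8)
})
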