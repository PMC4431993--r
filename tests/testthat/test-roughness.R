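test_that("the printed-formula values hold on a hand-computed example", {
  hm <- HeightMap(matrix(c(1, 2, 3, 4), 2, 2), 10)
  r <- roughnessReport(hm)
  v <- r@values
  expect_equal(v[["Zbar"]], 2.5)
  expect_equal(v[["Ra"]], 1.0)
  expect_equal(v[["Rq"]], sqrt(1.25))
  expect_equal(v[["Rt"]], 3)
  expect_equal(v[["Rmvd"]], 1.5)
  expect_equal(v[["Rmph"]], 1.5)
  expect_equal(v[["Zmedian"]], 2.5)
})

test_that("constant surfaces degrade gracefully", {
  # constant non-negative height, the zero-referenced AFM convention under
  # which Zbar coincides with the plain mean
  r <- roughnessReport(HeightMap(matrix(7, 8, 8), 1))
  expect_identical(r@values[["Ra"]], 0)
  expect_identical(r@values[["Rq"]], 0)
  expect_identical(r@values[["Rt"]], 0)
  expect_identical(r@values[["Zbar"]], 7)
  expect_true(all(c("RskAbs", "RkuAbs") %in% r@undefined))
  expect_true(is.na(r@values[["RskAbs"]]))

  p <- heightPDF(HeightMap(matrix(-7, 8, 8), 1))
  expect_length(p@density, 1)
  expect_equal(sum(p@density * diff(p@binEdges)), 1)
})

test_that("Gaussian surfaces recover their moments", {
  hm <- randomMap(512, seed = 99, mean = 50, sd = 10)
  v <- roughnessReport(hm)@values
  expect_equal(v[["Rq"]], 10, tolerance = 0.05)
  expect_equal(v[["RskSigned"]], 0, tolerance = 0.05)
  expect_equal(v[["RkuSigned"]], 3, tolerance = 0.1)
  expect_equal(v[["RkuAbs"]], 3, tolerance = 0.1)
  # absolute-moment skewness of a Gaussian: E|X|^3 / sigma^3 = 2 sqrt(2/pi)
  expect_equal(v[["RskAbs"]], 2 * sqrt(2 / pi), tolerance = 0.05)
})

test_that("statistics agree with the loop-based oracle", {
  for (s in 1:20) {
    hm <- randomMap(17, 23, seed = s, mean = runif(1, -20, 80),
                    sd = runif(1, 1, 30))
    v <- roughnessReport(hm)@values
    o <- roughnessOracle(heights(hm))
    for (k in c("Zbar", "Ra", "Rq", "Rt", "Rmvd", "Rmph", "RskAbs", "RkuAbs"))
      expect_equal(v[[k]], o[[k]], tolerance = 1e-12)
  }
})

test_that("order and translation invariants hold", {
  for (s in 1:10) {
    hm <- zeroRef(randomMap(32, seed = s))
    v <- roughnessReport(hm)@values
    expect_gte(v[["Rq"]], v[["Ra"]])
    expect_equal(v[["Rt"]], v[["Rmvd"]] + v[["Rmph"]], tolerance = 1e-10)
    shifted <- hm
    shifted@heights <- shifted@heights + 13
    vs <- roughnessReport(shifted)@values
    expect_equal(vs[["Zbar"]], v[["Zbar"]] + 13, tolerance = 1e-10)
    for (k in c("Ra", "Rq", "Rt", "RskAbs", "RkuAbs"))
      expect_equal(vs[[k]], v[[k]], tolerance = 1e-9)
  }
})

test_that("the height PDF is a normalized density consistent with the median", {
  hm <- randomMap(64, seed = 3)
  p <- heightPDF(hm, 40)
  expect_equal(sum(p@density * diff(p@binEdges)), 1, tolerance = 1e-12)
  # median recovered from the PDF within one bin of the sample median
  cum <- cumsum(p@density * diff(p@binEdges))
  i <- which(cum >= 0.5)[1]
  expect_lt(abs(p@binEdges[i + 1] - median(heights(hm))),
            diff(p@binEdges)[1] * 1.5)

  # near-flat distribution has near-flat density
  z <- matrix(seq(0, 100, length.out = 4096), 64, 64)
  pf <- heightPDF(HeightMap(z, 1), 10)
  expect_lt(max(abs(pf@density - 0.01)), 2e-4)
})

test_that("mode estimation uses bin centres with lowest-bin tie-break", {
  z <- matrix(c(rep(0, 6), rep(10, 6), 2, 3, 5, 7), 4, 4)
  # bins = 2 over [0, 10]: both bins hold 8 values; tie breaks low
  expect_equal(roughnessReport(HeightMap(z, 1), bins = 2)@values[["Zmode"]],
               2.5)
})

test_that("unimodality is detected for single-peaked surfaces only", {
  g <- randomMap(128, seed = 21, mean = 40, sd = 8)
  u <- unimodalityCheck(heightPDF(g), roughnessReport(g))
  expect_true(u$unimodal)
  expect_identical(u$nModes, 1L)

  st <- makeFixture("step", 64, h0 = 0, h1 = 100)
  us <- unimodalityCheck(heightPDF(st, 64), roughnessReport(st, 64))
  expect_false(us$unimodal)
  expect_gte(us$nModes, 2L)
})
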