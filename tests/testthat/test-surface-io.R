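test_that("ascii matrix files read back with calibration and metadata", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# label demo", "0 1", "2 3"), f)
  hm <- readHeightMap(f, "ascii_matrix", pixelSize = 10)
  expect_identical(heights(hm), matrix(c(0, 2, 1, 3), 2, 2))
  expect_equal(unname(pixelSize(hm)), c(10, 10))
  expect_equal(unname(scanExtent(hm)), c(20, 20))
  expect_identical(sampleLabel(hm), "demo")

  # calibration from width_nm/height_nm headers
  f2 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# width_nm 40", "# height_nm 20", "0 1", "2 3"), f2)
  hm2 <- readHeightMap(f2, "ascii_matrix")
  expect_equal(unname(pixelSize(hm2)), c(20, 10))

  expect_error(readHeightMap(f, "ascii_matrix"), "pixelSize")
})

test_that("malformed ascii input is rejected with located errors", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("0 1", "2 x3"), f)
  expect_error(readHeightMap(f, "ascii_matrix", pixelSize = 1),
               "row 2, col 2")
  writeLines(c("0 1 2", "3 4"), f)
  expect_error(readHeightMap(f, "ascii_matrix", pixelSize = 1), "ragged")
  writeLines(c("0 1", "2 NaN"), f)
  expect_error(readHeightMap(f, "ascii_matrix", pixelSize = 1), "non-finite")
})

test_that("shuffled XYZ triplets are regridded to the ascii-equivalent map", {
  f <- withr::local_tempfile(fileext = ".xyz")
  # 2x2 grid at 10 nm pitch, shuffled row order; row 1 of the image is the
  # top (largest y)
  writeLines(c("10 0 3", "0 10 0", "10 10 1", "0 0 2"), f)
  hm <- readHeightMap(f, "xyz")
  expect_identical(heights(hm), matrix(c(0, 2, 1, 3), 2, 2))
  expect_equal(unname(pixelSize(hm)), c(10, 10))

  # incomplete lattice
  writeLines(c("0 0 1", "10 0 2", "0 10 3"), f)
  expect_error(readHeightMap(f, "xyz"), "complete regular grid")
})

test_that("write/read round-trips hold at format precision", {
  for (d in list(c(2, 2), c(3, 5), c(512, 512))) {
    hm <- randomMap(d[1], d[2], seed = sum(d))
    fa <- withr::local_tempfile(fileext = ".txt")
    writeHeightMap(hm, fa, "ascii_matrix")
    back <- readHeightMap(fa, "ascii_matrix")
    expect_equal(unname(pixelSize(back)), unname(pixelSize(hm)),
                 tolerance = 1e-9)
    expect_lt(max(abs(heights(back) - heights(hm))), 1e-6)

    # tiff32 is exact for float32-representable heights
    hm32 <- hm
    hm32@heights <- matrix(
      readBin(writeBin(as.vector(hm@heights), raw(), size = 4),
              "numeric", size = 4, n = length(hm@heights)),
      d[1], d[2])
    ft <- withr::local_tempfile(fileext = ".tif")
    writeHeightMap(hm32, ft, "tiff32")
    back32 <- readHeightMap(ft, "tiff32")
    expect_identical(heights(back32), heights(hm32))
    expect_equal(unname(pixelSize(back32)), unname(pixelSize(hm32)),
                 tolerance = 1e-6)
  }
})

test_that("injected non-finite values are rejected on every path", {
  for (i in 1:5) {
    hm <- randomMap(8, 8, seed = i)
    z <- heights(hm)
    z[sample(length(z), 1)] <- NaN
    expect_error(HeightMap(z, 1), "non-finite")
    ft <- withr::local_tempfile(fileext = ".tif")
    bad <- hm
    bad@heights <- z      # bypass constructor validation
    .writeTiff32 <- getFromNamespace(".writeTiff32", "afmtexture")
    .writeTiff32(bad, ft)
    expect_error(readHeightMap(ft, "tiff32"), "non-finite")
  }
})

test_that("auto format detection picks by extension", {
  hm <- randomMap(4, 4, seed = 9)
  ft <- withr::local_tempfile(fileext = ".tif")
  writeHeightMap(hm, ft)
  expect_s4_class(readHeightMap(ft), "HeightMap")
  fa <- withr::local_tempfile(fileext = ".dat")
  writeHeightMap(hm, fa)
  expect_equal(heights(readHeightMap(fa)), heights(hm), tolerance = 1e-9)
})

test_that("HeightMap validity enforces the type invariants", {
  expect_error(HeightMap(matrix(1, 1, 5), 1), "2 x 2")
  expect_error(HeightMap(matrix(1, 4, 4), -2), "positive")
  m <- HeightMap(matrix(1:16, 4, 4), c(2, 3))
  expect_equal(unname(scanExtent(m)), c(4 * 2, 4 * 3))
})
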