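#' Construct a HeightMap
#'
#' @param heights numeric matrix of heights (nm); row 1 is the top of the
#'   image, heights are positive away from the substrate.
#' @param pixelSize pixel pitch in nm/px; either a single value for square
#'   pixels or `c(x, y)`.
#' @param label sample name.
#' @param meta named character vector of metadata.
#' @return a validated [HeightMap-class].
#' @export
#' @examples
#' HeightMap(matrix(rnorm(64), 8, 8), pixelSize = 3.9, label = "demo")
HeightMap <- function(heights, pixelSize, label = "", meta = character()) {
  if (!is.matrix(heights)) heights <- as.matrix(heights)
  storage.mode(heights) <- "double"
  pixelSize <- as.numeric(pixelSize)
  if (length(pixelSize) == 1L) pixelSize <- c(pixelSize, pixelSize)
  new("HeightMap", heights = heights, pixelSizeX = pixelSize[1L],
      pixelSizeY = pixelSize[2L], label = as.character(label)[1L],
      meta = meta)
}

#' Read a height map from file
#'
#' Supported formats:
#' \describe{
#'   \item{`ascii_matrix`}{whitespace-separated matrix of heights in nm,
#'     `.` decimal point, with optional `#`-prefixed header lines. The
#'     recognized header keys `width_nm`, `height_nm` (physical scan extent)
#'     and `label` are parsed into calibration/metadata; other keys are kept
#'     as metadata.}
#'   \item{`xyz`}{three numeric columns x, y, z in nm; the points must form
#'     a complete regular grid (any row order).}
#'   \item{`tiff32`}{single-channel 32-bit float TIFF; pixel pitch is taken
#'     from the resolution tags when present.}
#'   \item{`auto`}{by file extension (`.tif`/`.tiff` = tiff32, `.xyz` = xyz,
#'     otherwise ascii_matrix).}
#' }
#'
#' @param path input file.
#' @param format one of `"auto"`, `"ascii_matrix"`, `"xyz"`, `"tiff32"`.
#' @param pixelSize pixel pitch in nm/px; required when the file carries no
#'   calibration of its own.
#' @param label sample label; defaults to a header label or the file name.
#' @return a validated [HeightMap-class]; files containing non-finite values
#'   are rejected.
#' @seealso [writeHeightMap()]
#' @export
readHeightMap <- function(path,
                          format = c("auto", "ascii_matrix", "xyz", "tiff32"),
                          pixelSize = NULL, label = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) .stopf("file not found: %s", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, tif = , tiff = "tiff32", xyz = "xyz",
                     "ascii_matrix")
  }
  switch(format,
    ascii_matrix = .readAsciiMatrix(path, pixelSize, label),
    xyz = .readXYZ(path, label),
    tiff32 = .readTiff32(path, pixelSize, label)
  )
}

.parseHeader <- function(lines) {
  hdr <- grep("^\\s*#", lines, value = TRUE)
  meta <- character()
  for (h in hdr) {
    m <- regmatches(h, regexec("^\\s*#\\s*([A-Za-z0-9_.-]+)\\s*[:=]?\\s*(.*)$", h))[[1L]]
    if (length(m) == 3L && nzchar(m[2L])) meta[m[2L]] <- trimws(m[3L])
  }
  meta
}

.readAsciiMatrix <- function(path, pixelSize, label) {
  lines <- readLines(path, warn = FALSE)
  meta <- .parseHeader(lines)
  body <- lines[!grepl("^\\s*#", lines)]
  body <- body[nzchar(trimws(body))]
  if (!length(body)) .stopf("no data rows in %s", path)
  toks <- strsplit(trimws(body), "\\s+")
  ncols <- length(toks[[1L]])
  rows <- vector("list", length(toks))
  for (i in seq_along(toks)) {
    if (length(toks[[i]]) != ncols)
      .stopf("ragged rows: row %d has %d values, expected %d",
             i, length(toks[[i]]), ncols)
    v <- suppressWarnings(as.numeric(toks[[i]]))
    # NaN/Inf tokens parse as non-finite numbers and fail validation below;
    # only genuinely non-numeric tokens are parse errors
    bad <- is.na(v) & !(tolower(toks[[i]]) %in%
                          c("nan", "-nan", "na", "inf", "-inf", "+inf",
                            "infinity", "-infinity"))
    if (any(bad)) {
      j <- which(bad)[1L]
      .stopf("malformed numeric cell at row %d, col %d: '%s'",
             i, j, toks[[i]][j])
    }
    v[is.na(v)] <- NaN
    rows[[i]] <- v
  }
  h <- do.call(rbind, rows)
  nbad <- sum(!is.finite(h))
  if (nbad > 0L) .stopf("%d non-finite height value(s) in %s", nbad, path)
  px <- pixelSize
  if (is.null(px)) {
    wx <- suppressWarnings(as.numeric(meta["width_nm"]))
    wy <- suppressWarnings(as.numeric(meta["height_nm"]))
    if (is.finite(wx) && is.finite(wy)) px <- c(wx / ncol(h), wy / nrow(h))
  }
  if (is.null(px) || anyNA(px))
    .stopf("ascii_matrix file carries no calibration; supply pixelSize")
  lab <- label
  if (is.null(lab)) lab <- unname(meta["label"])
  if (is.na(lab) || is.null(lab)) lab <- basename(path)
  HeightMap(h, px, label = lab, meta = meta[setdiff(names(meta), "label")])
}

.readXYZ <- function(path, label) {
  d <- utils::read.table(path, comment.char = "#",
                         colClasses = "numeric",
                         col.names = c("x", "y", "z"))
  if (any(!is.finite(as.matrix(d))))
    .stopf("%d non-finite value(s) in %s", sum(!is.finite(as.matrix(d))), path)
  xs <- sort(unique(d$x))
  ys <- sort(unique(d$y))
  if (length(xs) < 2L || length(ys) < 2L)
    .stopf("XYZ data does not span a 2D grid")
  if (nrow(d) != length(xs) * length(ys))
    .stopf("XYZ points do not form a complete regular grid (%d points for a %d x %d lattice)",
           nrow(d), length(ys), length(xs))
  stepx <- diff(xs)
  stepy <- diff(ys)
  if (max(abs(stepx - stepx[1L])) > 1e-6 * stepx[1L] ||
      max(abs(stepy - stepy[1L])) > 1e-6 * stepy[1L])
    .stopf("XYZ lattice is not regular")
  ix <- match(d$x, xs)
  iy <- match(d$y, ys)
  if (anyDuplicated(cbind(ix, iy))) .stopf("duplicate XYZ lattice points")
  h <- matrix(NA_real_, length(ys), length(xs))
  # row 1 = top of image = largest y
  h[cbind(length(ys) + 1L - iy, ix)] <- d$z
  lab <- if (is.null(label)) basename(path) else label
  HeightMap(h, c(stepx[1L], stepy[1L]), label = lab)
}

.readTiff32 <- function(path, pixelSize, label) {
  img <- tiff::readTIFF(path, as.is = FALSE, info = TRUE)
  if (length(dim(img)) == 3L) {
    if (dim(img)[3L] != 1L) .stopf("multi-channel TIFF not supported")
    img <- img[, , 1L]
  }
  at <- attributes(img)
  px <- pixelSize
  if (is.null(px) && !is.null(at$x.resolution) && !is.null(at$y.resolution) &&
      at$x.resolution > 0) {
    unit_nm <- switch(as.character(at$resolution.unit %||% "inch"),
                      cm = 1e7, inch = 2.54e7, 2.54e7)
    px <- c(unit_nm / at$x.resolution, unit_nm / at$y.resolution)
  }
  if (is.null(px))
    .stopf("TIFF carries no resolution tags; supply pixelSize")
  h <- matrix(as.numeric(img), nrow(img), ncol(img))
  nbad <- sum(!is.finite(h))
  if (nbad > 0L) .stopf("%d non-finite height value(s) in %s", nbad, path)
  lab <- if (is.null(label)) basename(path) else label
  HeightMap(h, px, label = lab)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a height map to file
#'
#' `ascii_matrix` emits `#`-prefixed header lines (`width_nm`, `height_nm`,
#' `label`, any metadata) followed by whitespace-separated rows of heights in
#' nm. `tiff32` writes an uncompressed single-strip 32-bit float TIFF with
#' the pixel pitch stored in the resolution tags (unit: cm); heights pass
#' through IEEE float32, so the round trip is exact for float32-representable
#' values.
#'
#' @param map a [HeightMap-class].
#' @param path output file.
#' @param format `"ascii_matrix"` or `"tiff32"` (`"auto"` picks by
#'   extension).
#' @return the path, invisibly.
#' @seealso [readHeightMap()]
#' @export
writeHeightMap <- function(map, path,
                           format = c("auto", "ascii_matrix", "tiff32")) {
  stopifnot(is(map, "HeightMap"))
  validObject(map)
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("tif", "tiff")) "tiff32" else "ascii_matrix"
  }
  switch(format,
    ascii_matrix = .writeAsciiMatrix(map, path),
    tiff32 = .writeTiff32(map, path)
  )
  invisible(path)
}

.writeAsciiMatrix <- function(map, path) {
  ext <- scanExtent(map)
  hdr <- c(
    sprintf("# width_nm %.10g", ext[["x"]]),
    sprintf("# height_nm %.10g", ext[["y"]]),
    sprintf("# label %s", map@label)
  )
  extra <- map@meta[setdiff(names(map@meta),
                            c("width_nm", "height_nm", "label"))]
  if (length(extra))
    hdr <- c(hdr, sprintf("# %s %s", names(extra), extra))
  body <- apply(map@heights, 1L, function(r)
    paste(format(r, digits = 15, trim = TRUE, scientific = FALSE),
          collapse = " "))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c(hdr, body), con)
}

# Minimal uncompressed little-endian single-strip TIFF, SampleFormat = IEEE
# float, 32 bits per sample, with X/YResolution in pixels per cm.
.writeTiff32 <- function(map, path) {
  h <- map@heights
  nr <- nrow(h)
  nc <- ncol(h)
  con <- tryCatch(file(path, "wb"), error = function(e)
    .stopf("cannot open '%s' for writing: %s", path, conditionMessage(e)))
  on.exit(close(con))
  u16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  u32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  entry <- function(tag, type, count, value) {
    u16(tag); u16(type); u32(count)
    if (type == 3L && count == 1L) { u16(value); u16(0L) } else u32(value)
  }
  ntags <- 13L
  ifd_off <- 8L
  ifd_size <- 2L + ntags * 12L + 4L
  res_off <- ifd_off + ifd_size        # two RATIONALs, 8 bytes each
  data_off <- res_off + 16L
  nbytes <- nr * nc * 4L

  writeChar("II", con, eos = NULL)     # little-endian magic
  u16(42L)
  u32(ifd_off)
  u16(ntags)                           # tags in ascending order
  entry(256L, 4L, 1L, nc)              # ImageWidth
  entry(257L, 4L, 1L, nr)              # ImageLength
  entry(258L, 3L, 1L, 32L)             # BitsPerSample
  entry(259L, 3L, 1L, 1L)              # Compression: none
  entry(262L, 3L, 1L, 1L)              # Photometric: BlackIsZero
  entry(273L, 4L, 1L, data_off)        # StripOffsets
  entry(277L, 3L, 1L, 1L)              # SamplesPerPixel
  entry(278L, 4L, 1L, nr)              # RowsPerStrip
  entry(279L, 4L, 1L, nbytes)          # StripByteCounts
  entry(282L, 5L, 1L, res_off)         # XResolution
  entry(283L, 5L, 1L, res_off + 8L)    # YResolution
  entry(296L, 3L, 1L, 3L)              # ResolutionUnit: cm
  entry(339L, 3L, 1L, 3L)              # SampleFormat: IEEE float
  u32(0L)                              # next IFD
  # px per cm as rationals scaled to keep 1e-6 relative precision
  for (p in c(map@pixelSizeX, map@pixelSizeY)) {
    den <- 1000L
    num <- round(1e7 / p * den)
    while (num > 2147483647) { den <- den %/% 10L; num <- round(1e7 / p * den) }
    u32(num); u32(den)
  }
  # sample data, row-major
  writeBin(as.numeric(t(h)), con, size = 4, endian = "little")
  invisible(path)
}
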