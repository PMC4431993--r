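#' Build a pyramidal tip model with a spherical apex
#'
#' The tip is the upper envelope of a sphere of radius `apexRadius` (the
#' apex cap) and a four-sided pyramid whose facets make `halfAngleDeg` with
#' the tip axis, rotated in-plane by `rotationDeg`. The envelope is sampled
#' on an `extentPx` x `extentPx` grid (odd side) at the pixel pitch of the
#' maps it will be applied to; the apex sits at the centre pixel with value
#' 0 and the body is non-positive. The defaults (12 nm apex, 45 degree
#' rotation) are the contact-tip model commonly used for surface-scan
#' reconstruction; the half-angle is a free parameter of the probe geometry.
#'
#' @param apexRadius apex radius of curvature (nm).
#' @param rotationDeg in-plane pyramid rotation (degrees).
#' @param halfAngleDeg sidewall half-angle between axis and facet (degrees).
#' @param pixelSize sampling pitch (nm/px), matching the target map.
#' @param extentPx odd grid side >= 3; must be wide enough to contain the
#'   spherical apex cap (lateral radius `apexRadius * sin(2 * halfAngle)`).
#' @return a validated [TipModel-class].
#' @seealso [dilateSurface()], [reconstructSurface()]
#' @export
#' @examples
#' tip <- buildTip(pixelSize = 2, extentPx = 15)
buildTip <- function(apexRadius = 12, rotationDeg = 45, halfAngleDeg = 17.5,
                     pixelSize, extentPx = 15L) {
  extentPx <- as.integer(extentPx)
  if (extentPx < 3L || extentPx %% 2L == 0L)
    .stopf("extentPx must be an odd integer >= 3")
  if (pixelSize <= 0) .stopf("pixelSize must be positive")
  theta <- halfAngleDeg * pi / 180
  # lateral distance at which the pyramid facet overtakes the sphere
  dCross <- apexRadius * sin(2 * theta)
  half <- (extentPx - 1L) / 2L * pixelSize
  if (half < dCross)
    .stopf("tip extent (%.3g nm half-width) too small for the %.3g nm spherical apex cap (needs %.3g nm)",
           half, apexRadius, dCross)
  ix <- seq.int(-(extentPx - 1L) / 2L, (extentPx - 1L) / 2L) * pixelSize
  x <- matrix(rep(ix, each = extentPx), extentPx, extentPx)   # col coord
  y <- matrix(rep(rev(ix), extentPx), extentPx, extentPx)     # row coord
  phi <- rotationDeg * pi / 180
  u <- cos(phi) * x + sin(phi) * y
  v <- -sin(phi) * x + cos(phi) * y
  pyr <- -pmax(abs(u), abs(v)) / tan(theta)
  d2 <- x^2 + y^2
  sph <- ifelse(d2 <= apexRadius^2,
                sqrt(pmax(apexRadius^2 - d2, 0)) - apexRadius, -Inf)
  tip <- pmax(sph, pyr)
  new("TipModel", shape = "pyramid", apexRadius = apexRadius,
      rotationDeg = rotationDeg, halfAngleDeg = halfAngleDeg,
      pixelSize = pixelSize, sampled = tip)
}

.checkTipCalibration <- function(map, tip) {
  px <- .requireSquarePixels(map)
  if (abs(px - tip@pixelSize) / px > 1e-6)
    .stopf("tip sampled at %.6g nm/px but map has %.6g nm/px",
           tip@pixelSize, px)
  invisible(px)
}

#' Forward tip imaging: grayscale dilation
#'
#' Models tip-surface convolution: the image the microscope records is the
#' grayscale morphological dilation of the true surface by the tip,
#' `out(x) = max_u [surface(x - u) + tip(u)]`. Borders are edge-replicated.
#'
#' @param trueSurface a [HeightMap-class].
#' @param tip a [TipModel-class] sampled at the surface's pixel size.
#' @return the imaged [HeightMap-class].
#' @seealso [reconstructSurface()], [buildTip()]
#' @export
dilateSurface <- function(trueSurface, tip) {
  stopifnot(is(trueSurface, "HeightMap"), is(tip, "TipModel"))
  .checkTipCalibration(trueSurface, tip)
  out <- trueSurface
  out@heights <- cpp_gray_dilate(trueSurface@heights, tip@sampled)
  out
}

#' Tip-compensated surface reconstruction: grayscale erosion
#'
#' Inverts the tip convolution as far as morphology allows: the
#' reconstruction is the grayscale erosion of the image by the reflected
#' tip, `rec(x) = min_u [image(x + u) - tip(u)]`. When the image is a
#' dilation of a true surface by the same tip, `rec >= true` pointwise with
#' equality wherever the certainty map is `TRUE` (pixels where the tip apex
#' was the unique touching point).
#'
#' @param image imaged [HeightMap-class].
#' @param tip the [TipModel-class] used (or assumed) for imaging.
#' @return a list with elements `surface` (reconstructed [HeightMap-class])
#'   and `certainty` (logical matrix).
#' @seealso [dilateSurface()]
#' @export
reconstructSurface <- function(image, tip) {
  stopifnot(is(image, "HeightMap"), is(tip, "TipModel"))
  .checkTipCalibration(image, tip)
  res <- cpp_gray_erode_certainty(image@heights, tip@sampled)
  out <- image
  out@heights <- res$reconstruction
  list(surface = out, certainty = res$certainty)
}
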