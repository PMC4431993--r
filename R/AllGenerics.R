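#' Accessors for HeightMap and friends
#'
#' `heights()` returns the raw height matrix (nm); `pixelSize()` the pixel
#' pitch `c(x = , y = )` in nm/px; `scanExtent()` the physical extent
#' `c(x = cols * pixelSizeX, y = rows * pixelSizeY)` in nm; `sampleLabel()`
#' the sample name; `metaData()` the free-form metadata.
#'
#' @param x a [HeightMap-class] (or, for `sampleLabel`, a report object).
#' @param value replacement value.
#' @return See the individual descriptions.
#' @name heightmap-accessors
#' @aliases heights pixelSize scanExtent sampleLabel metaData
#'
#' @examples
#' hm <- HeightMap(matrix(0:3, 2, 2), pixelSize = 10)
#' heights(hm)
#' pixelSize(hm)
#' scanExtent(hm)
NULL

#' @rdname heightmap-accessors
#' @export
setGeneric("heights", function(x) standardGeneric("heights"))

#' @rdname heightmap-accessors
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @rdname heightmap-accessors
#' @export
setGeneric("scanExtent", function(x) standardGeneric("scanExtent"))

#' @rdname heightmap-accessors
#' @export
setGeneric("sampleLabel", function(x) standardGeneric("sampleLabel"))

#' @rdname heightmap-accessors
#' @export
setGeneric("sampleLabel<-", function(x, value) standardGeneric("sampleLabel<-"))

#' @rdname heightmap-accessors
#' @export
setGeneric("metaData", function(x) standardGeneric("metaData"))

#' @describeIn heightmap-accessors the height matrix.
setMethod("heights", "HeightMap", function(x) x@heights)

#' @describeIn heightmap-accessors pixel pitch `c(x, y)` in nm/px.
setMethod("pixelSize", "HeightMap",
          function(x) c(x = x@pixelSizeX, y = x@pixelSizeY))

#' @describeIn heightmap-accessors physical extent `c(x, y)` in nm.
setMethod("scanExtent", "HeightMap", function(x)
  c(x = ncol(x@heights) * x@pixelSizeX, y = nrow(x@heights) * x@pixelSizeY))

#' @describeIn heightmap-accessors the sample label.
setMethod("sampleLabel", "HeightMap", function(x) x@label)

#' @describeIn heightmap-accessors replace the sample label.
setMethod("sampleLabel<-", "HeightMap", function(x, value) {
  x@label <- as.character(value)[1L]
  x
})

#' @describeIn heightmap-accessors the metadata vector.
setMethod("metaData", "HeightMap", function(x) x@meta)

#' @describeIn heightmap-accessors grid dimension `c(rows, cols)`.
#' @export
setMethod("dim", "HeightMap", function(x) dim(x@heights))

setMethod("show", "HeightMap", function(object) {
  d <- dim(object@heights)
  ext <- scanExtent(object)
  cat(sprintf(
    "HeightMap '%s': %d x %d px, %.4g x %.4g nm (%.4g nm/px)\n",
    object@label, d[1L], d[2L], ext["y"], ext["x"], object@pixelSizeX))
  r <- range(object@heights)
  cat(sprintf("  heights: [%.4g, %.4g] nm, mean %.4g nm\n",
              r[1L], r[2L], mean(object@heights)))
  invisible(NULL)
})

setMethod("show", "TipModel", function(object) {
  cat(sprintf(
    "TipModel (%s): apex %.3g nm, half-angle %.3g deg, rotation %.3g deg\n",
    object@shape, object@apexRadius, object@halfAngleDeg, object@rotationDeg))
  cat(sprintf("  sampled %d x %d px at %.4g nm/px, depth to %.4g nm\n",
              nrow(object@sampled), ncol(object@sampled), object@pixelSize,
              min(object@sampled)))
  invisible(NULL)
})

setMethod("show", "RoughnessReport", function(object) {
  cat(sprintf("RoughnessReport '%s' (N = %d)\n", object@label,
              object@nPoints))
  v <- object@values
  cat(sprintf(
    "  Zbar %.4g  Ra %.4g  Rq %.4g  Rt %.4g  Rmvd %.4g  Rmph %.4g (nm)\n",
    v["Zbar"], v["Ra"], v["Rq"], v["Rt"], v["Rmvd"], v["Rmph"]))
  cat(sprintf("  skew (abs/signed) %.4g / %.4g  kurt %.4g / %.4g\n",
              v["RskAbs"], v["RskSigned"], v["RkuAbs"], v["RkuSigned"]))
  if (length(object@undefined))
    cat("  undefined:", paste(object@undefined, collapse = ", "), "\n")
  invisible(NULL)
})

setMethod("show", "FractalEstimate", function(object) {
  cat(sprintf("FractalEstimate [%s]: Df = %.4f (slope %.4f, r^2 %.4f)\n",
              object@method, object@Df, object@slope, object@rSquared))
  cat(sprintf("  %d log-log points, %d in fit range\n",
              nrow(object@points), length(object@fitRange)))
  if (length(object@warn))
    cat("  warnings:", paste(object@warn, collapse = "; "), "\n")
  invisible(NULL)
})

setMethod("show", "MinkowskiCurves", function(object) {
  cat(sprintf(
    "MinkowskiCurves: %d thresholds over [%.4g, %.4g] nm (N = %d px)\n",
    length(object@thresholds), min(object@thresholds),
    max(object@thresholds), object@nPixels))
  cat(sprintf("  chi range [%.3g, %.3g] per px, max S %.3g per px\n",
              min(object@chi), max(object@chi), max(object@S)))
  invisible(NULL)
})

setMethod("show", "SceneSpec", function(object) {
  cat(sprintf(
    "SceneSpec: %d^2 px at %.4g nm/px, H = %.2f, Rq target %.4g nm, seed %d\n",
    object@sizePx, object@pixelSize, object@hurst, object@rmsTarget,
    object@seed))
  if (!is.null(object@particles)) {
    p <- object@particles
    cat(sprintf("  particles: %d caps, radius %.3g +/- %.3g nm, %s\n",
                p@count, p@radiusMean, p@radiusSd, p@placement))
  }
  invisible(NULL)
})

setMethod("show", "SampleReport", function(object) {
  cat(sprintf("SampleReport '%s'\n", object@label))
  if (!is.null(object@roughness)) {
    v <- object@roughness@values
    cat(sprintf("  roughness: Zbar %.4g, Ra %.4g, Rq %.4g nm\n",
                v["Zbar"], v["Ra"], v["Rq"]))
  }
  if (length(object@fractal)) {
    df <- vapply(object@fractal, function(e) e@Df, numeric(1))
    cat("  fractal Df:",
        paste(sprintf("%s %.3f", names(df), df), collapse = ", "), "\n")
  }
  if (!is.null(object@minkowski))
    cat(sprintf("  minkowski: %d thresholds\n",
                length(object@minkowski@thresholds)))
  if (length(object@skipped))
    cat("  skipped:", paste(names(object@skipped), collapse = ", "), "\n")
  invisible(NULL)
})
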