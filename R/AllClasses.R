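#' @import methods
NULL

#' HeightMap: a calibrated AFM height image
#'
#' The universal data object of the package: a rows x cols grid of surface
#' heights in nanometres together with the physical pixel pitch. Row 1 is the
#' top of the image and heights are positive away from the substrate.
#'
#' @slot heights numeric matrix of heights (nm); all values finite.
#' @slot pixelSizeX,pixelSizeY physical pixel pitch (nm per pixel), > 0.
#' @slot label free-text sample name.
#' @slot meta named character vector of free-form metadata.
#'
#' @seealso [readHeightMap()], [writeHeightMap()], [heights()], [pixelSize()]
#' @export
setClass("HeightMap",
  representation(
    heights = "matrix",
    pixelSizeX = "numeric",
    pixelSizeY = "numeric",
    label = "character",
    meta = "character"
  ),
  prototype(label = "", meta = character())
)

setValidity("HeightMap", function(object) {
  msg <- character()
  h <- object@heights
  if (!is.numeric(h)) msg <- c(msg, "heights must be a numeric matrix")
  if (nrow(h) < 2L || ncol(h) < 2L)
    msg <- c(msg, "height map must be at least 2 x 2")
  if (is.numeric(h) && any(!is.finite(h)))
    msg <- c(msg, sprintf("%d non-finite height value(s)", sum(!is.finite(h))))
  for (s in c("pixelSizeX", "pixelSizeY")) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v) || v <= 0)
      msg <- c(msg, sprintf("%s must be a single positive number", s))
  }
  if (length(object@label) != 1L) msg <- c(msg, "label must be a single string")
  if (length(msg)) msg else TRUE
})

#' TipModel: a sampled AFM tip shape
#'
#' Geometric model of the scanning tip used for morphological dilation and
#' erosion: the upper envelope of a spherical apex cap and a four-sided
#' pyramid, sampled on a grid at the pixel pitch of the target map. The apex
#' sits at the centre pixel with value 0 and the body is non-positive.
#'
#' @slot shape tip family; currently `"pyramid"`.
#' @slot apexRadius apex radius of curvature (nm).
#' @slot rotationDeg in-plane rotation of the pyramid (degrees).
#' @slot halfAngleDeg sidewall half-angle between axis and facet (degrees).
#' @slot pixelSize sampling pitch (nm per pixel).
#' @slot sampled tip height grid (nm, <= 0), odd side lengths.
#'
#' @seealso [buildTip()], [dilateSurface()], [reconstructSurface()]
#' @export
setClass("TipModel",
  representation(
    shape = "character",
    apexRadius = "numeric",
    rotationDeg = "numeric",
    halfAngleDeg = "numeric",
    pixelSize = "numeric",
    sampled = "matrix"
  )
)

setValidity("TipModel", function(object) {
  msg <- character()
  s <- object@sampled
  if (nrow(s) %% 2L == 0L || ncol(s) %% 2L == 0L)
    msg <- c(msg, "sampled tip grid must have odd side lengths")
  ctr <- s[(nrow(s) + 1L) %/% 2L, (ncol(s) + 1L) %/% 2L]
  if (!isTRUE(all.equal(ctr, 0)))
    msg <- c(msg, "tip apex (centre pixel) must be 0")
  if (any(s > 1e-12)) msg <- c(msg, "tip heights must be <= 0")
  if (object@pixelSize <= 0) msg <- c(msg, "pixelSize must be positive")
  if (length(msg)) msg else TRUE
})

#' RoughnessReport: amplitude statistics of a height map
#'
#' Holds the amplitude roughness parameters of a height map: mean absolute
#' height Zbar, plain mean, median Z1/2, mode Zmp, Ra, Rq, total range Rt,
#' maximum valley depth Rmvd, maximum peak height Rmph, and skewness/kurtosis
#' in two conventions (absolute-moment, as used in the AFM literature this
#' package follows, and conventional signed). All deviation statistics are
#' taken about Zbar = mean(|Z|), which equals the plain mean for
#' zero-referenced maps.
#'
#' @slot values named numeric vector of the statistics.
#' @slot nPoints number of samples N.
#' @slot undefined character vector naming statistics that are undefined
#'   (e.g. skewness/kurtosis when Rq = 0).
#' @slot label sample label carried over from the map.
#'
#' @seealso [roughnessReport()], [heightPDF()]
#' @export
setClass("RoughnessReport",
  representation(
    values = "numeric",
    nPoints = "integer",
    undefined = "character",
    label = "character"
  ),
  prototype(undefined = character(), label = "")
)

.roughnessFields <- c(
  "Zbar", "Zmean", "Zmedian", "Zmode", "Ra", "Rq", "Rt", "Rmvd", "Rmph",
  "RskAbs", "RkuAbs", "RskSigned", "RkuSigned"
)

setValidity("RoughnessReport", function(object) {
  msg <- character()
  if (!identical(names(object@values), .roughnessFields))
    msg <- c(msg, "values must carry the full named statistic set")
  if (length(object@nPoints) != 1L || object@nPoints < 4L)
    msg <- c(msg, "nPoints must be a single integer >= 4")
  if (length(msg)) msg else TRUE
})

#' HeightPDF: binned probability density of heights
#'
#' @slot binEdges bin edges (nm), length nBins + 1.
#' @slot density density per bin (1/nm); integrates to 1.
#'
#' @seealso [heightPDF()], [unimodalityCheck()]
#' @export
setClass("HeightPDF",
  representation(binEdges = "numeric", density = "numeric")
)

setValidity("HeightPDF", function(object) {
  msg <- character()
  if (length(object@binEdges) != length(object@density) + 1L)
    msg <- c(msg, "binEdges must have one more entry than density")
  if (is.unsorted(object@binEdges, strictly = TRUE))
    msg <- c(msg, "binEdges must be strictly increasing")
  if (any(object@density < 0)) msg <- c(msg, "density must be non-negative")
  tot <- sum(object@density * diff(object@binEdges))
  if (!isTRUE(all.equal(tot, 1, tolerance = 1e-8)))
    msg <- c(msg, "density must integrate to 1")
  if (length(msg)) msg else TRUE
})

#' FractalEstimate: one fractal-dimension estimate
#'
#' Result of one scaling-curve estimator: the log-log point set, the fitted
#' slope over the fit range, and the derived fractal dimension.
#'
#' @slot method one of `"variance"`, `"cube_counting"`, `"triangulation"`,
#'   `"power_spectrum"`, `"structure_function"`, `"variation"`.
#' @slot Df estimated fractal dimension.
#' @slot slope,intercept,rSquared least-squares fit of log statistic on log
#'   scale over the fit range (NA for degenerate flat surfaces).
#' @slot points two-column matrix `(log_scale, log_stat)`.
#' @slot fitRange integer indices of `points` used in the fit.
#' @slot warn character vector of warnings (e.g. Df outside \[2, 3\],
#'   degenerate surface); never silently clamped.
#'
#' @seealso [fractalDimension()], [fitLogLog()]
#' @export
setClass("FractalEstimate",
  representation(
    method = "character",
    Df = "numeric",
    slope = "numeric",
    intercept = "numeric",
    rSquared = "numeric",
    points = "matrix",
    fitRange = "integer",
    warn = "character"
  ),
  prototype(warn = character())
)

.fractalMethods <- c(
  "variance", "cube_counting", "triangulation", "power_spectrum",
  "structure_function", "variation"
)

setValidity("FractalEstimate", function(object) {
  msg <- character()
  if (!(object@method %in% .fractalMethods))
    msg <- c(msg, "unknown estimator method")
  if (ncol(object@points) != 2L)
    msg <- c(msg, "points must be a two-column matrix")
  if (length(object@fitRange) > 0L && length(object@fitRange) < 4L)
    msg <- c(msg, "fit range must contain at least 4 points")
  if (length(msg)) msg else TRUE
})

#' MinkowskiCurves: threshold-sweep Minkowski functionals
#'
#' Two-dimensional discrete Minkowski functionals of a height map as
#' functions of the binarization threshold z: covered volume fraction V(z)
#' (white = height >= z), boundary density S(z) (4-neighbour white/black
#' pixel pairs per pixel) and connectivity chi(z) = (number of 8-connected
#' white components minus number of 4-connected black components) per pixel.
#' Raw component and pair counts are retained alongside the per-pixel
#' normalized curves.
#'
#' @slot thresholds threshold grid (nm), both endpoints of the height range
#'   included.
#' @slot V volume fraction in \[0, 1\] per threshold.
#' @slot S boundary density per threshold.
#' @slot chi connectivity per pixel per threshold.
#' @slot counts integer matrix (n_white, n_pairs, c_white, c_black).
#' @slot nPixels number of image pixels N.
#'
#' @seealso [minkowskiCurves()], [connectivityLandmarks()],
#'   [volumeSymmetryScore()]
#' @export
setClass("MinkowskiCurves",
  representation(
    thresholds = "numeric",
    V = "numeric",
    S = "numeric",
    chi = "numeric",
    counts = "matrix",
    nPixels = "integer"
  )
)

setValidity("MinkowskiCurves", function(object) {
  msg <- character()
  n <- length(object@thresholds)
  if (n < 3L) msg <- c(msg, "need at least 3 thresholds")
  if (length(object@V) != n || length(object@S) != n ||
      length(object@chi) != n)
    msg <- c(msg, "V, S, chi must match the threshold grid length")
  if (length(object@V) == n && any(diff(object@V) > 1e-12))
    msg <- c(msg, "V must be non-increasing in z")
  if (any(object@S < 0)) msg <- c(msg, "S must be non-negative")
  if (length(msg)) msg else TRUE
})

#' ParticleFieldSpec: parameters of a deposited particle field
#'
#' Describes a field of spherical-cap particles (emulating nanodrug
#' aggregates) deposited on a background surface by pointwise maximum.
#'
#' @slot count number of particles (>= 0).
#' @slot radiusMean,radiusSd lateral radius distribution (nm); truncated
#'   normal clipped at 1 pixel and at 3 radiusSd.
#' @slot heightScale cap apex height as a fraction of the lateral radius,
#'   in (0, 1].
#' @slot placement `"uniform"` or `"clustered"`.
#' @slot clusterCount,clusterSpread clustered placement: number of cluster
#'   centres and Gaussian spread (nm) around them.
#'
#' @seealso [particleFieldSpec()], [depositParticles()]
#' @export
setClass("ParticleFieldSpec",
  representation(
    count = "integer",
    radiusMean = "numeric",
    radiusSd = "numeric",
    heightScale = "numeric",
    placement = "character",
    clusterCount = "integer",
    clusterSpread = "numeric"
  )
)

setValidity("ParticleFieldSpec", function(object) {
  msg <- character()
  if (object@count < 0L) msg <- c(msg, "count must be >= 0")
  if (object@radiusMean <= 0) msg <- c(msg, "radiusMean must be positive")
  if (object@radiusSd < 0) msg <- c(msg, "radiusSd must be >= 0")
  if (object@heightScale <= 0 || object@heightScale > 1)
    msg <- c(msg, "heightScale must lie in (0, 1]")
  if (!(object@placement %in% c("uniform", "clustered")))
    msg <- c(msg, "placement must be 'uniform' or 'clustered'")
  if (object@placement == "clustered" && object@clusterCount < 1L)
    msg <- c(msg, "clustered placement needs clusterCount >= 1")
  if (length(msg)) msg else TRUE
})

#' SceneSpec: parameters of a synthetic AFM scene
#'
#' Full description of a synthetic surface: a self-affine fractional
#' Brownian background with Hurst exponent `hurst` and target RMS roughness
#' `rmsTarget`, optionally with a deposited particle field, plus the RNG
#' seed. Identical specs (including seed) generate bit-identical surfaces.
#'
#' @slot sizePx grid side length (pixels); a power of two >= 16.
#' @slot pixelSize pixel pitch (nm per pixel).
#' @slot hurst Hurst exponent H in (0, 1); ground-truth dimension 3 - H.
#' @slot rmsTarget target sample R_q of the background (nm).
#' @slot particles a [ParticleFieldSpec-class] or NULL.
#' @slot seed integer RNG seed.
#'
#' @seealso [sceneSpec()], [generateFbmSurface()], [generateScene()]
#' @export
setClass("SceneSpec",
  representation(
    sizePx = "integer",
    pixelSize = "numeric",
    hurst = "numeric",
    rmsTarget = "numeric",
    particles = "ANY",
    seed = "integer"
  ),
  prototype(particles = NULL)
)

setValidity("SceneSpec", function(object) {
  msg <- character()
  n <- object@sizePx
  if (n < 16L || bitwAnd(n, n - 1L) != 0L)
    msg <- c(msg, "sizePx must be a power of two >= 16")
  if (object@hurst <= 0 || object@hurst >= 1)
    msg <- c(msg, "hurst must lie strictly in (0, 1)")
  if (object@rmsTarget < 0) msg <- c(msg, "rmsTarget must be >= 0")
  if (object@pixelSize <= 0) msg <- c(msg, "pixelSize must be positive")
  if (!is.null(object@particles)) {
    if (!is(object@particles, "ParticleFieldSpec"))
      msg <- c(msg, "particles must be a ParticleFieldSpec or NULL")
    else validObject(object@particles)
  }
  if (length(msg)) msg else TRUE
})

#' AnalysisConfig: configuration of the per-sample pipeline
#'
#' @slot zeroReference shift heights so the minimum is 0 before roughness
#'   statistics (AFM convention).
#' @slot tip optional [TipModel-class]; when present, erosion-based surface
#'   reconstruction is applied before the stages named in `tipStages`.
#' @slot tipStages stages that receive the reconstructed map (subset of
#'   `"roughness"`, `"fractal"`, `"minkowski"`); default `"fractal"`.
#' @slot bins histogram bin count for the height PDF and mode estimate.
#' @slot fractalMethods estimator subset to run.
#' @slot bsplineFactor B-spline resampling factor applied before fractal
#'   estimation (1 = off).
#' @slot fitRange `"auto"` or `c(i0, i1)` point indices for the log-log fits.
#' @slot nThresholds Minkowski threshold count.
#' @slot seed seed for any stochastic stage.
#'
#' @seealso [analysisConfig()], [analyzeSample()]
#' @export
setClass("AnalysisConfig",
  representation(
    zeroReference = "logical",
    tip = "ANY",
    tipStages = "character",
    bins = "integer",
    fractalMethods = "character",
    bsplineFactor = "integer",
    fitRange = "ANY",
    nThresholds = "integer",
    seed = "integer"
  ),
  prototype(tip = NULL, fitRange = "auto")
)

setValidity("AnalysisConfig", function(object) {
  msg <- character()
  if (!is.null(object@tip) && !is(object@tip, "TipModel"))
    msg <- c(msg, "tip must be a TipModel or NULL")
  bad <- setdiff(object@tipStages, c("roughness", "fractal", "minkowski"))
  if (length(bad)) msg <- c(msg, "unknown tip stage(s)")
  if (!all(object@fractalMethods %in% .fractalMethods))
    msg <- c(msg, "unknown fractal method(s)")
  if (object@bins < 2L) msg <- c(msg, "bins must be >= 2")
  if (object@bsplineFactor < 1L) msg <- c(msg, "bsplineFactor must be >= 1")
  if (object@nThresholds < 3L) msg <- c(msg, "nThresholds must be >= 3")
  if (length(msg)) msg else TRUE
})

#' SampleReport: full per-sample analysis result
#'
#' @slot label sample label.
#' @slot roughness a [RoughnessReport-class] (or NULL if the stage failed).
#' @slot pdf a [HeightPDF-class] (or NULL).
#' @slot fractal named list of [FractalEstimate-class] objects.
#' @slot minkowski a [MinkowskiCurves-class] (or NULL).
#' @slot landmarks list of Minkowski landmark thresholds.
#' @slot skipped named character vector mapping skipped stages to reasons.
#' @slot provenance list: input hash, config echo, package version.
#'
#' @seealso [analyzeSample()], [compareSamples()], [writeSampleReport()]
#' @export
setClass("SampleReport",
  representation(
    label = "character",
    roughness = "ANY",
    pdf = "ANY",
    fractal = "list",
    minkowski = "ANY",
    landmarks = "list",
    skipped = "character",
    provenance = "list"
  ),
  prototype(roughness = NULL, pdf = NULL, minkowski = NULL,
            skipped = character())
)
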