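#' Threshold-sweep 2D Minkowski functionals
#'
#' For each threshold z on an evenly spaced grid spanning the height range
#' (both endpoints included), the map is binarized (white = height >= z) and
#' three discrete Minkowski functionals are computed:
#' \describe{
#'   \item{V(z)}{white pixel fraction; monotone non-increasing from 1 (at
#'     the minimum height) to 0 (above the maximum).}
#'   \item{S(z)}{boundary density: 4-neighbour white/black pixel pairs per
#'     pixel; zero at both extremes, maximal at intermediate thresholds.}
#'   \item{chi(z)}{connectivity (Euler-Poincare characteristic) per pixel:
#'     (number of 8-connected white components - number of 4-connected
#'     black components) / N. Negative when many disconnected low (flat)
#'     regions dominate, positive when disconnected high (rough) regions
#'     dominate.}
#' }
#' The 8/4 connectivity pairing avoids the digital-topology paradox;
#' components touching the image border count as components. Raw counts are
#' kept alongside the per-pixel curves so scans of different sizes can be
#' compared either way. A constant surface yields the documented degenerate
#' output (V = 1 throughout its single-valued grid, S = 0, chi = 1/N).
#'
#' @param map a [HeightMap-class] with square pixels.
#' @param nThresholds number of thresholds (>= 3).
#' @return a [MinkowskiCurves-class].
#' @seealso [connectivityLandmarks()], [volumeSymmetryScore()],
#'   [countComponents()]
#' @export
#' @examples
#' hm <- makeFixture("step", sizePx = 64, h0 = 0, h1 = 100)
#' mk <- minkowskiCurves(hm, 101)
#' mk@V[51]  # 0.5 at mid-threshold
minkowskiCurves <- function(map, nThresholds = 256L) {
  stopifnot(is(map, "HeightMap"))
  .requireSquarePixels(map)
  nThresholds <- as.integer(nThresholds)
  if (nThresholds < 3L) .stopf("nThresholds must be >= 3")
  z <- map@heights
  r <- range(z)
  thresholds <- if (r[1L] == r[2L]) rep(r[1L], nThresholds) else
    seq(r[1L], r[2L], length.out = nThresholds)
  counts <- cpp_minkowski_sweep(z, thresholds)
  colnames(counts) <- c("n_white", "n_pairs", "c_white", "c_black")
  n <- length(z)
  new("MinkowskiCurves", thresholds = thresholds,
      V = counts[, "n_white"] / n, S = counts[, "n_pairs"] / n,
      chi = (counts[, "c_white"] - counts[, "c_black"]) / n,
      counts = counts, nPixels = as.integer(n))
}

#' Count connected components of a binary image
#'
#' @param mask logical matrix (TRUE = foreground).
#' @param connectivity 4 or 8.
#' @return integer component count; border-touching components are counted.
#' @export
countComponents <- function(mask, connectivity = 8L) {
  stopifnot(is.logical(mask), is.matrix(mask))
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(4L, 8L)) .stopf("connectivity must be 4 or 8")
  cpp_count_components(mask, connectivity)
}

#' Landmark thresholds of Minkowski curves
#'
#' Extracts the characteristic thresholds used to compare Minkowski curves
#' across samples: the global minimum and maximum of the connectivity chi,
#' the maximum of the boundary S, the V = 0.5 crossing (linearly
#' interpolated between bracketing thresholds), and the vanishing threshold
#' (first threshold after the chi maximum where |chi| drops below `tol`).
#' Plateaus of chi (maximal runs staying within `tol` of the run mean, of
#' at least `minPlateauLen` thresholds) are reported with start threshold
#' and length. Chi landmarks are searched over non-trivial thresholds only
#' (where 0 < V < 1); when chi vanishes identically there the chi landmarks
#' are undefined and flagged.
#'
#' @param curves a [MinkowskiCurves-class].
#' @param tol tolerance on |chi| (per pixel) for the vanishing threshold
#'   and plateau detection; default `2 / nPixels`.
#' @param minPlateauLen minimum plateau length in thresholds.
#' @return list: `vHalf`, `chiMin`, `chiMax`, `sMax`, `chiVanish` (nm),
#'   `chiDefined` (logical), `plateaus` (data.frame start/length).
#' @export
connectivityLandmarks <- function(curves, tol = NULL, minPlateauLen = 5L) {
  stopifnot(is(curves, "MinkowskiCurves"))
  th <- curves@thresholds
  chi <- curves@chi
  V <- curves@V
  if (is.null(tol)) tol <- 2 / curves@nPixels
  # V = 0.5 crossing by linear interpolation between bracketing thresholds
  vHalf <- NA_real_
  i <- which(V[-length(V)] >= 0.5 & V[-1L] < 0.5)
  if (length(i)) {
    i <- i[1L]
    if (V[i] == V[i + 1L]) vHalf <- th[i]
    else vHalf <- th[i] + (V[i] - 0.5) / (V[i] - V[i + 1L]) * (th[i + 1L] - th[i])
  } else if (any(V == 0.5)) vHalf <- th[which(V == 0.5)[1L]]
  # chi landmarks are searched over non-trivial thresholds only (0 < V < 1):
  # the all-white/all-black extremes contribute a trivial +/-1/N
  nt <- which(V > 0 & V < 1)
  chiDefined <- length(nt) > 0L && any(chi[nt] != 0)
  if (chiDefined) {
    iMin <- nt[which.min(chi[nt])]
    iMax <- nt[which.max(chi[nt])]
    after <- which(abs(chi) <= tol & seq_along(chi) > iMax)
    chiVanish <- if (length(after)) th[after[1L]] else NA_real_
    chiMin <- th[iMin]
    chiMax <- th[iMax]
  } else {
    chiMin <- chiMax <- chiVanish <- NA_real_
  }
  sMax <- th[which.max(curves@S)]
  # maximal runs where chi stays within tol of the run mean
  pl <- list()
  start <- 1L
  for (j in seq_along(chi)) {
    run <- chi[start:j]
    if (max(run) - min(run) > 2 * tol) {
      if (j - start >= minPlateauLen)
        pl[[length(pl) + 1L]] <- c(start, j - start)
      start <- j
    }
  }
  if (length(chi) - start + 1L >= minPlateauLen)
    pl[[length(pl) + 1L]] <- c(start, length(chi) - start + 1L)
  plateaus <- if (length(pl)) {
    m <- do.call(rbind, pl)
    data.frame(startThreshold = th[m[, 1L]], length = m[, 2L])
  } else data.frame(startThreshold = numeric(), length = integer())
  list(vHalf = vHalf, chiMin = chiMin, chiMax = chiMax, sMax = sMax,
       chiVanish = chiVanish, chiDefined = chiDefined, plateaus = plateaus)
}

#' Point-symmetry score of the Minkowski volume curve
#'
#' Quantifies how nearly the volume curve V(z) is point-symmetric about its
#' V = 0.5 crossing z0.5: `score = 1 - mean over offsets d of
#' |V(z0.5 + d) + V(z0.5 - d) - 1|`, with V interpolated linearly and
#' extended by 1 below and 0 above the threshold grid. A perfectly
#' point-symmetric curve (e.g. a symmetric height distribution) scores 1;
#' heavy one-sided deposition, which skews the distribution, lowers the
#' score.
#'
#' @param curves a [MinkowskiCurves-class].
#' @return score in \[0, 1\] (NA when V never crosses 0.5).
#' @export
volumeSymmetryScore <- function(curves) {
  stopifnot(is(curves, "MinkowskiCurves"))
  th <- curves@thresholds
  lm <- connectivityLandmarks(curves)
  z0 <- lm$vHalf
  if (!is.finite(z0)) return(NA_real_)
  Vfun <- stats::approxfun(th, curves@V, yleft = 1, yright = 0, ties = "ordered")
  dmax <- max(z0 - th[1L], th[length(th)] - z0)
  step <- (th[length(th)] - th[1L]) / (length(th) - 1L)
  if (dmax <= step) return(1)
  d <- seq(step, dmax, by = step)
  score <- 1 - mean(abs(Vfun(z0 + d) + Vfun(z0 - d) - 1))
  max(0, min(1, score))
}

#' Export Minkowski curves as a data.frame
#'
#' Columns z, V, S, chi (plus raw counts), one row per threshold, ready for
#' CSV export or plotting.
#'
#' @param x a [MinkowskiCurves-class].
#' @param ... unused.
#' @return a data.frame.
#' @export
as.data.frame.MinkowskiCurves <- function(x, ...) {
  data.frame(z = x@thresholds, V = x@V, S = x@S, chi = x@chi,
             nWhite = x@counts[, "n_white"], nPairs = x@counts[, "n_pairs"],
             cWhite = x@counts[, "c_white"], cBlack = x@counts[, "c_black"])
}
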