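#' Estimate the fractal dimension of a height map
#'
#' Six scaling-curve estimators of the surface fractal dimension Df (between
#' 2 for a smooth surface and 3 for an extremely rough one). Each builds a
#' log-log point set of a multiscale statistic, fits a straight line by
#' ordinary least squares over the fit range, and maps the slope to Df:
#' \describe{
#'   \item{cube_counting}{number N(l) of cubes of side l intersected by the
#'     surface, over dyadic l; heights are normalized so the full height
#'     range spans the lateral extent (making the count unit-free), and the
#'     lattice of constant l sees the surface at lattice resolution (cell
#'     corner spans; a full-box supremum would add a sampling-density bias
#'     on Gaussian surfaces); `Df = -slope` of ln N vs ln l.}
#'   \item{triangulation}{surface area A(l) from pairs of triangles on a
#'     grid of step l (area per unit projected area); heights are
#'     normalized to a fixed dimensionless relief (sample Rq equal to 8x
#'     the lateral extent) so the probed octaves sit in the self-affine
#'     scaling regime and the estimate is invariant to height units;
#'     `Df = 2 - slope` of ln A vs ln l.}
#'   \item{variance}{mean within-box height variance sigma^2(l) over dyadic
#'     boxes; `Df = 3 - slope/2`.}
#'   \item{power_spectrum}{1D periodograms of all rows and all columns,
#'     averaged; P is recorded against the spatial scale 1/f, and
#'     `Df = (7 - slope)/2` (equivalently `(7 + s_f)/2` for the slope s_f
#'     of ln P vs ln f). This estimator is not scale-free in height and may
#'     legitimately return Df < 2 on non-fractal surfaces; such values are
#'     flagged, never clamped.}
#'   \item{structure_function}{mean squared increment S(tau) over lags tau
#'     along both grid axes; `Df = 3 - slope/2`.}
#'   \item{variation}{mean height oscillation (max - min) of the surface
#'     sampled at scale l, over cells of side l; `Df = 3 - slope`.}
#' }
#'
#' Scales are dyadic from 2 px (1 px for triangulation/structure function)
#' up to a quarter of the side length; the automatic fit range drops the
#' largest-scale octave, where box statistics are poorest. The power
#' spectrum uses frequency indices up to side/16, away from the Nyquist
#' roll-off. Dyadic estimators operate on the leading power-of-two square
#' submatrix. A flat (zero-variance) surface has Df = 2 by definition for
#' cube counting, triangulation and variation, and raises a
#' degenerate-surface error for variance and structure function (whose
#' statistics are identically zero); estimates outside \[2, 3\] set a warning
#' flag.
#'
#' @param map a [HeightMap-class] with square pixels, side >= 16.
#' @param method estimator name (see above).
#' @param fitRange `"auto"` or `c(i0, i1)` indices into the point set.
#' @param bsplineFactor optional B-spline resampling factor applied first
#'   (1 = off; see [bsplineResample()]).
#' @return a [FractalEstimate-class].
#' @seealso [fitLogLog()], [generateFbmSurface()] for ground-truth surfaces
#'   with Df = 3 - H.
#' @export
#' @examples
#' hm <- generateFbmSurface(sceneSpec(sizePx = 256, hurst = 0.5, seed = 7))
#' fractalDimension(hm, "variance")
fractalDimension <- function(map,
                             method = c("variance", "cube_counting",
                                        "triangulation", "power_spectrum",
                                        "structure_function", "variation"),
                             fitRange = "auto", bsplineFactor = 1L) {
  method <- match.arg(method)
  stopifnot(is(map, "HeightMap"))
  px <- .requireSquarePixels(map)
  if (min(dim(map@heights)) < 16L)
    .stopf("fractal estimation needs a side length of at least 16 px")
  if (bsplineFactor > 1L) {
    map <- bsplineResample(map, bsplineFactor)
    px <- pixelSize(map)[["x"]]
  }
  z <- map@heights
  flat <- max(z) == min(z)
  if (flat) {
    if (method %in% c("variance", "structure_function"))
      .stopf("degenerate zero-variance surface: %s statistic is identically 0",
             method)
    return(new("FractalEstimate", method = method, Df = 2,
               slope = NA_real_, intercept = NA_real_, rSquared = NA_real_,
               points = matrix(numeric(), 0L, 2L,
                               dimnames = list(NULL, c("log_scale", "log_stat"))),
               fitRange = integer(), warn = "degenerate flat surface: Df = 2 by definition"))
  }
  pts <- switch(method,
    cube_counting = .ptsCubeCounting(z, px),
    triangulation = .ptsTriangulation(z, px),
    variance = .ptsVariance(z, px),
    power_spectrum = .ptsPowerSpectrum(z, px),
    structure_function = .ptsStructureFunction(z, px),
    variation = .ptsVariation(z, px)
  )
  fit <- fitLogLog(pts$points, fitRange)
  slope <- fit$slope
  Df <- switch(method,
    cube_counting = -slope,
    triangulation = 2 - slope,
    variance = 3 - slope / 2,
    power_spectrum = (7 - slope) / 2,
    structure_function = 3 - slope / 2,
    variation = 3 - slope
  )
  warn <- character()
  if (Df < 2 || Df > 3)
    warn <- sprintf("Df = %.3f outside [2, 3]; estimator unreliable on this surface", Df)
  new("FractalEstimate", method = method, Df = Df, slope = slope,
      intercept = fit$intercept, rSquared = fit$rSquared,
      points = pts$points, fitRange = fit$used, warn = warn)
}

# leading power-of-two square submatrix for dyadic box schemes
.dyadicCrop <- function(z) {
  n <- min(dim(z))
  n2 <- 2L^floor(log2(n))
  z[seq_len(n2), seq_len(n2), drop = FALSE]
}

.mkPoints <- function(scale, stat) {
  cbind(log_scale = log(scale), log_stat = ifelse(stat > 0, log(stat), -Inf))
}

# corner values of the cells of a subsampled grid (lattice resolution l)
.cellCorners <- function(z, l) {
  idx <- seq.int(1L, nrow(z), by = l)
  s <- z[idx, idx, drop = FALSE]
  m <- length(idx)
  list(a = s[-m, -m], b = s[-1L, -m], d = s[-m, -1L], e = s[-1L, -1L])
}

.ptsCubeCounting <- function(z, px) {
  z <- .dyadicCrop(z)
  n <- nrow(z)
  zn <- (z - min(z)) / (max(z) - min(z)) * n   # range spans lateral extent
  ls <- 2L^(1:floor(log2(n / 4L)))
  # the lattice of constant l resolves the surface at scale l: per cell,
  # count the height boxes spanned by its corner values (a full-box
  # supremum would add a sampling-density bias on Gaussian surfaces)
  Ns <- vapply(ls, function(l) {
    cc <- .cellCorners(zn, l)
    mx <- pmax(cc$a, cc$b, cc$d, cc$e)
    mn <- pmin(cc$a, cc$b, cc$d, cc$e)
    sum(floor(mx / l) - floor(mn / l) + 1)
  }, numeric(1))
  list(points = .mkPoints(ls * px, Ns))
}

.ptsTriangulation <- function(z, px, relief = 8) {
  z <- .dyadicCrop(z)
  n <- nrow(z)
  rq <- sqrt(mean((z - mean(z))^2))
  zn <- z * (relief * n / rq)                  # fixed dimensionless relief
  ls <- 2L^(0:floor(log2(n / 4L)))
  As <- vapply(ls, function(l) {
    idx <- seq.int(1L, n, by = l)
    s <- zn[idx, idx, drop = FALSE]
    m <- length(idx)
    z11 <- s[-m, -m]; z21 <- s[-1L, -m]; z12 <- s[-m, -1L]; z22 <- s[-1L, -1L]
    # triangles (z11, z21, z12) and (z21, z12, z22) on an l x l cell
    a1 <- 0.5 * sqrt((l * (z21 - z11))^2 + (l * (z12 - z11))^2 + l^4)
    a2 <- 0.5 * sqrt((l * (z21 - z22))^2 + (l * (z12 - z22))^2 + l^4)
    sum(a1 + a2) / (l * (m - 1L))^2            # area per unit projected area
  }, numeric(1))
  list(points = .mkPoints(ls * px, As))
}

.ptsVariance <- function(z, px) {
  z <- .dyadicCrop(z)
  z <- z - mean(z)                             # guard against cancellation
  n <- nrow(z)
  s1 <- z
  s2 <- z^2
  ls <- c()
  vs <- c()
  l <- 2L
  while (l <= n / 4L) {
    s1 <- .pool2(s1, "sum")
    s2 <- .pool2(s2, "sum")
    m <- l^2
    vs <- c(vs, mean(s2 / m - (s1 / m)^2))
    ls <- c(ls, l)
    l <- l * 2L
  }
  list(points = .mkPoints(ls * px, vs))
}

.ptsStructureFunction <- function(z, px) {
  n <- min(dim(z))
  taus <- 2L^(0:floor(log2(n / 4L)))
  ss <- vapply(taus, function(tau) {
    dx <- z[, -seq_len(tau), drop = FALSE] - z[, seq_len(ncol(z) - tau), drop = FALSE]
    dy <- z[-seq_len(tau), , drop = FALSE] - z[seq_len(nrow(z) - tau), , drop = FALSE]
    (sum(dx^2) + sum(dy^2)) / (length(dx) + length(dy))
  }, numeric(1))
  list(points = .mkPoints(taus * px, ss))
}

.ptsVariation <- function(z, px) {
  z <- .dyadicCrop(z)
  n <- nrow(z)
  ls <- 2L^(1:floor(log2(n / 4L)))
  # oscillation of the surface sampled at scale l (cell corner range);
  # self-affine scaling is then exact across scales
  vs <- vapply(ls, function(l) {
    cc <- .cellCorners(z, l)
    mean(pmax(cc$a, cc$b, cc$d, cc$e) - pmin(cc$a, cc$b, cc$d, cc$e))
  }, numeric(1))
  list(points = .mkPoints(ls * px, vs))
}

.ptsPowerSpectrum <- function(z, px) {
  z <- .dyadicCrop(z)
  n <- nrow(z)
  kmax <- max(4L, n %/% 16L)                   # keep clear of Nyquist roll-off
  prow <- Mod(stats::mvfft(t(z)))^2            # profiles along x
  pcol <- Mod(stats::mvfft(z))^2               # profiles along y
  pk <- (rowSums(prow) + rowSums(pcol))[2:(kmax + 1L)] / (2 * n * n)
  k <- seq_len(kmax)
  f <- k / (n * px)                            # 1/nm
  list(points = .mkPoints(1 / f, pk))
}

#' Least-squares fit of a log-log scaling curve
#'
#' Ordinary least squares of `log_stat` on `log_scale`. The `"auto"` fit
#' range excludes the largest-scale octave (scales above half the maximum,
#' where box statistics are poorest) and any point whose statistic is zero
#' (non-finite log); an explicit range `c(i0, i1)` selects point indices
#' directly. At least 4 usable points are required and duplicated scales
#' are rejected.
#'
#' @param points two-column matrix `(log_scale, log_stat)`.
#' @param fitRange `"auto"` or `c(i0, i1)`.
#' @return list with `slope`, `intercept`, `rSquared`, and `used` (indices).
#' @export
#' @examples
#' pts <- cbind(log_scale = log(2^(1:6)), log_stat = -2 * log(2^(1:6)) + 1)
#' fitLogLog(pts)  # slope -2, r^2 = 1
fitLogLog <- function(points, fitRange = "auto") {
  x <- points[, 1L]
  y <- points[, 2L]
  if (identical(fitRange, "auto")) {
    ok <- is.finite(y) & is.finite(x)
    smax <- max(x[ok])
    ok <- ok & (x <= smax - log(2) + 1e-12)
    used <- which(ok)
  } else {
    fitRange <- as.integer(fitRange)
    if (length(fitRange) != 2L || fitRange[1L] > fitRange[2L])
      .stopf("explicit fitRange must be c(i0, i1)")
    used <- seq.int(max(1L, fitRange[1L]), min(length(x), fitRange[2L]))
    used <- used[is.finite(y[used]) & is.finite(x[used])]
  }
  if (length(used) < 4L)
    .stopf("log-log fit needs at least 4 usable points (got %d)", length(used))
  if (anyDuplicated(x[used]))
    .stopf("duplicated scale values in log-log fit")
  xu <- x[used]
  yu <- y[used]
  xm <- mean(xu)
  ym <- mean(yu)
  sxx <- sum((xu - xm)^2)
  slope <- sum((xu - xm) * (yu - ym)) / sxx
  intercept <- ym - slope * xm
  sst <- sum((yu - ym)^2)
  ssr <- sum((yu - (intercept + slope * xu))^2)
  r2 <- if (sst > 0) 1 - ssr / sst else 1
  list(slope = slope, intercept = intercept, rSquared = r2, used = used)
}

#' Cubic-spline resampling of a height map
#'
#' Separable cubic (natural) spline interpolation onto a `factor`-times
#' finer grid; `factor = 1` returns the input unchanged. Spline
#' interpolation reproduces linear fields exactly; on rough surfaces it
#' smooths below the original pixel scale, which slightly biases
#' fine-scale fractal statistics (quantified in the package vignette), so
#' resampling is off by default in the analysis pipeline.
#'
#' @param map a [HeightMap-class].
#' @param factor integer >= 1.
#' @return a [HeightMap-class] with `factor`-times more pixels per side and
#'   `pixelSize / factor` pitch.
#' @export
bsplineResample <- function(map, factor = 1L) {
  stopifnot(is(map, "HeightMap"))
  factor <- as.integer(factor)
  if (factor < 1L) .stopf("factor must be >= 1")
  if (factor == 1L) return(map)
  z <- map@heights
  nr <- nrow(z)
  nc <- ncol(z)
  xin <- seq_len(nc)
  xout <- seq(1, nc + 1 - 1 / factor, by = 1 / factor)
  tmp <- t(apply(z, 1L, function(row)
    stats::spline(xin, row, xout = xout, method = "natural")$y))
  yin <- seq_len(nr)
  yout <- seq(1, nr + 1 - 1 / factor, by = 1 / factor)
  out <- apply(tmp, 2L, function(col)
    stats::spline(yin, col, xout = yout, method = "natural")$y)
  HeightMap(out, pixelSize(map) / factor, label = map@label,
            meta = map@meta)
}
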