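#' Amplitude roughness statistics of a height map
#'
#' Computes the full amplitude-parameter set over all N = rows x cols
#' heights Z_i:
#' \describe{
#'   \item{Zbar}{mean absolute height, `mean(|Z_i|)`. For zero-referenced
#'     (non-negative) maps this equals the plain mean, which is also
#'     reported as `Zmean`.}
#'   \item{Ra}{`mean(|Z_i - Zbar|)`.}
#'   \item{Rq}{`sqrt(mean((Z_i - Zbar)^2))`.}
#'   \item{Rt}{total height range `|Zmax - Zmin|`.}
#'   \item{Rmvd, Rmph}{maximum valley depth `|min(Z_i - Zbar)|` and maximum
#'     peak height `max(Z_i - Zbar)`; `Rt = Rmvd + Rmph` whenever Zbar lies
#'     inside the height range.}
#'   \item{RskAbs, RkuAbs}{absolute-moment skewness
#'     `mean(|Z_i - Zbar|^3) / Rq^3` and kurtosis
#'     `mean(|Z_i - Zbar|^4) / Rq^4`, the convention used in the AFM
#'     nanotexture literature this package follows (RskAbs is therefore
#'     non-negative).}
#'   \item{RskSigned, RkuSigned}{conventional signed third and fourth
#'     standardized moments about the plain mean (a Gaussian surface gives
#'     approximately 0 and 3).}
#'   \item{Zmedian, Zmode}{sample median, and the centre of the maximal
#'     histogram bin (`bins` bins over the height range; ties break to the
#'     lowest bin).}
#' }
#' When `Rq = 0` (constant surface) the skewness and kurtosis are reported
#' as `NA` and flagged in the `undefined` slot rather than propagating NaN.
#'
#' @param map a [HeightMap-class].
#' @param bins histogram bin count for the mode estimate.
#' @return a [RoughnessReport-class].
#' @seealso [heightPDF()], [unimodalityCheck()]
#' @export
#' @examples
#' hm <- HeightMap(matrix(c(1, 2, 3, 4), 2, 2), pixelSize = 10)
#' roughnessReport(hm)
roughnessReport <- function(map, bins = 256L) {
  stopifnot(is(map, "HeightMap"))
  validObject(map)
  z <- as.vector(map@heights)
  n <- length(z)
  zbar <- mean(abs(z))
  zmean <- mean(z)
  dev <- z - zbar
  ra <- mean(abs(dev))
  rq <- sqrt(mean(dev^2))
  rt <- abs(max(z) - min(z))
  rmvd <- abs(min(dev))
  rmph <- max(dev)
  undefined <- character()
  if (rq > 0) {
    rskAbs <- mean(abs(dev)^3) / rq^3
    rkuAbs <- mean(dev^4) / rq^4
    s <- sqrt(mean((z - zmean)^2))
    rskSigned <- mean((z - zmean)^3) / s^3
    rkuSigned <- mean((z - zmean)^4) / s^4
  } else {
    rskAbs <- rkuAbs <- rskSigned <- rkuSigned <- NA_real_
    undefined <- c("RskAbs", "RkuAbs", "RskSigned", "RkuSigned")
  }
  zmed <- stats::median(z)
  zmode <- .histogramMode(z, bins)
  vals <- c(
    Zbar = zbar, Zmean = zmean, Zmedian = zmed, Zmode = zmode,
    Ra = ra, Rq = rq, Rt = rt, Rmvd = rmvd, Rmph = rmph,
    RskAbs = rskAbs, RkuAbs = rkuAbs,
    RskSigned = rskSigned, RkuSigned = rkuSigned
  )
  new("RoughnessReport", values = vals, nPoints = as.integer(n),
      undefined = undefined, label = map@label)
}

.histogramMode <- function(z, bins) {
  r <- range(z)
  if (r[1L] == r[2L]) return(r[1L])
  edges <- seq(r[1L], r[2L], length.out = bins + 1L)
  counts <- .binCounts(z, edges)
  i <- which.max(counts)               # which.max ties break to lowest bin
  (edges[i] + edges[i + 1L]) / 2
}

# histogram counts with right-closed last bin
.binCounts <- function(z, edges) {
  idx <- findInterval(z, edges, rightmost.closed = TRUE)
  tabulate(idx, nbins = length(edges) - 1L)
}

#' Binned probability density of heights
#'
#' Normalized histogram of the heights over `[Zmin, Zmax]`:
#' `sum(density * binWidth) = 1`. A constant surface yields the documented
#' degenerate convention of a single 1-nm-wide bin holding all mass.
#'
#' @param map a [HeightMap-class].
#' @param bins number of bins (>= 2).
#' @return a [HeightPDF-class].
#' @seealso [roughnessReport()], [unimodalityCheck()]
#' @export
heightPDF <- function(map, bins = 256L) {
  stopifnot(is(map, "HeightMap"))
  bins <- as.integer(bins)
  if (bins < 2L) .stopf("bins must be >= 2")
  z <- as.vector(map@heights)
  r <- range(z)
  if (r[1L] == r[2L]) {
    return(new("HeightPDF", binEdges = c(r[1L] - 0.5, r[1L] + 0.5),
               density = 1))
  }
  edges <- seq(r[1L], r[2L], length.out = bins + 1L)
  counts <- .binCounts(z, edges)
  dens <- counts / (length(z) * diff(edges))
  new("HeightPDF", binEdges = edges, density = dens)
}

#' Check unimodality of the height distribution
#'
#' A surface's height PDF is considered unimodal when the mean, median and
#' mode nearly coincide (gaps at most `tolerance * Rq`) and the smoothed
#' density has a single local maximum. This mirrors the qualitative
#' mean/median/mode-agreement argument used when interpreting AFM height
#' distributions of tissue scans.
#'
#' @param pdf a [HeightPDF-class] of the map.
#' @param report the [RoughnessReport-class] of the same map.
#' @param tolerance gap tolerance as a multiple of Rq.
#' @return a list: `unimodal` (logical), `meanMedianGap`, `medianModeGap`
#'   (nm), `nModes` (count of smoothed local maxima).
#' @export
unimodalityCheck <- function(pdf, report, tolerance = 0.5) {
  stopifnot(is(pdf, "HeightPDF"), is(report, "RoughnessReport"))
  v <- report@values
  g1 <- abs(v[["Zmean"]] - v[["Zmedian"]])
  g2 <- abs(v[["Zmedian"]] - v[["Zmode"]])
  nModes <- .countModes(pdf@density)
  rq <- v[["Rq"]]
  uni <- nModes <= 1L && (rq == 0 || (g1 <= tolerance * rq &&
                                      g2 <= tolerance * rq))
  list(unimodal = uni, meanMedianGap = unname(g1), medianModeGap = unname(g2),
       nModes = nModes)
}

# count modes of the binned density: Gaussian smoothing (bandwidth ~ 1/24 of
# the range), then peaks filtered by topographic prominence, so sampling
# wobble on a genuinely unimodal distribution does not register as extra
# modes while well-separated populations do
.countModes <- function(d, promFrac = 0.1) {
  n <- length(d)
  if (n < 3L) return(1L)
  bw <- max(2, n / 24)
  i <- seq_len(n)
  W <- outer(i, i, function(a, b) stats::dnorm(a - b, sd = bw))
  sm <- as.vector(W %*% d) / colSums(W)
  d2 <- diff(sign(diff(c(-Inf, sm, -Inf))))
  pk <- which(d2 == -2)
  if (length(pk) <= 1L) return(length(pk))
  prom <- vapply(pk, function(p) {
    v <- sm[p]
    lef <- if (p > 1L) sm[seq_len(p - 1L)] else numeric()
    rig <- if (p < n) sm[(p + 1L):n] else numeric()
    keyL <- if (!length(lef)) -Inf
      else if (any(lef > v)) min(lef[max(which(lef > v)):(p - 1L)])
      else min(lef)
    keyR <- if (!length(rig)) -Inf
      else if (any(rig > v)) min(rig[1:min(which(rig > v))])
      else min(rig)
    v - max(keyL, keyR)
  }, numeric(1))
  sum(prom >= promFrac * max(sm))
}

#' Tabulate roughness reports
#'
#' One row per report with columns in the order used for amplitude-statistic
#' tables of AFM studies: sample, Zbar, Ra, Rq, then the remaining
#' statistics.
#'
#' @param reports a list of [RoughnessReport-class] objects (or a single
#'   one).
#' @return a data.frame.
#' @export
roughnessTable <- function(reports) {
  if (is(reports, "RoughnessReport")) reports <- list(reports)
  rows <- lapply(reports, function(r) {
    v <- r@values
    data.frame(
      sample = r@label, Zbar = v[["Zbar"]], Ra = v[["Ra"]], Rq = v[["Rq"]],
      Zmedian = v[["Zmedian"]], Zmode = v[["Zmode"]], Rt = v[["Rt"]],
      Rmvd = v[["Rmvd"]], Rmph = v[["Rmph"]], RskAbs = v[["RskAbs"]],
      RkuAbs = v[["RkuAbs"]], RskSigned = v[["RskSigned"]],
      RkuSigned = v[["RkuSigned"]], N = r@nPoints,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
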