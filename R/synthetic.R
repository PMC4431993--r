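#' Describe a synthetic AFM scene
#'
#' Constructors for [SceneSpec-class] and [ParticleFieldSpec-class]. The
#' defaults emulate a 2 x 2 um tissue scan at 512 x 512 px: a self-affine
#' background with Hurst exponent 0.55 and R_q 16 nm (atheromatous-like
#' scale), and a moderate field of ~35 nm radius caps standing in for
#' dendrimer aggregates while keeping the height PDF unimodal; heavier
#' fields (e.g. count 120, radius 80 nm, heightScale 0.8) emulate strongly
#' agglomerated samples whose volume curves turn asymmetric.
#'
#' @param sizePx grid side length in pixels (power of two, >= 16).
#' @param pixelSize pixel pitch in nm/px.
#' @param hurst Hurst exponent H in (0, 1); the generated background has
#'   ground-truth fractal dimension 3 - H.
#' @param rmsTarget target sample R_q of the background in nm (enforced
#'   exactly by rescaling).
#' @param particles optional [ParticleFieldSpec-class].
#' @param seed integer RNG seed; identical specs generate bit-identical
#'   surfaces.
#' @return a validated [SceneSpec-class].
#' @seealso [generateFbmSurface()], [generateScene()], [depositParticles()]
#' @export
#' @examples
#' spec <- sceneSpec(sizePx = 256, hurst = 0.5, rmsTarget = 10, seed = 1)
#' hm <- generateFbmSurface(spec)
sceneSpec <- function(sizePx = 512L, pixelSize = 2000 / 512, hurst = 0.55,
                      rmsTarget = 16, particles = NULL, seed = 1L) {
  new("SceneSpec", sizePx = as.integer(sizePx),
      pixelSize = as.numeric(pixelSize), hurst = as.numeric(hurst),
      rmsTarget = as.numeric(rmsTarget), particles = particles,
      seed = as.integer(seed))
}

#' @param count number of particles.
#' @param radiusMean,radiusSd lateral cap radius distribution in nm
#'   (truncated normal, clipped at 1 px and at 3 radiusSd).
#' @param heightScale cap apex height as a fraction of its radius, (0, 1].
#' @param placement `"uniform"` or `"clustered"`.
#' @param clusterCount,clusterSpread clustered placement parameters (number
#'   of cluster centres; Gaussian spread in nm).
#' @rdname sceneSpec
#' @export
particleFieldSpec <- function(count = 60L, radiusMean = 35, radiusSd = 8,
                              heightScale = 0.35,
                              placement = c("uniform", "clustered"),
                              clusterCount = 8L, clusterSpread = 150) {
  new("ParticleFieldSpec", count = as.integer(count),
      radiusMean = as.numeric(radiusMean), radiusSd = as.numeric(radiusSd),
      heightScale = as.numeric(heightScale),
      placement = match.arg(placement),
      clusterCount = as.integer(clusterCount),
      clusterSpread = as.numeric(clusterSpread))
}

#' Generate a self-affine fractional Brownian surface
#'
#' Spectral synthesis: a Gaussian white complex spectrum is shaped by the
#' isotropic radial power law P(f) proportional to f^(-2(H+1)) (the 2D
#' surface convention, for which the fractal dimension is 3 - H), the zero
#' frequency is removed, and the inverse FFT's real part is rescaled so the
#' sample mean is exactly 0 and the sample R_q exactly `rmsTarget`.
#'
#' @param spec a [SceneSpec-class]; its `particles` slot is ignored here.
#' @return a [HeightMap-class] of side `sizePx`.
#' @seealso [sceneSpec()], [generateScene()]
#' @export
generateFbmSurface <- function(spec) {
  stopifnot(is(spec, "SceneSpec"))
  validObject(spec)
  n <- spec@sizePx
  H <- spec@hurst
  k <- c(0:(n / 2), seq.int(-(n / 2 - 1), -1))   # FFT frequency indices
  f2 <- outer(k^2, k^2, "+")
  amp <- f2^(-(H + 1) / 2)
  amp[1L, 1L] <- 0                               # mean-free surface
  z <- .withSeed(spec@seed, {
    re <- matrix(stats::rnorm(n * n), n, n)
    im <- matrix(stats::rnorm(n * n), n, n)
    Re(stats::fft(amp * complex(real = re, imaginary = im), inverse = TRUE))
  })
  z <- z - mean(z)
  s <- sqrt(mean(z^2))
  z <- if (s > 0) z * (spec@rmsTarget / s) else z * 0
  HeightMap(z, spec@pixelSize,
            label = sprintf("fbm_H%.2f_seed%d", H, spec@seed))
}

# spherical cap profile: lateral radius r, apex height a = heightScale * r,
# so the sphere radius is R = (r^2 + a^2) / (2 a); height above the base at
# lateral distance d <= r is sqrt(R^2 - d^2) - (R - a).
.capProfile <- function(d, r, heightScale) {
  a <- heightScale * r
  R <- (r^2 + a^2) / (2 * a)
  h <- sqrt(pmax(R^2 - d^2, 0)) - (R - a)
  h[d > r] <- 0
  pmax(h, 0)
}

#' Deposit spherical-cap particles on a surface
#'
#' Each particle is a spherical cap of lateral radius r (drawn from the
#' spec's truncated normal) and apex height `heightScale * r`, seated on the
#' background at its centre pixel's height and combined with the current
#' surface by pointwise maximum (non-interpenetrating solids). Particle i
#' always draws from the same derived sub-seed, so increasing `count`
#' leaves earlier particles unchanged.
#'
#' @param base background [HeightMap-class].
#' @param particles a [ParticleFieldSpec-class].
#' @param seed integer seed for placement and radii.
#' @return a [HeightMap-class] with the same dimensions and calibration as
#'   `base`; no pixel is ever lowered.
#' @seealso [particleFieldSpec()], [generateScene()]
#' @export
depositParticles <- function(base, particles, seed = 1L) {
  stopifnot(is(base, "HeightMap"), is(particles, "ParticleFieldSpec"))
  validObject(particles)
  z <- base@heights
  if (particles@count == 0L) return(base)
  px <- .requireSquarePixels(base)
  nr <- nrow(z)
  nc <- ncol(z)
  ext <- scanExtent(base)
  # cluster centres come from a fixed sub-seed, each particle's centre and
  # radius from its own: particle i is identical no matter how many
  # particles follow it
  clusters <- if (particles@placement == "clustered") {
    .withSeed(.subSeed(seed, 0L), {
      cbind(stats::runif(particles@clusterCount, 0, ext[["x"]]),
            stats::runif(particles@clusterCount, 0, ext[["y"]]))
    })
  } else NULL
  for (i in seq_len(particles@count)) {
    draw <- .withSeed(.subSeed(seed, i), {
      if (particles@placement == "uniform") {
        c(stats::runif(1L, 0, ext[["x"]]), stats::runif(1L, 0, ext[["y"]]),
          stats::rnorm(1L, particles@radiusMean, particles@radiusSd))
      } else {
        k <- (i - 1L) %% particles@clusterCount + 1L
        c(clusters[k, ] + stats::rnorm(2L, 0, particles@clusterSpread),
          stats::rnorm(1L, particles@radiusMean, particles@radiusSd))
      }
    })
    r <- min(max(draw[3L], particles@radiusMean - 3 * particles@radiusSd),
             particles@radiusMean + 3 * particles@radiusSd)
    r <- max(r, px)                              # at least one pixel
    cx <- min(max(draw[1L], 0), ext[["x"]])
    cy <- min(max(draw[2L], 0), ext[["y"]])
    # pixel centre coordinates; row 1 = top = largest y
    ci <- round(cx / px + 0.5)
    ri <- round((ext[["y"]] - cy) / px + 0.5)
    ci <- min(max(ci, 1L), nc)
    ri <- min(max(ri, 1L), nr)
    baseZ <- z[ri, ci]
    w <- ceiling(r / px)
    rows <- max(1L, ri - w):min(nr, ri + w)
    cols <- max(1L, ci - w):min(nc, ci + w)
    xg <- (cols - 0.5) * px
    yg <- ext[["y"]] - (rows - 0.5) * px
    d <- sqrt(outer((yg - cy)^2, (xg - cx)^2, "+"))
    cap <- baseZ + .capProfile(d, r, particles@heightScale)
    inside <- d <= r
    sub <- z[rows, cols, drop = FALSE]
    sub[inside] <- pmax(sub[inside], cap[inside])
    z[rows, cols] <- sub
  }
  out <- base
  out@heights <- z
  out@label <- sprintf("%s+particles%d", base@label, particles@count)
  out
}

#' Generate a full synthetic scene
#'
#' Convenience wrapper: fBm background from `spec`, then particle
#' deposition when `spec@particles` is present (using the same seed).
#'
#' @param spec a [SceneSpec-class].
#' @return a [HeightMap-class].
#' @export
generateScene <- function(spec) {
  hm <- generateFbmSurface(spec)
  if (!is.null(spec@particles))
    hm <- depositParticles(hm, spec@particles, seed = spec@seed)
  hm
}

#' Exact geometric fixtures
#'
#' Deterministic surfaces with closed-form texture statistics, used as
#' oracles for the Minkowski and fractal estimators:
#' \describe{
#'   \item{plane}{constant height `h0` (optionally inclined: `slope` nm per
#'     pixel along x).}
#'   \item{step}{left half `h0`, right half `h1`.}
#'   \item{disk_field}{`k` disjoint disks of radius `r` px at height `h1`
#'     over a background `h0`, laid out on a regular lattice.}
#'   \item{checkerboard}{single-pixel alternation between `h0` and `h1`.}
#' }
#'
#' @param kind fixture type.
#' @param sizePx grid side length.
#' @param pixelSize pixel pitch (nm/px).
#' @param h0,h1 low/high plateau heights (nm).
#' @param k,r disk field: number of disks and radius in pixels.
#' @param slope plane inclination in nm per pixel along x (default 0).
#' @return a [HeightMap-class].
#' @export
#' @examples
#' makeFixture("step", sizePx = 64, h0 = 0, h1 = 100)
makeFixture <- function(kind = c("plane", "step", "disk_field",
                                 "checkerboard"),
                        sizePx = 256L, pixelSize = 1,
                        h0 = 0, h1 = 100, k = 3L, r = 10L, slope = 0) {
  kind <- match.arg(kind)
  n <- as.integer(sizePx)
  z <- switch(kind,
    plane = matrix(h0, n, n) + slope * matrix(rep(seq_len(n) - 1L, each = n), n, n),
    step = {
      m <- matrix(h0, n, n)
      m[, (n %/% 2L + 1L):n] <- h1
      m
    },
    disk_field = {
      m <- matrix(h0, n, n)
      per <- ceiling(sqrt(k))
      pitch <- n / per
      if (pitch < 2 * r + 2)
        .stopf("%d disks of radius %d px do not fit disjointly in %d px",
               k, r, n)
      placed <- 0L
      for (gy in seq_len(per)) {
        for (gx in seq_len(per)) {
          if (placed >= k) break
          cy <- round((gy - 0.5) * pitch)
          cx <- round((gx - 0.5) * pitch)
          rows <- (cy - r):(cy + r)
          cols <- (cx - r):(cx + r)
          d <- sqrt(outer((rows - cy)^2, (cols - cx)^2, "+"))
          sub <- m[rows, cols]
          sub[d <= r] <- h1
          m[rows, cols] <- sub
          placed <- placed + 1L
        }
      }
      m
    },
    checkerboard = {
      idx <- outer(seq_len(n), seq_len(n), "+")
      matrix(ifelse(idx %% 2L == 0L, h0, h1), n, n)
    }
  )
  HeightMap(z, pixelSize, label = kind)
}

#' Serialize a SceneSpec to a flat key=value file
#'
#' @param spec a [SceneSpec-class].
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeSceneSpec <- function(spec, path) {
  stopifnot(is(spec, "SceneSpec"))
  kv <- c(
    size_px = spec@sizePx, pixel_size = spec@pixelSize, hurst = spec@hurst,
    rms_target = spec@rmsTarget, seed = spec@seed
  )
  lines <- sprintf("%s=%.10g", names(kv), as.numeric(kv))
  p <- spec@particles
  if (!is.null(p)) {
    pv <- c(particle_count = p@count, radius_mean = p@radiusMean,
            radius_sd = p@radiusSd, height_scale = p@heightScale,
            cluster_count = p@clusterCount, cluster_spread = p@clusterSpread)
    lines <- c(lines, sprintf("%s=%.10g", names(pv), as.numeric(pv)),
               sprintf("placement=%s", p@placement))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @param path file written by [writeSceneSpec()].
#' @rdname writeSceneSpec
#' @export
readSceneSpec <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  kv <- strsplit(lines, "=", fixed = TRUE)
  vals <- stats::setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  num <- function(k, d = NULL) {
    if (k %in% names(vals)) as.numeric(vals[[k]]) else d
  }
  particles <- NULL
  if ("particle_count" %in% names(vals)) {
    particles <- particleFieldSpec(
      count = num("particle_count"), radiusMean = num("radius_mean", 40),
      radiusSd = num("radius_sd", 10), heightScale = num("height_scale", 0.6),
      placement = if ("placement" %in% names(vals)) vals[["placement"]] else "uniform",
      clusterCount = num("cluster_count", 8), clusterSpread = num("cluster_spread", 150))
  }
  sceneSpec(sizePx = num("size_px"), pixelSize = num("pixel_size"),
            hurst = num("hurst"), rmsTarget = num("rms_target"),
            particles = particles, seed = num("seed", 1))
}
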