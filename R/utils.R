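# internal helpers

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
.withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic sub-seed stream: particle i always draws from the same
# sub-seed regardless of how many particles are requested.
.subSeed <- function(seed, i) {
  as.integer((as.numeric(seed) %% 65011 + 1) * 30011 + i * 7919) %% 2147483629L
}

# fractal/Minkowski estimators assume isotropic sampling
.requireSquarePixels <- function(map) {
  dx <- map@pixelSizeX
  dy <- map@pixelSizeY
  if (abs(dx - dy) / dx > 1e-6)
    stop("operation requires square pixels (|dx - dy|/dx <= 1e-6); got ",
         dx, " x ", dy, " nm/px", call. = FALSE)
  invisible(dx)
}

.isPowerOfTwo <- function(n) n >= 1 && bitwAnd(as.integer(n), as.integer(n) - 1L) == 0L

# 2x2 block pooling on a square matrix with even side
.pool2 <- function(m, op = c("max", "min", "sum")) {
  op <- match.arg(op)
  n <- nrow(m)
  i <- seq.int(1L, n, 2L)
  a <- m[i, i, drop = FALSE]
  b <- m[i + 1L, i, drop = FALSE]
  d <- m[i, i + 1L, drop = FALSE]
  e <- m[i + 1L, i + 1L, drop = FALSE]
  switch(op,
    max = pmax(a, b, d, e),
    min = pmin(a, b, d, e),
    sum = a + b + d + e
  )
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
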