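# Independent oracles, deliberately naive: plain loops over the printed
# formulas and a BFS flood fill. They never share code with the package
# implementations they check.

# loop-based amplitude statistics
roughnessOracle <- function(z) {
  z <- as.vector(z)
  n <- length(z)
  zbar <- 0
  for (v in z) zbar <- zbar + abs(v)
  zbar <- zbar / n
  ra <- rq <- s3 <- s4 <- 0
  for (v in z) {
    d <- v - zbar
    ra <- ra + abs(d)
    rq <- rq + d^2
    s3 <- s3 + abs(d)^3
    s4 <- s4 + abs(d)^4
  }
  ra <- ra / n
  rq <- sqrt(rq / n)
  list(
    Zbar = zbar, Ra = ra, Rq = rq,
    Rt = abs(max(z) - min(z)),
    Rmvd = abs(min(z - zbar)), Rmph = max(z - zbar),
    RskAbs = if (rq > 0) s3 / (n * rq^3) * n / n else NA,
    RkuAbs = if (rq > 0) s4 / (n * rq^4) * n / n else NA
  )
}

# stack-based flood fill component count
floodFillCount <- function(mask, conn = 8) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  if (conn == 8) {
    dr <- c(-1, 1, 0, 0, -1, -1, 1, 1)
    dc <- c(0, 0, -1, 1, -1, 1, -1, 1)
  } else {
    dr <- c(-1, 1, 0, 0)
    dc <- c(0, 0, -1, 1)
  }
  count <- 0L
  stack <- integer(nr * nc)               # column-major pixel indices
  for (c0 in seq_len(nc)) {
    for (r0 in seq_len(nr)) {
      if (!mask[r0, c0] || seen[r0, c0]) next
      count <- count + 1L
      top <- 1L
      stack[1L] <- (c0 - 1L) * nr + r0
      seen[r0, c0] <- TRUE
      while (top > 0L) {
        p <- stack[top]
        top <- top - 1L
        pr <- (p - 1L) %% nr + 1L
        pc <- (p - 1L) %/% nr + 1L
        for (k in seq_along(dr)) {
          r <- pr + dr[k]
          cc <- pc + dc[k]
          if (r >= 1 && r <= nr && cc >= 1 && cc <= nc &&
              mask[r, cc] && !seen[r, cc]) {
            seen[r, cc] <- TRUE
            top <- top + 1L
            stack[top] <- (cc - 1L) * nr + r
          }
        }
      }
    }
  }
  count
}

# Minkowski triple at one threshold, by direct counting
minkowskiOracle <- function(z, th) {
  w <- z >= th
  nr <- nrow(w)
  nc <- ncol(w)
  pairs <- 0L
  for (r in 1:(nr - 1)) for (cc in 1:nc) pairs <- pairs + (w[r, cc] != w[r + 1, cc])
  for (r in 1:nr) for (cc in 1:(nc - 1)) pairs <- pairs + (w[r, cc] != w[r, cc + 1])
  list(
    nWhite = as.integer(sum(w)), nPairs = as.integer(pairs),
    cWhite = floodFillCount(w, 8), cBlack = floodFillCount(!w, 4)
  )
}

randomMap <- function(nr, nc = nr, seed = 1, mean = 50, sd = 10, px = 2) {
  set.seed(seed)
  HeightMap(matrix(rnorm(nr * nc, mean, sd), nr, nc), px,
            label = sprintf("rnd%d", seed))
}

zeroRef <- function(hm) {
  hm@heights <- hm@heights - min(hm@heights)
  hm
}
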