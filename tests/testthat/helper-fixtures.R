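# Shared fixtures and independent oracles. Expensive objects are built once
# per session and cached.

.fixtureCache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.fixtureCache[[key]])) .fixtureCache[[key]] <- builder()
  .fixtureCache[[key]]
}

# homogeneous all-white 1D bar domain
barDomain <- function(nx, dx = 1, D = 12.84) {
  z <- array(0, c(nx, 1, 1))
  tm <- tissueMap(z, array(1, c(nx, 1, 1)), z, spacing = c(dx, 1, 1))
  buildDiffusionMap(tm, D)
}

# homogeneous all-white cube domain
cubeDomain <- function(n, D, spacing = 1) {
  z <- array(0, c(n, n, n))
  tm <- tissueMap(z, array(1, c(n, n, n)), z, spacing = rep(spacing, 3))
  buildDiffusionMap(tm, D)
}

ballMask <- function(n, centre, radius) {
  co <- as.matrix(expand.grid(1:n, 1:n, 1:n))
  d2 <- (co[, 1] - centre[1])^2 + (co[, 2] - centre[2])^2 +
    (co[, 3] - centre[3])^2
  m <- array(FALSE, c(n, n, n))
  m[co[d2 <= radius^2, , drop = FALSE]] <- TRUE
  m
}

# the default-scale virtual patient used by the end-to-end recovery checks
defaultPatient <- function() {
  cached("defaultPatient", function() makeVirtualPatient(seed = 1))
}

# a small, fast virtual patient for unit-level pipeline tests
smallPatient <- function() {
  cached("smallPatient", function() {
    makeVirtualPatient(targetVolume = 2, shape = c(48, 48, 48),
                       marginPrimary = 8, marginBoost = 6, seed = 11)
  })
}

# --- independent oracles -----------------------------------------------------

# O(n * |kernel|) shift-OR dilation oracle
bruteDilate <- function(mask, margin, spacing = c(1, 1, 1)) {
  n <- dim(mask)
  r <- ceiling(margin / spacing)
  out <- array(FALSE, n)
  src <- which(mask, arr.ind = TRUE)
  for (i in -r[1]:r[1]) for (j in -r[2]:r[2]) for (k in -r[3]:r[3]) {
    if ((i * spacing[1])^2 + (j * spacing[2])^2 + (k * spacing[3])^2 >
        margin^2 + 1e-9) next
    dst <- sweep(src, 2, c(i, j, k), `+`)
    ok <- dst[, 1] >= 1 & dst[, 1] <= n[1] & dst[, 2] >= 1 &
      dst[, 2] <= n[2] & dst[, 3] >= 1 & dst[, 3] <= n[3]
    out[dst[ok, , drop = FALSE]] <- TRUE
  }
  out
}

# O(n^2) brute-force signed surface distances, plain loops
bruteSurfaceDistance <- function(predMask, obsMask, spacing = c(1, 1, 1)) {
  isSurface <- function(mask) {
    n <- dim(mask)
    out <- array(FALSE, n)
    idx <- which(mask, arr.ind = TRUE)
    for (r in seq_len(nrow(idx))) {
      v <- idx[r, ]
      bg <- FALSE
      for (o in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                     c(0, 0, 1), c(0, 0, -1))) {
        w <- v + o
        if (any(w < 1) || any(w > n) || !mask[w[1], w[2], w[3]]) {
          bg <- TRUE; break
        }
      }
      if (bg) out[v[1], v[2], v[3]] <- TRUE
    }
    out
  }
  ps <- which(isSurface(predMask), arr.ind = TRUE)
  os <- which(isSurface(obsMask), arr.ind = TRUE)
  out <- numeric(nrow(ps))
  for (r in seq_len(nrow(ps))) {
    best <- Inf
    for (q in seq_len(nrow(os))) {
      d2 <- sum(((ps[r, ] - os[q, ]) * spacing)^2)
      if (d2 < best) best <- d2
    }
    v <- ps[r, ]
    sgn <- if (obsMask[v[1], v[2], v[3]]) -1 else 1
    out[r] <- sgn * sqrt(best)
  }
  out
}

# linear least-squares slope, for front-speed fits
slopeOf <- function(x, y) stats::coef(stats::lm(y ~ x))[[2]]
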