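# Small numeric helpers shared across modules: Gaussian kernels, separable
# convolution, world-coordinate grids, sub-voxel translation.

FWHM_TO_SIGMA <- 1 / (2 * sqrt(2 * log(2)))

# Speed of light used by the TOF kernel and the theoretical SNR-gain
# predictor, in m/s.
SPEED_OF_LIGHT <- 2.998e8

# Spatial FWHM (mm) of the TOF localisation kernel for a timing resolution in
# picoseconds: c * dt / 2.
tofKernelFwhmMm <- function(tofFwhmPs) {
  SPEED_OF_LIGHT * tofFwhmPs * 1e-12 / 2 * 1000
}

# World coordinates (mm) of voxel centres along one axis, centred on 0.
axisCoords <- function(n, step) (seq_len(n) - 1 - (n - 1) / 2) * step

# Normalised, truncated (+/- 4 sigma) 1D Gaussian kernel sampled at `step`.
gaussianKernel1D <- function(fwhm, step) {
  if (fwhm <= 0) return(1)
  sigma <- fwhm * FWHM_TO_SIGMA
  half <- max(1L, ceiling(4 * sigma / step))
  x <- (-half:half) * step
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Zero-padded convolution along one axis of a 3D array, implemented as a
# banded-matrix product so that the adjoint used in reconstruction is exact
# (the kernel is symmetric).
convolveAxis <- function(a, kernel, axis) {
  if (length(kernel) == 1L) return(a)
  d <- dim(a)
  n <- d[axis]
  half <- (length(kernel) - 1L) %/% 2L
  K <- matrix(0, n, n)
  for (o in -half:half) {
    lo <- max(1L, 1L - o); hi <- min(n, n - o)
    if (lo > hi) next
    i <- seq.int(lo, hi)
    K[cbind(i, i + o)] <- kernel[o + half + 1L]
  }
  perm <- c(axis, setdiff(1:3, axis))
  ap <- aperm(a, perm)
  m <- K %*% matrix(ap, nrow = n)
  dim(m) <- d[perm]
  aperm(m, order(perm))
}

# Separable 3D Gaussian blur; fwhm and voxel are per-axis (mm).
gaussianBlur3D <- function(a, fwhm, voxel) {
  fwhm <- rep(fwhm, length.out = 3)
  for (ax in 1:3) {
    if (fwhm[ax] > 0)
      a <- convolveAxis(a, gaussianKernel1D(fwhm[ax], voxel[ax]), ax)
  }
  a
}

# Integer shift along one axis with zero padding.
shiftAxisInt <- function(a, k, axis) {
  if (k == 0L) return(a)
  n <- dim(a)[axis]
  out <- array(0, dim(a))
  if (abs(k) >= n) return(out)
  src <- if (k > 0) seq_len(n - k) else seq.int(1 - k, n)
  dst <- if (k > 0) seq.int(1 + k, n) else seq_len(n + k)
  if (axis == 1L) out[dst, , ] <- a[src, , ]
  else if (axis == 2L) out[, dst, ] <- a[, src, ]
  else out[, , dst] <- a[, , src]
  out
}

# Sub-voxel translation by linear interpolation (zero padding outside).
translateArray <- function(a, shiftMm, voxel) {
  for (ax in 1:3) {
    s <- shiftMm[ax] / voxel[ax]
    if (s == 0) next
    k <- floor(s)
    f <- s - k
    a0 <- shiftAxisInt(a, as.integer(k), ax)
    if (f > 0) {
      a1 <- shiftAxisInt(a, as.integer(k) + 1L, ax)
      a <- (1 - f) * a0 + f * a1
    } else a <- a0
  }
  a
}

# Run code with a private, restored RNG state (keyed deterministic draws
# without disturbing the caller's stream).
withLocalSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Voxel mask (logical array) of a sphere given in world mm.
sphereMask <- function(dims, voxel, center, radius) {
  x <- axisCoords(dims[1], voxel[1]) - center[1]
  y <- axisCoords(dims[2], voxel[2]) - center[2]
  z <- axisCoords(dims[3], voxel[3]) - center[3]
  r2 <- radius^2
  # bounding box keeps this cheap on large grids
  ix <- which(abs(x) <= radius)
  iy <- which(abs(y) <= radius)
  iz <- which(abs(z) <= radius)
  m <- array(FALSE, dims)
  if (!length(ix) || !length(iy) || !length(iz)) return(m)
  sub <- outer(x[ix]^2, y[iy]^2, `+`)
  sub <- outer(sub, z[iz]^2, `+`) <= r2
  m[ix, iy, iz] <- sub
  m
}

# Fitted FWHM of a 1D profile by linear interpolation of half-maximum
# crossings (used by tests and calibration diagnostics).
profileFWHM <- function(values, coords) {
  pk <- which.max(values)
  half <- values[pk] / 2
  left <- NA_real_
  for (i in seq.int(pk, 2)) {
    if (values[i - 1] <= half) {
      left <- coords[i - 1] + (half - values[i - 1]) /
        (values[i] - values[i - 1]) * (coords[i] - coords[i - 1])
      break
    }
  }
  right <- NA_real_
  for (i in seq.int(pk, length(values) - 1)) {
    if (values[i + 1] <= half) {
      right <- coords[i] + (values[i] - half) /
        (values[i] - values[i + 1]) * (coords[i + 1] - coords[i])
      break
    }
  }
  right - left
}
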