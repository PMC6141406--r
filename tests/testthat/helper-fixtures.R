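# Small fixtures shared across test files; everything is generated in code.

# Compact IQ phantom on a 3 mm grid (full cross-section, reduced axial extent)
smallIQ <- function(voxel = c(3, 3, 3), matrix = c(96, 96, 16), ...) {
  generateIQPhantom(phantomSpec(voxelSize = voxel, matrixSize = matrix, ...))
}

# Uniform disc image (single- or multi-slice), centred in the FOV
discImage <- function(n = 64, voxel = 3, radius = 50, value = 5, nslice = 1,
                      sliceThickness = voxel) {
  co <- (seq_len(n) - 1 - (n - 1) / 2) * voxel
  m2 <- outer(co^2, co^2, `+`) <= radius^2
  a <- array(0, c(n, n, nslice))
  for (s in seq_len(nslice)) a[, , s][m2] <- value
  new("ActivityImage", data = a, voxelSize = c(voxel, voxel, sliceThickness))
}

discMask <- function(n, voxel, radius) {
  co <- (seq_len(n) - 1 - (n - 1) / 2) * voxel
  outer(co^2, co^2, `+`) <= radius^2
}

# All-ones attenuation factors matching a sinogram (no attenuation)
unitAttn <- function(sino) {
  new("AttenuationFactors", data = array(1, dim(sino@data)[1:3]),
      binSize = sino@binSize, sliceThickness = sino@sliceThickness,
      angles = sino@angles)
}

zeroSino <- function(sino) {
  new("Sinogram", data = array(0, dim(sino@data)[1:3]),
      binSize = sino@binSize, sliceThickness = sino@sliceThickness,
      angles = sino@angles)
}

# Noise-free projection set with the additive estimates consistent with the
# prompts (for reconstruction tests on deterministic data)
noiseFreeCase <- function(dro, ..., params = NULL) {
  if (is.null(params)) params <- simulationParams(...)
  ps <- simulateNoiseFree(dro, params)
  list(ps = ps,
       countScale = params@sensitivityFactor * params@scanDuration *
         params@decayFactor)
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / max(abs(expected), .Machine$double.eps), tol)
}
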