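# Slice-wise 2D projector.
#
# The system model is a ray-driven line-integral operator with bilinear
# interpolation, assembled once per (matrix size, voxel size) geometry as a
# sparse matrix A of dimension (128 angles * n bins) x n^2. Forward projection
# is A %*% x and back projection is t(A) %*% y, so the pair is an exact
# adjoint — the property OSEM requires. Angles are uniform over [0, pi),
# half-open; radial bin spacing equals the transaxial voxel size; line
# integrals carry units value*mm.

N_ANGLES <- 128L

.projCache <- new.env(parent = emptyenv())

projectionAngles <- function() (seq_len(N_ANGLES) - 1) / N_ANGLES * pi

# Build (or fetch) the projection model for an n x n grid with transaxial
# voxel size `voxel` (mm). Returns an environment with the sparse matrix A,
# lazily split per-angle rows, and geometry.
projectionModel <- function(n, voxel) {
  key <- sprintf("n%d_v%.6g", n, voxel)
  if (!is.null(.projCache[[key]])) return(.projCache[[key]])
  angles <- projectionAngles()
  R <- n * voxel / 2
  s <- axisCoords(n, voxel)                  # radial bin centres
  tt <- seq(-R, R, by = voxel)               # sample positions along rays
  m <- length(tt)
  triplets <- vector("list", N_ANGLES)
  for (a in seq_len(N_ANGLES)) {
    ca <- cos(angles[a]); sa <- sin(angles[a])
    # ray for bin j: p(t) = s_j * (ca, sa) + t * (-sa, ca)
    px <- outer(s * ca, -tt * sa, `+`)       # [bin, sample]
    py <- outer(s * sa,  tt * ca, `+`)
    fx <- px / voxel + (n - 1) / 2
    fy <- py / voxel + (n - 1) / 2
    keep <- fx >= 0 & fx <= n - 1 & fy >= 0 & fy <= n - 1
    if (!any(keep)) next
    bin <- rep(seq_len(n), times = m)[keep]
    fx <- fx[keep]; fy <- fy[keep]
    ix <- pmin(floor(fx), n - 2); iy <- pmin(floor(fy), n - 2)
    wx <- fx - ix; wy <- fy - iy
    row <- (a - 1L) * n + bin
    # 4 bilinear corners; column index is 1-based x + n*(y)
    c00 <- ix + 1L + n * iy
    triplets[[a]] <- list(
      i = c(row, row, row, row),
      j = c(c00, c00 + 1L, c00 + n, c00 + n + 1L),
      x = voxel * c((1 - wx) * (1 - wy), wx * (1 - wy),
                    (1 - wx) * wy, wx * wy))
  }
  A <- Matrix::sparseMatrix(
    i = unlist(lapply(triplets, `[[`, "i")),
    j = unlist(lapply(triplets, `[[`, "j")),
    x = unlist(lapply(triplets, `[[`, "x")),
    dims = c(N_ANGLES * n, n * n))
  model <- new.env(parent = emptyenv())
  model$A <- A
  model$n <- n
  model$voxel <- voxel
  model$angles <- angles
  model$byAngle <- NULL   # per-angle row blocks, built on demand (TOF path)
  .projCache[[key]] <- model
  model
}

modelAngleBlocks <- function(model) {
  if (is.null(model$byAngle)) {
    n <- model$n
    model$byAngle <- lapply(seq_len(N_ANGLES), function(a)
      model$A[(a - 1L) * n + seq_len(n), , drop = FALSE])
  }
  model$byAngle
}

checkProjectable <- function(img) {
  d <- dim(img@data)
  if (d[1] != d[2])
    stop("projection requires a square transaxial matrix, got ",
         d[1], " x ", d[2])
  if (abs(img@voxelSize[1] - img@voxelSize[2]) > 1e-9)
    stop("projection requires isotropic in-plane voxels")
  if (any(!is.finite(img@data)))
    stop("image contains non-finite voxels")
}

# Rearrange [slice, angle, bin] <-> row-major (angle-major rows) matrices.
sinoToMat <- function(data) {
  d <- dim(data)
  matrix(aperm(data, c(3, 2, 1)), nrow = d[2] * d[3], ncol = d[1])
}
matToSino <- function(m, nslice, n) {
  aperm(array(as.matrix(m), c(n, N_ANGLES, nslice)), c(3, 2, 1))
}

#' Forward project an image into stacked sinograms
#'
#' Slice-wise 2D Radon transform over 128 angles; line integrals in units
#' value*mm. The radial bin count equals the transaxial matrix size.
#'
#' @param img a [VoxelImage-class] with non-negative values
#' @return a [Sinogram-class] \code{[slice, angle, bin]}
#' @export
forwardProject <- function(img) {
  checkProjectable(img)
  if (min(img@data) < -1e-9) stop("image must be non-negative")
  d <- dim(img@data)
  model <- projectionModel(d[1], img@voxelSize[1])
  X <- matrix(img@data, nrow = d[1] * d[2], ncol = d[3])
  Y <- model$A %*% X
  new("Sinogram",
      data = matToSino(Y, d[3], d[1]),
      binSize = img@voxelSize[1],
      sliceThickness = img@voxelSize[3],
      angles = model$angles)
}

#' Back project stacked sinograms (exact adjoint of [forwardProject()])
#'
#' This is the unfiltered adjoint operator required by the OSEM update, not a
#' filtered backprojection reconstruction.
#'
#' @param sino a [Sinogram-class]
#' @return an [ActivityImage-class] on the matching grid
#' @export
backProject <- function(sino) {
  stopifnot(is(sino, "Sinogram"))
  if (any(!is.finite(sino@data))) stop("sinogram contains non-finite values")
  d <- dim(sino@data)
  n <- d[3]
  model <- projectionModel(n, sino@binSize)
  X <- Matrix::crossprod(model$A, sinoToMat(sino@data))
  new("ActivityImage",
      data = array(as.matrix(X), c(n, n, d[1])),
      voxelSize = c(sino@binSize, sino@binSize, sino@sliceThickness))
}

# TOF weight matrix for one angle: [n^2 voxels x n TOF bins]; entry (v, t) is
# the probability that an emission in voxel v is recorded in TOF bin t.
# Kernel: Gaussian of spatial FWHM c*dt/2 centred at the voxel's coordinate
# along the ray, truncated at +/- 4 sigma and renormalised per voxel so the
# TOF axis marginalises exactly to the non-TOF projection.
tofWeights <- function(model, angleIdx, tofFwhmPs) {
  n <- model$n; voxel <- model$voxel
  sigma <- tofKernelFwhmMm(tofFwhmPs) * FWHM_TO_SIGMA
  co <- axisCoords(n, voxel)
  ca <- cos(model$angles[angleIdx]); sa <- sin(model$angles[angleIdx])
  # coordinate along the ray direction (-sa, ca) for every voxel
  u <- outer(-co * sa, co * ca, `+`)         # [x, y]
  centers <- co                              # TOF bin centres along the ray
  W <- exp(-outer(as.vector(u), centers, `-`)^2 / (2 * sigma^2))
  W[W < exp(-8)] <- 0                        # truncate at 4 sigma
  rs <- rowSums(W)
  zero <- rs == 0
  if (any(zero)) {
    nearest <- pmin(pmax(round(as.vector(u)[zero] / voxel + (n + 1) / 2), 1), n)
    W[cbind(which(zero), nearest)] <- 1
    rs[zero] <- 1
  }
  W / rs
}

#' Forward project with time-of-flight binning
#'
#' Distributes the activity along each ray into TOF bins with a 1D Gaussian of
#' spatial FWHM c*dt/2 centred at the emission position along the line of
#' response. The TOF-bin axis has the same length as the radial axis and bin
#' spacing equal to the radial field of view divided by the matrix size.
#' Summing over the TOF axis reproduces [forwardProject()] exactly (the
#' truncated kernels are renormalised).
#'
#' @param img a [VoxelImage-class]
#' @param tofFwhmPs timing resolution delta-t in picoseconds (> 0)
#' @return a [TOFSinogram-class] \code{[slice, angle, bin, tof]}
#' @export
forwardProjectTOF <- function(img, tofFwhmPs) {
  if (!is.numeric(tofFwhmPs) || is.na(tofFwhmPs) || tofFwhmPs <= 0)
    stop("tofFwhmPs must be a positive timing resolution in ps")
  checkProjectable(img)
  d <- dim(img@data)
  n <- d[1]; nslice <- d[3]
  model <- projectionModel(n, img@voxelSize[1])
  blocks <- modelAngleBlocks(model)
  X <- matrix(img@data, nrow = n * n, ncol = nslice)
  out <- array(0, c(nslice, N_ANGLES, n, n))
  for (a in seq_len(N_ANGLES)) {
    W <- tofWeights(model, a, tofFwhmPs)
    for (s in seq_len(nslice)) {
      out[s, a, , ] <- as.matrix(blocks[[a]] %*% (W * X[, s]))
    }
  }
  new("TOFSinogram",
      data = out,
      binSize = img@voxelSize[1],
      sliceThickness = img@voxelSize[3],
      angles = model$angles,
      tofFwhmPs = tofFwhmPs,
      tofBinSize = img@voxelSize[1])
}

#' Collapse a TOF sinogram over the TOF axis
#' @param sino a [TOFSinogram-class]
#' @return the marginal non-TOF [Sinogram-class]
#' @export
collapseTOF <- function(sino) {
  stopifnot(is(sino, "TOFSinogram"))
  d <- dim(sino@data)
  new("Sinogram",
      data = array(rowSums(matrix(sino@data, prod(d[1:3]), d[4])), d[1:3]),
      binSize = sino@binSize, sliceThickness = sino@sliceThickness,
      angles = sino@angles)
}

#' Smooth an image with the system point-spread function
#'
#' Gaussian convolution simulating the spatial resolution of the scanner
#' (and, if chosen larger, positron range). Total activity of interior objects
#' is conserved (kernels are normalised; only mass blurred off the grid is
#' lost). A zero FWHM on any axis is the identity on that axis.
#'
#' @param img an [ActivityImage-class] (any [VoxelImage-class] accepted)
#' @param fwhm Gaussian FWHM in mm, scalar or per-axis 3-vector; all >= 0
#' @return the smoothed image
#' @export
smoothSystemPSF <- function(img, fwhm) {
  fwhm <- rep(as.numeric(fwhm), length.out = 3)
  if (any(fwhm < 0)) stop("fwhm must be >= 0 per axis")
  out <- img
  out@data <- gaussianBlur3D(img@data, fwhm, img@voxelSize)
  out
}

# Carney-style 120 kVp bilinear scaling constants (cm^-1); continuous at the
# breakpoint with the soft-tissue segment through (-1000 HU, 0).
CT_SOFT_SLOPE <- 9.6e-5
CT_BREAK_HU <- 47
CT_BONE_SLOPE <- 5.10e-5
CT_BONE_INTERCEPT <- 0.0471

#' Convert a CT image (HU) to 511 keV attenuation coefficients
#'
#' Piecewise-linear (bilinear) scaling assuming 120 kVp CT data: a soft-tissue
#' segment through (-1000 HU, 0 cm^-1) up to the breakpoint, and a shallower
#' bone segment above it. Monotone non-decreasing and non-negative; input is
#' clipped below -1024 HU.
#'
#' @param ct a [CTImage-class] in Hounsfield units
#' @param softSlope soft-tissue slope per (HU + 1000), cm^-1
#' @param breakHU breakpoint in HU
#' @param boneSlope,boneIntercept bone segment mu = boneSlope*(HU+1000) +
#'   boneIntercept, cm^-1
#' @return an [AttenuationMap-class] in cm^-1
#' @export
ctToMu <- function(ct, softSlope = CT_SOFT_SLOPE, breakHU = CT_BREAK_HU,
                   boneSlope = CT_BONE_SLOPE, boneIntercept = CT_BONE_INTERCEPT) {
  stopifnot(is(ct, "VoxelImage"))
  hu <- pmax(ct@data, -1024)
  mu <- ifelse(hu <= breakHU,
               softSlope * (hu + 1000),
               boneSlope * (hu + 1000) + boneIntercept)
  mu <- pmax(mu, 0)
  new("AttenuationMap", data = array(mu, dim(ct@data)), voxelSize = ct@voxelSize)
}

#' Attenuation survival factors from an attenuation map
#'
#' Forward projects mu (cm^-1) and applies exp(-integral), with the line
#' integral converted from mm to cm. Factors are 1 wherever the line integral
#' is zero.
#'
#' @param mu an [AttenuationMap-class] (cm^-1, non-negative)
#' @return [AttenuationFactors-class] indexed like a [Sinogram-class]
#' @export
attenuationFactors <- function(mu) {
  stopifnot(is(mu, "VoxelImage"))
  if (min(mu@data) < -1e-9) stop("attenuation coefficients must be >= 0")
  p <- forwardProject(mu)
  new("AttenuationFactors",
      data = exp(-0.1 * p@data),
      binSize = p@binSize, sliceThickness = p@sliceThickness,
      angles = p@angles)
}
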