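# Ordinary-Poisson OSEM reconstruction with optional TOF and resolution
# modelling, plus post-reconstruction Gaussian filtering and reblurred
# Van-Cittert deconvolution.

#' Construct reconstruction parameters
#'
#' @param matrixChoice `"ORG"` (reconstruct on the input grid) or one of
#'   `"128"`, `"170"`, `"256"`, `"400"` — matrix sizes with implied transaxial
#'   voxel sizes of 4, 3, 2 and 1.3 mm (the slice thickness of the input is
#'   kept). The resampling is applied by the pipeline before simulation.
#' @param iterations OSEM iterations (default 4)
#' @param subsets OSEM subsets (default 16); must divide the 128 angles
#' @param tofFwhmPs TOF kernel width for the reconstruction model (ps); NA
#'   matches the prompts' own timing resolution
#' @param rmFWHM resolution-modelling FWHM in mm (scalar or 3-vector); NA or
#'   NULL disables RM
#' @param postFilterFWHM post-reconstruction Gaussian FWHM in mm (0 = off)
#' @param vanCittert logical; apply reblurred Van-Cittert deconvolution
#' @param vcIterations deconvolution iterations (default 10)
#' @param vcFWHM deconvolution kernel FWHM in mm
#' @param vcAlpha relaxation factor (classical value 1)
#' @return a [ReconParams-class]
#' @export
reconParams <- function(matrixChoice = "ORG", iterations = 4L, subsets = 16L,
                        tofFwhmPs = NA_real_, rmFWHM = NULL,
                        postFilterFWHM = 0, vanCittert = FALSE,
                        vcIterations = 10L, vcFWHM = 5, vcAlpha = 1) {
  if (is.null(rmFWHM)) rmFWHM <- rep(NA_real_, 3)
  new("ReconParams",
      matrixChoice = as.character(matrixChoice),
      iterations = as.integer(iterations),
      subsets = as.integer(subsets),
      tofFwhmPs = as.numeric(tofFwhmPs),
      rmFWHM = rep(as.numeric(rmFWHM), length.out = 3),
      postFilterFWHM = postFilterFWHM,
      vcEnabled = isTRUE(vanCittert),
      vcIterations = as.integer(vcIterations),
      vcFWHM = vcFWHM,
      vcAlpha = vcAlpha)
}

#' Transaxial voxel size implied by a matrix choice
#' @param matrixChoice one of "128", "170", "256", "400"
#' @return voxel size in mm
#' @export
matrixChoiceVoxel <- function(matrixChoice) {
  switch(matrixChoice,
         "128" = 4, "170" = 3, "256" = 2, "400" = 1.3,
         stop("no implied voxel size for matrix choice ", matrixChoice))
}

OSEM_EPS <- 1e-12
SENS_MASK_REL <- 1e-8

#' Ordinary-Poisson OSEM reconstruction
#'
#' Multiplicative OP-OSEM with angle-stride subsets (subset k takes angles k,
#' k+subsets, ...). The update for subset S is
#' x <- x / sens_S * H'_S\[ a y / (a H_S x + s + r) \], with attenuation
#' factors a as weights, scatter/randoms estimates s, r as additive terms,
#' sens_S = H'_S(a), and H including the resolution-modelling convolution
#' and/or TOF binning when enabled. The image is initialised uniform inside
#' the reconstruction FOV circle; voxels with negligible sensitivity are
#' masked to zero.
#'
#' @param prompts noisy counts, a [Sinogram-class] or [TOFSinogram-class]
#' @param attn [AttenuationFactors-class] used for weighting
#' @param scatterEst,randomsEst additive term estimates ([Sinogram-class])
#' @param params a [ReconParams-class]
#' @return the reconstructed [ActivityImage-class] (no post-filtering; see
#'   [postFilter()] and [vanCittertDeconvolve()])
#' @export
osemReconstruct <- function(prompts, attn, scatterEst, randomsEst, params) {
  stopifnot(is(prompts, "Sinogram"), is(attn, "AttenuationFactors"),
            is(params, "ReconParams"))
  validObject(params)
  d <- dim(prompts@data)
  nslice <- d[1]; n <- d[3]
  if (!identical(dim(attn@data)[1:3], d[1:3]) ||
      !identical(dim(scatterEst@data)[1:3], d[1:3]) ||
      !identical(dim(randomsEst@data)[1:3], d[1:3]))
    stop("prompts, attenuation and additive estimates are dimensionally inconsistent")
  tof <- is(prompts, "TOFSinogram")
  model <- projectionModel(n, prompts@binSize)
  nsub <- params@subsets
  subsetAngles <- lapply(seq_len(nsub), function(k) seq.int(k, N_ANGLES, by = nsub))
  vox <- c(prompts@binSize, prompts@binSize, prompts@sliceThickness)
  useRM <- all(is.finite(params@rmFWHM)) && any(params@rmFWHM > 0)
  blurRM <- function(xmat) {
    a <- array(xmat, c(n, n, nslice))
    matrix(gaussianBlur3D(a, params@rmFWHM, vox), n * n, nslice)
  }

  # FOV circle mask
  co <- axisCoords(n, prompts@binSize)
  fov <- as.vector(outer(co^2, co^2, `+`) <= (n * prompts@binSize / 2)^2)

  aMat <- sinoToMat(attn@data)                     # [rows x slice]
  addMat <- sinoToMat(scatterEst@data + randomsEst@data)
  rowsOf <- function(angles) as.vector(outer(seq_len(n), (angles - 1L) * n, `+`))

  # per-subset operator blocks and sensitivity images sens_S = H'_S(a)
  Asub <- vector("list", nsub)
  aSub <- vector("list", nsub)
  addSub <- vector("list", nsub)
  ySub <- if (!tof) vector("list", nsub) else NULL
  yMat <- if (!tof) sinoToMat(prompts@data) else NULL
  sens <- vector("list", nsub)
  for (k in seq_len(nsub)) {
    rows <- rowsOf(subsetAngles[[k]])
    Asub[[k]] <- model$A[rows, , drop = FALSE]
    aSub[[k]] <- aMat[rows, , drop = FALSE]
    addSub[[k]] <- addMat[rows, , drop = FALSE]
    if (!tof) ySub[[k]] <- yMat[rows, , drop = FALSE]
    s <- as.matrix(Matrix::crossprod(Asub[[k]], aSub[[k]]))
    if (useRM) s <- blurRM(s)
    sens[[k]] <- s
  }
  sensMax <- max(vapply(sens, max, numeric(1)))
  alive <- fov & (Reduce(pmin, lapply(sens, function(s) apply(s, 1, min))) >
                    SENS_MASK_REL * sensMax)

  x <- matrix(0, n * n, nslice)
  x[alive, ] <- 1

  if (tof) {
    ntof <- d[4]
    tofPs <- if (!is.na(params@tofFwhmPs)) params@tofFwhmPs else prompts@tofFwhmPs
    blocks <- modelAngleBlocks(model)
    Wcache <- vector("list", N_ANGLES)
    getW <- function(a) {
      if (is.null(Wcache[[a]])) Wcache[[a]] <<- tofWeights(model, a, tofPs)
      Wcache[[a]]
    }
    addTof <- (scatterEst@data + randomsEst@data) / ntof  # [slice, angle, bin]
  }

  for (it in seq_len(params@iterations)) {
    for (k in seq_len(nsub)) {
      angles <- subsetAngles[[k]]
      xb <- if (useRM) blurRM(x) else x
      if (!tof) {
        proj <- as.matrix(Asub[[k]] %*% xb)
        den <- aSub[[k]] * proj + addSub[[k]] + OSEM_EPS
        ratio <- aSub[[k]] * ySub[[k]] / den
        bp <- as.matrix(Matrix::crossprod(Asub[[k]], ratio))
      } else {
        bp <- matrix(0, n * n, nslice)
        for (a in angles) {
          W <- getW(a)
          Ablk <- blocks[[a]]
          for (s in seq_len(nslice)) {
            proj <- as.matrix(Ablk %*% (W * xb[, s]))        # [bin x tof]
            av <- attn@data[s, a, ]
            den <- av * proj + addTof[s, a, ] + OSEM_EPS     # recycles over tof
            ratio <- av * prompts@data[s, a, , ] / den
            bp[, s] <- bp[, s] + rowSums(W * as.matrix(Matrix::crossprod(Ablk, ratio)))
          }
        }
      }
      if (useRM) bp <- blurRM(bp)
      xn <- x * bp / sens[[k]]
      xn[!alive, ] <- 0
      xn[!is.finite(xn)] <- 0
      x <- xn
    }
  }
  new("ActivityImage", data = array(x, c(n, n, nslice)), voxelSize = vox)
}

#' Post-reconstruction Gaussian filter
#'
#' @param img an [ActivityImage-class]
#' @param fwhm isotropic Gaussian FWHM in mm (0 is the identity)
#' @return the filtered image
#' @export
postFilter <- function(img, fwhm) {
  if (fwhm < 0) stop("fwhm must be >= 0")
  if (fwhm == 0) return(img)
  smoothSystemPSF(img, fwhm)
}

#' Reblurred Van-Cittert deconvolution
#'
#' Iterates f <- f + alpha * h (x) (g - h (x) f) with h a Gaussian of the
#' given FWHM and f0 = g, for `nIter` iterations (default 10); negative values
#' are clipped to zero after the final iteration. Aborts if the iterate norm
#' grows beyond 10x the input (divergence guard).
#'
#' @param img the reconstructed [ActivityImage-class] g
#' @param kernelFWHM deconvolution kernel FWHM in mm (0 is the identity)
#' @param nIter number of iterations (default 10)
#' @param alpha relaxation factor (default 1, classical Van-Cittert)
#' @return the deconvolved image
#' @export
vanCittertDeconvolve <- function(img, kernelFWHM, nIter = 10L, alpha = 1) {
  stopifnot(nIter >= 1)
  if (kernelFWHM < 0) stop("kernelFWHM must be >= 0")
  if (kernelFWHM == 0 || alpha == 0) return(img)
  g <- img@data
  f <- g
  g0 <- sqrt(sum(g^2))
  for (i in seq_len(nIter)) {
    r <- g - gaussianBlur3D(f, kernelFWHM, img@voxelSize)
    f <- f + alpha * gaussianBlur3D(r, kernelFWHM, img@voxelSize)
    if (sqrt(sum(f^2)) > 10 * g0)
      stop("Van-Cittert deconvolution diverged (iterate norm grew > 10x)")
  }
  out <- img
  out@data <- pmax(f, 0)
  out
}

# Post-reconstruction chain driven by ReconParams (used by the pipeline).
applyPostProcessing <- function(img, params) {
  if (params@postFilterFWHM > 0) img <- postFilter(img, params@postFilterFWHM)
  if (params@vcEnabled)
    img <- vanCittertDeconvolve(img, params@vcFWHM, params@vcIterations,
                                params@vcAlpha)
  img
}

# Poisson log-likelihood of counts y under the current image estimate
# (monitoring/diagnostics; OSEM itself does not evaluate it).
poissonLogLik <- function(prompts, attn, scatterEst, randomsEst, img,
                          rmFWHM = NULL) {
  xb <- img
  if (!is.null(rmFWHM) && all(is.finite(rmFWHM)) && any(rmFWHM > 0))
    xb@data <- gaussianBlur3D(img@data, rmFWHM, img@voxelSize)
  p <- forwardProject(xb)
  lambda <- attn@data * p@data + scatterEst@data + randomsEst@data
  y <- if (is(prompts, "TOFSinogram")) collapseTOF(prompts)@data else prompts@data
  keep <- lambda > 0
  sum(y[keep] * log(lambda[keep])) - sum(lambda)
}
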