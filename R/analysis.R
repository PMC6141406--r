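# Quantitative evaluation: background COV, recovery coefficients, replicate
# mean/SD images, theoretical COV predictors and sensitivity calibration.

#' Build the IQ-phantom analysis ROI set
#'
#' Sphere ROIs are exact geometric masks at the known phantom positions (no
#' image-based segmentation). Background ROIs are `nROIs` spheres of radius
#' `radius` placed at deterministic pseudo-random positions inside the torso
#' (eroded in-plane by the ROI radius), at least `margin` mm away from every
#' hot sphere surface. On grids with a reduced axial extent the background
#' ROIs may be clipped by the image; their voxels are pooled as available.
#'
#' @param dro a [DROPair-class] from [generateIQPhantom()] (its provenance
#'   provides sphere positions and grid)
#' @param radius background ROI radius in mm (default 30)
#' @param nROIs number of background ROIs (default 6)
#' @param margin minimum gap between ROI surface and sphere surface, mm
#' @param seed fixed seed for the reproducible "random" placement
#' @return an [ROISet-class]
#' @export
iqROISet <- function(dro, radius = 30, nROIs = 6L, margin = 10, seed = 42L) {
  stopifnot(is(dro, "DROPair"))
  prov <- dro@provenance
  if (!identical(prov$kind, "nema-iq"))
    stop("iqROISet requires an IQ-phantom DRO with generator provenance")
  centers <- prov$sphereCenters
  diam <- prov$sphereDiameters
  vox <- dro@activity@voxelSize
  dims <- dim(dro@activity@data)
  zHalf <- min(dims[3] * vox[3], prov$axialLength) / 2
  lung <- isTRUE(prov$spec@lungInsert)
  pick <- withLocalSeed(seed, {
    cand <- cbind(runif(20000, -(TORSO_RECT_HALF + TORSO_RADIUS),
                        TORSO_RECT_HALF + TORSO_RADIUS),
                  runif(20000, -TORSO_RADIUS, TORSO_RADIUS),
                  runif(20000, -zHalf, zHalf))
    ok <- inTorso2D(cand[, 1], cand[, 2], erodeBy = radius)
    if (lung)
      ok <- ok & sqrt(cand[, 1]^2 + cand[, 2]^2) >= LUNG_INSERT_RADIUS + radius + margin
    for (i in seq_len(nrow(centers))) {
      d2 <- (cand[, 1] - centers[i, 1])^2 + (cand[, 2] - centers[i, 2])^2 +
        (cand[, 3] - centers[i, 3])^2
      ok <- ok & d2 >= (diam[i] / 2 + radius + margin)^2
    }
    cand[ok, , drop = FALSE]
  })
  if (nrow(pick) < nROIs)
    stop("could not place ", nROIs, " background ROIs of radius ", radius,
         " mm with a ", margin, " mm sphere margin on this grid; found ",
         nrow(pick))
  new("ROISet",
      sphereCenters = centers,
      sphereDiameters = diam,
      bgCenters = pick[seq_len(nROIs), , drop = FALSE],
      bgRadius = radius)
}

# scalar/vector in-torso test used by the ROI placer
inTorso2D <- function(x, y, erodeBy = 0) {
  R <- TORSO_RADIUS - erodeBy
  (abs(x) <= TORSO_RECT_HALF & abs(y) <= R) |
    (abs(x) > TORSO_RECT_HALF & (abs(x) - TORSO_RECT_HALF)^2 + y^2 <= R^2)
}

#' Manually specified ROI set
#'
#' For non-IQ objects (e.g. a uniform cylinder) where the caller knows valid
#' background positions.
#'
#' @param bgCenters numeric matrix (m x 3) of background ROI centres, mm
#' @param bgRadius background ROI radius, mm
#' @param sphereCenters optional numeric matrix (n x 3) of sphere centres, mm
#' @param sphereDiameters sphere diameters matching `sphereCenters`, mm
#' @return an [ROISet-class]
#' @export
roiSet <- function(bgCenters, bgRadius, sphereCenters = NULL,
                   sphereDiameters = numeric(0)) {
  if (is.null(sphereCenters)) sphereCenters <- matrix(numeric(0), 0, 3)
  new("ROISet", sphereCenters = as.matrix(sphereCenters),
      sphereDiameters = as.numeric(sphereDiameters),
      bgCenters = as.matrix(bgCenters), bgRadius = bgRadius)
}

# Pooled background voxel values (concatenated over ROIs; overlapping ROIs
# contribute their voxels once per ROI, matching per-ROI pooling).
pooledBackground <- function(img, rois) {
  dims <- dim(img@data)
  vox <- img@voxelSize
  vals <- c()
  for (i in seq_len(nrow(rois@bgCenters))) {
    m <- sphereMask(dims, vox, rois@bgCenters[i, ], rois@bgRadius)
    vals <- c(vals, img@data[m])
  }
  vals
}

#' Background coefficient of variation
#'
#' COV = SD / mean over the pooled voxels of the background ROIs — the image
#' noise metric. The population SD is used (divisor N).
#'
#' @param img an [ActivityImage-class]
#' @param rois an [ROISet-class]
#' @return the COV (dimensionless, >= 0)
#' @export
backgroundCOV <- function(img, rois) {
  stopifnot(is(img, "VoxelImage"), is(rois, "ROISet"))
  v <- pooledBackground(img, rois)
  if (!length(v)) stop("background ROIs contain no voxels inside the image")
  m <- mean(v)
  if (m == 0) stop("background ROI mean is zero; COV undefined")
  sqrt(mean((v - m)^2)) / m
}

#' Sphere recovery coefficients
#'
#' Mean and maximum value within each sphere ROI divided by the expected
#' (true) activity concentration. Quantifies partial-volume losses; RC_max is
#' always >= RC_mean.
#'
#' @param img an [ActivityImage-class]
#' @param rois an [ROISet-class] with sphere ROIs
#' @param expected the true sphere activity concentration (> 0), kBq/mL
#' @return list with `rcMean` and `rcMax`, one value per sphere (in the
#'   ROI-set's sphere order)
#' @export
recoveryCoefficients <- function(img, rois, expected) {
  stopifnot(expected > 0, nrow(rois@sphereCenters) > 0)
  dims <- dim(img@data)
  vox <- img@voxelSize
  ns <- nrow(rois@sphereCenters)
  rcMean <- rcMax <- numeric(ns)
  for (i in seq_len(ns)) {
    m <- sphereMask(dims, vox, rois@sphereCenters[i, ], rois@sphereDiameters[i] / 2)
    if (!any(m)) stop("sphere ", i, " lies outside the image")
    v <- img@data[m]
    rcMean[i] <- mean(v) / expected
    rcMax[i] <- max(v) / expected
  }
  list(rcMean = rcMean, rcMax = rcMax)
}

#' Voxelwise mean and SD images of a replicate stack
#'
#' @param stack a [ReplicateStack-class] with >= 2 replicates
#' @return list with `meanImage` and `sdImage` (sample SD, divisor N-1)
#' @export
replicateStatistics <- function(stack) {
  stopifnot(is(stack, "ReplicateStack"))
  d <- dim(stack@images)
  nrep <- d[4]
  if (nrep < 2L) stop("at least 2 replicates are required")
  m <- matrix(stack@images, prod(d[1:3]), nrep)
  mu <- rowMeans(m)
  ss <- rowSums((m - mu)^2) / (nrep - 1)
  list(meanImage = new("ActivityImage", data = array(mu, d[1:3]),
                       voxelSize = stack@voxelSize),
       sdImage = new("ActivityImage", data = array(sqrt(ss), d[1:3]),
                     voxelSize = stack@voxelSize))
}

#' Expected COV after a change of scan duration
#'
#' COV_t2 = sqrt(t1 / t2) * COV_t1: counting statistics predict the background
#' COV to scale with the inverse square root of the scan duration.
#'
#' @param cov1 COV observed at duration `t1`
#' @param t1,t2 scan durations in seconds (> 0)
#' @return the predicted COV at `t2`
#' @export
expectedCOVScaling <- function(cov1, t1, t2) {
  if (t1 <= 0 || t2 <= 0) stop("durations must be positive")
  if (cov1 < 0) stop("COV must be >= 0")
  sqrt(t1 / t2) * cov1
}

#' Expected TOF SNR gain
#'
#' For a cylindrical object of diameter D, TOF reconstruction reduces the
#' background COV by sqrt(c * dt / (2 D)); the SNR gain is the reciprocal,
#' sqrt(2 D / (c * dt)).
#'
#' @param tofFwhmPs timing resolution delta-t in ps (> 0)
#' @param diameterM object diameter D in metres (> 0; default 0.27)
#' @return the expected SNR gain (dimensionless)
#' @export
expectedTOFGain <- function(tofFwhmPs, diameterM = 0.27) {
  if (tofFwhmPs <= 0 || diameterM <= 0) stop("inputs must be positive")
  sqrt(2 * diameterM / (SPEED_OF_LIGHT * tofFwhmPs * 1e-12))
}

#' Calibrate the sensitivity factor to a target background COV
#'
#' Searches the sensitivity factor until the mean background COV over
#' `nCalibrationReplicates` reconstructed replicates is within `tol`
#' (relative) of `targetCOV`. Expected counts are linear in the factor, so the
#' noise-free projection is computed once and rescaled per trial; the search
#' itself is a damped fixed-point iteration on the counting-statistics
#' relation COV ~ factor^(-1/2) (monotone decreasing: a higher factor means a
#' higher sensitivity and less percentage noise).
#'
#' @param dro a [DROPair-class]
#' @param targetCOV the COV to match (> 0)
#' @param simParams a [SimulationParams-class]; its `sensitivityFactor` is the
#'   starting guess and its seed drives the calibration noise draws
#' @param reconParams a [ReconParams-class]
#' @param rois an [ROISet-class]; defaults to [iqROISet()] of the DRO
#' @param nCalibrationReplicates replicates per COV evaluation (default 3)
#' @param tol relative tolerance on the achieved COV (default 0.05)
#' @param maxEval maximum COV evaluations before giving up
#' @param bounds admissible factor range
#' @return list with `sensitivityFactor`, `achievedCOV` and the search
#'   `history` (data.frame of factor, cov)
#' @export
calibrateSensitivity <- function(dro, targetCOV, simParams, reconParams,
                                 rois = NULL, nCalibrationReplicates = 3L,
                                 tol = 0.05, maxEval = 8L,
                                 bounds = c(1e-7, 1e3)) {
  if (!is.numeric(targetCOV) || targetCOV <= 0)
    stop("targetCOV must be positive")
  if (is.null(rois)) rois <- iqROISet(dro)
  seed <- simParams@seed
  if (is.na(seed)) seed <- 20180918L %% .Machine$integer.max
  psBase <- simulateNoiseFree(dro, simParams)
  f0 <- simParams@sensitivityFactor
  evalCOV <- function(f) {
    ps <- scaleProjectionSet(psBase, f / f0)
    seeds <- withLocalSeed(seed + 1L, sample.int(.Machine$integer.max,
                                                 nCalibrationReplicates))
    covs <- vapply(seeds, function(s) {
      prompts <- addPoissonNoise(ps, seed = s)
      img <- osemReconstruct(prompts, ps@attenuation, ps@scatter, ps@randoms,
                             reconParams)
      img <- applyPostProcessing(img, reconParams)
      backgroundCOV(img, rois)
    }, numeric(1))
    mean(covs)
  }
  f <- f0
  hist <- data.frame(factor = numeric(0), cov = numeric(0))
  for (i in seq_len(maxEval)) {
    cv <- evalCOV(f)
    hist <- rbind(hist, data.frame(factor = f, cov = cv))
    if (abs(cv - targetCOV) <= tol * targetCOV)
      return(list(sensitivityFactor = f, achievedCOV = cv, history = hist))
    f <- f * (cv / targetCOV)^2
    if (f < bounds[1] || f > bounds[2])
      stop(sprintf(paste0("target COV %.4g outside the achievable range: ",
                          "achieved COVs in [%.4g, %.4g] for factors in ",
                          "[%.4g, %.4g]"),
                   targetCOV, min(hist$cov), max(hist$cov),
                   min(hist$factor), max(hist$factor)))
  }
  stop(sprintf(paste0("calibration did not converge in %d evaluations; ",
                      "achieved COVs in [%.4g, %.4g] (target %.4g)"),
               maxEval, min(hist$cov), max(hist$cov), targetCOV))
}

#' Analyse a replicate stack
#'
#' Computes the background COV per replicate (and its mean), the recovery
#' coefficients of the replicate-mean image, and the voxelwise mean/SD images.
#'
#' @param stack a [ReplicateStack-class]
#' @param rois an [ROISet-class]
#' @param expected true sphere activity for the RCs; NA skips RCs
#' @return an [AnalysisResult-class]
#' @export
analyzeReplicates <- function(stack, rois, expected = NA_real_) {
  stopifnot(is(stack, "ReplicateStack"), is(rois, "ROISet"))
  nrep <- dim(stack@images)[4]
  covs <- vapply(seq_len(nrep), function(i)
    backgroundCOV(getReplicate(stack, i), rois), numeric(1))
  st <- replicateStatistics(stack)
  if (!is.na(expected) && nrow(rois@sphereCenters) > 0) {
    rc <- recoveryCoefficients(st$meanImage, rois, expected)
  } else rc <- list(rcMean = numeric(0), rcMax = numeric(0))
  new("AnalysisResult",
      covPerReplicate = covs,
      covMean = mean(covs),
      rcMean = rc$rcMean,
      rcMax = rc$rcMax,
      meanImage = st$meanImage,
      sdImage = st$sdImage,
      params = list(scanDuration = stack@simParams@scanDuration,
                    tofFwhmPs = stack@simParams@tofFwhmPs,
                    expectedActivity = expected,
                    diameterM = 0.27))
}
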