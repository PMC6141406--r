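# Noise-free projection of a DRO into trues / scatter / randoms expectations,
# Poisson noise, repositioning and replicate generation.

#' Construct simulation parameters
#'
#' @param sensitivityFactor counts per (kBq/mL * mm * s); the global scale
#'   mapping projected activity and scan time to expected counts. Calibrate it
#'   with [calibrateSensitivity()] to match a physical scanner's noise.
#' @param scanDuration frame duration in seconds
#' @param randomsFraction simulated randoms / trues (uniform over projection
#'   space), in [0, 1]
#' @param scatterFraction simulated scatter / trues (100 mm FWHM blurred
#'   object, projected and attenuated), in [0, 1]
#' @param systemFWHM system resolution FWHM in mm (scalar or 3-vector;
#'   default 5 mm)
#' @param tofFwhmPs timing resolution in ps, or NA for non-TOF data
#' @param nReplicates number of noisy replicates (default 10)
#' @param seed master seed; NA draws one from the session RNG
#' @param maxShift maximum repositioning shift per axis, mm
#' @param ctMisalignment PET-CT misalignment (applied to the mu/CT map used
#'   for correction only), mm
#' @param decayFactor frame-level tracer decay scale on expected counts
#' @return a [SimulationParams-class]
#' @export
simulationParams <- function(sensitivityFactor = 0.005,
                             scanDuration = 120,
                             randomsFraction = 0.3,
                             scatterFraction = 0.35,
                             systemFWHM = 5,
                             tofFwhmPs = NA_real_,
                             nReplicates = 10L,
                             seed = NA_integer_,
                             maxShift = c(0, 0, 0),
                             ctMisalignment = c(0, 0, 0),
                             decayFactor = 1) {
  new("SimulationParams",
      sensitivityFactor = sensitivityFactor,
      scanDuration = scanDuration,
      randomsFraction = randomsFraction,
      scatterFraction = scatterFraction,
      systemFWHM = rep(as.numeric(systemFWHM), length.out = 3),
      tofFwhmPs = as.numeric(tofFwhmPs),
      nReplicates = as.integer(nReplicates),
      seed = as.integer(seed),
      maxShift = rep(as.numeric(maxShift), length.out = 3),
      ctMisalignment = rep(as.numeric(ctMisalignment), length.out = 3),
      decayFactor = decayFactor)
}

droMu <- function(dro) {
  if (is(dro@attenuation, "CTImage")) ctToMu(dro@attenuation) else dro@attenuation
}

#' Uniform randoms component
#'
#' Random coincidences are distributed uniformly over the projection space;
#' the total equals `randomsFraction * truesTotal` exactly.
#'
#' @param randomsFraction fraction in [0, 1]
#' @param truesTotal total expected true counts
#' @param like a [Sinogram-class] providing the target geometry
#' @return a constant [Sinogram-class]
#' @export
randomsComponent <- function(randomsFraction, truesTotal, like) {
  stopifnot(randomsFraction >= 0, randomsFraction <= 1)
  d <- dim(like@data)[1:3]
  new("Sinogram",
      data = array(randomsFraction * truesTotal / prod(d), d),
      binSize = like@binSize, sliceThickness = like@sliceThickness,
      angles = like@angles)
}

#' Scatter component
#'
#' The scatter distribution is the PSF-smoothed activity blurred with a
#' 100 mm FWHM Gaussian, forward projected and attenuated, then rescaled so
#' its total equals `scatterFraction * truesTotal` (the scatter fraction is
#' defined as scattered over true events).
#'
#' @param smoothedActivity the system-PSF-smoothed [ActivityImage-class]
#' @param attn [AttenuationFactors-class] on the matching geometry
#' @param scatterFraction fraction in [0, 1]
#' @param truesTotal total expected true counts
#' @param scatterKernelFWHM blur kernel FWHM in mm (default 100)
#' @return a [Sinogram-class]
#' @export
scatterComponent <- function(smoothedActivity, attn, scatterFraction,
                             truesTotal, scatterKernelFWHM = 100) {
  stopifnot(scatterFraction >= 0, scatterFraction <= 1)
  blurred <- smoothSystemPSF(smoothedActivity, scatterKernelFWHM)
  p <- forwardProject(blurred)
  sc <- p@data * attn@data
  tot <- sum(sc)
  target <- scatterFraction * truesTotal
  p@data <- if (tot > 0) sc * (target / tot) else array(0, dim(sc))
  p
}

#' Noise-free projection of a DRO
#'
#' Produces the expected-count model: trues = sensitivity x duration x decay x
#' attenuation x projection of the PSF-smoothed activity (TOF-resolved when
#' `tofFwhmPs` is set), plus the scatter and randoms expectations. Fully
#' deterministic.
#'
#' @param dro a [DROPair-class]; a CT attenuation image is converted with
#'   [ctToMu()]
#' @param params a [SimulationParams-class]
#' @param attnOverride optional [AttenuationMap-class] to use for the trues
#'   attenuation (repositioning truth), overriding the DRO's map
#' @return a [ProjectionSet-class]
#' @export
simulateNoiseFree <- function(dro, params, attnOverride = NULL) {
  stopifnot(is(dro, "DROPair"), is(params, "SimulationParams"))
  validObject(params)
  mu <- if (is.null(attnOverride)) droMu(dro) else attnOverride
  if (!identical(dim(dro@activity@data), dim(mu@data)))
    stop("activity and attenuation grids differ: ",
         paste(dim(dro@activity@data), collapse = "x"), " vs ",
         paste(dim(mu@data), collapse = "x"))
  scale <- params@sensitivityFactor * params@scanDuration * params@decayFactor
  sm <- smoothSystemPSF(dro@activity, params@systemFWHM)
  af <- attenuationFactors(mu)
  p <- forwardProject(sm)
  truesNonTof <- p@data * af@data * scale
  truesTotal <- sum(truesNonTof)
  if (!is.na(params@tofFwhmPs)) {
    ptof <- forwardProjectTOF(sm, params@tofFwhmPs)
    ptof@data <- ptof@data * as.vector(af@data) * scale  # recycles over TOF axis
    trues <- ptof
  } else {
    trues <- p
    trues@data <- truesNonTof
  }
  scatter <- scatterComponent(sm, af, params@scatterFraction, truesTotal)
  randoms <- randomsComponent(params@randomsFraction, truesTotal, p)
  new("ProjectionSet", trues = trues, scatter = scatter, randoms = randoms,
      attenuation = af, params = params)
}

# Rescale all expected-count components (linearity in the sensitivity factor;
# used by the calibration search).
scaleProjectionSet <- function(ps, k) {
  ps@trues@data <- ps@trues@data * k
  ps@scatter@data <- ps@scatter@data * k
  ps@randoms@data <- ps@randoms@data * k
  ps@params@sensitivityFactor <- ps@params@sensitivityFactor * k
  ps
}

#' Draw noisy prompts from a noise-free projection set
#'
#' Independent Poisson draw per sinogram bin (and per TOF bin when the trues
#' are TOF-resolved) with mean trues + scatter + randoms; scatter and randoms
#' are spread uniformly across TOF bins. Reproducible for a given seed.
#'
#' @param ps a [ProjectionSet-class]
#' @param seed integer seed, or NULL to use the current RNG stream
#' @return noisy prompts, a [Sinogram-class] or [TOFSinogram-class]
#' @export
addPoissonNoise <- function(ps, seed = NULL) {
  stopifnot(is(ps, "ProjectionSet"))
  trues <- ps@trues
  if (is(trues, "TOFSinogram")) {
    ntof <- dim(trues@data)[4]
    lambda <- trues@data + as.vector(ps@scatter@data + ps@randoms@data) / ntof
  } else {
    lambda <- trues@data + ps@scatter@data + ps@randoms@data
  }
  if (any(!is.finite(lambda)) || min(lambda) < 0)
    stop("expected counts must be finite and non-negative")
  draw <- function() array(as.numeric(rpois(length(lambda), lambda)), dim(lambda))
  out <- trues
  out@data <- if (is.null(seed)) draw() else withLocalSeed(seed, draw())
  out
}

#' Apply patient repositioning and PET-CT misalignment
#'
#' Draws one random translation (uniform per axis in [-maxShift, +maxShift])
#' and applies it to both the activity and the attenuation truth; the
#' attenuation map returned for correction purposes is additionally offset by
#' the PET-CT misalignment. Linear interpolation with zero padding.
#'
#' @param dro a [DROPair-class]
#' @param maxShift per-axis maximum shift, mm
#' @param ctMisalignment per-axis CT offset, mm
#' @param seed integer seed for the shift draw (NULL: current stream)
#' @return list with elements `dro` (shifted truth pair), `correctionMu`
#'   (the [AttenuationMap-class] to use for attenuation correction) and
#'   `shift` (the drawn translation, mm)
#' @export
applyRepositioning <- function(dro, maxShift = c(0, 0, 0),
                               ctMisalignment = c(0, 0, 0), seed = NULL) {
  stopifnot(is(dro, "DROPair"))
  maxShift <- rep(as.numeric(maxShift), length.out = 3)
  ctMisalignment <- rep(as.numeric(ctMisalignment), length.out = 3)
  vox <- dro@activity@voxelSize
  fov <- dim(dro@activity@data) * vox
  if (any(maxShift > fov / 2)) stop("maxShift exceeds half the field of view")
  drawShift <- function() runif(3, -maxShift, maxShift)
  shift <- if (all(maxShift == 0)) c(0, 0, 0)
  else if (is.null(seed)) drawShift() else withLocalSeed(seed, drawShift())
  mu <- droMu(dro)
  out <- dro
  if (any(shift != 0)) {
    out@activity@data <- translateArray(dro@activity@data, shift, vox)
    muT <- mu
    muT@data <- translateArray(mu@data, shift, vox)
    out@attenuation <- muT
    lost <- 1 - sum(out@activity@data) / max(sum(dro@activity@data), .Machine$double.eps)
    if (lost > 0.01)
      warning(sprintf("repositioning shifted %.1f%% of the activity outside the FOV",
                      100 * lost))
  } else out@attenuation <- mu
  corr <- out@attenuation
  total <- shift + ctMisalignment
  if (any(ctMisalignment != 0)) {
    corr <- mu
    corr@data <- translateArray(mu@data, total, vox)
  }
  list(dro = out, correctionMu = corr, shift = shift)
}

#' Simulate a stack of statistically equivalent replicates
#'
#' Computes the noise-free projection once, then draws `nReplicates`
#' independent Poisson realisations and reconstructs each with
#' [osemReconstruct()] (plus any post-filter / Van-Cittert step requested in
#' the reconstruction parameters). Per-replicate seeds are derived
#' deterministically from the master seed, so the whole stack is reproducible.
#'
#' @param dro a [DROPair-class]
#' @param simParams a [SimulationParams-class]
#' @param reconParams a [ReconParams-class]
#' @return a [ReplicateStack-class]
#' @export
simulateReplicates <- function(dro, simParams, reconParams) {
  stopifnot(is(dro, "DROPair"))
  seed <- simParams@seed
  if (is.na(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  seeds <- withLocalSeed(seed, sample.int(.Machine$integer.max, simParams@nReplicates))
  corrMu <- NULL
  if (any(simParams@maxShift > 0) || any(simParams@ctMisalignment != 0)) {
    repos <- applyRepositioning(dro, simParams@maxShift,
                                simParams@ctMisalignment, seed = seed)
    dro <- repos$dro
    corrMu <- repos$correctionMu
  }
  ps <- simulateNoiseFree(dro, simParams)
  attnRecon <- if (is.null(corrMu)) ps@attenuation else attenuationFactors(corrMu)
  # OSEM solves for the count-scaled image; rescale back to kBq/mL
  countScale <- simParams@sensitivityFactor * simParams@scanDuration *
    simParams@decayFactor
  images <- NULL
  for (i in seq_len(simParams@nReplicates)) {
    prompts <- addPoissonNoise(ps, seed = seeds[i])
    img <- osemReconstruct(prompts, attnRecon, ps@scatter, ps@randoms, reconParams)
    img@data <- img@data / countScale
    img <- applyPostProcessing(img, reconParams)
    if (is.null(images))
      images <- array(0, c(dim(img@data), simParams@nReplicates))
    images[, , , i] <- img@data
  }
  new("ReplicateStack", images = images, voxelSize = img@voxelSize,
      seeds = as.integer(seeds), simParams = simParams,
      reconParams = reconParams)
}
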