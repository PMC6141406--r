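#' @import methods
#' @importFrom Matrix sparseMatrix t crossprod
#' @importFrom stats rpois runif sd
NULL

# ---------------------------------------------------------------------------
# Voxelised 3D images
# ---------------------------------------------------------------------------

#' Voxelised 3D image
#'
#' Base container for 3D images on a regular grid. Axial slices run along the
#' third array axis; voxel indices are 0-based in world-coordinate formulas and
#' the grid is centred on the world origin (the centre of the field of view).
#' World units are millimetres throughout.
#'
#' @slot data numeric 3D array, indexed \code{[x, y, slice]}.
#' @slot voxelSize numeric length-3 vector of voxel edge lengths in mm.
#'
#' @seealso [ActivityImage-class], [AttenuationMap-class], [CTImage-class]
#' @export
setClass("VoxelImage", representation(data = "array", voxelSize = "numeric"))

setValidity("VoxelImage", function(object) {
  if (length(dim(object@data)) != 3L)
    return("image data must be a 3D array")
  if (length(object@voxelSize) != 3L || any(!is.finite(object@voxelSize)) ||
      any(object@voxelSize <= 0))
    return("voxelSize must be 3 positive finite values (mm)")
  TRUE
})

#' Activity image (kBq/mL)
#' @export
setClass("ActivityImage", contains = "VoxelImage")

#' Attenuation map (linear attenuation coefficient at 511 keV, cm^-1)
#' @export
setClass("AttenuationMap", contains = "VoxelImage")

#' CT image in Hounsfield units
#' @export
setClass("CTImage", contains = "VoxelImage")

# ---------------------------------------------------------------------------
# Phantom types
# ---------------------------------------------------------------------------

#' NEMA NU 2 image-quality phantom specification
#'
#' Describes the digital reference object (DRO) to generate: six fillable
#' spheres on the standard ring inside a torso-shaped background compartment.
#' The torso cross-section is two half-circles joined by a rectangle; its
#' axial length is derived from the requested background volume.
#'
#' @slot sphereDiameters inner sphere diameters in mm, strictly increasing.
#' @slot backgroundVolumeML fillable background volume in mL.
#' @slot backgroundActivity background activity concentration, kBq/mL.
#' @slot sphereActivity sphere activity concentration(s), kBq/mL; length 1 or
#'   one value per sphere.
#' @slot lungInsert logical; include the central low-density lung insert.
#' @slot voxelSize voxel size in mm (3-vector).
#' @slot matrixSize image matrix (3-vector of positive integers).
#' @export
setClass("PhantomSpec", representation(
  sphereDiameters = "numeric",
  backgroundVolumeML = "numeric",
  backgroundActivity = "numeric",
  sphereActivity = "numeric",
  lungInsert = "logical",
  voxelSize = "numeric",
  matrixSize = "integer"
))

setValidity("PhantomSpec", function(object) {
  d <- object@sphereDiameters
  if (length(d) != 6L || any(d <= 0) || any(diff(d) <= 0))
    return("sphereDiameters must be 6 strictly increasing positive values")
  if (object@backgroundVolumeML <= 0) return("backgroundVolumeML must be > 0")
  if (object@backgroundActivity < 0 || any(object@sphereActivity < 0))
    return("activities must be >= 0")
  if (!length(object@sphereActivity) %in% c(1L, 6L))
    return("sphereActivity must have length 1 or 6")
  if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
    return("voxelSize must be 3 positive values")
  if (length(object@matrixSize) != 3L || any(object@matrixSize < 1L))
    return("matrixSize must be 3 positive integers")
  TRUE
})

#' Paired activity and attenuation digital reference objects
#'
#' @slot activity the activity [ActivityImage-class].
#' @slot attenuation matched [AttenuationMap-class] or [CTImage-class] on the
#'   same grid.
#' @slot provenance list recording the generator parameters (phantom geometry,
#'   sphere centres/diameters, compartment values) used to build the pair.
#' @export
setClass("DROPair", representation(
  activity = "ActivityImage",
  attenuation = "VoxelImage",
  provenance = "list"
))

setValidity("DROPair", function(object) {
  if (!identical(dim(object@activity@data), dim(object@attenuation@data)))
    return("activity and attenuation images must share the same grid")
  if (!isTRUE(all.equal(object@activity@voxelSize, object@attenuation@voxelSize)))
    return("activity and attenuation images must share the same voxel size")
  if (!is(object@attenuation, "AttenuationMap") && !is(object@attenuation, "CTImage"))
    return("attenuation must be an AttenuationMap or a CTImage")
  TRUE
})

# ---------------------------------------------------------------------------
# Projection data
# ---------------------------------------------------------------------------

#' Stacked 2D sinograms
#'
#' Slice-wise projection data: 128 angles uniformly spaced over [0, pi)
#' (half-open) and one radial bin per transaxial voxel of the source grid.
#' Values are line integrals in units value*mm (or expected counts, after the
#' simulator scales them).
#'
#' @slot data numeric array \code{[slice, angle, radial_bin]}.
#' @slot binSize radial bin width in mm (equals the transaxial voxel size).
#' @slot sliceThickness axial slice thickness in mm.
#' @slot angles projection angles in radians.
#' @export
setClass("Sinogram", representation(
  data = "array",
  binSize = "numeric",
  sliceThickness = "numeric",
  angles = "numeric"
))

setValidity("Sinogram", function(object) {
  nd <- length(dim(object@data))
  if (!(nd %in% c(3L, 4L))) return("sinogram data must be 3D (or 4D for TOF)")
  if (dim(object@data)[2] != length(object@angles))
    return("angle axis must match the angles slot")
  if (object@binSize <= 0 || object@sliceThickness <= 0)
    return("binSize and sliceThickness must be positive")
  TRUE
})

#' Time-of-flight sinogram
#'
#' Adds a TOF-bin axis of the same length as the radial axis. Summing over the
#' TOF axis reproduces the non-TOF sinogram to floating tolerance.
#'
#' @slot tofFwhmPs coincidence timing resolution delta-t in picoseconds.
#' @slot tofBinSize TOF bin width along the ray, in mm.
#' @export
setClass("TOFSinogram", contains = "Sinogram", representation(
  tofFwhmPs = "numeric",
  tofBinSize = "numeric"
))

setValidity("TOFSinogram", function(object) {
  if (length(dim(object@data)) != 4L)
    return("TOF sinogram data must be 4D [slice, angle, bin, tof]")
  if (dim(object@data)[4] != dim(object@data)[3])
    return("TOF bin count must equal the radial bin count (matrix size)")
  if (object@tofFwhmPs <= 0) return("tofFwhmPs must be positive")
  TRUE
})

#' Per-LOR attenuation survival factors
#'
#' Multiplicative factors exp(-integral of mu dl) in (0, 1], indexed like a
#' [Sinogram-class].
#' @export
setClass("AttenuationFactors", contains = "Sinogram")

setValidity("AttenuationFactors", function(object) {
  v <- object@data
  if (any(v <= 0) || any(v > 1 + 1e-12))
    return("attenuation factors must lie in (0, 1]")
  TRUE
})

# ---------------------------------------------------------------------------
# Parameter objects
# ---------------------------------------------------------------------------

#' Acquisition / simulation parameters
#'
#' @slot sensitivityFactor global scale mapping projected activity*time to
#'   expected counts (counts per kBq/mL * mm * s). The calibration knob that
#'   matches simulated noise to a physical scanner.
#' @slot scanDuration scan (frame) duration in seconds.
#' @slot randomsFraction simulated randoms / trues, in [0, 1].
#' @slot scatterFraction simulated scatter / trues, in [0, 1].
#' @slot systemFWHM system spatial resolution, Gaussian FWHM per axis in mm.
#' @slot tofFwhmPs timing resolution in ps; NA disables TOF data generation.
#' @slot nReplicates number of statistically equivalent noisy replicates.
#' @slot seed master random seed (NA draws one from the session RNG).
#' @slot maxShift maximum random repositioning shift per axis, mm.
#' @slot ctMisalignment PET-CT misalignment applied to the CT/mu map only, mm.
#' @slot decayFactor frame-level decay scale applied to expected counts.
#' @export
setClass("SimulationParams", representation(
  sensitivityFactor = "numeric",
  scanDuration = "numeric",
  randomsFraction = "numeric",
  scatterFraction = "numeric",
  systemFWHM = "numeric",
  tofFwhmPs = "numeric",
  nReplicates = "integer",
  seed = "integer",
  maxShift = "numeric",
  ctMisalignment = "numeric",
  decayFactor = "numeric"
))

setValidity("SimulationParams", function(object) {
  if (object@sensitivityFactor <= 0) return("sensitivityFactor must be > 0")
  if (object@scanDuration <= 0) return("scanDuration must be > 0")
  if (object@randomsFraction < 0 || object@randomsFraction > 1)
    return("randomsFraction must be in [0, 1]")
  if (object@scatterFraction < 0 || object@scatterFraction > 1)
    return("scatterFraction must be in [0, 1]")
  if (length(object@systemFWHM) != 3L || any(object@systemFWHM < 0))
    return("systemFWHM must be 3 non-negative values (mm)")
  if (!is.na(object@tofFwhmPs) && object@tofFwhmPs <= 0)
    return("tofFwhmPs must be positive (or NA for non-TOF)")
  if (object@nReplicates < 1L) return("nReplicates must be >= 1")
  if (length(object@maxShift) != 3L || any(object@maxShift < 0))
    return("maxShift must be 3 non-negative values (mm)")
  if (length(object@ctMisalignment) != 3L)
    return("ctMisalignment must have length 3")
  if (object@decayFactor <= 0) return("decayFactor must be > 0")
  TRUE
})

#' Reconstruction parameters
#'
#' @slot matrixChoice one of \code{"ORG"}, \code{"128"}, \code{"170"},
#'   \code{"256"}, \code{"400"}; the non-ORG choices imply transaxial voxel
#'   sizes of 4, 3, 2 and 1.3 mm respectively (the slice thickness is kept).
#' @slot iterations OSEM iterations (default 4).
#' @slot subsets OSEM subsets (default 16); must divide the 128 angles.
#' @slot tofFwhmPs TOF kernel width used in the reconstruction model, ps;
#'   NA means "match the prompts" (TOF is used iff the prompts carry TOF bins).
#' @slot rmFWHM resolution-modelling Gaussian FWHM per axis in mm; any NA
#'   disables RM.
#' @slot postFilterFWHM post-reconstruction Gaussian filter FWHM in mm (0 off).
#' @slot vcEnabled,vcIterations,vcFWHM,vcAlpha reblurred Van-Cittert
#'   deconvolution settings (10 iterations by default, classical alpha = 1).
#' @export
setClass("ReconParams", representation(
  matrixChoice = "character",
  iterations = "integer",
  subsets = "integer",
  tofFwhmPs = "numeric",
  rmFWHM = "numeric",
  postFilterFWHM = "numeric",
  vcEnabled = "logical",
  vcIterations = "integer",
  vcFWHM = "numeric",
  vcAlpha = "numeric"
))

setValidity("ReconParams", function(object) {
  if (!object@matrixChoice %in% c("ORG", "128", "170", "256", "400"))
    return("matrixChoice must be one of ORG, 128, 170, 256, 400")
  if (object@iterations < 1L) return("iterations must be >= 1")
  if (object@subsets < 1L || 128L %% object@subsets != 0L)
    return("subsets must divide the 128 projection angles")
  if (!is.na(object@tofFwhmPs) && object@tofFwhmPs <= 0)
    return("tofFwhmPs must be positive (or NA)")
  if (length(object@rmFWHM) != 3L) return("rmFWHM must have length 3")
  if (object@postFilterFWHM < 0) return("postFilterFWHM must be >= 0")
  if (object@vcIterations < 1L) return("vcIterations must be >= 1")
  TRUE
})

# ---------------------------------------------------------------------------
# Simulation products
# ---------------------------------------------------------------------------

#' Noise-free projection data with additive components
#'
#' @slot trues expected true-coincidence counts ([Sinogram-class] or
#'   [TOFSinogram-class]), attenuated and scaled by sensitivity and duration.
#' @slot scatter expected scatter counts (non-TOF [Sinogram-class]).
#' @slot randoms expected random counts (uniform non-TOF [Sinogram-class]).
#' @slot attenuation the [AttenuationFactors-class] used.
#' @slot params the [SimulationParams-class] echo.
#' @export
setClass("ProjectionSet", representation(
  trues = "Sinogram",
  scatter = "Sinogram",
  randoms = "Sinogram",
  attenuation = "AttenuationFactors",
  params = "SimulationParams"
))

#' Stack of statistically equivalent reconstructed replicates
#'
#' @slot images numeric 4D array \code{[x, y, slice, replicate]}.
#' @slot voxelSize voxel size of the reconstructed images, mm.
#' @slot seeds per-replicate noise seeds derived from the master seed.
#' @slot simParams,reconParams parameter echoes.
#' @export
setClass("ReplicateStack", representation(
  images = "array",
  voxelSize = "numeric",
  seeds = "integer",
  simParams = "SimulationParams",
  reconParams = "ReconParams"
))

setValidity("ReplicateStack", function(object) {
  if (length(dim(object@images)) != 4L)
    return("images must be a 4D array [x, y, slice, replicate]")
  TRUE
})

# ---------------------------------------------------------------------------
# Analysis types
# ---------------------------------------------------------------------------

#' Regions of interest for image-quality analysis
#'
#' Sphere ROIs are exact geometric masks at the true phantom positions;
#' background ROIs are spheres (default radius 30 mm) placed in the background
#' compartment, away from the hot spheres.
#'
#' @slot sphereCenters numeric matrix (n x 3) of sphere centres, mm.
#' @slot sphereDiameters sphere inner diameters, mm.
#' @slot bgCenters numeric matrix (m x 3) of background ROI centres, mm.
#' @slot bgRadius background ROI radius, mm.
#' @export
setClass("ROISet", representation(
  sphereCenters = "matrix",
  sphereDiameters = "numeric",
  bgCenters = "matrix",
  bgRadius = "numeric"
))

setValidity("ROISet", function(object) {
  if (ncol(object@sphereCenters) != 3L && nrow(object@sphereCenters) > 0L)
    return("sphereCenters must have 3 columns")
  if (nrow(object@sphereCenters) != length(object@sphereDiameters))
    return("one diameter per sphere centre required")
  if (ncol(object@bgCenters) != 3L && nrow(object@bgCenters) > 0L)
    return("bgCenters must have 3 columns")
  if (object@bgRadius <= 0) return("bgRadius must be positive")
  TRUE
})

#' Replicate-stack analysis result
#'
#' @slot covPerReplicate background COV of each replicate.
#' @slot covMean mean background COV over replicates.
#' @slot rcMean,rcMax per-sphere recovery coefficients of the mean image.
#' @slot meanImage,sdImage voxelwise mean and sample-SD images.
#' @slot params list echoing analysis inputs (durations, TOF delta-t, phantom
#'   diameter D used by the theoretical predictors, expected activity).
#' @export
setClass("AnalysisResult", representation(
  covPerReplicate = "numeric",
  covMean = "numeric",
  rcMean = "numeric",
  rcMax = "numeric",
  meanImage = "ActivityImage",
  sdImage = "ActivityImage",
  params = "list"
))
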