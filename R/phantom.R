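# NEMA NU 2 image-quality phantom digital reference objects.
#
# Torso cross-section: two half-circles of radius TORSO_RADIUS joined by a
# rectangle of half-width TORSO_RECT_HALF (width 280 mm, height 210 mm). The
# axial length is derived from the requested background volume so that the
# fillable background (torso minus spheres minus optional lung insert) matches
# it. Six spheres sit on the standard 114.4 mm-diameter ring in the central
# transaxial plane. Voxels are assigned by centre-point membership, which
# keeps compartment activity ratios exact on the label masks.

TORSO_RADIUS <- 105       # mm, half-circle radius (phantom half-height)
TORSO_RECT_HALF <- 35     # mm, half-width of the joining rectangle
SPHERE_RING_RADIUS <- 57.2  # mm, sphere centres to phantom axis
LUNG_INSERT_RADIUS <- 25  # mm, central cylindrical low-density insert
MU_WATER_511 <- 0.096     # cm^-1 at 511 keV
MU_LUNG_511 <- 0.03       # cm^-1, inflated-lung equivalent

# Ring angles (deg) and the sphere diameter order around the ring. The two
# smallest spheres sit on the +/- x axis so background ROIs remain placeable
# on thin axial grids.
SPHERE_RING_ANGLES <- c(0, 60, 120, 180, 240, 300)
SPHERE_RING_ORDER <- c(10, 17, 22, 13, 28, 37)

#' Create a NEMA IQ phantom specification
#'
#' Defaults follow the standard image-quality phantom: sphere inner diameters
#' 10, 13, 17, 22, 28 and 37 mm, a 9400 mL background at 2.1 kBq/mL, and a
#' 10:1 sphere-to-background activity ratio (21 kBq/mL). The default grid is
#' 300 x 224 x 200 at 1 mm so the whole phantom fits.
#'
#' @param sphereDiameters sphere inner diameters in mm (6, strictly increasing)
#' @param backgroundVolumeML fillable background volume, mL
#' @param backgroundActivity background activity, kBq/mL
#' @param sphereActivity sphere activity (kBq/mL); a single value or one per
#'   sphere. Alternatively give `ratio` instead.
#' @param ratio sphere:background activity ratio; used when `sphereActivity`
#'   is missing
#' @param lungInsert include the central low-density lung insert
#' @param voxelSize voxel size in mm (scalar or 3-vector)
#' @param matrixSize image matrix (3-vector)
#' @return a [PhantomSpec-class]
#' @export
phantomSpec <- function(sphereDiameters = c(10, 13, 17, 22, 28, 37),
                        backgroundVolumeML = 9400,
                        backgroundActivity = 2.1,
                        sphereActivity = NULL,
                        ratio = 10,
                        lungInsert = FALSE,
                        voxelSize = c(1, 1, 1),
                        matrixSize = c(300L, 224L, 200L)) {
  if (is.null(sphereActivity)) sphereActivity <- backgroundActivity * ratio
  new("PhantomSpec",
      sphereDiameters = as.numeric(sphereDiameters),
      backgroundVolumeML = backgroundVolumeML,
      backgroundActivity = backgroundActivity,
      sphereActivity = as.numeric(sphereActivity),
      lungInsert = lungInsert,
      voxelSize = rep(as.numeric(voxelSize), length.out = 3),
      matrixSize = as.integer(rep(matrixSize, length.out = 3)))
}

# Geometry derived from a spec: sphere centres/diameters and the torso axial
# length that yields the requested background volume.
phantomGeometry <- function(spec) {
  # requested diameters mapped onto the standard ring order by size rank
  # (supports arbitrary diameter sets, not just the defaults)
  diam <- sort(spec@sphereDiameters)[rank(SPHERE_RING_ORDER)]
  ang <- SPHERE_RING_ANGLES * pi / 180
  centers <- cbind(SPHERE_RING_RADIUS * cos(ang),
                   SPHERE_RING_RADIUS * sin(ang),
                   0)
  area <- pi * TORSO_RADIUS^2 + 2 * TORSO_RECT_HALF * 2 * TORSO_RADIUS
  sphVol <- sum(4 / 3 * pi * (spec@sphereDiameters / 2)^3)
  if (spec@lungInsert) area <- area - pi * LUNG_INSERT_RADIUS^2
  axialLength <- (spec@backgroundVolumeML * 1000 + sphVol) / area
  list(centers = centers, diameters = diam, axialLength = axialLength,
       torsoRadius = TORSO_RADIUS, rectHalf = TORSO_RECT_HALF,
       ringRadius = SPHERE_RING_RADIUS, lungRadius = LUNG_INSERT_RADIUS)
}

# 2D in-plane torso membership for world coordinates x (vector), y (vector).
torsoMask2D <- function(x, y, erodeBy = 0) {
  R <- TORSO_RADIUS - erodeBy
  xa <- abs(outer(x, rep(1, length(y))))
  yy <- outer(rep(1, length(x)), y)
  inRect <- xa <= TORSO_RECT_HALF & abs(yy) <= R
  inCirc <- (xa - TORSO_RECT_HALF)^2 + yy^2 <= R^2 & xa > TORSO_RECT_HALF
  inRect | inCirc
}

#' Generate the NEMA IQ phantom DRO pair
#'
#' Builds matched activity and attenuation/CT images: background activity
#' inside the torso, sphere activities inside the six spheres, zero outside;
#' water-equivalent mu (0.096 cm^-1 at 511 keV) inside the torso, or HU
#' (0 inside, -1000 outside) in CT output mode. Sphere centres lie on the
#' standard ring in the central transaxial plane. If the grid is axially
#' shorter than the phantom, the torso is clipped (reduced axial extent);
#' the in-plane cross-section must fit.
#'
#' @param spec a [PhantomSpec-class]
#' @param attenuationKind `"mu"` for a 511 keV attenuation map or `"ct"` for a
#'   Hounsfield-unit CT image (exercises the CT conversion path)
#' @param superSample integer >= 1; when > 1, compartment membership is
#'   evaluated on a superSample^3 sub-voxel grid and averaged (antialiasing).
#'   The default 1 gives a binary DRO with exact activity ratios on the label
#'   masks.
#' @return a [DROPair-class] whose provenance records the full geometry
#' @examples
#' dro <- generateIQPhantom(phantomSpec(voxelSize = 3, matrixSize = c(96, 96, 16)))
#' dro
#' @export
generateIQPhantom <- function(spec, attenuationKind = c("mu", "ct"),
                              superSample = 1L) {
  attenuationKind <- match.arg(attenuationKind)
  validObject(spec)
  vox <- spec@voxelSize
  dims <- spec@matrixSize
  if (max(vox) > min(spec@sphereDiameters) / 2)
    stop("voxel size (", max(vox), " mm) too coarse: must not exceed the ",
         "smallest sphere radius (", min(spec@sphereDiameters) / 2, " mm)")
  geo <- phantomGeometry(spec)
  if (dims[1] * vox[1] < 2 * (TORSO_RECT_HALF + TORSO_RADIUS) ||
      dims[2] * vox[2] < 2 * TORSO_RADIUS)
    stop("phantom cross-section (", 2 * (TORSO_RECT_HALF + TORSO_RADIUS), " x ",
         2 * TORSO_RADIUS, " mm) exceeds the matrix extent (",
         dims[1] * vox[1], " x ", dims[2] * vox[2], " mm)")

  # sphereActivity is given in diameter order; reorder to ring order
  if (length(spec@sphereActivity) == 6L) {
    sphereVals <- spec@sphereActivity[match(geo$diameters, spec@sphereDiameters)]
  } else sphereVals <- rep(spec@sphereActivity, 6)

  buildMasks <- function(offset = c(0, 0, 0)) {
    x <- axisCoords(dims[1], vox[1]) + offset[1]
    y <- axisCoords(dims[2], vox[2]) + offset[2]
    z <- axisCoords(dims[3], vox[3]) + offset[3]
    t2 <- torsoMask2D(x, y)
    zin <- abs(z) <= geo$axialLength / 2
    torso <- array(outer(as.vector(t2), zin, FUN = "&"), dims)
    spheres <- lapply(seq_len(6), function(i)
      sphereMask(dims, vox, geo$centers[i, ] - offset, geo$diameters[i] / 2))
    lung <- NULL
    if (spec@lungInsert) {
      l2 <- outer(x^2, y^2, `+`) <= geo$lungRadius^2
      lung <- array(outer(as.vector(l2), zin, FUN = "&"), dims)
    }
    list(torso = torso, spheres = spheres, lung = lung)
  }

  accumulate <- function(masks) {
    act <- array(0, dims)
    sphereAny <- array(FALSE, dims)
    for (i in seq_len(6)) sphereAny <- sphereAny | masks$spheres[[i]]
    bg <- masks$torso & !sphereAny
    if (!is.null(masks$lung)) bg <- bg & !masks$lung
    act[bg] <- spec@backgroundActivity
    for (i in seq_len(6)) act[masks$spheres[[i]]] <- sphereVals[i]
    att <- array(0, dims)
    if (attenuationKind == "mu") {
      att[masks$torso] <- MU_WATER_511
      if (!is.null(masks$lung)) att[masks$lung] <- MU_LUNG_511
    } else {
      att[] <- -1000
      att[masks$torso] <- 0
      if (!is.null(masks$lung)) att[masks$lung] <- -700
    }
    list(act = act, att = att)
  }

  superSample <- as.integer(superSample)
  if (superSample <= 1L) {
    img <- accumulate(buildMasks())
  } else {
    act <- array(0, dims); att <- array(0, dims)
    offs <- (seq_len(superSample) - (superSample + 1) / 2) / superSample
    for (ox in offs) for (oy in offs) for (oz in offs) {
      sub <- accumulate(buildMasks(c(ox * vox[1], oy * vox[2], oz * vox[3])))
      act <- act + sub$act; att <- att + sub$att
    }
    img <- list(act = act / superSample^3, att = att / superSample^3)
  }

  attClass <- if (attenuationKind == "mu") "AttenuationMap" else "CTImage"
  prov <- list(kind = "nema-iq",
               spec = spec,
               sphereCenters = geo$centers,
               sphereDiameters = geo$diameters,
               sphereActivities = sphereVals,
               axialLength = geo$axialLength,
               attenuationKind = attenuationKind,
               superSample = superSample)
  new("DROPair",
      activity = new("ActivityImage", data = img$act, voxelSize = vox),
      attenuation = new(attClass, data = img$att, voxelSize = vox),
      provenance = prov)
}

#' Generate a uniform cylinder DRO pair
#'
#' A water-filled cylinder of the given diameter with uniform activity,
#' centred in the field of view with its axis along the slice direction.
#' Used for TOF noise-behaviour studies, where theory assumes a cylindrical
#' object.
#'
#' @param diameter cylinder diameter, mm (default 270, i.e. 27 cm)
#' @param activity activity concentration, kBq/mL
#' @param voxelSize,matrixSize output grid (mm; 3-vectors)
#' @param length cylinder length in mm; defaults to the full axial extent
#' @param attenuationKind `"mu"` or `"ct"` (see [generateIQPhantom()])
#' @return a [DROPair-class]
#' @export
generateCylinderPhantom <- function(diameter = 270, activity = 2.1,
                                    voxelSize = c(6, 6, 6),
                                    matrixSize = c(64L, 64L, 3L),
                                    length = NULL,
                                    attenuationKind = c("mu", "ct")) {
  attenuationKind <- match.arg(attenuationKind)
  vox <- rep(as.numeric(voxelSize), length.out = 3)
  dims <- as.integer(rep(matrixSize, length.out = 3))
  if (diameter > min(dims[1] * vox[1], dims[2] * vox[2]))
    stop("cylinder diameter exceeds the matrix extent")
  x <- axisCoords(dims[1], vox[1]); y <- axisCoords(dims[2], vox[2])
  z <- axisCoords(dims[3], vox[3])
  if (is.null(length)) length <- dims[3] * vox[3]
  in2d <- outer(x^2, y^2, `+`) <= (diameter / 2)^2
  zin <- abs(z) <= length / 2
  mask <- array(outer(as.vector(in2d), zin, FUN = "&"), dims)
  act <- array(0, dims); act[mask] <- activity
  att <- array(0, dims)
  if (attenuationKind == "mu") att[mask] <- MU_WATER_511
  else { att[] <- -1000; att[mask] <- 0 }
  attClass <- if (attenuationKind == "mu") "AttenuationMap" else "CTImage"
  new("DROPair",
      activity = new("ActivityImage", data = act, voxelSize = vox),
      attenuation = new(attClass, data = att, voxelSize = vox),
      provenance = list(kind = "cylinder", diameter = diameter,
                        activity = activity, length = length,
                        attenuationKind = attenuationKind))
}

#' Modify a DRO pair: compartment activities, matrix and slice thickness
#'
#' Rescales the labelled compartments of a generated DRO to the requested
#' activity concentrations and/or resamples it onto a new grid. Resampling
#' regenerates the compartment masks from the recorded generator geometry on
#' the new grid, which conserves the compartment shapes and total activity
#' (mass) up to voxelisation error.
#'
#' @param dro a [DROPair-class] produced by [generateIQPhantom()]
#' @param backgroundActivity new background activity, kBq/mL
#' @param sphereActivity new sphere activity (single value or one per sphere),
#'   kBq/mL
#' @param newMatrix optional new matrix size (3-vector)
#' @param newVoxelSize optional new voxel size (3-vector, mm)
#' @param newSliceThickness optional new slice thickness (mm); shorthand for
#'   changing only the axial voxel size
#' @param superSample sub-voxel supersampling used when regenerating on a new
#'   grid; the default 2 antialiases compartment boundaries so that total
#'   activity is conserved through the resampling (within voxelisation error).
#'   Calls that keep the original grid stay binary (the generator's own
#'   setting), so an identity call returns the input voxelwise.
#' @return a [DROPair-class] on the requested grid
#' @examples
#' dro <- generateIQPhantom(phantomSpec(voxelSize = 3, matrixSize = c(96, 96, 16)))
#' dro23 <- modifyDRO(dro, backgroundActivity = 2.1, sphereActivity = 23)
#' @export
modifyDRO <- function(dro, backgroundActivity = NULL, sphereActivity = NULL,
                      newMatrix = NULL, newVoxelSize = NULL,
                      newSliceThickness = NULL, superSample = 2L) {
  stopifnot(is(dro, "DROPair"))
  prov <- dro@provenance
  if (!identical(prov$kind, "nema-iq"))
    stop("modifyDRO requires a DRO generated by generateIQPhantom ",
         "(provenance carries the compartment geometry)")
  spec <- prov$spec
  if (!is.null(backgroundActivity)) {
    if (backgroundActivity < 0) stop("background activity must be >= 0")
    spec@backgroundActivity <- backgroundActivity
  }
  if (!is.null(sphereActivity)) {
    if (any(sphereActivity < 0)) stop("sphere activity must be >= 0")
    spec@sphereActivity <- as.numeric(sphereActivity)
  }
  if (!is.null(newSliceThickness)) {
    newVoxelSize <- c(spec@voxelSize[1:2], newSliceThickness)
  }
  if (!is.null(newVoxelSize))
    spec@voxelSize <- rep(as.numeric(newVoxelSize), length.out = 3)
  if (!is.null(newMatrix))
    spec@matrixSize <- as.integer(rep(newMatrix, length.out = 3))
  regrid <- !is.null(newMatrix) || !is.null(newVoxelSize)
  if (regrid) {
    newExtent <- spec@matrixSize * spec@voxelSize
    need <- c(2 * (TORSO_RECT_HALF + TORSO_RADIUS), 2 * TORSO_RADIUS)
    oldExtent <- dim(dro@activity@data) * dro@activity@voxelSize
    if (newExtent[1] < min(need[1], oldExtent[1]) ||
        newExtent[2] < min(need[2], oldExtent[2]))
      stop("new grid does not cover the phantom cross-section")
  }
  ss <- if (regrid) max(as.integer(superSample), prov$superSample)
  else prov$superSample
  generateIQPhantom(spec, attenuationKind = prov$attenuationKind,
                    superSample = ss)
}
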