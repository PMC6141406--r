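# NIfTI input/output and run configuration.

#' Read a NIfTI image
#'
#' Only 3D NIfTI (.nii / .nii.gz) is supported: 4D inputs are rejected
#' (dynamic studies are not supported) and the legacy ECAT7 container is
#' rejected with an explicit message.
#'
#' @param path path to a NIfTI file
#' @param kind interpretation of the voxel values: `"activity"` (kBq/mL),
#'   `"mu"` (cm^-1 at 511 keV) or `"ct"` (HU)
#' @return an [ActivityImage-class], [AttenuationMap-class] or
#'   [CTImage-class]
#' @export
readImage <- function(path, kind = c("activity", "mu", "ct")) {
  kind <- match.arg(kind)
  if (grepl("\\.v$", path, ignore.case = TRUE))
    stop("unsupported format: ECAT7 ('.v') is not supported; provide NIfTI")
  if (!file.exists(path)) stop("file not found: ", path)
  ni <- RNifti::readNifti(path)
  d <- dim(ni)
  if (length(d) == 4L && d[4] > 1L)
    stop("4D input not supported (dynamic studies cannot be simulated)")
  if (length(d) == 4L) { ni <- ni[, , , 1]; d <- dim(ni) }
  if (length(d) != 3L) stop("expected a 3D image, got ", length(d), " dimensions")
  vox <- abs(RNifti::pixdim(ni)[1:3])
  cls <- switch(kind, activity = "ActivityImage", mu = "AttenuationMap",
                ct = "CTImage")
  new(cls, data = array(as.numeric(ni), d), voxelSize = vox)
}

#' Write an image to NIfTI
#'
#' @param img a [VoxelImage-class]
#' @param path output path (.nii or .nii.gz)
#' @return the path, invisibly
#' @export
writeImage <- function(img, path) {
  stopifnot(is(img, "VoxelImage"))
  ni <- RNifti::asNifti(img@data)
  RNifti::pixdim(ni) <- img@voxelSize
  RNifti::writeNifti(ni, path)
  invisible(path)
}

#' Read a pipeline run configuration
#'
#' A YAML file mirroring the arguments of [runPipeline()]: top-level keys
#' `phantom` (passed to [phantomSpec()]), or `activityPath`/`attenuationPath`
#' (+ `attenuationKind`), `simulation` (passed to [simulationParams()]),
#' `reconstruction` (passed to [reconParams()]), `analysis`
#' (`expectedActivity`, `roiRadius`, `roiSeed`), and `outputDir`.
#' All parameter invariants are re-validated at load.
#'
#' @param path YAML configuration file
#' @return a validated named list
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  validateRunConfig(cfg)
}

#' Validate a run configuration list
#' @param cfg a named list (see [readRunConfig()])
#' @return the list, with parameter objects attached
#' @export
validateRunConfig <- function(cfg) {
  if (is.null(cfg$phantom) && is.null(cfg$activityPath))
    stop("config needs either a 'phantom' block or an 'activityPath'")
  if (!is.null(cfg$activityPath)) {
    if (is.null(cfg$attenuationPath))
      stop("'attenuationPath' is required with 'activityPath'")
    for (p in c(cfg$activityPath, cfg$attenuationPath))
      if (!file.exists(p)) stop("input does not exist: ", p)
  }
  cfg$simParams <- do.call(simulationParams, as.list(cfg$simulation))
  cfg$reconParamsObj <- do.call(reconParams, as.list(cfg$reconstruction))
  validObject(cfg$simParams)
  validObject(cfg$reconParamsObj)
  if (is.null(cfg$outputDir)) cfg$outputDir <- "."
  cfg
}

# Stable fingerprint of the configuration for provenance records.
configHash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(cfg, f)
  unname(tools::md5sum(f))
}

#' Run the end-to-end simulation pipeline
#'
#' Generates (or reads) the DRO pair, optionally resamples it to the
#' reconstruction matrix choice, simulates the requested number of noisy
#' replicates, reconstructs them, and writes the replicate images, the
#' mean/SD images, a delimited analysis table (COV per replicate, RC per
#' sphere) and a JSON sidecar with full provenance (configuration hash and
#' seeds) to the output directory.
#'
#' @param cfg configuration list (see [readRunConfig()]) or a path to a YAML
#'   file
#' @return the [AnalysisResult-class], invisibly; side effect: files under
#'   `cfg$outputDir`
#' @export
runPipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- readRunConfig(cfg)
  else cfg <- validateRunConfig(cfg)
  dir.create(cfg$outputDir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    message(sprintf("[petsim] %s", name))
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE))
  }

  dro <- stage("phantom/input", {
    if (!is.null(cfg$phantom)) {
      generateIQPhantom(do.call(phantomSpec, as.list(cfg$phantom)))
    } else {
      act <- readImage(cfg$activityPath, "activity")
      kind <- if (identical(cfg$attenuationKind, "ct")) "ct" else "mu"
      att <- readImage(cfg$attenuationPath, kind)
      if (!identical(dim(act@data), dim(att@data)))
        stop("activity grid ", paste(dim(act@data), collapse = "x"),
             " does not match attenuation grid ",
             paste(dim(att@data), collapse = "x"))
      new("DROPair", activity = act, attenuation = att,
          provenance = list(kind = "external",
                            activityPath = cfg$activityPath,
                            attenuationPath = cfg$attenuationPath))
    }
  })

  rp <- cfg$reconParamsObj
  if (rp@matrixChoice != "ORG") {
    dro <- stage("resample to reconstruction matrix", {
      nv <- matrixChoiceVoxel(rp@matrixChoice)
      nm <- as.integer(rp@matrixChoice)
      modifyDRO(dro, newMatrix = c(nm, nm, dim(dro@activity@data)[3]),
                newVoxelSize = c(nv, nv, dro@activity@voxelSize[3]))
    })
  }

  stack <- stage("simulate + reconstruct replicates",
                 simulateReplicates(dro, cfg$simParams, rp))

  result <- stage("analysis", {
    roiRadius <- if (!is.null(cfg$analysis$roiRadius)) cfg$analysis$roiRadius else 30
    roiSeed <- if (!is.null(cfg$analysis$roiSeed)) cfg$analysis$roiSeed else 42L
    expected <- if (!is.null(cfg$analysis$expectedActivity))
      cfg$analysis$expectedActivity
    else if (identical(dro@provenance$kind, "nema-iq"))
      max(dro@provenance$sphereActivities)
    else NA_real_
    if (identical(dro@provenance$kind, "nema-iq")) {
      rois <- iqROISet(dro, radius = roiRadius, seed = roiSeed)
      analyzeReplicates(stack, rois, expected)
    } else {
      NULL
    }
  })

  stage("write outputs", {
    for (i in seq_len(dim(stack@images)[4]))
      writeImage(getReplicate(stack, i),
                 file.path(cfg$outputDir, sprintf("replicate_%03d.nii.gz", i)))
    st <- replicateStatistics(stack)
    writeImage(st$meanImage, file.path(cfg$outputDir, "mean.nii.gz"))
    writeImage(st$sdImage, file.path(cfg$outputDir, "sd.nii.gz"))
    report <- list(configHash = configHash(cfg[setdiff(names(cfg),
                                                       c("simParams", "reconParamsObj"))]),
                   seeds = stack@seeds)
    if (!is.null(result)) {
      report$covPerReplicate <- result@covPerReplicate
      report$covMean <- result@covMean
      report$rcMean <- result@rcMean
      report$rcMax <- result@rcMax
      tab <- data.frame(replicate = seq_along(result@covPerReplicate),
                        cov = result@covPerReplicate)
      utils::write.csv(tab, file.path(cfg$outputDir, "cov.csv"), row.names = FALSE)
      if (length(result@rcMean)) {
        rc <- data.frame(diameter = iqSphereDiameters(dro),
                         rcMean = result@rcMean, rcMax = result@rcMax)
        utils::write.csv(rc, file.path(cfg$outputDir, "rc.csv"), row.names = FALSE)
      }
    }
    jsonlite::write_json(report, file.path(cfg$outputDir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
  })
  invisible(result)
}

iqSphereDiameters <- function(dro) dro@provenance$sphereDiameters
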