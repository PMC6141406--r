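# Accessors and show methods.

#' Image voxel data
#' @param object a [VoxelImage-class], [Sinogram-class] or container object
#' @return the underlying numeric array
#' @export
setGeneric("imageData", function(object) standardGeneric("imageData"))

#' @rdname imageData
#' @export
setMethod("imageData", "VoxelImage", function(object) object@data)

#' @rdname imageData
#' @export
setMethod("imageData", "Sinogram", function(object) object@data)

#' Voxel size in mm
#' @param object a [VoxelImage-class]
#' @return numeric length-3 vector (mm)
#' @export
setGeneric("voxelSize", function(object) standardGeneric("voxelSize"))

#' @rdname voxelSize
#' @export
setMethod("voxelSize", "VoxelImage", function(object) object@voxelSize)

#' @export
setMethod("dim", "VoxelImage", function(x) dim(x@data))

#' @export
setMethod("dim", "Sinogram", function(x) dim(x@data))

setMethod("show", "VoxelImage", function(object) {
  d <- dim(object@data)
  cat(sprintf("%s %d x %d x %d, voxel %s mm, range [%.4g, %.4g]\n",
              class(object), d[1], d[2], d[3],
              paste(signif(object@voxelSize, 4), collapse = " x "),
              min(object@data), max(object@data)))
})

setMethod("show", "Sinogram", function(object) {
  d <- dim(object@data)
  extra <- if (length(d) == 4L)
    sprintf(", %d TOF bins (%.0f ps)", d[4], object@tofFwhmPs) else ""
  cat(sprintf("%s: %d slices, %d angles, %d radial bins (%.3g mm)%s, total %.6g\n",
              class(object), d[1], d[2], d[3], object@binSize, extra,
              sum(object@data)))
})

setMethod("show", "DROPair", function(object) {
  cat(sprintf("DROPair (%s attenuation)\n  activity:    ",
              if (is(object@attenuation, "CTImage")) "CT/HU" else "mu/511keV"))
  show(object@activity)
  cat("  attenuation: ")
  show(object@attenuation)
})

setMethod("show", "ReplicateStack", function(object) {
  d <- dim(object@images)
  cat(sprintf("ReplicateStack: %d replicates of %d x %d x %d (voxel %s mm)\n",
              d[4], d[1], d[2], d[3],
              paste(signif(object@voxelSize, 4), collapse = " x ")))
})

setMethod("show", "AnalysisResult", function(object) {
  cat("AnalysisResult\n")
  cat(sprintf("  background COV (mean over %d replicates): %.4f\n",
              length(object@covPerReplicate), object@covMean))
  if (length(object@rcMean)) {
    cat("  RC_mean:", paste(sprintf("%.3f", object@rcMean), collapse = " "), "\n")
    cat("  RC_max: ", paste(sprintf("%.3f", object@rcMax)), "\n")
  }
})

#' Extract one replicate as an image
#' @param stack a [ReplicateStack-class]
#' @param i replicate index
#' @return an [ActivityImage-class]
#' @export
getReplicate <- function(stack, i) {
  stopifnot(is(stack, "ReplicateStack"), i >= 1, i <= dim(stack@images)[4])
  new("ActivityImage", data = stack@images[, , , i, drop = TRUE],
      voxelSize = stack@voxelSize)
}
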