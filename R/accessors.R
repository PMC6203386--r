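#' @include AllGenerics.R
NULL

#' @rdname imgData
setMethod("imgData", "ImageVolume", function(x) x@data)
#' @rdname imgData
setMethod("imgData", "LabelMap", function(x) x@labels)

#' @rdname voxelSize
setMethod("voxelSize", "ImageVolume",
          function(x) sqrt(colSums(x@affine[1:3, 1:3]^2)))
#' @rdname voxelSize
setMethod("voxelSize", "LabelMap",
          function(x) sqrt(colSums(x@affine[1:3, 1:3]^2)))

#' @rdname worldAffine
setMethod("worldAffine", "ImageVolume", function(x) x@affine)
#' @rdname worldAffine
setMethod("worldAffine", "LabelMap", function(x) x@affine)

#' @rdname modality
setMethod("modality", "ImageVolume", function(x) x@modality)

#' @rdname frameSchedule
setMethod("frameSchedule", "ImageVolume", function(x) x@schedule)
#' @rdname frameSchedule
setMethod("frameSchedule", "TAC",
          function(x) new("FrameSchedule",
                          start = x@midTime * 60 - x@duration / 2,
                          duration = x@duration))

#' @rdname midTimes
setMethod("midTimes", "FrameSchedule",
          function(x) (x@start + x@duration / 2) / 60)
#' @rdname midTimes
setMethod("midTimes", "TAC", function(x) x@midTime)

#' @rdname nFrames
setMethod("nFrames", "FrameSchedule", function(x) length(x@start))
#' @rdname nFrames
setMethod("nFrames", "ImageVolume", function(x) {
  d <- dim(x@data)
  if (length(d) == 4L) d[4L] else 1L
})

#' @rdname regionNames
setMethod("regionNames", "LabelMap", function(x) names(x@regions))

#' @rdname activity
setMethod("activity", "TAC", function(x) x@activity)

#' @rdname bindingPotential
setMethod("bindingPotential", "SRTMFit", function(x) x@bp)

setMethod("show", "FrameSchedule", function(object) {
  cat(sprintf("FrameSchedule: %d frames, %.0f s total (%.1f min)\n",
              nFrames(object), sum(object@duration),
              sum(object@duration) / 60))
})

setMethod("show", "ImageVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("ImageVolume [%s]: %s voxels @ %s mm\n", object@modality,
              paste(d, collapse = " x "),
              paste(signif(voxelSize(object), 3), collapse = " x ")))
  if (!is.null(object@schedule))
    cat(sprintf("  dynamic, %d frames over %.1f min\n",
                nFrames(object@schedule),
                sum(object@schedule@duration) / 60))
})

setMethod("show", "LabelMap", function(object) {
  cat(sprintf("LabelMap: %s voxels, regions: %s\n",
              paste(dim(object@labels), collapse = " x "),
              paste(names(object@regions), collapse = ", ")))
})

setMethod("show", "TAC", function(object) {
  cat(sprintf("TAC [%s]: %d frames, peak %.2f kBq/mL\n",
              object@region, length(object@midTime),
              max(object@activity)))
})

setMethod("show", "SRTMFit", function(object) {
  cat(sprintf("SRTMFit: BP_ND = %.3f, R1 = %.3f, k2 = %.4f /min (%s)\n",
              object@bp, object@R1, object@k2,
              if (object@converged) "converged" else "NOT converged"))
})

setMethod("show", "RigidTransform", function(object) {
  cat(sprintf("RigidTransform: t = (%s) mm, rot = (%s) deg\n",
              paste(signif(object@translation, 4), collapse = ", "),
              paste(signif(object@rotation * 180 / pi, 4), collapse = ", ")))
})

setMethod("show", "BasisWarp", function(object) {
  cat(sprintf("BasisWarp: cutoff %d (%d basis/axis), max |coef| %.3f mm\n",
              object@cutoff, object@cutoff^3, max(abs(object@coef))))
})

setMethod("show", "TransformChain", function(object) {
  cat(sprintf("TransformChain of %d transforms: %s\n",
              length(object@transforms),
              paste(vapply(object@transforms, class, character(1)),
                    collapse = " -> ")))
})

setMethod("show", "Cohort", function(object) {
  gt <- vapply(object@subjects, function(s) s$truth@genotype, character(1))
  cat(sprintf("Cohort: %d subjects (%d WT, %d HET), seed %d\n",
              length(object@subjects), sum(gt == "WT"), sum(gt == "HET"),
              object@seed))
})
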