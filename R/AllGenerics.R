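#' @include AllClasses.R
NULL

#' Voxel data of a volume or label map
#' @param x an ImageVolume or LabelMap
#' @return the underlying array
#' @export
setGeneric("imgData", function(x) standardGeneric("imgData"))

#' Voxel size in mm per spatial axis
#' @param x an ImageVolume or LabelMap
#' @return numeric length 3 (mm)
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' Voxel-to-world affine (RAS mm, 0-based voxel indices)
#' @param x an ImageVolume or LabelMap
#' @return 4x4 matrix
#' @export
setGeneric("worldAffine", function(x) standardGeneric("worldAffine"))

#' Modality tag of a volume
#' @param x an ImageVolume
#' @return character scalar
#' @export
setGeneric("modality", function(x) standardGeneric("modality"))

#' Frame schedule attached to a volume
#' @param x an ImageVolume or TAC
#' @return a FrameSchedule or NULL
#' @export
setGeneric("frameSchedule", function(x) standardGeneric("frameSchedule"))

#' Frame mid-times in minutes
#' @param x a FrameSchedule or TAC
#' @return numeric vector (min)
#' @export
setGeneric("midTimes", function(x) standardGeneric("midTimes"))

#' Number of frames
#' @param x a FrameSchedule or 4D ImageVolume
#' @return integer
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' Region names of a label map
#' @param x a LabelMap
#' @return character vector
#' @export
setGeneric("regionNames", function(x) standardGeneric("regionNames"))

#' Regional activity values of a TAC (kBq/mL)
#' @param x a TAC
#' @return numeric vector
#' @export
setGeneric("activity", function(x) standardGeneric("activity"))

#' Binding potential (BP_ND) of a kinetic fit
#' @param x an SRTMFit
#' @return numeric scalar
#' @export
setGeneric("bindingPotential", function(x) standardGeneric("bindingPotential"))

#' Apply a spatial transform to world points
#'
#' Maps an N x 3 matrix of world coordinates (mm) through a rigid
#' transform, a cosine-basis warp, or a lazily evaluated chain (elements
#' applied first to last).
#'
#' @param transform a RigidTransform, BasisWarp or TransformChain
#' @param points N x 3 numeric matrix of world coordinates (mm)
#' @return N x 3 matrix of mapped world coordinates
#' @export
setGeneric("applyTransform",
           function(transform, points) standardGeneric("applyTransform"))

#' Invert a transform
#'
#' Rigid transforms (and chains of rigid transforms) are invertible in
#' closed form; basis warps are not and raise an error.
#'
#' @param transform a RigidTransform or rigid-only TransformChain
#' @return the inverse transform
#' @export
setGeneric("invertTransform",
           function(transform) standardGeneric("invertTransform"))
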