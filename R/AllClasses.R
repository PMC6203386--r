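#' @import methods
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' Dynamic-frame schedule
#'
#' Frame timing of a dynamic PET acquisition: per-frame start times and
#' durations in seconds. Frames must be contiguous and non-overlapping.
#' Mid-times (in minutes) are derived, not stored.
#'
#' @slot start numeric, frame start times (s), first frame starts at 0.
#' @slot duration numeric, frame durations (s), strictly positive.
#' @export
setClass("FrameSchedule",
  representation(start = "numeric", duration = "numeric"))

setValidity("FrameSchedule", function(object) {
  s <- object@start; d <- object@duration
  if (length(s) != length(d)) return("start and duration lengths differ")
  if (length(s) == 0L) return("empty schedule")
  if (any(d <= 0)) return("frame durations must be > 0")
  if (any(abs(s[-1] - (s[-length(s)] + d[-length(d)])) > 1e-6))
    return("frames must be contiguous and non-overlapping")
  TRUE
})

setClassUnion("FrameScheduleOrNULL", c("FrameSchedule", "NULL"))

#' Image volume
#'
#' A 3D (x, y, z) or 4D (x, y, z, frame) voxel grid with a voxel-to-world
#' affine (RAS, mm; voxel centers at integer 0-based indices) and a modality
#' tag. 4D volumes carry a \linkS4class{FrameSchedule} whose frame count
#' equals the 4th dimension.
#'
#' @slot data numeric array, 3D or 4D.
#' @slot affine 4x4 voxel-to-world matrix (mm), invertible.
#' @slot modality one of "MRI", "CT", "PET-static", "PET-dynamic", "BP-map".
#' @slot schedule FrameSchedule for 4D data, otherwise NULL.
#' @export
setClass("ImageVolume",
  representation(data = "array", affine = "matrix", modality = "character",
                 schedule = "FrameScheduleOrNULL"))

.modalities <- c("MRI", "CT", "PET-static", "PET-dynamic", "BP-map")

setValidity("ImageVolume", function(object) {
  d <- dim(object@data)
  if (!(length(d) %in% c(3L, 4L))) return("data must be a 3D or 4D array")
  if (!all(dim(object@affine) == c(4L, 4L))) return("affine must be 4x4")
  if (abs(det(object@affine)) < 1e-12) return("affine must be invertible")
  vs <- sqrt(colSums(object@affine[1:3, 1:3]^2))
  if (any(vs <= 0)) return("voxel sizes must be strictly positive")
  if (!(object@modality %in% .modalities))
    return(paste("unknown modality:", object@modality))
  nbad <- sum(!is.finite(object@data))
  if (nbad > 0) return(sprintf("%d non-finite voxel(s) in data", nbad))
  if (length(d) == 4L) {
    if (is.null(object@schedule))
      return("4D volume requires a frame schedule")
    if (length(object@schedule@start) != d[4L])
      return("schedule frame count must equal 4th dimension")
  }
  TRUE
})

#' Integer-coded anatomical label map
#'
#' Region labels (striatum L/R, cerebellum, whole brain, skull, ...) on an
#' image grid. Background is 0; region codes are unique and named through
#' the \code{regions} table.
#'
#' @slot labels integer 3D array of region codes.
#' @slot affine 4x4 voxel-to-world matrix (mm).
#' @slot regions named integer vector mapping region name -> code.
#' @export
setClass("LabelMap",
  representation(labels = "array", affine = "matrix", regions = "integer"))

setValidity("LabelMap", function(object) {
  if (length(dim(object@labels)) != 3L) return("labels must be 3D")
  if (!all(dim(object@affine) == c(4L, 4L))) return("affine must be 4x4")
  if (anyDuplicated(object@regions)) return("region codes must be unique")
  if (anyDuplicated(names(object@regions))) return("region names must be unique")
  if (any(object@regions == 0L)) return("code 0 is reserved for background")
  TRUE
})

#' Regional time-activity curve
#'
#' Mean regional activity concentration (kBq/mL) per dynamic frame, with
#' frame mid-times (min) and durations (s).
#'
#' @slot midTime numeric, frame mid-times (min), strictly increasing.
#' @slot duration numeric, frame durations (s).
#' @slot activity numeric, mean activity (kBq/mL) per frame.
#' @slot region region name the curve was extracted from.
#' @export
setClass("TAC",
  representation(midTime = "numeric", duration = "numeric",
                 activity = "numeric", region = "character"))

setValidity("TAC", function(object) {
  n <- length(object@midTime)
  if (length(object@duration) != n || length(object@activity) != n)
    return("midTime, duration and activity must have equal length")
  if (n > 1 && any(diff(object@midTime) <= 0))
    return("mid-times must be strictly increasing")
  if (any(object@duration <= 0)) return("durations must be > 0")
  TRUE
})

#' Simplified reference tissue model fit
#'
#' SRTM parameters relating a target-region TAC to a reference-region TAC:
#' delivery ratio R1, target efflux rate k2 (1/min) and binding potential
#' BP_ND. The apparent efflux rate k2a = k2 / (1 + BP_ND) is derived.
#'
#' @slot R1 numeric, delivery ratio (unitless).
#' @slot k2 numeric, efflux rate constant (1/min), > 0 for converged fits.
#' @slot bp numeric, non-displaceable binding potential (unitless).
#' @slot rss numeric, weighted residual sum of squares.
#' @slot converged logical.
#' @slot fitted numeric, model-predicted target activity per frame.
#' @export
setClass("SRTMFit",
  representation(R1 = "numeric", k2 = "numeric", bp = "numeric",
                 rss = "numeric", converged = "logical", fitted = "numeric"))

setValidity("SRTMFit", function(object) {
  if (isTRUE(object@converged)) {
    if (!is.finite(object@bp)) return("converged fit must have finite BP_ND")
    if (!(object@k2 > 0)) return("converged fit must have k2 > 0")
  }
  TRUE
})

#' Rigid-body transform
#'
#' 6-parameter rigid motion: translation (mm) and intrinsic z-y-x Euler
#' rotation (radians) about a fixed rotation center (world mm). Maps world
#' points as x -> R (x - c) + c + t. The identity has all parameters 0.
#'
#' @slot translation numeric length 3, mm.
#' @slot rotation numeric length 3, radians (z, y, x intrinsic order).
#' @slot center numeric length 3, rotation center in world mm.
#' @export
setClass("RigidTransform",
  representation(translation = "numeric", rotation = "numeric",
                 center = "numeric"))

setValidity("RigidTransform", function(object) {
  if (length(object@translation) != 3L || length(object@rotation) != 3L ||
      length(object@center) != 3L) return("parameters must have length 3")
  if (!all(is.finite(c(object@translation, object@rotation, object@center))))
    return("parameters must be finite")
  TRUE
})

#' Low-frequency cosine-basis deformation
#'
#' A smooth displacement field over a domain grid, parameterized per world
#' axis by coefficients on a separable 3D cosine basis (the \code{cutoff}
#' lowest frequencies per spatial axis, so cutoff^3 basis functions per
#' displacement component). Zero coefficients give the identity warp.
#' Maps world points as x -> x + d(x) with d in mm.
#'
#' @slot coef (cutoff^3) x 3 matrix of displacement coefficients (mm).
#' @slot cutoff integer, basis frequencies per axis.
#' @slot regWeight regularization weight used at estimation time.
#' @slot domainDim integer length 3, grid size of the warp domain.
#' @slot domainAffine 4x4 voxel-to-world matrix of the warp domain.
#' @export
setClass("BasisWarp",
  representation(coef = "matrix", cutoff = "integer", regWeight = "numeric",
                 domainDim = "integer", domainAffine = "matrix"))

setValidity("BasisWarp", function(object) {
  k <- object@cutoff
  if (length(k) != 1L || k < 1L) return("cutoff must be a positive integer")
  if (!all(dim(object@coef) == c(k^3, 3L)))
    return("coef must be cutoff^3 x 3")
  if (length(object@domainDim) != 3L) return("domainDim must have length 3")
  if (!all(dim(object@domainAffine) == c(4L, 4L)))
    return("domainAffine must be 4x4")
  TRUE
})

#' Lazily evaluated transform chain
#'
#' An ordered list of transforms applied first-to-last to world points.
#' Produced by \code{\link{composeTransforms}} when the composition cannot
#' be collapsed to a single rigid transform.
#'
#' @slot transforms list of RigidTransform / BasisWarp objects.
#' @export
setClass("TransformChain", representation(transforms = "list"))

setValidity("TransformChain", function(object) {
  ok <- vapply(object@transforms,
               function(t) is(t, "RigidTransform") || is(t, "BasisWarp") ||
                 is(t, "TransformChain"), logical(1))
  if (!all(ok)) return("chain elements must be spatial transforms")
  TRUE
})

#' Digital mouse-brain phantom specification
#'
#' Geometry, tissue intensities, acquisition characteristics and
#' inter-subject variability of the multimodal phantom generator. Regions
#' are ellipsoids (brain, striatum L/R, cerebellum) plus an ellipsoidal
#' skull shell; all regions lie inside the head field of view.
#'
#' @slot geometry list: per-modality grid dims/voxel sizes and region
#'   ellipsoid centers/semi-axes (mm, world coordinates).
#' @slot intensity list: per-tissue mean intensities for MRI (T2-like) and
#'   CT (skull well above the 500 threshold, soft tissue below).
#' @slot acquisition list: PET PSF FWHM (mm), per-modality noise scales,
#'   MRI bias-field amplitude.
#' @slot variability list: random rigid pose ranges (mm, deg) and smooth
#'   deformation amplitude (mm) for inter-subject variation.
#' @export
setClass("PhantomSpec",
  representation(geometry = "list", intensity = "list",
                 acquisition = "list", variability = "list"))

setValidity("PhantomSpec", function(object) {
  g <- object@geometry; it <- object@intensity
  need <- c("dimMRI", "voxMRI", "dimPET", "voxPET", "dimCT", "voxCT",
            "brain", "striatumL", "striatumR", "cerebellum", "skull")
  if (!all(need %in% names(g)))
    return(paste("geometry missing:",
                 paste(setdiff(need, names(g)), collapse = ", ")))
  if (it$ct[["skull"]] <= 500)
    return("CT skull mean intensity must exceed the 500 threshold")
  if (any(unlist(it$ct[c("brain", "striatum", "cerebellum")]) >= 500))
    return("CT soft-tissue intensities must be below 500")
  TRUE
})

#' Per-subject ground truth of a simulated animal
#'
#' @slot id subject identifier.
#' @slot genotype "WT" or "HET".
#' @slot bp true striatal BP_ND (> 0).
#' @slot R1 true delivery ratio.
#' @slot k2 true efflux rate (1/min).
#' @slot poseMRI rigid pose of the animal in the MRI acquisition frame.
#' @slot posePET rigid pose in the PET/CT acquisition frame (shared gantry).
#' @slot deform smooth anatomical deformation (shape variability), or NULL.
#' @slot striatumScale linear semi-axis scale applied to the striatum
#'   (atrophy^(1/3) for HET before subject noise).
#' @slot striatalVolume true striatal label volume (mm^3, both sides).
#' @slot brainVolume whole-brain label volume (mm^3).
#' @slot labels LabelMap in the subject MRI frame.
#' @export
setClass("SubjectGroundTruth",
  representation(id = "character", genotype = "character", bp = "numeric",
                 R1 = "numeric", k2 = "numeric",
                 poseMRI = "RigidTransform", posePET = "RigidTransform",
                 deform = "ANY", striatumScale = "numeric",
                 striatalVolume = "numeric", brainVolume = "numeric",
                 labels = "ANY"))

setValidity("SubjectGroundTruth", function(object) {
  if (!(object@genotype %in% c("WT", "HET"))) return("genotype must be WT or HET")
  if (object@bp <= 0) return("true BP_ND must be > 0")
  TRUE
})

#' Simulated multimodal cohort
#'
#' A list of subjects (ground truth plus MRI / CT / dynamic PET / static
#' PET volumes) with the generating configuration and seed; reproducible
#' as a pure function of (config, seed).
#'
#' @slot subjects list; each element has $truth and optionally $mri, $ct,
#'   $pet (4D), $static.
#' @slot spec the PhantomSpec used.
#' @slot config generation configuration (group sizes, distributions).
#' @slot seed integer seed the cohort was generated from.
#' @export
setClass("Cohort",
  representation(subjects = "list", spec = "PhantomSpec", config = "list",
                 seed = "integer"))

setValidity("Cohort", function(object) {
  if (length(object@subjects) == 0L) return("cohort has no subjects")
  ok <- vapply(object@subjects,
               function(s) is(s$truth, "SubjectGroundTruth"), logical(1))
  if (!all(ok)) return("every subject needs a SubjectGroundTruth")
  TRUE
})
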