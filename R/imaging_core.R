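#' @include geometry.R accessors.R
NULL

#' Construct an ImageVolume
#'
#' @param data 3D or 4D numeric array (x, y, z[, frame]).
#' @param affine 4x4 voxel-to-world matrix (mm). If NULL, built from
#'   \code{voxelSize} with the world origin at the volume center.
#' @param voxelSize mm per axis (used only when \code{affine} is NULL).
#' @param modality one of "MRI", "CT", "PET-static", "PET-dynamic", "BP-map".
#' @param schedule a \linkS4class{FrameSchedule} (required for 4D data).
#' @return an \linkS4class{ImageVolume}
#' @examples
#' vol <- imageVolume(array(1, c(8, 8, 8)), voxelSize = c(0.2, 0.2, 0.25),
#'                    modality = "MRI")
#' voxelSize(vol)
#' @export
imageVolume <- function(data, affine = NULL, voxelSize = c(1, 1, 1),
                        modality = "MRI", schedule = NULL) {
  data <- as.array(data)
  if (is.null(affine)) {
    affine <- diag(c(voxelSize, 1))
    affine[1:3, 4] <- -voxelSize * (dim(data)[1:3] - 1) / 2
  }
  new("ImageVolume", data = data, affine = affine, modality = modality,
      schedule = schedule)
}

#' Construct a LabelMap
#'
#' @param labels integer 3D array of region codes (0 = background).
#' @param affine 4x4 voxel-to-world matrix; or NULL with \code{voxelSize}.
#' @param regions named integer vector, region name -> code.
#' @param voxelSize mm per axis when \code{affine} is NULL.
#' @return a \linkS4class{LabelMap}
#' @export
labelMap <- function(labels, affine = NULL, regions,
                     voxelSize = c(1, 1, 1)) {
  labels <- as.array(labels)
  storage.mode(labels) <- "integer"
  if (is.null(affine)) {
    affine <- diag(c(voxelSize, 1))
    affine[1:3, 4] <- -voxelSize * (dim(labels)[1:3] - 1) / 2
  }
  new("LabelMap", labels = labels, affine = affine,
      regions = structure(as.integer(regions), names = names(regions)))
}

#' Construct a frame schedule
#'
#' @param duration frame durations in seconds (frames are contiguous,
#'   starting at \code{start0}).
#' @param start0 start time of the first frame (s), default 0.
#' @return a \linkS4class{FrameSchedule}
#' @export
frameScheduleFromDurations <- function(duration, start0 = 0) {
  start <- start0 + c(0, cumsum(duration))[seq_along(duration)]
  new("FrameSchedule", start = start, duration = duration)
}

#' The default 90-minute dynamic schedule
#'
#' 39 frames of increasing duration (12x10 s, 3x20 s, 3x30 s, 3x60 s,
#' 3x150 s, 15x300 s) covering 5400 s = 90 min, the standard acquisition
#' this package models.
#'
#' @return a \linkS4class{FrameSchedule} with 39 frames totalling 5400 s
#' @examples
#' sched <- defaultFrameSchedule()
#' nFrames(sched)          # 39
#' sum(sched@duration)     # 5400 s
#' @export
defaultFrameSchedule <- function() {
  frameScheduleFromDurations(c(rep(10, 12), rep(20, 3), rep(30, 3),
                               rep(60, 3), rep(150, 3), rep(300, 15)))
}

#' A short dynamic schedule for reduced-scale simulations
#'
#' 12 frames spanning the same 90 minutes (4x30 s, 4x120 s, 4x1200 s);
#' useful where the full 39-frame schedule is unnecessarily fine.
#'
#' @return a \linkS4class{FrameSchedule}
#' @export
coarseFrameSchedule <- function() {
  frameScheduleFromDurations(c(rep(30, 4), rep(120, 4), rep(1200, 4)))
}

.scheduleSidecar <- function(path) paste0(path, ".frames.tsv")

#' Read / write NIfTI-1 volumes
#'
#' \code{readVolume} reads a 3D or 4D NIfTI-1 file into an
#' \linkS4class{ImageVolume}; \code{writeVolume} writes one. 4D volumes
#' carry their frame schedule in a TSV sidecar
#' (\code{<path>.frames.tsv} with columns frame_start_s,
#' frame_duration_s), written and re-read automatically. Round trips
#' preserve data, voxel size and affine to better than 1e-6.
#'
#' @param path file path (.nii or .nii.gz).
#' @param modality modality tag to attach on read.
#' @param schedule optional FrameSchedule overriding the sidecar.
#' @param vol an ImageVolume to write.
#' @return \code{readVolume}: an ImageVolume; \code{writeVolume}: the
#'   path, invisibly.
#' @export
readVolume <- function(path, modality = "MRI", schedule = NULL) {
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("malformed NIfTI file '", path,
                                           "': ", conditionMessage(e)))
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = c(4L, 4L))
  pd <- RNifti::niftiHeader(path)$pixdim[2:4]  # raw, unsanitized header
  if (any(pd <= 0))
    stop("invalid NIfTI header: non-positive voxel size (",
         paste(signif(pd, 4), collapse = ", "), ")")
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr))
  nbad <- sum(!is.finite(arr))
  if (nbad > 0)
    stop("volume contains ", nbad, " non-finite voxel(s)")
  if (length(dim(arr)) == 4L && is.null(schedule)) {
    sc <- .scheduleSidecar(path)
    if (file.exists(sc)) {
      tab <- utils::read.delim(sc)
      schedule <- new("FrameSchedule", start = tab$frame_start_s,
                      duration = tab$frame_duration_s)
    } else {
      stop("4D volume '", path, "' has no frame-schedule sidecar and no ",
           "schedule was supplied")
    }
  }
  if (length(dim(arr)) == 3L) schedule <- NULL
  new("ImageVolume", data = arr, affine = aff, modality = modality,
      schedule = schedule)
}

#' @rdname readVolume
#' @export
writeVolume <- function(vol, path) {
  stopifnot(is(vol, "ImageVolume"))
  vs <- voxelSize(vol)
  img <- RNifti::asNifti(vol@data,
                         reference = list(pixdim = c(-1, vs, rep(0, 4))))
  RNifti::sform(img) <- structure(vol@affine, code = 2L)
  RNifti::qform(img) <- structure(vol@affine, code = 2L)
  RNifti::writeNifti(img, path)
  if (!is.null(vol@schedule)) {
    utils::write.table(
      data.frame(frame_start_s = vol@schedule@start,
                 frame_duration_s = vol@schedule@duration),
      .scheduleSidecar(path), sep = "\t", row.names = FALSE,
      quote = FALSE)
  }
  invisible(path)
}

#' Read / write a LabelMap as integer NIfTI plus JSON name table
#'
#' @param lab a LabelMap (for writing).
#' @param path NIfTI path; the name table goes to \code{<path>.regions.json}.
#' @return \code{readLabelMap}: a LabelMap; \code{writeLabelMap}: the path.
#' @export
writeLabelMap <- function(lab, path) {
  stopifnot(is(lab, "LabelMap"))
  vol <- imageVolume(lab@labels * 1.0, affine = lab@affine, modality = "MRI")
  writeVolume(vol, path)
  jsonlite::write_json(as.list(lab@regions), paste0(path, ".regions.json"),
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeLabelMap
#' @export
readLabelMap <- function(path) {
  vol <- readVolume(path)
  reg <- jsonlite::read_json(paste0(path, ".regions.json"),
                             simplifyVector = TRUE)
  labelMap(round(vol@data), affine = vol@affine,
           regions = structure(unlist(reg), names = names(reg)))
}

#' Resample a volume through a spatial transform
#'
#' Trilinear interpolation of \code{vol} onto \code{targetGeometry}. The
#' transform maps target-world points into the source volume's world frame
#' (the pull-back convention used by all registration outputs here), so
#' \code{resampleVolume(moving, rigidRegister(moving, fixed), fixed)}
#' yields the moving image aligned to the fixed one. 4D volumes are
#' resampled frame-wise through the one 3D transform, preserving the
#' schedule; out-of-field voxels take \code{fill}.
#'
#' @param vol source ImageVolume (3D or 4D).
#' @param transform RigidTransform, BasisWarp or TransformChain; NULL means
#'   identity.
#' @param targetGeometry an ImageVolume, LabelMap, or list(dim, affine)
#'   defining the output grid; defaults to the source grid.
#' @param fill value for voxels mapped outside the source field of view.
#' @return an ImageVolume on the target grid
#' @export
resampleVolume <- function(vol, transform = NULL, targetGeometry = NULL,
                           fill = 0) {
  stopifnot(is(vol, "ImageVolume"))
  geom <- geometryOf(if (is.null(targetGeometry)) vol else targetGeometry)
  pts <- gridWorld(geom)
  if (!is.null(transform)) pts <- applyTransform(transform, pts)
  idx <- worldToVoxel(vol@affine, pts)
  plan <- trilinearPlan(idx, dim(vol@data)[1:3])
  d <- dim(vol@data)
  if (length(d) == 3L) {
    out <- array(applyPlan(plan, vol@data, fill), geom$dim)
  } else {
    out <- array(0, c(geom$dim, d[4]))
    for (f in seq_len(d[4]))
      out[, , , f] <- applyPlan(plan, vol@data[, , , f], fill)
  }
  new("ImageVolume", data = out, affine = geom$affine,
      modality = vol@modality, schedule = vol@schedule)
}

#' Resample a label map (per-region trilinear indicator, majority vote)
#'
#' Each region's indicator image is resampled trilinearly and a voxel is
#' assigned the region with the largest interpolated weight, provided
#' that weight exceeds \code{threshold}; used to carry VOIs across
#' spaces. The default 0.5 is a plain majority vote; quantification VOIs
#' use a stricter threshold (see \code{\link{quantifyIndividual}}) so the
#' transferred region stays inside its source region and reference-region
#' TACs are not contaminated by neighboring tissue.
#'
#' @param lab a LabelMap.
#' @param transform transform mapping target world -> label world (or NULL).
#' @param targetGeometry output grid (default: label grid).
#' @param threshold minimum interpolated indicator weight for membership.
#' @return a LabelMap on the target grid
#' @export
resampleLabelMap <- function(lab, transform = NULL, targetGeometry = NULL,
                             threshold = 0.5) {
  stopifnot(is(lab, "LabelMap"))
  geom <- geometryOf(if (is.null(targetGeometry)) lab else targetGeometry)
  pts <- gridWorld(geom)
  if (!is.null(transform)) pts <- applyTransform(transform, pts)
  idx <- worldToVoxel(lab@affine, pts)
  plan <- trilinearPlan(idx, dim(lab@labels))
  best <- numeric(prod(geom$dim))
  out <- integer(prod(geom$dim))
  for (nm in names(lab@regions)) {
    code <- lab@regions[[nm]]
    w <- applyPlan(plan, (lab@labels == code) * 1.0, 0)
    take <- w > threshold & w > best
    out[take] <- code
    best[take] <- w[take]
  }
  labelMap(array(out, geom$dim), affine = geom$affine,
           regions = lab@regions)
}

#' Zero sub-threshold CT voxels
#'
#' Replaces CT values below \code{cutoff} with 0 (default 500), isolating
#' the bright skull for skull-driven registration.
#'
#' @param ct a CT ImageVolume.
#' @param cutoff intensity threshold, default 500.
#' @return the thresholded ImageVolume
#' @export
thresholdCT <- function(ct, cutoff = 500) {
  stopifnot(is(ct, "ImageVolume"))
  if (modality(ct) != "CT") stop("thresholdCT expects a CT volume")
  d <- ct@data
  d[d < cutoff] <- 0
  new("ImageVolume", data = d, affine = ct@affine, modality = "CT",
      schedule = ct@schedule)
}

#' Crop a volume to the bounding box of a mask
#'
#' Cuts \code{vol} to the bounding box of the non-background voxels of
#' \code{mask} (a LabelMap on the same grid, or any of its regions via
#' \code{region}), dilated by \code{margin} mm per axis. The affine is
#' shifted so world coordinates are preserved.
#'
#' @param vol an ImageVolume.
#' @param mask a LabelMap on the same grid.
#' @param margin dilation of the bounding box in mm (per axis).
#' @param region optional region name; default uses all non-zero labels.
#' @return the cropped ImageVolume
#' @export
cropBrain <- function(vol, mask, margin = 0, region = NULL) {
  stopifnot(is(vol, "ImageVolume"), is(mask, "LabelMap"))
  if (!all(dim(mask@labels) == dim(vol@data)[1:3]))
    stop("mask grid does not match volume grid")
  m <- if (is.null(region)) mask@labels != 0L else
    mask@labels == mask@regions[[region]]
  if (!any(m)) stop("empty mask: nothing to crop to")
  w <- which(m, arr.ind = TRUE)
  mv <- ceiling(margin / voxelSize(vol))
  d <- dim(vol@data)[1:3]
  lo <- pmax(apply(w, 2, min) - mv, 1)
  hi <- pmin(apply(w, 2, max) + mv, d)
  dat <- if (length(dim(vol@data)) == 3L)
    vol@data[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  else
    vol@data[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], , drop = FALSE]
  aff <- vol@affine
  aff[1:3, 4] <- voxelToWorld(vol@affine, matrix(lo - 1, 1, 3))[1, ]
  new("ImageVolume", data = dat, affine = aff, modality = vol@modality,
      schedule = vol@schedule)
}

#' Region volume in mm^3
#'
#' Voxel count times voxel volume for a named region.
#'
#' @param lab a LabelMap.
#' @param region region name.
#' @return volume in mm^3
#' @export
voiVolume <- function(lab, region) {
  stopifnot(is(lab, "LabelMap"))
  if (!(region %in% names(lab@regions)))
    stop("unknown region '", region, "'")
  sum(lab@labels == lab@regions[[region]]) * prod(voxelSize(lab))
}

#' Striatum / whole-brain volume ratio
#'
#' The striatal volume (left + right if present as separate regions, or a
#' single "striatum" region) normalized to the whole-brain volume.
#'
#' @param lab a LabelMap with striatal and whole-brain regions.
#' @param brainRegion name of the whole-brain region.
#' @return the volume ratio (unitless)
#' @export
striatumBrainRatio <- function(lab, brainRegion = "brain") {
  strs <- intersect(c("striatumL", "striatumR", "striatum"),
                    names(lab@regions))
  if (length(strs) == 0L) stop("no striatal region in label map")
  sv <- sum(vapply(strs, function(r) voiVolume(lab, r), numeric(1)))
  bv <- voiVolume(lab, brainRegion)
  # brain code marks the whole brain; striatum/cerebellum are coded
  # separately inside it, so add them back to the denominator
  inner <- intersect(c(strs, "cerebellum"), names(lab@regions))
  bv <- bv + sum(vapply(inner, function(r) voiVolume(lab, r), numeric(1)))
  sv / bv
}

.shiftMask <- function(m, ax, by) {
  d <- dim(m)
  out <- array(FALSE, d)
  src <- lapply(d, seq_len)
  dst <- src
  if (by > 0) { src[[ax]] <- 1:(d[ax] - by); dst[[ax]] <- (1 + by):d[ax] }
  else { src[[ax]] <- (1 - by):d[ax]; dst[[ax]] <- 1:(d[ax] + by) }
  out[dst[[1]], dst[[2]], dst[[3]]] <- m[src[[1]], src[[2]], src[[3]]]
  out
}

.erodeOnce6 <- function(m) {
  m & .shiftMask(m, 1, 1) & .shiftMask(m, 1, -1) &
    .shiftMask(m, 2, 1) & .shiftMask(m, 2, -1) &
    .shiftMask(m, 3, 1) & .shiftMask(m, 3, -1)
}

.dilateOnce6 <- function(m) {
  m | .shiftMask(m, 1, 1) | .shiftMask(m, 1, -1) |
    .shiftMask(m, 2, 1) | .shiftMask(m, 2, -1) |
    .shiftMask(m, 3, 1) | .shiftMask(m, 3, -1)
}

#' Erode a region to a volume fraction
#'
#' Iterative 6-connected morphological erosion of a region until its
#' volume first falls to at most \code{fraction} of the original; the
#' result is wholly contained in the original region. Used to form the
#' "focal" inner-striatum VOI (default fraction 0.5) that limits partial
#' volume contamination at the region rim.
#'
#' @param lab a LabelMap.
#' @param region region name.
#' @param fraction target volume fraction in (0, 1]; 1 returns the input.
#' @return a LabelMap in which \code{region} is replaced by its eroded core
#' @export
erodeToFraction <- function(lab, region, fraction = 0.5) {
  stopifnot(is(lab, "LabelMap"), fraction > 0, fraction <= 1)
  if (!(region %in% names(lab@regions)))
    stop("unknown region '", region, "'")
  code <- lab@regions[[region]]
  m <- lab@labels == code
  n0 <- sum(m)
  if (n0 == 0L) stop("region '", region, "' is empty")
  if (fraction == 1) return(lab)
  target <- fraction * n0
  m2 <- m
  while (sum(m2) > target) {
    m3 <- .erodeOnce6(m2)
    if (!any(m3))
      stop("region '", region, "' vanishes before reaching fraction ",
           fraction, "; achievable minimum is ", sum(m2), " of ", n0,
           " voxels")
    m2 <- m3
  }
  out <- lab@labels
  out[m & !m2] <- 0L
  labelMap(out, affine = lab@affine, regions = lab@regions)
}

#' Keep the hottest fraction of a region
#'
#' Restricts \code{region} to its ceil(fraction * N) highest-intensity
#' voxels in \code{img} (a static or BP-map volume). Ties are broken by
#' lexicographic voxel index, so the selection is deterministic.
#'
#' @param img a 3D ImageVolume on the label grid.
#' @param lab a LabelMap.
#' @param region region name.
#' @param fraction fraction of voxels to keep, in (0, 1].
#' @return a LabelMap in which \code{region} keeps only its hottest voxels
#' @export
hottestFraction <- function(img, lab, region, fraction = 0.2) {
  stopifnot(is(img, "ImageVolume"), is(lab, "LabelMap"),
            fraction > 0, fraction <= 1)
  if (length(dim(img@data)) != 3L)
    stop("hottestFraction needs a static 3D volume or BP map")
  if (!all(dim(img@data) == dim(lab@labels)))
    stop("image and label grids differ")
  code <- lab@regions[[region]]
  if (is.null(code) || is.na(code)) stop("unknown region '", region, "'")
  vox <- which(lab@labels == code)
  if (length(vox) == 0L) stop("region '", region, "' is empty")
  n <- ceiling(fraction * length(vox))
  ord <- vox[order(-img@data[vox], vox)]
  keep <- ord[seq_len(n)]
  out <- lab@labels
  out[setdiff(vox, keep)] <- 0L
  labelMap(out, affine = lab@affine, regions = lab@regions)
}
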