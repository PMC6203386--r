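#' @include templates.R
NULL

.routeResult <- function(dyn, provenance) list(dyn = dyn,
                                               provenance = provenance)

.excluded <- function(route, id, reason) {
  warning("subject ", id, " excluded from ", route, " route: ", reason)
  list(dyn = NULL,
       provenance = list(route = route, subject = id, excluded = TRUE,
                         reason = reason))
}

#' MRI template-based normalization of a subject's dynamic PET
#'
#' Step 1: the subject's thresholded CT is rigidly registered to the
#' subject's own MRI (downhill simplex, NMI) and that mapping carries the
#' PET (acquired on the same gantry as the CT). Step 2: the subject MRI
#' is normalized (rigid + cosine-basis warp) to the MRI template. The
#' dynamic PET is resampled once through the composed chain, so the data
#' are interpolated a single time.
#'
#' @param subject a cohort subject (list with $mri, $ct, $pet, $truth).
#' @param templates result of \code{\link{buildTemplates}}.
#' @param ctThreshold CT threshold before registration (default 500).
#' @param iterations,cutoff,regWeight warp settings.
#' @return list(dyn, provenance): the template-space 4D volume (NULL if
#'   the subject was excluded for a failed registration) and a provenance
#'   record listing the 2 estimated transforms
#' @export
routeMRI <- function(subject, templates, ctThreshold = 500,
                     iterations = 16, cutoff = 3, regWeight = 1) {
  id <- subject$truth@id
  rigCT <- tryCatch(
    rigidRegister(thresholdCT(subject$ct, ctThreshold), subject$mri,
                  metric = "nmi"),
    error = function(e) NULL)
  if (is.null(rigCT) || !isTRUE(attr(rigCT, "converged")))
    return(.excluded("mri", id, "CT-to-MRI rigid registration failed"))
  norm <- .normalizeToTemplate(subject$mri, templates$mri,
                               metric = "ncc", iterations = iterations,
                               cutoff = cutoff, regWeight = regWeight)
  if (!norm$converged)
    return(.excluded("mri", id, "MRI-to-template normalization failed"))
  chain <- composeTransforms(norm$chain, rigCT)
  dyn <- resampleVolume(subject$pet, chain, templates$petGrid)
  .routeResult(dyn, list(
    route = "mri", subject = id, excluded = FALSE,
    transforms = list(ct_to_mri = rigCT, mri_to_template = norm$chain),
    nEstimated = 2L))
}

#' PET template-based normalization
#'
#' The subject's static PET is normalized (rigid + cosine-basis warp)
#' directly to the tracer PET template; the estimated mapping is applied
#' to all dynamic frames in one resampling pass.
#'
#' @inheritParams routeMRI
#' @return list(dyn, provenance) with 1 estimated transform
#' @export
routePET <- function(subject, templates, iterations = 16, cutoff = 3,
                     regWeight = 1) {
  id <- subject$truth@id
  static <- if (!is.null(subject$static)) subject$static else
    staticPET(subject$pet)
  norm <- tryCatch(
    .normalizeToTemplate(static, templates$pet, metric = "ncc",
                         iterations = iterations, cutoff = cutoff,
                         regWeight = regWeight),
    error = function(e) NULL)
  if (is.null(norm) || !norm$converged)
    return(.excluded("pet", id, "static-PET-to-template warp failed"))
  dyn <- resampleVolume(subject$pet, norm$chain, templates$petGrid)
  .routeResult(dyn, list(
    route = "pet", subject = id, excluded = FALSE,
    transforms = list(pet_to_template = norm$chain), nEstimated = 1L))
}

#' CT template-based normalization
#'
#' The subject's thresholded CT is rigidly registered (downhill simplex)
#' to the CT template and the rigid mapping alone carries the dynamic
#' PET; no non-linear shape correction is applied, which is what makes
#' this route vulnerable to anatomical variability.
#'
#' @inheritParams routeMRI
#' @return list(dyn, provenance) with 1 estimated rigid transform
#' @export
routeCT <- function(subject, templates, ctThreshold = 500) {
  id <- subject$truth@id
  rig <- tryCatch(
    rigidRegister(thresholdCT(subject$ct, ctThreshold), templates$ct,
                  metric = "ncc"),
    error = function(e) NULL)
  if (is.null(rig) || !isTRUE(attr(rig, "converged")))
    return(.excluded("ct", id, "CT-to-CT-template rigid failed"))
  dyn <- resampleVolume(subject$pet, rig, templates$petGrid)
  .routeResult(dyn, list(
    route = "ct", subject = id, excluded = FALSE,
    transforms = list(ct_to_template = rig), nEstimated = 1L))
}

#' Extract a striatal TAC over one or several regions
#'
#' Unweighted mean over the union of the named regions' voxels.
#'
#' @param dyn 4D dynamic volume.
#' @param lab LabelMap on its grid.
#' @param regions character vector of region names (e.g. both striatal
#'   sides).
#' @return a TAC
#' @export
extractTACUnion <- function(dyn, lab, regions) {
  codes <- lab@regions[regions]
  if (any(is.na(codes))) stop("unknown region(s)")
  d <- dim(dyn@data)
  vox <- which(lab@labels %in% codes)
  if (length(vox) == 0L) stop("empty region union")
  nvox3 <- prod(d[1:3])
  act <- vapply(seq_len(d[4]), function(f)
    mean(dyn@data[vox + (f - 1) * nvox3]), numeric(1))
  tac(midTimes(dyn@schedule), dyn@schedule@duration, act,
      paste(regions, collapse = "+"))
}

#' Quantify BP_ND of a normalized dynamic volume with template VOIs
#'
#' Extracts the striatal (left + right) and cerebellar TACs with the
#' shared VOI set and fits SRTM with the cerebellum as reference.
#'
#' @param dyn template-space 4D volume.
#' @param vois template-space LabelMap.
#' @param weighting SRTM frame weighting.
#' @return list(fit, striatumTAC, cerebellumTAC)
#' @export
quantifyVOI <- function(dyn, vois, weighting = "duration") {
  st <- extractTACUnion(dyn, vois, c("striatumL", "striatumR"))
  cb <- extractTACUnion(dyn, vois, "cerebellum")
  fit <- srtmFit(st, cb, weighting = weighting)
  list(fit = fit, striatumTAC = st, cerebellumTAC = cb)
}

#' Individual-MRI ("manual VOI") quantification in subject space
#'
#' The reference standard of the study design: the subject's own labels
#' (standing in for VOIs manually delineated on the individual MRI) are
#' carried into the PET frame through the estimated CT-to-MRI rigid and
#' the TACs are extracted from the native dynamic PET, so no template
#' normalization is involved.
#'
#' @param subject a cohort subject.
#' @param ctRigid optional precomputed CT->MRI rigid (MRI world -> PET
#'   world); estimated if NULL.
#' @param ctThreshold CT threshold (default 500).
#' @param weighting SRTM frame weighting.
#' @param voiThreshold membership threshold for the VOI transfer to the
#'   PET grid; the conservative default keeps transferred VOIs inside
#'   their source regions (uncontaminated reference TACs).
#' @return list(fit, striatumTAC, cerebellumTAC, labels)
#' @export
quantifyIndividual <- function(subject, ctRigid = NULL, ctThreshold = 500,
                               weighting = "duration",
                               voiThreshold = 0.75) {
  if (is.null(ctRigid))
    ctRigid <- rigidRegister(thresholdCT(subject$ct, ctThreshold),
                             subject$mri, metric = "nmi")
  labPET <- resampleLabelMap(subject$truth@labels,
                             invertTransform(ctRigid),
                             geometryOf(subject$pet),
                             threshold = voiThreshold)
  st <- extractTACUnion(subject$pet, labPET, c("striatumL", "striatumR"))
  cb <- extractTACUnion(subject$pet, labPET, "cerebellum")
  fit <- srtmFit(st, cb, weighting = weighting)
  list(fit = fit, striatumTAC = st, cerebellumTAC = cb, labels = labPET)
}
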