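#' @include phantom.R
NULL

.wtSubjects <- function(cohort)
  Filter(function(s) s$truth@genotype == "WT", cohort@subjects)

# rigid pre-alignment followed by cosine-basis warping of `moving` to
# `fixedVol`; returns the composed pull-back (fixed world -> moving world)
# and the warp component separately
.normalizeToTemplate <- function(moving, fixedVol, metric = "ncc",
                                 iterations = 16, cutoff = 3,
                                 regWeight = 1) {
  rig <- rigidRegister(moving, fixedVol, metric = metric)
  aligned <- resampleVolume(moving, rig, geometryOf(fixedVol))
  warp <- nonlinearRegister(aligned, fixedVol, iterations = iterations,
                            cutoff = cutoff, regWeight = regWeight)
  list(chain = composeTransforms(warp, rig), rigid = rig, warp = warp,
       converged = isTRUE(attr(rig, "converged")))
}

#' Build the MRI template and template-space VOIs
#'
#' All WT MRIs are normalized (rigid pre-alignment plus non-linear
#' cosine-basis warping) to the first WT animal's MRI, whose grid defines
#' the template space; the voxelwise mean of the normalized images is the
#' MRI template. Template-space VOIs are derived by majority-vote fusion
#' of the subjects' warped ground-truth labels (each region is kept where
#' more than \code{voteThreshold} of subjects agree), the reproducible
#' surrogate for manual delineation on the template.
#'
#' @param cohort a Cohort with MRI volumes (only WT subjects are used).
#' @param iterations,cutoff,regWeight warp settings (defaults 16, 3, 1).
#' @param voteThreshold label-fusion vote fraction (default 0.5).
#' @return list(template, vois, transforms, subjects): the template
#'   ImageVolume, a LabelMap of fused VOIs, one pull-back transform
#'   (template world -> subject MRI world) per WT subject, and their ids
#' @export
buildMRITemplate <- function(cohort, iterations = 16, cutoff = 3,
                             regWeight = 1, voteThreshold = 0.5) {
  wt <- .wtSubjects(cohort)
  if (length(wt) < 2) stop("need at least 2 WT subjects")
  refGeom <- geometryOf(wt[[1]]$mri)
  n <- length(wt)
  acc <- array(0, refGeom$dim)
  transforms <- vector("list", n)
  votes <- list()
  regionCodes <- wt[[1]]$truth@labels@regions
  for (nm in names(regionCodes)) votes[[nm]] <- numeric(prod(refGeom$dim))
  for (i in seq_len(n)) {
    s <- wt[[i]]
    if (i == 1) {
      norm <- list(chain = identityTransform())
      # first animal anchors the space; estimate only the warp residual
      warp <- nonlinearRegister(s$mri, s$mri, iterations = iterations,
                                cutoff = cutoff, regWeight = regWeight)
      norm <- list(chain = warp)
    } else {
      norm <- .normalizeToTemplate(s$mri, wt[[1]]$mri,
                                   iterations = iterations,
                                   cutoff = cutoff, regWeight = regWeight)
      norm <- list(chain = norm$chain)
    }
    transforms[[i]] <- norm$chain
    acc <- acc + resampleVolume(s$mri, norm$chain, refGeom)@data
    lab <- s$truth@labels
    pts <- applyTransform(norm$chain, gridWorld(refGeom))
    idx <- worldToVoxel(lab@affine, pts)
    plan <- trilinearPlan(idx, dim(lab@labels))
    for (nm in names(regionCodes))
      votes[[nm]] <- votes[[nm]] +
        applyPlan(plan, (lab@labels == regionCodes[[nm]]) * 1.0, 0)
  }
  tpl <- imageVolume(acc / n, affine = refGeom$affine, modality = "MRI")
  labArr <- integer(prod(refGeom$dim))
  # brain first so inner structures override it; skull last
  for (nm in c("brain", "cerebellum", "striatumL", "striatumR", "skull")) {
    if (is.null(votes[[nm]])) next
    labArr[votes[[nm]] / n > voteThreshold] <- regionCodes[[nm]]
  }
  vois <- labelMap(array(labArr, refGeom$dim), affine = refGeom$affine,
                   regions = regionCodes)
  list(template = tpl, vois = vois, transforms = transforms,
       subjects = vapply(wt, function(s) s$truth@id, character(1)))
}

#' Build the tracer PET template in MRI-template space
#'
#' For each WT subject the (thresholded) CT is rigidly registered to the
#' subject MRI (cross-modality NMI), giving the CT/PET -> MRI mapping;
#' the static PET is then carried through the composed (MRI -> template
#' warp) o (CT -> MRI rigid) chain onto the template grid and the images
#' are averaged voxelwise. Because the result is co-registered to the MRI
#' template, the MRI-template VOIs apply to it directly.
#'
#' @param cohort a Cohort with CT and static PET volumes.
#' @param mriTemplate result of \code{\link{buildMRITemplate}}.
#' @param ctThreshold CT threshold applied before registration.
#' @return list(template, ctRigids): the PET template ImageVolume and the
#'   per-subject CT->MRI rigid transforms (MRI world -> CT/PET world)
#' @export
buildPETTemplate <- function(cohort, mriTemplate, ctThreshold = 500,
                             petGrid = NULL) {
  wt <- .wtSubjects(cohort)
  refGeom <- if (is.null(petGrid)) geometryOf(mriTemplate$template) else
    geometryOf(petGrid)
  acc <- array(0, refGeom$dim)
  ctRigids <- vector("list", length(wt))
  for (i in seq_along(wt)) {
    s <- wt[[i]]
    if (is.null(s$static)) stop("subject ", s$truth@id, " has no static PET")
    rig <- rigidRegister(thresholdCT(s$ct, ctThreshold), s$mri,
                         metric = "nmi")
    ctRigids[[i]] <- rig
    chain <- composeTransforms(mriTemplate$transforms[[i]], rig)
    acc <- acc + resampleVolume(s$static, chain, refGeom)@data
  }
  tpl <- imageVolume(acc / length(wt), affine = refGeom$affine,
                     modality = "PET-static")
  list(template = tpl, ctRigids = ctRigids)
}

#' Select the CT template
#'
#' The first WT animal's thresholded CT, resampled into MRI-template
#' space through that subject's own transforms, so the CT template is
#' spatially registered to the MRI template and the MRI-template VOIs
#' remain valid for the CT route.
#'
#' @param cohort a Cohort.
#' @param mriTemplate result of \code{\link{buildMRITemplate}}.
#' @param ctRigid the first subject's CT->MRI rigid (estimated if NULL).
#' @param ctThreshold CT threshold (default 500).
#' @return a CT ImageVolume on the template grid
#' @export
selectCTTemplate <- function(cohort, mriTemplate, ctRigid = NULL,
                             ctThreshold = 500) {
  wt <- .wtSubjects(cohort)
  s <- wt[[1]]
  if (is.null(s$ct)) stop("first WT subject has no CT")
  thr <- thresholdCT(s$ct, ctThreshold)
  if (is.null(ctRigid))
    ctRigid <- rigidRegister(thr, s$mri, metric = "nmi")
  chain <- composeTransforms(mriTemplate$transforms[[1]], ctRigid)
  resampleVolume(thr, chain, geometryOf(mriTemplate$template))
}

#' Build all three templates in one shared space
#'
#' Convenience wrapper running \code{\link{buildMRITemplate}},
#' \code{\link{buildPETTemplate}} and \code{\link{selectCTTemplate}}; all
#' outputs share the first WT animal's MRI grid, so the fused VOI set
#' quantifies all three normalization routes.
#'
#' @param cohort a Cohort with full image sets.
#' @param iterations,cutoff,regWeight warp settings.
#' @param ctThreshold CT threshold (default 500).
#' @return list(mri, pet, ct, vois, mriTransforms, ctRigids)
#' @export
buildTemplates <- function(cohort, iterations = 16, cutoff = 3,
                           regWeight = 1, ctThreshold = 500) {
  mriT <- buildMRITemplate(cohort, iterations = iterations,
                           cutoff = cutoff, regWeight = regWeight)
  # PET-resolution grid in the template world frame (anchored, like the
  # template itself, to the first WT animal): dynamic data are quantified
  # at their native resolution so resampling does not dilute small VOIs
  wt1 <- .wtSubjects(cohort)[[1]]
  petGrid <- imgGeometry(dim(wt1$pet@data)[1:3], wt1$pet@affine)
  petT <- buildPETTemplate(cohort, mriT, ctThreshold = ctThreshold,
                           petGrid = petGrid)
  ctT <- selectCTTemplate(cohort, mriT, ctRigid = petT$ctRigids[[1]],
                          ctThreshold = ctThreshold)
  voisPET <- resampleLabelMap(mriT$vois, NULL, petGrid, threshold = 0.75)
  list(mri = mriT$template, pet = petT$template, ct = ctT,
       vois = mriT$vois, voisPET = voisPET, petGrid = petGrid,
       mriTransforms = mriT$transforms, ctRigids = petT$ctRigids,
       subjects = mriT$subjects)
}
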