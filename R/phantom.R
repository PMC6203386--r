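#' @include registration.R kinetics.R
NULL

#' Construct a phantom specification
#'
#' Defaults describe a mouse-head-scale multimodal phantom: a fine
#' T2-like MRI grid (0.2 x 0.2 x 0.25 mm), a coarse PET grid (0.776 mm
#' isotropic) and an intermediate CT grid, ellipsoidal brain, left/right
#' striatum and cerebellum plus an ellipsoidal skull shell whose CT
#' intensity sits well above the 500 threshold. Inter-subject variability
#' combines random rigid poses per acquisition frame (MRI vs PET/CT) and
#' a smooth low-frequency shape deformation.
#'
#' @param dimMRI,voxMRI MRI grid size / voxel size (mm).
#' @param dimPET,voxPET PET grid size / voxel size (mm).
#' @param dimCT,voxCT CT grid size / voxel size (mm).
#' @param psfFWHM PET point-spread FWHM (mm), default 1.5.
#' @param noisePET PET noise scale: per-voxel SD is
#'   \code{noisePET * sqrt(activity / frame_duration_s)}.
#' @param noiseMRI,noiseCT additive Gaussian noise SDs.
#' @param biasAmp amplitude of the smooth multiplicative MRI bias field.
#' @param poseMM,poseDeg half-ranges of the uniform random rigid pose
#'   (mm per axis, degrees per axis).
#' @param deformAmp SD (mm) of the random cosine-basis shape-deformation
#'   coefficients (constant term excluded).
#' @return a \linkS4class{PhantomSpec}
#' @export
phantomSpec <- function(dimMRI = c(80, 80, 48), voxMRI = c(0.2, 0.2, 0.25),
                        dimPET = c(21, 21, 15), voxPET = rep(0.776, 3),
                        dimCT = c(40, 40, 30), voxCT = rep(0.4, 3),
                        psfFWHM = 1.5, noisePET = 2, noiseMRI = 4,
                        noiseCT = 20, biasAmp = 0.1,
                        poseMM = 1.0, poseDeg = 4, deformAmp = 0.15) {
  geometry <- list(
    dimMRI = as.integer(dimMRI), voxMRI = voxMRI,
    dimPET = as.integer(dimPET), voxPET = voxPET,
    dimCT = as.integer(dimCT), voxCT = voxCT,
    brain = list(center = c(0, 0, 0), semi = c(3.4, 5.2, 2.4)),
    striatumL = list(center = c(-1.5, 1.6, 0.35), semi = c(1.1, 1.75, 1.0)),
    striatumR = list(center = c(1.5, 1.6, 0.35), semi = c(1.1, 1.75, 1.0)),
    cerebellum = list(center = c(0, -3.4, 0.2), semi = c(2.1, 1.3, 1.3)),
    # inner skull surface offset from the brain center (varying shell
    # thickness) plus bony landmarks (tympanic bullae, frontal ridge):
    # without such asymmetries an ellipsoidal shell is nearly invariant
    # under rotation and skull-driven registration is ill-posed
    skull = list(inner = 1.10, outerPad = 0.7,
                 innerOffset = c(0, 0.4, -0.2),
                 features = list(
                   list(center = c(-2.2, -3.8, -1.6),
                        semi = c(0.8, 0.9, 0.7)),
                   list(center = c(2.2, -3.8, -1.6),
                        semi = c(0.8, 0.9, 0.7)),
                   list(center = c(0, 5.3, 0.5),
                        semi = c(0.9, 1.0, 0.5)))))
  intensity <- list(
    # striatum/brain T2 contrast is subtle (manual delineation territory),
    # so normalization is driven by brain surface and cerebellum edges
    mri = c(brain = 100, striatum = 96, cerebellum = 92, skull = 35,
            background = 5),
    ct = c(brain = 100, striatum = 100, cerebellum = 100, skull = 1500,
           background = 0))
  acquisition <- list(psfFWHM = psfFWHM, noisePET = noisePET,
                      noiseMRI = noiseMRI, noiseCT = noiseCT,
                      biasAmp = biasAmp)
  variability <- list(poseMM = poseMM, poseDeg = poseDeg,
                      deformAmp = deformAmp)
  new("PhantomSpec", geometry = geometry, intensity = intensity,
      acquisition = acquisition, variability = variability)
}

#' A reduced-scale phantom specification
#'
#' Same anatomy and variability as \code{\link{phantomSpec}} on coarser
#' grids (0.5 mm-scale MRI, ~0.8 mm PET); intended for fast simulation
#' studies where full resolution is unnecessary.
#'
#' @param ... overrides passed on to \code{\link{phantomSpec}}.
#' @return a \linkS4class{PhantomSpec}
#' @export
coarsePhantomSpec <- function(...) {
  args <- list(dimMRI = c(36, 36, 26), voxMRI = c(0.45, 0.45, 0.5),
               dimPET = c(21, 21, 15), voxPET = rep(0.8, 3),
               dimCT = c(32, 32, 24), voxCT = rep(0.5, 3))
  args[names(list(...))] <- list(...)
  do.call(phantomSpec, args)
}

.geomFor <- function(spec, which) {
  g <- spec@geometry
  d <- g[[paste0("dim", which)]]
  v <- g[[paste0("vox", which)]]
  aff <- diag(c(v, 1))
  aff[1:3, 4] <- -v * (d - 1) / 2
  imgGeometry(d, aff)
}

#' Grid geometry of a phantom modality
#' @param spec a PhantomSpec
#' @param modality "MRI", "PET" or "CT"
#' @return list(dim, affine)
#' @export
phantomGeometry <- function(spec, modality = c("MRI", "PET", "CT")) {
  .geomFor(spec, match.arg(modality))
}

.inEllipsoid <- function(pts, center, semi) {
  dx <- sweep(pts, 2, center)
  rowSums(sweep(dx, 2, semi, "/")^2) <= 1
}

.phantomRegionCodes <- c(brain = 1L, striatumL = 2L, striatumR = 3L,
                         cerebellum = 4L, skull = 5L)

# random subject pose + shape deformation
.drawJitter <- function(spec) {
  v <- spec@variability
  mkPose <- function() rigidTransform(
    translation = stats::runif(3, -v$poseMM, v$poseMM),
    rotation = stats::runif(3, -v$poseDeg, v$poseDeg) * pi / 180)
  deform <- NULL
  if (v$deformAmp > 0) {
    geom <- .geomFor(spec, "MRI")
    coef <- matrix(stats::rnorm(27 * 3, 0, v$deformAmp), 27, 3)
    coef[1, ] <- 0  # constant term belongs to pose, not shape
    deform <- basisWarp(coef, domain = geom, cutoff = 3L)
  }
  list(poseMRI = mkPose(), posePET = mkPose(), deform = deform)
}

# map acquisition-frame world points into canonical anatomy coordinates
.toCanonical <- function(pts, pose, deform) {
  y <- applyTransform(pose, pts)
  if (!is.null(deform)) y <- applyTransform(deform, y)
  y
}

#' Render the subject's anatomy as a label map on a grid
#'
#' Evaluates the subject's deformed, posed ellipsoid anatomy at the voxel
#' centers of \code{geom}. Inner structures (striatum, cerebellum)
#' override the brain code; the skull shell overrides everything.
#'
#' @param truth a SubjectGroundTruth.
#' @param spec the PhantomSpec the subject was generated from.
#' @param geom target grid (list(dim, affine), ImageVolume or LabelMap).
#' @param frame "mri" or "petct": which acquisition pose to use.
#' @param regions subset of region names to render (default all).
#' @return a \linkS4class{LabelMap}
#' @export
renderLabels <- function(truth, spec, geom, frame = c("mri", "petct"),
                         regions = names(.phantomRegionCodes)) {
  frame <- match.arg(frame)
  geom <- geometryOf(geom)
  pose <- if (frame == "mri") truth@poseMRI else truth@posePET
  pts <- .toCanonical(gridWorld(geom), pose, truth@deform)
  g <- spec@geometry
  lab <- integer(nrow(pts))
  sSemi <- g$striatumL$semi * truth@striatumScale
  if ("brain" %in% regions)
    lab[.inEllipsoid(pts, g$brain$center, g$brain$semi)] <- 1L
  if ("cerebellum" %in% regions)
    lab[.inEllipsoid(pts, g$cerebellum$center, g$cerebellum$semi)] <- 4L
  if ("striatumL" %in% regions)
    lab[.inEllipsoid(pts, g$striatumL$center, sSemi)] <- 2L
  if ("striatumR" %in% regions)
    lab[.inEllipsoid(pts, g$striatumR$center, sSemi)] <- 3L
  if ("skull" %in% regions) {
    sk <- .inEllipsoid(pts, g$brain$center,
                       g$brain$semi * g$skull$inner + g$skull$outerPad) &
      !.inEllipsoid(pts, g$brain$center + g$skull$innerOffset,
                    g$brain$semi * g$skull$inner)
    for (f in g$skull$features)
      sk <- sk | .inEllipsoid(pts, f$center, f$semi)
    sk <- sk & lab == 0L  # never overwrite brain tissue
    lab[sk] <- 5L
  }
  labelMap(array(lab, geom$dim), affine = geom$affine,
           regions = .phantomRegionCodes[regions])
}

# anti-aliased striatal volume: interior voxels count fully; the one-voxel
# boundary shell is refined by supersampled membership evaluation (plain
# voxel counting carries ~1% lattice error on a structure this small)
.striatalVolumeFine <- function(truth, spec, lab, factor = 3L) {
  g <- spec@geometry
  aff <- lab@affine
  vox <- sqrt(colSums(aff[1:3, 1:3]^2))
  vv <- prod(vox)
  off <- as.matrix(expand.grid(
    x = ((seq_len(factor) - 0.5) / factor) - 0.5,
    y = ((seq_len(factor) - 0.5) / factor) - 0.5,
    z = ((seq_len(factor) - 0.5) / factor) - 0.5))
  total <- 0
  for (side in c("striatumL", "striatumR")) {
    code <- .phantomRegionCodes[[side]]
    m <- lab@labels == code
    if (!any(m)) next
    core <- .erodeOnce6(m)
    band <- which(.dilateOnce6(m) & !core, arr.ind = TRUE) - 1L
    total <- total + sum(core) * vv
    idx <- band[rep(seq_len(nrow(band)), each = nrow(off)), , drop = FALSE] +
      off[rep(seq_len(nrow(off)), times = nrow(band)), , drop = FALSE]
    pts <- .toCanonical(voxelToWorld(aff, idx), truth@poseMRI,
                        truth@deform)
    semi <- g[[side]]$semi * truth@striatumScale
    total <- total + sum(.inEllipsoid(pts, g[[side]]$center, semi)) *
      vv / factor^3
  }
  total
}

.touchesBoundary <- function(lab) {
  m <- lab@labels != 0L
  d <- dim(m)
  any(m[1, , ], m[d[1], , ], m[, 1, ], m[, d[2], ],
      m[, , 1], m[, , d[3]])
}

#' Generate one subject's anatomy and ground truth
#'
#' Draws the subject's pose and shape jitter, applies the genotype's
#' striatal atrophy (HET striatal semi-axes scaled by atrophy^(1/3), so
#' the expected striatal volume is \code{atrophy} times the matched WT
#' volume; whole-brain volume is unaffected) and renders the ground-truth
#' label map in the subject MRI frame. If the jittered anatomy leaves the
#' grid the draw is repeated (with a warning), at most 10 times.
#'
#' @param spec a PhantomSpec.
#' @param genotype "WT" or "HET".
#' @param id subject identifier.
#' @param bp,R1,k2 true striatal kinetic parameters.
#' @param atrophy HET striatal volume factor (default 0.923).
#' @param labelScale integer >= 1; renders the ground-truth label grid at
#'   labelScale-times coarser resolution (volumetric accuracy is carried
#'   by supersampled counting, so volumetrics-only studies can use 2).
#' @return a \linkS4class{SubjectGroundTruth}
#' @export
makeAnatomy <- function(spec, genotype = c("WT", "HET"), id = "s1",
                        bp = 1.86, R1 = 1.0, k2 = 0.2, atrophy = 0.923,
                        labelScale = 1L) {
  genotype <- match.arg(genotype)
  scale <- if (genotype == "HET") atrophy^(1 / 3) else 1
  geomMRI <- .geomFor(spec, "MRI")
  if (labelScale > 1L) {
    d <- pmax(geomMRI$dim %/% labelScale, 2L)
    vox <- spec@geometry$voxMRI * labelScale
    aff <- diag(c(vox, 1))
    aff[1:3, 4] <- -vox * (d - 1) / 2
    geomMRI <- imgGeometry(d, aff)
  }
  for (attempt in 1:10) {
    j <- .drawJitter(spec)
    truth <- new("SubjectGroundTruth", id = id, genotype = genotype,
                 bp = bp, R1 = R1, k2 = k2, poseMRI = j$poseMRI,
                 posePET = j$posePET, deform = j$deform,
                 striatumScale = scale, striatalVolume = NA_real_,
                 brainVolume = NA_real_, labels = NULL)
    lab <- renderLabels(truth, spec, geomMRI, frame = "mri")
    if (!.touchesBoundary(lab)) {
      truth@labels <- lab
      truth@striatalVolume <- .striatalVolumeFine(truth, spec, lab)
      truth@brainVolume <- voiVolume(lab, "brain") +
        voiVolume(lab, "striatumL") + voiVolume(lab, "striatumR") +
        voiVolume(lab, "cerebellum")
      return(truth)
    }
    warning("jittered anatomy left the grid; regenerating (attempt ",
            attempt, ")")
  }
  stop("anatomy left the grid in 10 consecutive jitter draws")
}

.biasField <- function(geom, amp) {
  pts <- gridWorld(geom)
  L <- apply(pts, 2, function(x) diff(range(x)) + 1e-9)
  u <- sweep(sweep(pts, 2, apply(pts, 2, min)), 2, L, "/")
  ph <- stats::runif(3, 0, 2 * pi)
  1 + amp * (sin(pi * u[, 1] + ph[1]) * sin(pi * u[, 2] + ph[2]) *
               sin(pi * u[, 3] + ph[3]))
}

.tissueImage <- function(lab, means) {
  lut <- c(means[["background"]], means[["brain"]], means[["striatum"]],
           means[["striatum"]], means[["cerebellum"]], means[["skull"]])
  array(lut[lab@labels + 1L], dim(lab@labels))
}

#' Synthesize a T2-like MRI for a subject
#'
#' Piecewise-constant tissue intensities plus an optional smooth
#' multiplicative bias field and additive Gaussian noise, on the MRI grid
#' in the subject's MRI acquisition frame.
#'
#' @param truth a SubjectGroundTruth.
#' @param spec a PhantomSpec.
#' @param noise logical; FALSE gives the noise- and bias-free image.
#' @return an MRI ImageVolume
#' @export
synthMRI <- function(truth, spec, noise = TRUE) {
  geom <- .geomFor(spec, "MRI")
  lab <- if (!is.null(truth@labels) &&
               sameGeometry(truth@labels, geom)) truth@labels
  else renderLabels(truth, spec, geom, frame = "mri")
  img <- .tissueImage(lab, spec@intensity$mri)
  if (noise) {
    a <- spec@acquisition
    if (a$biasAmp > 0)
      img <- img * array(.biasField(geom, a$biasAmp), dim(img))
    if (a$noiseMRI > 0)
      img <- img + array(stats::rnorm(length(img), 0, a$noiseMRI), dim(img))
  }
  imageVolume(img, affine = geom$affine, modality = "MRI")
}

#' Synthesize a CT for a subject
#'
#' Bright skull shell (mean intensity well above the 500 threshold) over
#' uniform soft tissue, on the CT grid in the PET/CT acquisition frame.
#'
#' @inheritParams synthMRI
#' @return a CT ImageVolume
#' @export
synthCT <- function(truth, spec, noise = TRUE) {
  geom <- .geomFor(spec, "CT")
  lab <- renderLabels(truth, spec, geom, frame = "petct")
  img <- .tissueImage(lab, spec@intensity$ct)
  if (noise && spec@acquisition$noiseCT > 0)
    img <- img + array(stats::rnorm(length(img), 0,
                                    spec@acquisition$noiseCT), dim(img))
  imageVolume(img, affine = geom$affine, modality = "CT")
}

#' Synthesize a reference-region (cerebellar) TAC
#'
#' Smooth uptake-washout curve
#' \eqn{C_R(t) = A (e^{-\lambda_1 t} - e^{-\lambda_2 t})} with
#' \eqn{\lambda_2 > \lambda_1 > 0}, evaluated at the schedule's frame
#' mid-times. Defaults peak near 6 minutes at ~20 kBq/mL.
#'
#' @param schedule a FrameSchedule.
#' @param A amplitude (kBq/mL).
#' @param lambda1 washout rate (1/min).
#' @param lambda2 uptake rate (1/min), must exceed lambda1.
#' @return a TAC named "cerebellum"
#' @export
synthReferenceTAC <- function(schedule, A = 30, lambda1 = 0.03,
                              lambda2 = 0.45) {
  stopifnot(is(schedule, "FrameSchedule"))
  if (lambda2 <= lambda1 || lambda1 <= 0)
    stop("need lambda2 > lambda1 > 0")
  tm <- midTimes(schedule)
  tac(tm, schedule@duration,
      A * (exp(-lambda1 * tm) - exp(-lambda2 * tm)), "cerebellum")
}

#' Synthesize a dynamic PET volume for a subject
#'
#' Striatal voxels follow the SRTM forward model with the subject's true
#' (R1, k2, BP_ND); cerebellar voxels follow the reference TAC; remaining
#' brain follows SRTM with a low background BP_ND. Each frame is blurred
#' with the Gaussian PSF and, if \code{noise}, degraded with zero-mean
#' Gaussian noise of variance proportional to activity / frame duration.
#'
#' @param truth a SubjectGroundTruth.
#' @param spec a PhantomSpec.
#' @param refTac cerebellar reference TAC on the acquisition schedule.
#' @param backgroundBP BP_ND of non-striatal brain tissue (default 0.2).
#' @param noise logical; FALSE gives the noise-free volume.
#' @param psf logical; FALSE skips the PSF blur.
#' @return a 4D "PET-dynamic" ImageVolume with attached schedule
#' @export
synthDynamicPET <- function(truth, spec, refTac, backgroundBP = 0.2,
                            noise = TRUE, psf = TRUE) {
  stopifnot(is(refTac, "TAC"))
  geom <- .geomFor(spec, "PET")
  lab <- renderLabels(truth, spec, geom, frame = "petct")
  sched <- new("FrameSchedule",
               start = refTac@midTime * 60 - refTac@duration / 2,
               duration = refTac@duration)
  nt <- length(refTac@midTime)
  striTac <- srtmForward(truth@R1, truth@k2, truth@bp, refTac)@activity
  bgTac <- srtmForward(1.0, truth@k2, backgroundBP, refTac)@activity
  curves <- rbind(background = 0, brain = bgTac,
                  striatumL = striTac, striatumR = striTac,
                  cerebellum = refTac@activity, skull = 0)
  a <- spec@acquisition
  sigmaVox <- if (psf && a$psfFWHM > 0)
    (a$psfFWHM / 2.354820) / spec@geometry$voxPET else rep(0, 3)
  out <- array(0, c(geom$dim, nt))
  labIdx <- lab@labels + 1L
  for (f in seq_len(nt)) {
    frame <- array(curves[cbind(labIdx + 0L, f)], geom$dim)
    if (any(sigmaVox > 0)) frame <- gaussBlur3d(frame, sigmaVox)
    if (noise && a$noisePET > 0) {
      sdv <- a$noisePET * sqrt(pmax(frame, 0.05) / sched@duration[f])
      frame <- frame + array(stats::rnorm(length(frame), 0, sdv),
                             dim(frame))
    }
    out[, , , f] <- frame
  }
  new("ImageVolume", data = out, affine = geom$affine,
      modality = "PET-dynamic", schedule = sched)
}

#' Static PET: duration-weighted time average of a dynamic volume
#'
#' @param dyn a 4D dynamic ImageVolume with schedule.
#' @return a 3D "PET-static" ImageVolume
#' @export
staticPET <- function(dyn) {
  stopifnot(is(dyn, "ImageVolume"), length(dim(dyn@data)) == 4L)
  w <- dyn@schedule@duration / sum(dyn@schedule@duration)
  d <- dim(dyn@data)
  acc <- array(0, d[1:3])
  for (f in seq_len(d[4])) acc <- acc + w[f] * dyn@data[, , , f]
  imageVolume(acc, affine = dyn@affine, modality = "PET-static")
}

#' Cohort generation configuration
#'
#' @param nWT,nHET group sizes (defaults 16 and 15).
#' @param seed integer random seed (mandatory for reproducibility).
#' @param spec a PhantomSpec.
#' @param bpWT,bpHET c(mean, SD) of the true striatal BP_ND per genotype,
#'   truncated at 0; defaults c(1.86, 0.20) and c(1.06, 0.24).
#' @param R1 c(mean, SD) of the true delivery ratio.
#' @param k2 c(mean, SD) of the true efflux rate (1/min).
#' @param atrophy HET striatal volume factor (default 0.923 = -7.7%).
#' @param backgroundBP BP_ND of non-striatal brain.
#' @param schedule FrameSchedule for the dynamic acquisition.
#' @param refA,refLambda1,refLambda2 reference-TAC shape parameters.
#' @param images logical: synthesize MRI/CT/PET volumes (TRUE) or only
#'   anatomy/ground truth (FALSE, for volumetric studies).
#' @param labels logical: render ground-truth label maps (FALSE skips
#'   anatomy rendering entirely, for distribution-only studies).
#' @param noise,psf passed to the image synthesizers.
#' @return a configuration list for \code{\link{generateCohort}}
#' @export
cohortConfig <- function(nWT = 16, nHET = 15, seed = 1,
                         spec = phantomSpec(),
                         bpWT = c(1.86, 0.20), bpHET = c(1.06, 0.24),
                         R1 = c(1.0, 0.05), k2 = c(0.2, 0.02),
                         atrophy = 0.923, backgroundBP = 0.2,
                         schedule = defaultFrameSchedule(),
                         refA = 30, refLambda1 = 0.03, refLambda2 = 0.45,
                         images = TRUE, labels = TRUE, noise = TRUE,
                         psf = TRUE) {
  if (nWT < 1 || nHET < 1) stop("group sizes must be positive")
  list(nWT = nWT, nHET = nHET, seed = as.integer(seed), spec = spec,
       bpWT = bpWT, bpHET = bpHET, R1 = R1, k2 = k2, atrophy = atrophy,
       backgroundBP = backgroundBP, schedule = schedule, refA = refA,
       refLambda1 = refLambda1, refLambda2 = refLambda2, images = images,
       labels = labels, noise = noise, psf = psf)
}

.truncNorm <- function(n, mean, sd, lower = 0) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x <= lower)
  while (length(bad) > 0) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] <= lower]
  }
  x
}

#' Generate a multimodal cohort
#'
#' Draws each subject's true BP_ND from its genotype's (truncated) normal
#' distribution, R1 and k2 from shared distributions, and pose/shape
#' jitter from the phantom spec, then synthesizes MRI, CT, dynamic PET
#' and static PET per subject. The cohort is a pure function of the
#' configuration (including its seed).
#'
#' @param config a list from \code{\link{cohortConfig}}.
#' @return a \linkS4class{Cohort}
#' @export
generateCohort <- function(config) {
  set.seed(config$seed)
  n <- config$nWT + config$nHET
  genotype <- c(rep("WT", config$nWT), rep("HET", config$nHET))
  bp <- numeric(n)
  bp[genotype == "WT"] <- .truncNorm(config$nWT, config$bpWT[1],
                                     config$bpWT[2])
  bp[genotype == "HET"] <- .truncNorm(config$nHET, config$bpHET[1],
                                      config$bpHET[2])
  r1 <- .truncNorm(n, config$R1[1], config$R1[2], lower = 0.2)
  k2 <- .truncNorm(n, config$k2[1], config$k2[2], lower = 0.02)
  refTac <- synthReferenceTAC(config$schedule, config$refA,
                              config$refLambda1, config$refLambda2)
  renderLab <- !isFALSE(config$labels) || isTRUE(config$images)
  labelScale <- if (isTRUE(config$images)) 1L else 2L
  subjects <- vector("list", n)
  for (i in seq_len(n)) {
    truth <- if (renderLab) {
      makeAnatomy(config$spec, genotype[i], id = sprintf("sub-%02d", i),
                  bp = bp[i], R1 = r1[i], k2 = k2[i],
                  atrophy = config$atrophy, labelScale = labelScale)
    } else {
      j <- .drawJitter(config$spec)
      new("SubjectGroundTruth", id = sprintf("sub-%02d", i),
          genotype = genotype[i], bp = bp[i], R1 = r1[i], k2 = k2[i],
          poseMRI = j$poseMRI, posePET = j$posePET, deform = j$deform,
          striatumScale = if (genotype[i] == "HET")
            config$atrophy^(1 / 3) else 1,
          striatalVolume = NA_real_, brainVolume = NA_real_,
          labels = NULL)
    }
    s <- list(truth = truth)
    if (isTRUE(config$images)) {
      s$mri <- synthMRI(truth, config$spec, noise = config$noise)
      s$ct <- synthCT(truth, config$spec, noise = config$noise)
      s$pet <- synthDynamicPET(truth, config$spec, refTac,
                               backgroundBP = config$backgroundBP,
                               noise = config$noise, psf = config$psf)
      s$static <- staticPET(s$pet)
    }
    subjects[[i]] <- s
  }
  new("Cohort", subjects = subjects, spec = config$spec,
      config = config, seed = config$seed)
}

#' Write a cohort to disk (NIfTI volumes + JSON manifest)
#'
#' @param cohort a Cohort with images.
#' @param dir output directory.
#' @return the manifest path, invisibly
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- lapply(cohort@subjects, function(s) {
    id <- s$truth@id
    entry <- list(id = id, genotype = s$truth@genotype,
                  true_bp = s$truth@bp, true_R1 = s$truth@R1,
                  true_k2 = s$truth@k2,
                  striatal_volume_mm3 = s$truth@striatalVolume,
                  brain_volume_mm3 = s$truth@brainVolume)
    if (!is.null(s$mri)) {
      for (mod in c("mri", "ct", "pet", "static")) {
        p <- file.path(dir, paste0(id, "_", mod, ".nii"))
        writeVolume(s[[mod]], p)
        entry[[paste0(mod, "_path")]] <- p
      }
      lp <- file.path(dir, paste0(id, "_labels.nii"))
      writeLabelMap(s$truth@labels, lp)
      entry$labels_path <- lp
    }
    entry
  })
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(list(seed = cohort@seed, subjects = manifest), mp,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(mp)
}
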