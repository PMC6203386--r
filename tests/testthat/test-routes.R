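test_that("route provenance reports the estimated transforms", {
  fx <- cleanCohortWithTemplates()
  s <- fx$cohort@subjects[[2]]
  resM <- routeMRI(s, fx$templates)
  expect_false(resM$provenance$excluded)
  expect_equal(resM$provenance$nEstimated, 2L)
  expect_named(resM$provenance$transforms,
               c("ct_to_mri", "mri_to_template"))
  resP <- routePET(s, fx$templates)
  expect_equal(resP$provenance$nEstimated, 1L)
  resC <- routeCT(s, fx$templates)
  expect_equal(resC$provenance$nEstimated, 1L)
  # all routes emit dynamic volumes on the shared quantification grid
  for (res in list(resM, resP, resC)) {
    expect_equal(dim(res$dyn@data)[1:3],
                 petnorm:::geometryOf(fx$templates$petGrid)$dim)
    expect_equal(nFrames(res$dyn), nFrames(s$pet))
  }
})

test_that("jitter-free noise-free subjects pass through routes unchanged", {
  fx <- cleanCohortWithTemplates()
  s <- fx$cohort@subjects[[2]]
  truthTac <- srtmForward(s$truth@R1, s$truth@k2, s$truth@bp,
                          synthReferenceTAC(coarseFrameSchedule()))
  for (routeFn in list(
    function() routeMRI(s, fx$templates),
    function() routePET(s, fx$templates),
    function() routeCT(s, fx$templates))) {
    res <- routeFn()
    q <- quantifyVOI(res$dyn, fx$templates$voisPET)
    # template-space striatal TAC matches the true kinetics within 2%
    expect_lt(max(abs(activity(q$striatumTAC) - activity(truthTac))) /
                max(activity(truthTac)), 0.02)
    expect_lt(abs(q$fit@bp - s$truth@bp) / s$truth@bp, 0.01)
  }
  # CT route on the template-defining subject recovers the identity
  rig <- routeCT(fx$cohort@subjects[[1]],
                 fx$templates)$provenance$transforms$ct_to_template
  expect_rigid_close(rig, identityTransform(), tolMM = 0.1, tolDeg = 0.5)
})

test_that("a known rigid offset is absorbed by the MRI route", {
  fx <- cleanCohortWithTemplates()
  s <- fx$cohort@subjects[[3]]
  # re-acquire the same animal with a known PET/CT pose offset (images
  # synthesized in the new frame, so no extra interpolation pass); the
  # scanner PSF is on, as in any realistic acquisition, and MRI/CT are
  # at near-study resolution so the cross-modality rigid is accurate
  off <- rigidTransform(c(0.8, -0.5, 0.3), c(2, -1, 2) * pi / 180)
  specPSF <- phantomSpec(dimMRI = c(54, 54, 40), voxMRI = rep(0.3, 3),
                         dimCT = c(54, 54, 40), voxCT = rep(0.3, 3),
                         poseMM = 0, poseDeg = 0, deformAmp = 0,
                         noisePET = 0, noiseMRI = 0, noiseCT = 0,
                         biasAmp = 0)
  truth2 <- s$truth
  truth2@posePET <- composeTransforms(off, truth2@posePET)
  ref <- synthReferenceTAC(coarseFrameSchedule())
  mk <- function(tr) {
    list(truth = tr, mri = synthMRI(tr, specPSF, noise = FALSE),
         ct = synthCT(tr, specPSF, noise = FALSE),
         pet = synthDynamicPET(tr, specPSF, ref, noise = FALSE,
                               psf = TRUE))
  }
  sOff <- mk(truth2)
  sOff$static <- staticPET(sOff$pet)
  q <- quantifyVOI(routeMRI(sOff, fx$templates)$dyn,
                   fx$templates$voisPET)
  # reference: the same dynamic data normalized through the exactly known
  # inverse pose (one trilinear pass, like the route itself), so the
  # check isolates what registration can control
  oracle <- resampleVolume(sOff$pet, invertTransform(off),
                           fx$templates$petGrid)
  qO <- quantifyVOI(oracle, fx$templates$voisPET)
  # >= 95% of the striatal activity an exact normalization recovers
  expect_gt(mean(activity(q$striatumTAC) / activity(qO$striatumTAC)),
            0.95)
})

test_that("individual-label quantification matches truth on clean data", {
  fx <- cleanCohortWithTemplates()
  s <- fx$cohort@subjects[[4]]
  ind <- quantifyIndividual(s)
  expect_lt(abs(ind$fit@bp - s$truth@bp) / s$truth@bp, 0.01)
  expect_true(ind$fit@converged)
})
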