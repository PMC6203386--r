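test_that("SRTM forward model has the right algebraic limits", {
  sched <- defaultFrameSchedule()
  ref <- synthReferenceTAC(sched)
  # BP = 0, R1 = 1 collapses to the reference curve
  expect_equal(activity(srtmForward(1, 0.2, 0, ref)), activity(ref))
  # very fast efflux: quasi-equilibrium C_T ~ (1 + BP) C_R at late times
  bp <- 0.8
  fastEq <- srtmForward(1, 50, bp, ref)
  late <- which(midTimes(ref) > 60)
  expect_equal(activity(fastEq)[late] / activity(ref)[late],
               rep(1 + bp, length(late)), tolerance = 0.02)
  expect_error(srtmForward(1, -0.1, 1, ref), "k2")
  expect_error(srtmForward(1, 0.2, -1.5, ref), "BP")
})

test_that("reference TAC follows its closed form", {
  sched <- defaultFrameSchedule()
  l1 <- 0.03; l2 <- 0.45; A <- 30
  ref <- synthReferenceTAC(sched, A, l1, l2)
  tm <- midTimes(sched)
  expect_equal(activity(ref), A * (exp(-l1 * tm) - exp(-l2 * tm)))
  # peak location from calculus on the closed form
  tPeak <- log(l2 / l1) / (l2 - l1)
  fine <- seq(0.01, 90, by = 0.01)
  cr <- A * (exp(-l1 * fine) - exp(-l2 * fine))
  expect_equal(fine[which.max(cr)], tPeak, tolerance = 0.01)
  expect_equal(activity(synthReferenceTAC(sched, A = 0)),
               rep(0, 39))
  expect_error(synthReferenceTAC(sched, lambda1 = 0.5, lambda2 = 0.1),
               "lambda")
})

test_that("SRTM fit recovers parameters across the identifiability grid", {
  sched <- defaultFrameSchedule()
  ref <- synthReferenceTAC(sched)
  # headline recovery at the WT-like operating point
  tgt <- srtmForward(1.0, 0.2, 1.86, ref)
  fit <- srtmFit(tgt, ref)
  expect_true(fit@converged)
  expect_lt(abs(bindingPotential(fit) - 1.86), 1e-2)
  # target identical to reference: null binding
  null <- srtmFit(ref, ref)
  expect_lt(abs(null@bp), 1e-3)
  expect_lt(abs(null@R1 - 1), 1e-3)
  # sweep R1 x k2 x BP
  for (R1 in c(0.5, 1.0, 1.5))
    for (k2 in c(0.05, 0.2, 0.5))
      for (bp in c(0.2, 1.0, 3.0)) {
        f <- srtmFit(srtmForward(R1, k2, bp, ref), ref)
        expect_lt(abs(f@bp - bp) / bp, 0.01)
        expect_lt(abs(f@R1 - R1) / R1, 0.01)
      }
})

test_that("BP_ND is invariant to common rescaling and to grid refinement", {
  sched <- defaultFrameSchedule()
  ref <- synthReferenceTAC(sched)
  tgt <- srtmForward(0.9, 0.15, 1.2, ref)
  f1 <- srtmFit(tgt, ref)
  scaled <- tac(tgt@midTime, tgt@duration, 7.3 * activity(tgt))
  refScaled <- tac(ref@midTime, ref@duration, 7.3 * activity(ref))
  f2 <- srtmFit(scaled, refScaled)
  expect_equal(f2@bp, f1@bp, tolerance = 1e-6)
  # finer convolution grid changes BP by < 0.1%
  f3 <- srtmFit(tgt, ref, fineDt = 0.02)
  expect_lt(abs(f3@bp - f1@bp) / f1@bp, 1e-3)
})

test_that("fit is approximately unbiased under frame noise", {
  sched <- defaultFrameSchedule()
  ref <- synthReferenceTAC(sched)
  tgt <- srtmForward(1.0, 0.2, 1.0, ref)
  set.seed(17)
  bps <- replicate(250, {
    noisy <- tac(tgt@midTime, tgt@duration,
                 activity(tgt) * (1 + rnorm(39, 0, 0.05)))
    srtmFit(noisy, ref)@bp
  })
  expect_lt(abs(mean(bps) - 1.0), 0.05)
})

test_that("TAC extraction is the per-frame regional mean", {
  sched <- frameScheduleFromDurations(c(60, 60))
  arr <- array(0, c(4, 4, 1, 2))
  arr[, , , 1] <- 3; arr[, , , 2] <- 5
  dyn <- imageVolume(arr, modality = "PET-dynamic", schedule = sched)
  lab <- array(0L, c(4, 4, 1)); lab[1:2, 1, 1] <- 1L
  lm <- labelMap(lab, regions = c(striatum = 1))
  expect_equal(activity(extractTAC(dyn, lm, "striatum")), c(3, 5))
  # half 2 / half 4 -> 3
  arr2 <- array(2, c(4, 4, 1, 2)); arr2[1, 1, 1, ] <- c(2, 2)
  arr2[1:2, 1:2, 1, ] <- 2; arr2[3:4, 1:2, 1, ] <- 4
  lab2 <- array(0L, c(4, 4, 1)); lab2[, 1:2, 1] <- 1L
  dyn2 <- imageVolume(arr2, modality = "PET-dynamic", schedule = sched)
  lm2 <- labelMap(lab2, regions = c(striatum = 1))
  expect_equal(activity(extractTAC(dyn2, lm2, "striatum")), c(3, 3))
  # single-voxel region returns that voxel's time course
  lab3 <- array(0L, c(4, 4, 1)); lab3[2, 3, 1] <- 1L
  dyn@data[2, 3, 1, ] <- c(11, 13)
  lm3 <- labelMap(lab3, regions = c(striatum = 1))
  expect_equal(activity(extractTAC(dyn, lm3, "striatum")), c(11, 13))
  expect_error(extractTAC(dyn, labelMap(array(0L, c(4, 4, 1)),
                                        regions = c(striatum = 1)),
                          "striatum"), "empty")
})

test_that("voxelwise basis-function map matches the VOI-level fit", {
  sched <- coarseFrameSchedule()
  ref <- synthReferenceTAC(sched)
  tgt <- srtmForward(1.0, 0.2, 1.5, ref)
  nt <- nFrames(sched)
  arr <- array(0, c(4, 4, 2, nt))
  for (f in seq_len(nt)) {
    arr[, , 1, f] <- activity(tgt)[f]   # uniform striatum-like slab
    arr[, , 2, f] <- activity(ref)[f]   # reference-like slab
  }
  dyn <- imageVolume(arr, modality = "PET-dynamic", schedule = sched)
  map <- bpMap(dyn, ref)
  expect_equal(modality(map), "BP-map")
  voiFit <- srtmFit(tgt, ref)
  expect_equal(mean(imgData(map)[, , 1]), voiFit@bp, tolerance = 1e-3)
  # reference-region voxels map to BP ~ 0
  expect_lt(max(abs(imgData(map)[, , 2])), 0.02)
  expect_error(bpMap(dyn, ref, k2aGrid = numeric(0)), "empty")
})
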