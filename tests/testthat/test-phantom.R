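test_that("striatal atrophy scales the volume ratio by the set factor", {
  spec <- phantomSpec(poseMM = 0, poseDeg = 0, deformAmp = 0)
  set.seed(1)
  wt <- makeAnatomy(spec, "WT")
  het <- makeAnatomy(spec, "HET", atrophy = 0.923)
  rWT <- wt@striatalVolume / wt@brainVolume
  rHET <- het@striatalVolume / het@brainVolume
  expect_equal(rHET / rWT, 0.923, tolerance = 0.005)
  # whole-brain volume untouched by the genotype
  expect_equal(het@brainVolume, wt@brainVolume, tolerance = 1e-8)
  # determinism: same seed, same labels
  set.seed(5); a <- makeAnatomy(spec, "WT")
  set.seed(5); b <- makeAnatomy(spec, "WT")
  expect_identical(imgData(a@labels), imgData(b@labels))
})

test_that("synthetic MRI and CT honor their tissue intensity tables", {
  spec <- coarsePhantomSpec()
  set.seed(6)
  truth <- makeAnatomy(spec, "WT")
  mri0 <- synthMRI(truth, spec, noise = FALSE)
  lab <- truth@labels
  it <- spec@intensity$mri
  expect_equal(unique(imgData(mri0)[imgData(lab) == 1L]),
               unname(it[["brain"]]))
  expect_equal(unique(imgData(mri0)[imgData(lab) == 0L]),
               unname(it[["background"]]))
  ct0 <- synthCT(truth, spec, noise = FALSE)
  labCT <- renderLabels(truth, spec, petnorm:::geometryOf(ct0),
                        frame = "petct")
  # thresholding the noise-free CT retains exactly the skull voxels
  thr <- thresholdCT(ct0, 500)
  expect_identical(imgData(thr) > 0, imgData(labCT) == 5L)
  # two noise realizations share tissue means within 3 SE (bias field
  # off, so the only stochastic term is the additive voxel noise)
  spec2 <- coarsePhantomSpec(biasAmp = 0)
  set.seed(7); m1 <- synthMRI(truth, spec2)
  set.seed(8); m2 <- synthMRI(truth, spec2)
  brainVox <- imgData(lab) == 1L
  se <- sqrt(2) * spec2@acquisition$noiseMRI / sqrt(sum(brainVox))
  expect_lt(abs(mean(imgData(m1)[brainVox]) -
                  mean(imgData(m2)[brainVox])), 3 * se)
})

test_that("dynamic PET synthesis matches the forward kinetics exactly", {
  spec <- coarsePhantomSpec()
  set.seed(10)
  truth <- makeAnatomy(spec, "WT", bp = 1.86)
  sched <- coarseFrameSchedule()
  ref <- synthReferenceTAC(sched)
  pet <- synthDynamicPET(truth, spec, ref, noise = FALSE, psf = FALSE)
  labP <- renderLabels(truth, spec, petnorm:::geometryOf(pet),
                       frame = "petct")
  st <- extractTACUnion(pet, labP, c("striatumL", "striatumR"))
  expect_equal(activity(st),
               activity(srtmForward(truth@R1, truth@k2, truth@bp, ref)),
               tolerance = 1e-6)
  cb <- extractTACUnion(pet, labP, "cerebellum")
  expect_equal(activity(cb), activity(ref), tolerance = 1e-6)
  # the time-averaged image is hottest in the striatum
  static <- staticPET(synthDynamicPET(truth, spec, ref, noise = FALSE,
                                      psf = TRUE))
  mStri <- mean(imgData(static)[imgData(labP) %in% 2:3])
  for (code in c(1L, 4L))
    expect_gt(mStri, mean(imgData(static)[imgData(labP) == code]))
})

test_that("PET noise follows the stated activity/duration law", {
  spec <- coarsePhantomSpec()
  set.seed(12)
  truth <- makeAnatomy(spec, "WT")
  dur <- c(75, 300)  # quadruple the duration, at fixed activity
  ref <- tac(c(1, 2), c(75, 300), c(20, 20))
  # constant activity: use a schedule-consistent reference
  sched <- frameScheduleFromDurations(dur)
  ref <- tac(midTimes(sched), dur, c(20, 20))
  set.seed(1)
  pet <- synthDynamicPET(truth, spec, ref, noise = TRUE, psf = FALSE)
  labP <- renderLabels(truth, spec, petnorm:::geometryOf(pet),
                       frame = "petct")
  cereb <- which(imgData(labP) == 4L)  # follows ref: same activity/frame
  n3 <- prod(dim(imgData(pet))[1:3])
  sd1 <- sd(imgData(pet)[cereb])
  sd2 <- sd(imgData(pet)[cereb + n3])
  expect_equal(sd1 / sd2, 2, tolerance = 0.25)
})

test_that("cohort generation is a pure function of (config, seed)", {
  spec <- coarsePhantomSpec()
  cfg <- cohortConfig(nWT = 2, nHET = 2, seed = 33, spec = spec,
                      schedule = coarseFrameSchedule())
  c1 <- generateCohort(cfg)
  c2 <- generateCohort(cfg)
  expect_identical(
    lapply(c1@subjects, function(s) imgData(s$pet)),
    lapply(c2@subjects, function(s) imgData(s$pet)))
  expect_identical(
    vapply(c1@subjects, function(s) s$truth@bp, numeric(1)),
    vapply(c2@subjects, function(s) s$truth@bp, numeric(1)))
  # manifest write round trip
  dir <- tempfile()
  mp <- writeCohort(c1, dir)
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  expect_equal(man$seed, 33)
  expect_equal(nrow(man$subjects), 4)
  back <- readVolume(man$subjects$pet_path[1], modality = "PET-dynamic")
  expect_equal(imgData(back), imgData(c1@subjects[[1]]$pet),
               tolerance = 1e-6)
})

test_that("true BP_ND distributions match the configured group models", {
  spec <- coarsePhantomSpec()
  cfg <- cohortConfig(nWT = 200, nHET = 200, seed = 21, spec = spec,
                      images = FALSE, labels = FALSE)
  cohort <- generateCohort(cfg)
  bp <- vapply(cohort@subjects, function(s) s$truth@bp, numeric(1))
  gt <- vapply(cohort@subjects, function(s) s$truth@genotype,
               character(1))
  expect_lt(abs(mean(bp[gt == "WT"]) - 1.86), 3 * 0.20 / sqrt(200))
  expect_lt(abs(mean(bp[gt == "HET"]) - 1.06), 3 * 0.24 / sqrt(200))
  expect_true(all(bp > 0))
  # zero SDs: every subject sits at the genotype mean
  cfg0 <- cohortConfig(nWT = 3, nHET = 3, seed = 4, spec = spec,
                       bpWT = c(1.5, 0), bpHET = c(0.8, 0),
                       images = FALSE, labels = FALSE)
  bp0 <- vapply(generateCohort(cfg0)@subjects, function(s) s$truth@bp,
                numeric(1))
  expect_equal(bp0, c(rep(1.5, 3), rep(0.8, 3)))
  expect_error(cohortConfig(nWT = 0), "positive")
})
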