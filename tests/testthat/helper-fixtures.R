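# Shared fixtures, built once per test run and memoized.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, builder(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# a single jittered coarse-grid subject with noisy images
jitteredSubject <- function() fixture("jitteredSubject", function() {
  spec <- coarsePhantomSpec()
  set.seed(2)
  truth <- makeAnatomy(spec, "WT")
  list(spec = spec, truth = truth,
       mri = synthMRI(truth, spec),
       ct = synthCT(truth, spec))
})

# small noise-free, jitter-free cohort with templates (identity chains),
# used by template/route structure tests
cleanCohortWithTemplates <- function() {
  fixture("cleanCohort", function() {
    spec <- coarsePhantomSpec(poseMM = 0, poseDeg = 0, deformAmp = 0,
                              psfFWHM = 0, noisePET = 0, noiseMRI = 0,
                              noiseCT = 0, biasAmp = 0)
    # atrophy off: template-vs-anatomy shape mismatch is a studied
    # phenomenon, not a pipeline error, so the structural fixture
    # excludes it
    cfg <- cohortConfig(nWT = 3, nHET = 1, seed = 11, spec = spec,
                        schedule = coarseFrameSchedule(), noise = FALSE,
                        psf = FALSE, atrophy = 1.0)
    cohort <- generateCohort(cfg)
    templates <- buildTemplates(cohort)
    list(spec = spec, cohort = cohort, templates = templates)
  })
}

# delta-impulse volume on a unit grid
deltaVolume <- function(n = 9) {
  d <- array(0, rep(n, 3))
  mid <- (n + 1) / 2
  d[mid, mid, mid] <- 1
  imageVolume(d, voxelSize = c(1, 1, 1), modality = "PET-static")
}

expect_rigid_close <- function(est, true, tolMM = 0.1, tolDeg = 0.5) {
  expect_lt(max(abs(est@translation - true@translation)), tolMM)
  expect_lt(max(abs(est@rotation - true@rotation)) * 180 / pi, tolDeg)
}
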