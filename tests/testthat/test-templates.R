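test_that("the MRI template averages WT subjects on the first grid", {
  fx <- cleanCohortWithTemplates()
  cohort <- fx$cohort
  tpl <- buildMRITemplate(cohort)
  wt1 <- cohort@subjects[[1]]
  # first subject defines the template grid geometry
  expect_equal(dim(imgData(tpl$template)), dim(imgData(wt1$mri)))
  expect_equal(worldAffine(tpl$template), worldAffine(wt1$mri))
  # identical (jitter- and noise-free) subjects: template = subject MRI
  expect_lt(max(abs(imgData(tpl$template) - imgData(wt1$mri))), 1)
  # fused striatal VOI volume close to the mean subject striatal volume
  voiVol <- voiVolume(tpl$vois, "striatumL") +
    voiVolume(tpl$vois, "striatumR")
  meanSubj <- mean(vapply(petnorm:::.wtSubjects(cohort),
                          function(s) s$truth@striatalVolume, numeric(1)))
  expect_lt(abs(voiVol - meanSubj) / meanSubj, 0.15)
  # one transform per WT subject
  expect_length(tpl$transforms, 3)
  onlyHET <- new("Cohort",
                 subjects = cohort@subjects[
                   vapply(cohort@subjects,
                          function(s) s$truth@genotype == "HET",
                          logical(1))],
                 spec = cohort@spec, config = cohort@config,
                 seed = cohort@seed)
  expect_error(buildMRITemplate(onlyHET), "2 WT")
})

test_that("the PET template lives in template space with striatal uptake", {
  fx <- cleanCohortWithTemplates()
  templates <- fx$templates
  # templates and VOIs quantify on one shared grid
  expect_equal(dim(imgData(templates$pet)),
               petnorm:::geometryOf(templates$petGrid)$dim)
  vois <- templates$voisPET
  striMean <- mean(imgData(templates$pet)[imgData(vois) %in% 2:3])
  cbMean <- mean(imgData(templates$pet)[imgData(vois) == 4L])
  expect_gt(striMean / cbMean, 1)
  # jitter-free noise-free cohort: the template's striatal VOI mean
  # equals the WT subjects' mean static striatal uptake within 1%
  stri <- imgData(vois) %in% 2:3
  subjMeans <- vapply(petnorm:::.wtSubjects(fx$cohort), function(s)
    mean(imgData(staticPET(s$pet))[stri]), numeric(1))
  expect_equal(mean(imgData(templates$pet)[stri]), mean(subjMeans),
               tolerance = 0.01)
})

test_that("the CT template is the first animal's thresholded CT in
           template space", {
  fx <- cleanCohortWithTemplates()
  templates <- fx$templates
  mriGeom <- petnorm:::geometryOf(templates$mri)
  expect_equal(petnorm:::geometryOf(templates$ct)$dim, mriGeom$dim)
  expect_equal(petnorm:::geometryOf(templates$ct)$affine, mriGeom$affine)
  # sub-threshold soft tissue was zeroed, skull survives
  vals <- imgData(templates$ct)
  expect_gt(max(vals), 500)
  inBrain <- imgData(templates$vois) %in% 1:4
  expect_lt(stats::quantile(vals[inBrain], 0.95), 500)
  # world position of the skull centroid is preserved within 0.5 mm
  subjCT <- thresholdCT(fx$cohort@subjects[[1]]$ct)
  w1 <- which(imgData(subjCT) > 750, arr.ind = TRUE) - 1
  c1 <- colMeans(petnorm:::voxelToWorld(worldAffine(subjCT), w1))
  w2 <- which(vals > 750, arr.ind = TRUE) - 1
  c2 <- colMeans(petnorm:::voxelToWorld(worldAffine(templates$ct), w2))
  expect_lt(max(abs(c1 - c2)), 0.5)
})

test_that("templates are deterministic given the cohort", {
  fx <- cleanCohortWithTemplates()
  t2 <- buildTemplates(fx$cohort)
  expect_equal(imgData(t2$mri), imgData(fx$templates$mri))
  expect_equal(imgData(t2$pet), imgData(fx$templates$pet))
  expect_identical(imgData(t2$voisPET), imgData(fx$templates$voisPET))
})
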