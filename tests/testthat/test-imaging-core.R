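test_that("NIfTI round trip preserves data, voxel size and affine", {
  vol <- imageVolume(array(runif(8^3), c(8, 8, 8)),
                     voxelSize = c(0.2, 0.2, 0.25), modality = "MRI")
  f <- tempfile(fileext = ".nii")
  writeVolume(vol, f)
  back <- readVolume(f)
  expect_lt(max(abs(imgData(back) - imgData(vol))), 1e-6)
  expect_lt(max(abs(voxelSize(back) - voxelSize(vol))), 1e-6)
  expect_lt(max(abs(worldAffine(back) - worldAffine(vol))), 1e-6)

  ones <- imageVolume(array(1, c(8, 8, 8)))
  f2 <- tempfile(fileext = ".nii")
  writeVolume(ones, f2)
  expect_equal(imgData(readVolume(f2)), imgData(ones))
})

test_that("4D volumes carry their 39-frame schedule through the sidecar", {
  sched <- defaultFrameSchedule()
  dyn <- imageVolume(array(rnorm(4 * 4 * 4 * 39), c(4, 4, 4, 39)),
                     modality = "PET-dynamic", schedule = sched)
  f <- tempfile(fileext = ".nii")
  writeVolume(dyn, f)
  expect_true(file.exists(paste0(f, ".frames.tsv")))
  back <- readVolume(f, modality = "PET-dynamic")
  expect_equal(nFrames(back), 39L)
  expect_equal(frameSchedule(back)@duration, sched@duration)
  # 4D without any schedule is rejected
  file.remove(paste0(f, ".frames.tsv"))
  expect_error(readVolume(f), "schedule")
})

test_that("invalid volumes are rejected with informative errors", {
  expect_error(imageVolume(array(c(1, NA, rep(1, 6)), c(2, 2, 2))),
               "non-finite")
  expect_error(imageVolume(array(1, c(4, 4, 4)), modality = "XRAY"),
               "modality")
  # header with negative voxel size: patch pixdim[1] in place
  f <- tempfile(fileext = ".nii")
  writeVolume(imageVolume(array(1, c(4, 4, 4))), f)
  con <- file(f, "r+b")
  seek(con, 80, rw = "write")  # pixdim[1] of the NIfTI-1 header
  writeBin(-1, con, size = 4)
  close(con)
  expect_error(readVolume(f), "voxel size")
})

test_that("default frame schedule matches the 90-min protocol", {
  s <- defaultFrameSchedule()
  expect_equal(nFrames(s), 39L)
  expect_equal(sum(s@duration), 5400)
  expect_equal(s@start[1], 0)
  expect_equal(midTimes(s)[1], 5 / 60)
  # contiguity is enforced
  expect_error(new("FrameSchedule", start = c(0, 20), duration = c(10, 10)),
               "contiguous")
})

test_that("trilinear resampling reproduces analytic impulse weights", {
  vol <- deltaVolume(9)
  # identity: bitwise equal
  same <- resampleVolume(vol, NULL, NULL)
  expect_identical(imgData(same), imgData(vol))
  # sampling 1 voxel to the +x side moves the impulse one voxel down
  sh1 <- resampleVolume(vol, rigidTransform(c(1, 0, 0)))
  expect_equal(imgData(sh1)[4, 5, 5], 1)
  expect_equal(sum(imgData(sh1)), 1)
  # half-voxel: 50/50 split between neighbors
  shHalf <- resampleVolume(vol, rigidTransform(c(0.5, 0, 0)))
  expect_equal(imgData(shHalf)[4, 5, 5], 0.5)
  expect_equal(imgData(shHalf)[5, 5, 5], 0.5)
})

test_that("resampling is linear in the image and frame-wise in 4D", {
  set.seed(1)
  a <- array(runif(6^3), c(6, 6, 6))
  b <- array(runif(6^3), c(6, 6, 6))
  tr <- rigidTransform(c(0.3, -0.2, 0.6), c(0.05, 0, -0.03))
  res <- function(x) imgData(resampleVolume(imageVolume(x), tr))
  expect_equal(res(2 * a + 3 * b), 2 * res(a) + 3 * res(b),
               tolerance = 1e-12)
  sched <- frameScheduleFromDurations(c(60, 120))
  dyn <- imageVolume(array(c(a, b), c(6, 6, 6, 2)),
                     modality = "PET-dynamic", schedule = sched)
  rdyn <- resampleVolume(dyn, tr)
  expect_equal(rdyn@data[, , , 1], res(a))
  expect_equal(rdyn@data[, , , 2], res(b))
  expect_equal(frameSchedule(rdyn)@duration, sched@duration)
})

test_that("CT thresholding zeroes soft tissue and keeps skull", {
  ct <- imageVolume(array(c(100, 1500, 0, 700, 499, 500, 30, 1200),
                          c(2, 2, 2)), modality = "CT")
  out <- thresholdCT(ct)
  expect_equal(sort(unique(as.numeric(imgData(out)))),
               c(0, 500, 700, 1200, 1500))
  # all >= cutoff: identity
  hi <- imageVolume(array(600, c(3, 3, 3)), modality = "CT")
  expect_identical(imgData(thresholdCT(hi)), imgData(hi))
  zero <- imageVolume(array(0, c(3, 3, 3)), modality = "CT")
  expect_identical(imgData(thresholdCT(zero)), imgData(zero))
  expect_error(thresholdCT(imageVolume(array(1, c(3, 3, 3)))), "CT")
})

test_that("brain cropping keeps world coordinates intact", {
  vol <- imageVolume(array(rnorm(16^3), c(16, 16, 16)),
                     voxelSize = c(0.5, 0.5, 0.5))
  lab <- array(0L, c(16, 16, 16))
  lab[6:15, 4:13, 5:14] <- 1L
  mask <- labelMap(lab, affine = worldAffine(vol), regions = c(brain = 1))
  crop <- cropBrain(vol, mask, margin = 0)
  expect_equal(dim(imgData(crop)), c(10L, 10L, 10L))
  # world coordinate of the mask centroid is unchanged
  w <- which(lab == 1L, arr.ind = TRUE) - 1
  centroidWorld <- colMeans(petnorm:::voxelToWorld(worldAffine(vol), w))
  inCrop <- petnorm:::trilinearSampleWorld(
    imgData(vol), worldAffine(vol),
    matrix(centroidWorld, 1, 3))
  inOrig <- petnorm:::trilinearSampleWorld(
    imgData(crop), worldAffine(crop),
    matrix(centroidWorld, 1, 3))
  expect_equal(inCrop, inOrig)
  # full-volume mask: identity crop
  full <- labelMap(array(1L, c(16, 16, 16)), affine = worldAffine(vol),
                   regions = c(brain = 1))
  expect_identical(imgData(cropBrain(vol, full)), imgData(vol))
  empty <- labelMap(array(0L, c(16, 16, 16)), affine = worldAffine(vol),
                    regions = c(brain = 1))
  expect_error(cropBrain(vol, empty), "empty")
})

test_that("VOI volumes and striatum/brain ratio follow voxel arithmetic", {
  lab <- array(0L, c(10, 10, 10))
  lab[1:4, 1:5, 1:5] <- 1L   # 100 voxels
  lm <- labelMap(lab, regions = c(striatum = 1),
                 voxelSize = c(0.2, 0.2, 0.25))
  expect_equal(voiVolume(lm, "striatum"), 1.0)
  lm2 <- labelMap(array(0L, c(4, 4, 4)), regions = c(striatum = 1))
  expect_equal(voiVolume(lm2, "striatum"), 0)
  expect_error(voiVolume(lm, "thalamus"), "unknown region")
  # striatum = whole brain -> ratio 1
  all1 <- labelMap(array(1L, c(6, 6, 6)),
                   regions = c(striatum = 1, brain = 2))
  expect_equal(striatumBrainRatio(all1), 1.0)
})

test_that("erosion to a volume fraction stays inside the region", {
  lab <- array(0L, c(14, 14, 14))
  lab[3:12, 3:12, 3:12] <- 1L  # 10^3 cube
  lm <- labelMap(lab, regions = c(striatum = 1))
  expect_identical(erodeToFraction(lm, "striatum", 1)@labels, lm@labels)
  half <- erodeToFraction(lm, "striatum", 0.5)
  inside <- imgData(half) == 1L
  expect_lte(sum(inside), 500)
  expect_true(all(lab[inside] == 1L))
  # monotone in fraction
  q <- erodeToFraction(lm, "striatum", 0.2)
  expect_lte(sum(imgData(q) == 1L), sum(inside))
  expect_true(all(inside[imgData(q) == 1L]))
  one <- array(0L, c(5, 5, 5)); one[3, 3, 3] <- 1L
  lm1 <- labelMap(one, regions = c(striatum = 1))
  expect_error(erodeToFraction(lm1, "striatum", 0.5), "vanishes")
})

test_that("hottest-fraction VOI selects top voxels deterministically", {
  lab <- array(0L, c(10, 1, 1))
  lab[1:10, 1, 1] <- 1L
  lm <- labelMap(lab, regions = c(striatum = 1))
  img <- imageVolume(array(as.numeric(1:10), c(10, 1, 1)),
                     modality = "PET-static")
  hot <- hottestFraction(img, lm, "striatum", 0.2)
  expect_equal(which(imgData(hot) == 1L), c(9L, 10L))
  expect_identical(imgData(hottestFraction(img, lm, "striatum", 1)),
                   imgData(lm))
  # uniform intensities: exactly 20%, reproducible tie-break
  uni <- imageVolume(array(7, c(10, 1, 1)), modality = "PET-static")
  h1 <- hottestFraction(uni, lm, "striatum", 0.2)
  h2 <- hottestFraction(uni, lm, "striatum", 0.2)
  expect_equal(sum(imgData(h1) == 1L), 2L)
  expect_identical(imgData(h1), imgData(h2))
  # minimum kept intensity >= any excluded intensity
  set.seed(3)
  img2 <- imageVolume(array(rnorm(10), c(10, 1, 1)),
                      modality = "PET-static")
  h3 <- hottestFraction(img2, lm, "striatum", 0.4)
  kept <- imgData(img2)[imgData(h3) == 1L]
  dropped <- imgData(img2)[imgData(h3) == 0L & imgData(lm) == 1L]
  expect_gte(min(kept), max(dropped))
})
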