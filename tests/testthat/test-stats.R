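test_that("Cohen's d from the group summaries matches hand arithmetic", {
  expect_equal(round(cohensD(1.86, 0.20, 1.06, 0.24), 2), 3.62)
  expect_equal(round(cohensD(1.93, 0.24, 1.32, 0.13), 2), 3.16)
  expect_equal(round(cohensD(1.86, 0.29, 0.98, 0.32), 2), 2.88)
  expect_equal(cohensD(1.5, 0.2, 1.5, 0.3), 0)
  expect_identical(cohensD(2, 0, 1, 0), Inf)
  # antisymmetry and scale behavior
  set.seed(2)
  for (i in 1:10) {
    m <- runif(2, 0.5, 3); s <- runif(2, 0.05, 0.5)
    d <- cohensD(m[1], s[1], m[2], s[2])
    expect_equal(cohensD(m[2], s[2], m[1], s[1]), -d)
    k <- runif(1, 0.1, 5)
    expect_equal(cohensD(k * m[1], k * s[1], k * m[2], k * s[2]), d)
  }
  # the (n-1)-weighted alternative is available and differs when group
  # SDs differ
  dn <- cohensD(1.93, 0.24, 1.32, 0.13, pooling = "nweighted",
                n1 = 16, n2 = 15)
  expect_equal(round(dn, 2), 3.13)
})

test_that("percent differences use their explicit baseline", {
  expect_equal(round(percentDifference(1.86, 0.98, baseline = 1.86), 1),
               47.3)
  expect_equal(round(percentDifference(1.32, 0.98, baseline = 0.98), 1),
               34.7)
  expect_equal(percentDifference(2, 2, baseline = 2), 0)
  expect_error(percentDifference(1, 2, baseline = 0), "baseline")
})

test_that("Bland-Altman agrees with its closed forms", {
  set.seed(5)
  y <- runif(10, 0.5, 2)
  same <- blandAltman(y, y)
  expect_equal(same$bias, 0)
  expect_equal(unname(diff(same$loa)), 0)
  prop <- blandAltman(1.1 * y, y)
  expect_equal(prop$bias, 10)
  expect_equal(prop$sd, 0)
  delta <- 0.07
  offs <- blandAltman(y + delta, y)
  expect_equal(offs$bias, mean(100 * delta / y))
  expect_equal(unname(offs$loa["upper"] - offs$bias), 1.96 * offs$sd)
  expect_error(blandAltman(1:4, 1:3), "lengths")
})

test_that("Pearson p-values agree with a permutation oracle", {
  expect_equal(pearsonR(1:10, 2 * (1:10) + 1)$r, 1)
  expect_equal(pearsonR(1:10, -(1:10))$r, -1)
  set.seed(9)
  x <- rnorm(15); y <- 0.6 * x + rnorm(15, 0, 0.8)
  res <- pearsonR(x, y)
  robs <- abs(cor(x, y))
  perm <- mean(replicate(10000, abs(cor(x, sample(y))) >= robs))
  expect_lt(abs(res$p - perm), 3 * sqrt(perm * (1 - perm) / 10000) + 1e-3)
  expect_error(pearsonR(rep(1, 5), 1:5), "variance")
})

test_that("t-tests and Bonferroni correction behave as defined", {
  x <- c(1, 2, 3, 4); y <- c(1, 2, 3, 4)
  expect_equal(unpairedT(x, y)$t, 0)
  expect_equal(unpairedT(x, y)$p, 1)
  # t^2 equals the one-way ANOVA F for two groups
  set.seed(3)
  a <- rnorm(8, 1); b <- rnorm(9, 1.4)
  tt <- unpairedT(a, b)
  df <- data.frame(v = c(a, b),
                   g = rep(c("a", "b"), c(8, 9)))
  f <- summary(aov(v ~ g, df))[[1]]$`F value`[1]
  expect_equal(tt$t^2, f, tolerance = 1e-10)
  # Bonferroni: m comparisons at raw p multiply by m, cap at 1
  m <- matrix(rnorm(30), 10, 3,
              dimnames = list(NULL, c("mri", "pet", "ct")))
  pb <- pairedBonferroni(m)
  expect_equal(nrow(pb), 3)
  expect_equal(pb$pAdjusted, pmin(pb$p * 3, 1))
})

test_that("the route comparison table is internally consistent", {
  set.seed(13)
  n <- 10
  base <- data.frame(
    subject = rep(sprintf("s%02d", 1:(2 * n)), times = 3),
    genotype = rep(rep(c("WT", "HET"), each = n), times = 3),
    route = rep(c("mri", "pet", "ct"), each = 2 * n),
    bp = NA_real_)
  true <- c(rnorm(n, 1.8, 0.2), rnorm(n, 1.0, 0.2))
  base$bp <- rep(true, 3) + rnorm(nrow(base), 0, 0.05)
  t1 <- makeTable1(base)
  g <- t1$groups
  expect_equal(g$delta, g$meanWT - g$meanHET)
  for (i in seq_len(nrow(g)))
    expect_equal(g$d[i], cohensD(g$meanWT[i], g$sdWT[i], g$meanHET[i],
                                 g$sdHET[i]))
  expect_true(all(g$ciLow < g$delta & g$delta < g$ciHigh))
  # identical values across routes: all cross-route deltas vanish
  flat <- base; flat$bp <- rep(true, 3)
  t2 <- makeTable1(flat)
  expect_equal(t2$crossRoutes$delta, rep(0, nrow(t2$crossRoutes)))
  expect_equal(t2$crossRoutes$deltaPct, rep(0, nrow(t2$crossRoutes)))
  # WT duplicated as HET: no genotype effect
  dup <- base
  dup$bp[dup$genotype == "HET"] <- dup$bp[dup$genotype == "WT"]
  t3 <- makeTable1(dup)
  expect_equal(t3$groups$delta, rep(0, 3))
  expect_equal(t3$groups$d, rep(0, 3))
  expect_error(makeTable1(base[base$route != "ct", ]), "missing route")
  # text rendering carries one row per route and comparison
  txt <- capture.output(formatGroupTable(t1))
  expect_length(grep("^\\| (mri|pet|ct) \\|", txt), 3)
  expect_length(grep("^\\| \\w+-\\w+ \\|", txt), 6)
})

test_that("volumetric comparison reports the configured reduction", {
  df <- data.frame(genotype = rep(c("WT", "HET"), each = 6),
                   ratio = c(rep(0.09, 6), rep(0.09 * 0.923, 6)))
  df$ratio <- df$ratio + rep(c(-1, 1), 6) * 1e-5
  v <- volumetricsCompare(df)
  expect_equal(v$reductionPct, 7.7, tolerance = 0.01)
  same <- data.frame(genotype = rep(c("WT", "HET"), each = 4),
                     ratio = rep(c(0.089, 0.091), 4))
  expect_equal(volumetricsCompare(same)$reductionPct, 0, tolerance = 1e-9)
})
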