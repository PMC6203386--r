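#' @include routes.R
NULL

#' Cohen's d standardized mean difference
#'
#' d = (mean1 - mean2) / pooled SD. The default pooling is the
#' equal-weight root mean square sqrt((sd1^2 + sd2^2) / 2); an
#' (n-1)-weighted pooled SD is available via \code{pooling = "nweighted"}
#' (requires n1, n2). If both SDs are zero with unequal means the result
#' is signed infinity.
#'
#' @param mean1,sd1,mean2,sd2 group summaries.
#' @param pooling "equal" (default) or "nweighted".
#' @param n1,n2 group sizes (only for "nweighted").
#' @return Cohen's d
#' @examples
#' cohensD(1.86, 0.20, 1.06, 0.24)  # 3.62
#' @export
cohensD <- function(mean1, sd1, mean2, sd2,
                    pooling = c("equal", "nweighted"),
                    n1 = NULL, n2 = NULL) {
  pooling <- match.arg(pooling)
  if (sd1 < 0 || sd2 < 0) stop("SDs must be non-negative")
  pooled <- if (pooling == "equal") sqrt((sd1^2 + sd2^2) / 2) else {
    if (is.null(n1) || is.null(n2))
      stop("n-weighted pooling needs n1 and n2")
    sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2))
  }
  if (pooled == 0) {
    if (mean1 == mean2) return(0)
    return(sign(mean1 - mean2) * Inf)
  }
  (mean1 - mean2) / pooled
}

#' Percent difference against an explicit baseline
#'
#' 100 * (a - b) / baseline. The baseline is always passed explicitly so
#' every reported percentage records what it is relative to.
#'
#' @param a,b values to compare.
#' @param baseline denominator (must be non-zero).
#' @return percent difference
#' @examples
#' percentDifference(1.86, 0.98, baseline = 1.86)  # 47.3 (genotype, CT row)
#' @export
percentDifference <- function(a, b, baseline) {
  if (any(baseline == 0)) stop("zero baseline")
  100 * (a - b) / baseline
}

#' Bland-Altman agreement analysis
#'
#' Per-pair percent differences 100 * (x_i - y_i) / y_i against the
#' reference method y, their mean (bias), SD, and 95% limits of agreement
#' bias +/- 1.96 * SD, plus Pearson r and r^2 of the raw values. Pair
#' means (for plotting differences against) are returned alongside.
#'
#' @param x test-method values.
#' @param y reference-method values (the percent denominator).
#' @return list(differences, pairMeans, bias, sd, loa, r, r2)
#' @export
blandAltman <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(x) < 3) stop("need at least 3 pairs")
  d <- 100 * (x - y) / y
  bias <- mean(d)
  s <- stats::sd(d)
  r <- stats::cor(x, y)
  list(differences = d, pairMeans = (x + y) / 2, bias = bias, sd = s,
       loa = c(lower = bias - 1.96 * s, upper = bias + 1.96 * s),
       r = r, r2 = r^2)
}

#' Pearson correlation with two-tailed t-test p-value
#'
#' @param x,y paired values, n >= 3.
#' @return list(r, r2, p)
#' @export
pearsonR <- function(x, y) {
  if (length(x) < 3) stop("need n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: correlation undefined")
  ct <- stats::cor.test(x, y, method = "pearson",
                        alternative = "two.sided")
  list(r = unname(ct$estimate), r2 = unname(ct$estimate)^2,
       p = ct$p.value)
}

#' Unpaired two-sample t-test
#'
#' Classic (pooled-variance) two-tailed t-test.
#'
#' @param x,y group values, n >= 2 each.
#' @return list(t, df, p, ci) where ci is the 95% CI of mean(x) - mean(y)
#' @export
unpairedT <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) stop("need n >= 2 per group")
  tt <- stats::t.test(x, y, var.equal = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, ci = unname(tt$conf.int))
}

#' Bonferroni-corrected pairwise route comparisons
#'
#' Paired two-tailed t-tests between every pair of routes over the shared
#' subjects, with p-values multiplied by the number of comparisons
#' (capped at 1).
#'
#' @param values matrix or data.frame, rows = subjects, columns = routes.
#' @return data.frame(route1, route2, meanDiff, t, p, pAdjusted)
#' @export
pairedBonferroni <- function(values) {
  values <- as.matrix(values)
  routes <- colnames(values)
  if (is.null(routes)) routes <- paste0("route", seq_len(ncol(values)))
  pairs <- utils::combn(ncol(values), 2)
  m <- ncol(pairs)
  out <- data.frame(route1 = routes[pairs[1, ]],
                    route2 = routes[pairs[2, ]],
                    meanDiff = NA_real_, t = NA_real_, p = NA_real_)
  for (j in seq_len(m)) {
    a <- values[, pairs[1, j]]; b <- values[, pairs[2, j]]
    tt <- stats::t.test(a, b, paired = TRUE)
    out$meanDiff[j] <- mean(a - b)
    out$t[j] <- unname(tt$statistic)
    out$p[j] <- tt$p.value
  }
  out$pAdjusted <- pmin(out$p * m, 1)
  out
}

#' Group-comparison table across normalization routes
#'
#' The study's summary table: per route (MRI, PET, CT template) the WT
#' and HET group means and SDs of striatal BP_ND, the genotype difference
#' with percent (baseline: WT mean of that route), its 95% CI (pooled-t)
#' and Cohen's d (equal-weight pooled SD); plus the three cross-route
#' difference rows per genotype with percent differences (baseline: the
#' second route of each pair, recorded in the output).
#'
#' @param results data.frame with columns subject, genotype, route, bp.
#' @param routes routes to include, default c("mri", "pet", "ct").
#' @return list(groups, crossRoutes): two data.frames
#' @export
makeTable1 <- function(results, routes = c("mri", "pet", "ct")) {
  stopifnot(all(c("subject", "genotype", "route", "bp") %in%
                  names(results)))
  missing <- setdiff(routes, unique(results$route))
  if (length(missing) > 0)
    stop("missing route(s): ", paste(missing, collapse = ", "))
  groups <- do.call(rbind, lapply(routes, function(r) {
    wt <- results$bp[results$route == r & results$genotype == "WT"]
    het <- results$bp[results$route == r & results$genotype == "HET"]
    if (length(wt) < 2 || length(het) < 2)
      stop("need >= 2 subjects per genotype for route ", r)
    tt <- unpairedT(wt, het)
    data.frame(route = r, meanWT = mean(wt), sdWT = stats::sd(wt),
               nWT = length(wt), meanHET = mean(het),
               sdHET = stats::sd(het), nHET = length(het),
               delta = mean(wt) - mean(het),
               deltaPct = percentDifference(mean(wt), mean(het),
                                            baseline = mean(wt)),
               pctBaseline = "WT",
               ciLow = tt$ci[1], ciHigh = tt$ci[2],
               d = cohensD(mean(wt), stats::sd(wt), mean(het),
                           stats::sd(het)),
               p = tt$p)
  }))
  pairs <- utils::combn(routes, 2)
  crossRoutes <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    r1 <- pairs[2, j]; r2 <- pairs[1, j]  # later route minus earlier
    do.call(rbind, lapply(c("WT", "HET"), function(g) {
      v1 <- results$bp[results$route == r1 & results$genotype == g]
      v2 <- results$bp[results$route == r2 & results$genotype == g]
      data.frame(comparison = paste0(r1, "-", r2), genotype = g,
                 delta = mean(v1) - mean(v2),
                 deltaPct = percentDifference(mean(v1), mean(v2),
                                              baseline = mean(v2)),
                 pctBaseline = r2)
    }))
  }))
  list(groups = groups, crossRoutes = crossRoutes)
}

#' Render the group-comparison table as markdown-style text
#'
#' @param table1 result of \code{\link{makeTable1}}.
#' @return character vector of text lines, invisibly; printed to console
#' @export
formatGroupTable <- function(table1) {
  g <- table1$groups
  lines <- c(
    "| Route | WT | HET | Delta (genotype) | 95% CI | d | p |",
    "|---|---|---|---|---|---|---|",
    sprintf(
      "| %s | %.2f +/- %.2f | %.2f +/- %.2f | %.2f (%.1f%%) | %+.3f to %+.3f | %.2f | %.2g |",
      g$route, g$meanWT, g$sdWT, g$meanHET, g$sdHET, g$delta,
      g$deltaPct, g$ciLow, g$ciHigh, g$d, g$p),
    "", "| Comparison | Genotype | Delta | Delta % (baseline) |",
    "|---|---|---|---|",
    sprintf("| %s | %s | %.2f | %.1f%% (%s) |",
            table1$crossRoutes$comparison, table1$crossRoutes$genotype,
            table1$crossRoutes$delta, table1$crossRoutes$deltaPct,
            table1$crossRoutes$pctBaseline))
  cat(lines, sep = "\n")
  invisible(lines)
}

#' Volumetric genotype comparison
#'
#' Striatum / whole-brain volume ratios compared between genotypes with
#' an unpaired t-test; reports the percent reduction of the HET group
#' mean relative to WT.
#'
#' @param cohort a Cohort, or a data.frame with columns genotype, ratio.
#' @return list(meanWT, meanHET, reductionPct, t, p, perSubject)
#' @export
volumetricsCompare <- function(cohort) {
  if (is(cohort, "Cohort")) {
    df <- do.call(rbind, lapply(cohort@subjects, function(s)
      data.frame(subject = s$truth@id, genotype = s$truth@genotype,
                 ratio = s$truth@striatalVolume / s$truth@brainVolume,
                 striatalVolume = s$truth@striatalVolume,
                 brainVolume = s$truth@brainVolume)))
  } else df <- cohort
  wt <- df$ratio[df$genotype == "WT"]
  het <- df$ratio[df$genotype == "HET"]
  tt <- tryCatch(unpairedT(wt, het),
                 error = function(e) list(t = NA_real_, p = NA_real_))
  list(meanWT = mean(wt), meanHET = mean(het),
       reductionPct = 100 * (1 - mean(het) / mean(wt)),
       t = tt$t, p = tt$p, perSubject = df)
}
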