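#' @include imaging_core.R
NULL

#' Construct a TAC
#'
#' @param midTime frame mid-times (min), strictly increasing.
#' @param duration frame durations (s).
#' @param activity mean activity per frame (kBq/mL).
#' @param region region name.
#' @return a \linkS4class{TAC}
#' @export
tac <- function(midTime, duration, activity, region = "") {
  new("TAC", midTime = as.numeric(midTime), duration = as.numeric(duration),
      activity = as.numeric(activity), region = region)
}

#' Read / write TACs as TSV
#'
#' Columns: mid_time_min, duration_s, activity_kBq_per_mL.
#' @param x a TAC (for writing).
#' @param path TSV path.
#' @param region region name to attach on read.
#' @return \code{readTAC}: a TAC.
#' @export
writeTAC <- function(x, path) {
  utils::write.table(
    data.frame(mid_time_min = x@midTime, duration_s = x@duration,
               activity_kBq_per_mL = x@activity),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeTAC
#' @export
readTAC <- function(path, region = "") {
  tab <- utils::read.delim(path)
  tac(tab$mid_time_min, tab$duration_s, tab$activity_kBq_per_mL, region)
}

#' Extract a regional TAC from a dynamic volume
#'
#' Unweighted per-frame mean over the voxels of \code{region}; the frame
#' schedule is carried over from the volume.
#'
#' @param dyn a 4D PET ImageVolume with schedule.
#' @param lab a LabelMap on the same grid.
#' @param region region name.
#' @return a \linkS4class{TAC}
#' @export
extractTAC <- function(dyn, lab, region) {
  stopifnot(is(dyn, "ImageVolume"), is(lab, "LabelMap"))
  d <- dim(dyn@data)
  if (length(d) != 4L) stop("extractTAC needs a 4D dynamic volume")
  if (!all(d[1:3] == dim(lab@labels))) stop("grids differ")
  code <- lab@regions[[region]]
  if (is.null(code) || is.na(code)) stop("unknown region '", region, "'")
  vox <- which(lab@labels == code)
  if (length(vox) == 0L) stop("region '", region, "' is empty")
  nvox3 <- prod(d[1:3])
  act <- vapply(seq_len(d[4]), function(f)
    mean(dyn@data[vox + (f - 1) * nvox3]), numeric(1))
  sched <- dyn@schedule
  tac(midTimes(sched), sched@duration, act, region)
}

# convolution of a sampled curve with exp(-k * t) on its own uniform grid,
# exact for piecewise-linear input (interval-wise closed form, recursive)
.expConv <- function(tGrid, c, k) {
  n <- length(tGrid)
  if (n < 2) return(numeric(n))
  dt <- tGrid[2] - tGrid[1]
  out <- numeric(n)
  if (k * dt < 1e-12) {
    # near-zero rate: plain running trapezoid integral
    out[-1] <- cumsum((c[-n] + c[-1]) / 2 * dt)
    return(out)
  }
  e <- exp(-k * dt)
  # integral over one interval of (a + b*s) * exp(-k (dt - s)) ds
  i0 <- (1 - e) / k            # weight of value at interval start... (a)
  i1 <- (dt - i0) / k          # weight of slope term (b)
  for (i in 2:n) {
    a <- c[i - 1]; b <- (c[i] - c[i - 1]) / dt
    out[i] <- out[i - 1] * e + a * i0 + b * i1
  }
  out
}

#' SRTM forward model
#'
#' Predicts the target-region TAC from a reference-region TAC under the
#' simplified reference tissue model:
#' \deqn{C_T(t) = R_1 C_R(t) + (k_2 - R_1 k_{2a}) [C_R \otimes e^{-k_{2a} t}](t)}
#' with apparent efflux rate \eqn{k_{2a} = k_2 / (1 + BP_{ND})}. The
#' convolution is computed on a fine uniform grid (default 0.1 min) with
#' piecewise-linear \eqn{C_R}, then sampled at the frame mid-times.
#'
#' @param R1 delivery ratio (unitless).
#' @param k2 target efflux rate (1/min), > 0.
#' @param bp binding potential BP_ND, > -1.
#' @param ref reference-region TAC.
#' @param fineDt convolution grid step (min).
#' @return a TAC of predicted target activity at the reference mid-times
#' @export
srtmForward <- function(R1, k2, bp, ref, fineDt = 0.1) {
  stopifnot(is(ref, "TAC"))
  if (!is.finite(k2) || k2 <= 0) stop("k2 must be > 0")
  if (!is.finite(bp) || bp <= -1) stop("BP_ND must be > -1")
  k2a <- k2 / (1 + bp)
  tEnd <- max(ref@midTime)
  tGrid <- seq(0, tEnd, by = fineDt)
  if (tGrid[length(tGrid)] < tEnd) tGrid <- c(tGrid, tEnd)
  # piecewise-linear reference curve through (0, 0) and the mid-time samples
  cr <- stats::approx(c(0, ref@midTime), c(0, ref@activity), xout = tGrid,
                      rule = 2)$y
  conv <- .expConv(tGrid, cr, k2a)
  # R1 term uses the exact reference samples; only the convolution is
  # carried over from the fine grid
  convMid <- stats::approx(tGrid, conv, xout = ref@midTime, rule = 2)$y
  ctFrames <- R1 * ref@activity + (k2 - R1 * k2a) * convMid
  tac(ref@midTime, ref@duration, ctFrames, "srtm-forward")
}

#' Fit the simplified reference tissue model
#'
#' Weighted non-linear least squares of the SRTM forward model against a
#' target TAC, with weights proportional to frame duration (or uniform)
#' and multi-start Levenberg-Marquardt initialization. Parameters are
#' bounded (k2 > 0, BP_ND > -0.99); the lowest-RSS start wins, ties going
#' to the first.
#'
#' @param target target-region TAC.
#' @param ref reference-region TAC on the same time grid.
#' @param weighting "duration" (default) or "uniform".
#' @param starts matrix of starting values, columns (R1, k2, bp).
#' @param fineDt convolution grid step passed to \code{srtmForward}.
#' @return an \linkS4class{SRTMFit}
#' @examples
#' sched <- defaultFrameSchedule()
#' ref <- synthReferenceTAC(sched)
#' tgt <- srtmForward(1.0, 0.2, 1.5, ref)
#' fit <- srtmFit(tgt, ref)
#' bindingPotential(fit)   # ~1.5
#' @export
srtmFit <- function(target, ref, weighting = c("duration", "uniform"),
                    starts = NULL, fineDt = 0.1) {
  stopifnot(is(target, "TAC"), is(ref, "TAC"))
  if (length(target@midTime) != length(ref@midTime) ||
      max(abs(target@midTime - ref@midTime)) > 1e-6)
    stop("target and reference TACs must share one time grid")
  weighting <- match.arg(weighting)
  w <- if (weighting == "duration") target@duration else
    rep(1, length(target@duration))
  w <- w / mean(w)
  sw <- sqrt(w)
  if (is.null(starts))
    starts <- rbind(c(1.0, 0.1, 1.0), c(0.8, 0.3, 0.5), c(1.2, 0.05, 2.0))
  resid <- function(p)
    sw * (srtmForward(p[1], p[2], p[3], ref, fineDt)@activity -
            target@activity)
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = starts[i, ], fn = resid,
                         lower = c(0.01, 1e-4, -0.99),
                         upper = c(10, 5, 50),
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss - 1e-12)
      best <- list(par = fit$par, rss = rss, info = fit$info)
  }
  if (is.null(best)) {
    return(new("SRTMFit", R1 = NaN, k2 = NaN, bp = NaN, rss = NaN,
               converged = FALSE,
               fitted = rep(NaN, length(target@activity))))
  }
  p <- best$par
  fitted <- srtmForward(p[1], p[2], p[3], ref, fineDt)@activity
  new("SRTMFit", R1 = p[1], k2 = p[2], bp = p[3], rss = best$rss,
      converged = best$info %in% 1:4, fitted = fitted)
}

#' Apparent efflux rate of a fit
#' @param fit an SRTMFit
#' @return k2a = k2 / (1 + BP_ND), in 1/min
#' @export
k2a <- function(fit) fit@k2 / (1 + fit@bp)

#' Voxelwise BP_ND map by the basis-function method
#'
#' Linearizes SRTM over a logarithmic grid of apparent efflux rates k2a:
#' for each k2a the model is linear in (theta1, theta2) with basis
#' \eqn{B(t) = [C_R \otimes e^{-k_{2a} t}](t)}, solved per voxel by
#' weighted least squares; the k2a minimizing the residual wins, and
#' BP_ND = k2 / k2a - 1 with k2 = theta2 + theta1 k2a.
#'
#' @param dyn 4D dynamic ImageVolume with schedule.
#' @param ref reference-region TAC on the volume's frame grid.
#' @param mask optional logical/integer 3D array; voxels outside get 0.
#' @param k2aGrid grid of apparent efflux rates (1/min); default 100
#'   log-spaced points in [0.01, 1].
#' @param weighting "duration" or "uniform".
#' @param fineDt convolution grid step (min).
#' @param refine after the coarse sweep, re-sweep a fine local grid
#'   around each selected k2a (removes grid-quantization bias).
#' @return a "BP-map" ImageVolume
#' @export
bpMap <- function(dyn, ref, mask = NULL,
                  k2aGrid = exp(seq(log(0.01), log(1), length.out = 100)),
                  weighting = c("duration", "uniform"), fineDt = 0.1,
                  refine = TRUE) {
  stopifnot(is(dyn, "ImageVolume"), is(ref, "TAC"))
  if (length(k2aGrid) == 0L) stop("empty k2a basis grid")
  d <- dim(dyn@data)
  if (length(d) != 4L) stop("bpMap needs a 4D dynamic volume")
  weighting <- match.arg(weighting)
  w <- if (weighting == "duration") ref@duration else
    rep(1, length(ref@duration))
  w <- w / mean(w)
  nvox <- prod(d[1:3])
  vox <- if (is.null(mask)) seq_len(nvox) else which(mask != 0)
  Y <- matrix(dyn@data, nvox, d[4])[vox, , drop = FALSE]
  cr <- ref@activity
  tEnd <- max(ref@midTime)
  tGrid <- seq(0, tEnd, by = fineDt)
  crFine <- stats::approx(c(0, ref@midTime), c(0, cr), xout = tGrid,
                          rule = 2)$y
  wyc <- Y %*% (w * cr)              # per-voxel <y, w C_R>
  wyy <- Y^2 %*% w                   # per-voxel <y, w y>
  a11 <- sum(w * cr * cr)
  sweep1 <- function(grid) {
    bestRSS <- rep(Inf, length(vox))
    bestBP <- numeric(length(vox))
    bestIdx <- integer(length(vox))
    for (j in seq_along(grid)) {
      k <- grid[j]
      Bfine <- .expConv(tGrid, crFine, k)
      B <- stats::approx(tGrid, Bfine, xout = ref@midTime, rule = 2)$y
      a12 <- sum(w * cr * B)
      a22 <- sum(w * B * B)
      det <- a11 * a22 - a12^2
      if (det <= .Machine$double.eps * a11 * a22) next
      b2 <- Y %*% (w * B)
      th1 <- (a22 * wyc - a12 * b2) / det
      th2 <- (a11 * b2 - a12 * wyc) / det
      rss <- wyy - th1 * wyc - th2 * b2
      k2v <- th2 + th1 * k
      bp <- k2v / k - 1
      better <- rss < bestRSS
      bestRSS[better] <- rss[better]
      bestBP[better] <- bp[better]
      bestIdx[better] <- j
    }
    list(rss = bestRSS, bp = bestBP, idx = bestIdx)
  }
  res <- sweep1(k2aGrid)
  if (refine && length(k2aGrid) > 2) {
    gpad <- c(k2aGrid[1]^2 / k2aGrid[2], k2aGrid,
              k2aGrid[length(k2aGrid)]^2 / k2aGrid[length(k2aGrid) - 1])
    occupied <- sort(unique(res$idx[res$idx > 0]))
    fineGrid <- sort(unique(unlist(lapply(occupied, function(i)
      exp(seq(log(gpad[i]), log(gpad[i + 2]), length.out = 10))))))
    res2 <- sweep1(fineGrid)
    take <- res2$rss < res$rss
    res$bp[take] <- res2$bp[take]
  }
  out <- numeric(nvox)
  out[vox] <- res$bp
  imageVolume(array(out, d[1:3]), affine = dyn@affine, modality = "BP-map")
}
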