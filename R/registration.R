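#' @include transforms.R imaging_core.R
NULL

# joint-histogram similarity metrics over paired intensity samples
.nmi <- function(a, b, bins = 32L) {
  ra <- range(a); rb <- range(b)
  if (ra[1] == ra[2] || rb[1] == rb[2]) return(NA_real_)
  ia <- pmin(floor((a - ra[1]) / (ra[2] - ra[1]) * bins) + 1L, bins)
  ib <- pmin(floor((b - rb[1]) / (rb[2] - rb[1]) * bins) + 1L, bins)
  h <- tabulate(ia + bins * (ib - 1L), bins * bins)
  p <- h / sum(h)
  px <- rowSums(matrix(p, bins)); py <- colSums(matrix(p, bins))
  ent <- function(q) { q <- q[q > 0]; -sum(q * log(q)) }
  hxy <- ent(p)
  if (hxy == 0) return(2)
  (ent(px) + ent(py)) / hxy
}

.ncc <- function(a, b) {
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(a, b)
}

.similarity <- function(a, b, metric, bins = 32L) {
  v <- if (metric == "nmi") .nmi(a, b, bins) else .ncc(a, b)
  if (is.na(v)) -Inf else v
}

#' Similarity between two volumes on a shared grid
#'
#' Normalized mutual information (32-bin joint histogram) or normalized
#' cross-correlation between \code{moving} resampled through
#' \code{transform} and \code{fixed}, over in-field voxels.
#'
#' @param moving,fixed ImageVolumes.
#' @param transform transform mapping fixed world -> moving world (NULL =
#'   identity).
#' @param metric "nmi" or "ncc".
#' @return similarity value (higher is better)
#' @export
imageSimilarity <- function(moving, fixed, transform = NULL,
                            metric = c("nmi", "ncc")) {
  metric <- match.arg(metric)
  pts <- gridWorld(geometryOf(fixed))
  if (!is.null(transform)) pts <- applyTransform(transform, pts)
  idx <- worldToVoxel(moving@affine, pts)
  plan <- trilinearPlan(idx, dim(moving@data)[1:3])
  infield <- rowSums(plan$oob) == 0L
  if (mean(infield) < 0.2) return(-Inf)
  m <- applyPlan(plan, moving@data, 0)
  .similarity(m[infield], as.numeric(fixed@data)[infield], metric)
}

.smoothedData <- function(vol, sigmaVox) {
  if (sigmaVox <= 0) return(vol@data)
  gaussBlur3d(vol@data, rep(sigmaVox, 3))
}

#' Rigid 6-DOF registration by downhill simplex
#'
#' Estimates the rigid transform aligning \code{moving} to \code{fixed} by
#' maximizing an intensity similarity metric (default normalized mutual
#' information over a 32-bin joint histogram; normalized cross-correlation
#' for same-modality pairs) with Nelder-Mead downhill-simplex
#' minimization over the 6 parameters, in a coarse-to-fine Gaussian
#' smoothing pyramid. The rotation center is the fixed volume's world
#' center.
#'
#' The returned transform maps fixed-world points into the moving volume's
#' world frame, i.e. it is directly usable as
#' \code{resampleVolume(moving, transform, fixed)}.
#'
#' @param moving,fixed 3D ImageVolumes with overlapping world extents.
#' @param metric "nmi" (default) or "ncc".
#' @param init optional initial RigidTransform.
#' @param pyramid Gaussian smoothing sigmas (voxels), coarse to fine.
#' @param sampleStride voxel stride of the fixed-grid sample at each level
#'   (recycled); the final pattern-search polish always runs at stride 1.
#' @param maxit Nelder-Mead iterations per level.
#' @param restarts extra random restarts if the first solution fails to
#'   improve on the initialization.
#' @return a RigidTransform with attributes "cost" (negative similarity)
#'   and "converged"
#' @export
rigidRegister <- function(moving, fixed, metric = c("nmi", "ncc"),
                          init = NULL, pyramid = c(2, 0),
                          sampleStride = c(3, 2), maxit = 400,
                          restarts = 2) {
  metric <- match.arg(metric)
  stopifnot(is(moving, "ImageVolume"), is(fixed, "ImageVolume"))
  if (stats::sd(moving@data) == 0 || stats::sd(fixed@data) == 0)
    stop("degenerate (constant-intensity) image: cannot register")
  center <- worldCenter(fixed)
  geomF <- geometryOf(fixed)
  sampleStride <- rep_len(sampleStride, length(pyramid))
  par <- if (is.null(init)) rep(0, 6) else
    c(init@translation, init@rotation)
  # parameter scaling: mm vs radians
  pscale <- c(2, 2, 2, 0.06, 0.06, 0.06)

  dM <- dim(moving@data)[1:3]
  mAffInv <- solve(moving@affine)
  evalCost <- function(par, mpad, fvals, pts, bins = 32L) {
    t <- rigidTransform(par[1:3], par[4:6], center)
    tp <- applyTransform(t, pts)
    idx <- voxelToWorld(mAffInv, tp)
    sm <- .fastSample(mpad, dM, idx)
    if (mean(sm$infield) < 0.2) return(1e3)
    s <- .similarity(sm$values[sm$infield], fvals[sm$infield], metric,
                     bins)
    if (!is.finite(s)) return(1e3)
    -s
  }

  cost <- NA_real_
  allIdx <- gridIndices(geomF$dim)
  # strided sampling keeps the intensity marginals unbiased (any
  # content-driven subsampling would bias the histogram metric)
  levelSamples <- function(fdat, st) {
    sel <- allIdx[, 1] %% st == 0 & allIdx[, 2] %% st == 0 &
      allIdx[, 3] %% st == 0
    list(pts = voxelToWorld(geomF$affine, allIdx[sel, , drop = FALSE]),
         fvals = as.numeric(fdat)[sel])
  }
  for (lev in seq_along(pyramid)) {
    mpad <- .padArr(.smoothedData(moving, pyramid[lev]))
    fdat <- .smoothedData(fixed, pyramid[lev])
    smp <- levelSamples(fdat, sampleStride[lev])
    pts <- smp$pts
    fvals <- smp$fvals
    fn <- function(p) evalCost(p, mpad, fvals, pts)
    if (lev == 1L && is.null(init)) {
      # capture range: coarse translation grid search, then an axis-wise
      # rotation sweep, seed the simplex
      tgrid <- as.matrix(expand.grid(t1 = -2:2, t2 = -2:2, t3 = -2:2))
      costs <- apply(tgrid, 1, function(tt) fn(c(tt, par[4:6])))
      par[1:3] <- tgrid[which.min(costs), ]
      for (ax in 4:6) {
        angles <- c(-10, -5, 0, 5, 10) * pi / 180
        ac <- vapply(angles, function(a) {
          p <- par; p[ax] <- p[ax] + a; fn(p)
        }, numeric(1))
        par[ax] <- par[ax] + angles[which.min(ac)]
      }
    }
    for (rs in 0:restarts) {
      opt <- stats::optim(par, fn, method = "Nelder-Mead",
                          control = list(maxit = maxit, reltol = 1e-9,
                                         parscale = pscale))
      improved <- rs == 0 || opt$value < cost - 1e-8
      if (opt$value <= (if (rs == 0) Inf else cost)) {
        par <- opt$par
        cost <- opt$value
      }
      if (!improved) break  # restart simplex no longer helps
    }
    if (lev == length(pyramid)) {
      # pattern-search polish on the full voxel sample: robust to the
      # plateaus a binned metric leaves around its optimum
      smp <- levelSamples(fdat, 1L)
      pts <- smp$pts
      fvals <- smp$fvals
      # the polish runs on every voxel with a finer histogram: the
      # 32-bin metric has sub-voxel plateau ripples that can trap a
      # local search a few hundredths of a millimetre off the optimum
      fn <- function(p) evalCost(p, mpad, fvals, pts, bins = 128L)
      cost <- fn(par)
      idCost <- fn(rep(0, 6))
      if (idCost < cost) { par <- rep(0, 6); cost <- idCost }
      step <- c(rep(0.2, 3), rep(0.01, 3))
      for (round in 1:4) {
        for (k in 1:6) {
          for (sgn in c(1, -1)) {
            repeat {
              cand <- par; cand[k] <- cand[k] + sgn * step[k]
              cc <- fn(cand)
              if (cc < cost - 1e-10) { par <- cand; cost <- cc }
              else break
            }
          }
        }
        step <- step / 4
      }
    }
  }
  out <- rigidTransform(par[1:3], par[4:6], center)
  attr(out, "cost") <- cost
  attr(out, "converged") <- is.finite(cost) && cost < 999
  out
}

#' Non-linear registration on a low-frequency cosine basis
#'
#' Estimates a smooth deformation aligning \code{moving} (already
#' approximately rigid-aligned) to \code{template}. The displacement field
#' per world axis lives on a separable cosine basis with \code{cutoff}
#' frequencies per spatial axis (cutoff^3 basis functions per component).
#' The objective is the variance-normalized sum of squared intensity
#' differences after global intensity rescaling, plus \code{regWeight}
#' times the (diagonalized) bending energy of the displacement field. A
#' fixed number of outer L-BFGS iterations (default 16) with analytic
#' gradients is used; the best (lowest-objective) coefficients seen are
#' returned, so the reported objective never exceeds the identity-warp
#' objective.
#'
#' @param moving,template 3D ImageVolumes on overlapping world extents.
#' @param iterations outer iteration count (default 16).
#' @param cutoff cosine frequencies per axis (default 3).
#' @param regWeight bending-energy weight (default 1).
#' @param smoothSigma Gaussian smoothing (voxels) applied to both images
#'   during estimation; a vector runs a coarse-to-fine schedule, each
#'   level warm-starting the next. The returned warp applies to the raw
#'   data.
#' @param init optional BasisWarp (or coefficient matrix) to warm-start
#'   from.
#' @return a BasisWarp mapping template world -> moving world, with
#'   attributes "objective" (final) and "objective0" (identity warp)
#' @export
nonlinearRegister <- function(moving, template, iterations = 16,
                              cutoff = 3, regWeight = 1,
                              smoothSigma = c(2, 1, 0.5, 0.25),
                              init = NULL) {
  stopifnot(is(moving, "ImageVolume"), is(template, "ImageVolume"))
  geom <- geometryOf(template)
  extF <- apply(gridWorld(geom), 2, range)
  extM <- apply(gridWorld(geometryOf(moving)), 2, range)
  olap <- pmin(extF[2, ], extM[2, ]) - pmax(extF[1, ], extM[1, ])
  if (any(olap <= 0)) stop("world extents of the two volumes do not overlap")
  cutoff <- as.integer(cutoff)
  nb <- cutoff^3
  pts <- gridWorld(geom)
  Phi <- .warpBasis(pts, geom$dim, geom$affine, cutoff)
  pen <- .warpPenalty(geom$dim, geom$affine, cutoff)
  # bending-energy scale: normalized so the lowest non-zero frequency has
  # unit weight, then scaled so regWeight = 1 is a mild penalty relative
  # to the unit-variance SSD term (keeps small true warps recoverable
  # while damping high-frequency coefficients)
  pen <- pen / min(pen[pen > 0])
  pen <- pen * 1e-5
  dM <- dim(moving@data)[1:3]
  mAffInv <- solve(moving@affine)

  cvec <- if (is.null(init)) rep(0, 3 * nb) else {
    ic <- if (is(init, "BasisWarp")) init@coef else init
    stopifnot(all(dim(ic) == c(nb, 3L)))
    as.numeric(ic)
  }
  obj0 <- objFinest <- NA_real_
  for (lev in seq_along(smoothSigma)) {
    tdat <- .smoothedData(template, smoothSigma[lev])
    mdat <- .smoothedData(moving, smoothSigma[lev])
    fvals <- as.numeric(tdat)
    varf <- stats::var(fvals)
    if (varf == 0) stop("degenerate template (constant intensity)")
    gradPad <- lapply(imageGradient(mdat, voxelSize(moving)), .padArr)
    mpad <- .padArr(mdat)
    n <- length(fvals)
    cache <- new.env(parent = emptyenv())
    evalAt <- function(cv) {
      key <- paste(cv, collapse = ",")
      if (identical(cache$key, key)) return(cache$val)
      C <- matrix(cv, nb, 3)
      y <- pts + Phi %*% C
      idx <- voxelToWorld(mAffInv, y)
      m <- .fastSample(mpad, dM, idx)$values
      s <- sum(m * fvals) / max(sum(m * m), .Machine$double.eps)
      r <- s * m - fvals
      val <- list(C = C, idx = idx, m = m, s = s, r = r,
                  obj = sum(r^2) / (n * varf) + regWeight * sum(pen * C^2))
      cache$key <- key
      cache$val <- val
      val
    }
    objective <- function(cv) evalAt(cv)$obj
    gradient <- function(cv) {
      e <- evalAt(cv)
      g <- matrix(0, nb, 3)
      for (ax in 1:3) {
        ga <- .fastSample(gradPad[[ax]], dM, e$idx)$values
        g[, ax] <- (2 * e$s / (n * varf)) * crossprod(Phi, e$r * ga)
      }
      as.numeric(g + 2 * regWeight * pen * e$C)
    }
    opt <- stats::optim(cvec, objective, gradient, method = "L-BFGS-B",
                        control = list(maxit = iterations))
    if (lev == length(smoothSigma)) {
      # guarantee: never worse than the starting point at the finest level
      objStart <- objective(cvec)
      obj0 <- objective(rep(0, 3 * nb))
      if (opt$value <= objStart) {
        cvec <- opt$par
        objFinest <- opt$value
      } else objFinest <- objStart
    } else if (opt$value <= objective(cvec)) cvec <- opt$par
  }
  out <- basisWarp(matrix(cvec, nb, 3), domain = geom, cutoff = cutoff,
                   regWeight = regWeight)
  attr(out, "objective") <- objFinest
  attr(out, "objective0") <- obj0
  out
}
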