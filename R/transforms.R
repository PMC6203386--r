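#' @include accessors.R geometry.R
NULL

#' Construct a rigid transform
#'
#' @param translation length-3 numeric, mm.
#' @param rotation length-3 numeric, radians, intrinsic z-y-x Euler order.
#' @param center rotation center in world mm (default origin).
#' @return a \linkS4class{RigidTransform}
#' @export
rigidTransform <- function(translation = c(0, 0, 0),
                           rotation = c(0, 0, 0),
                           center = c(0, 0, 0)) {
  new("RigidTransform", translation = as.numeric(translation),
      rotation = as.numeric(rotation), center = as.numeric(center))
}

#' The identity transform
#' @return a RigidTransform with all parameters 0
#' @export
identityTransform <- function() rigidTransform()

.rotZYX <- function(r) {
  cz <- cos(r[1]); sz <- sin(r[1])
  cy <- cos(r[2]); sy <- sin(r[2])
  cx <- cos(r[3]); sx <- sin(r[3])
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3)
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3)
  Rz %*% Ry %*% Rx
}

#' Homogeneous 4x4 matrix of a rigid transform
#' @param transform a RigidTransform
#' @return 4x4 matrix acting on world column vectors
#' @export
rigidMatrix <- function(transform) {
  R <- .rotZYX(transform@rotation)
  M <- diag(4)
  M[1:3, 1:3] <- R
  M[1:3, 4] <- transform@center + transform@translation -
    R %*% transform@center
  M
}

#' Rigid transform from a homogeneous matrix
#'
#' Decomposes a rigid 4x4 matrix into z-y-x Euler angles and a
#' translation (rotation center at the origin).
#'
#' @param M 4x4 rigid homogeneous matrix.
#' @return a RigidTransform
#' @export
rigidFromMatrix <- function(M) {
  R <- M[1:3, 1:3]
  if (max(abs(crossprod(R) - diag(3))) > 1e-6)
    stop("matrix is not rigid (non-orthonormal rotation block)")
  ry <- asin(max(-1, min(1, -R[3, 1])))
  if (abs(cos(ry)) > 1e-9) {
    rz <- atan2(R[2, 1], R[1, 1])
    rx <- atan2(R[3, 2], R[3, 3])
  } else { # gimbal lock
    rz <- atan2(-R[1, 2], R[2, 2])
    rx <- 0
  }
  rigidTransform(translation = M[1:3, 4], rotation = c(rz, ry, rx))
}

#' @rdname applyTransform
setMethod("applyTransform", "RigidTransform", function(transform, points) {
  M <- rigidMatrix(transform)
  sweep(points %*% t(M[1:3, 1:3]), 2, M[1:3, 4], `+`)
})

# cosine basis values at world points over the warp domain:
# u in [0, 1] along each axis (clamped), phi_k(u) = cos(pi * k * u)
.warpBasis <- function(pts, domainDim, domainAffine, cutoff) {
  idx <- worldToVoxel(domainAffine, pts)
  n <- nrow(idx)
  B1 <- vector("list", 3)
  for (ax in 1:3) {
    u <- idx[, ax] / max(domainDim[ax] - 1L, 1L)
    u <- pmin(pmax(u, 0), 1)
    B1[[ax]] <- vapply(0:(cutoff - 1L), function(k) cos(pi * k * u),
                       numeric(n))
  }
  Phi <- matrix(0, n, cutoff^3)
  j <- 0L
  for (kz in 0:(cutoff - 1L)) for (ky in 0:(cutoff - 1L))
    for (kx in 0:(cutoff - 1L)) {
      j <- j + 1L
      Phi[, j] <- B1[[1]][, kx + 1L] * B1[[2]][, ky + 1L] *
        B1[[3]][, kz + 1L]
    }
  Phi
}

# frequency-squared-norm penalty weights per basis function (bending
# energy is diagonal in this separable cosine basis); mm^-4 scale
.warpPenalty <- function(domainDim, domainAffine, cutoff) {
  vs <- sqrt(colSums(domainAffine[1:3, 1:3]^2))
  L <- vs * pmax(domainDim - 1L, 1L)  # physical extent, mm
  w <- numeric(cutoff^3)
  j <- 0L
  for (kz in 0:(cutoff - 1L)) for (ky in 0:(cutoff - 1L))
    for (kx in 0:(cutoff - 1L)) {
      j <- j + 1L
      w[j] <- ((pi * kx / L[1])^2 + (pi * ky / L[2])^2 +
                 (pi * kz / L[3])^2)^2
    }
  w
}

#' Construct a cosine-basis warp
#'
#' @param coef (cutoff^3) x 3 coefficient matrix (mm); zero = identity.
#' @param domain grid geometry (ImageVolume, LabelMap or list(dim, affine))
#'   over which the basis is defined.
#' @param cutoff number of cosine frequencies per axis (default 3).
#' @param regWeight regularization weight recorded with the warp.
#' @return a \linkS4class{BasisWarp}
#' @export
basisWarp <- function(coef = NULL, domain, cutoff = 3L, regWeight = 1) {
  geom <- geometryOf(domain)
  cutoff <- as.integer(cutoff)
  if (is.null(coef)) coef <- matrix(0, cutoff^3, 3)
  new("BasisWarp", coef = coef, cutoff = cutoff, regWeight = regWeight,
      domainDim = geom$dim, domainAffine = geom$affine)
}

#' @rdname applyTransform
setMethod("applyTransform", "BasisWarp", function(transform, points) {
  if (max(abs(transform@coef)) == 0) return(points)
  Phi <- .warpBasis(points, transform@domainDim, transform@domainAffine,
                    transform@cutoff)
  points + Phi %*% transform@coef
})

#' @rdname applyTransform
setMethod("applyTransform", "TransformChain", function(transform, points) {
  for (t in transform@transforms) points <- applyTransform(t, points)
  points
})

#' Compose two spatial transforms
#'
#' Returns a transform equivalent to applying \code{t1} first and then
#' \code{t2} to world points. Rigid-rigid compositions collapse to a
#' single \linkS4class{RigidTransform}; any composition involving a warp
#' is stored as a lazily evaluated \linkS4class{TransformChain}.
#'
#' @param t1,t2 RigidTransform, BasisWarp or TransformChain.
#' @return the composed transform
#' @examples
#' a <- rigidTransform(translation = c(1, 0, 0))
#' b <- rigidTransform(rotation = c(pi / 2, 0, 0))
#' ab <- composeTransforms(a, b)  # translate, then rotate
#' @export
composeTransforms <- function(t1, t2) {
  if (is(t1, "RigidTransform") && is(t2, "RigidTransform"))
    return(rigidFromMatrix(rigidMatrix(t2) %*% rigidMatrix(t1)))
  parts <- function(t) if (is(t, "TransformChain")) t@transforms else list(t)
  new("TransformChain", transforms = c(parts(t1), parts(t2)))
}

#' @rdname invertTransform
setMethod("invertTransform", "RigidTransform", function(transform) {
  rigidFromMatrix(solve(rigidMatrix(transform)))
})

#' @rdname invertTransform
setMethod("invertTransform", "TransformChain", function(transform) {
  inv <- lapply(rev(transform@transforms), invertTransform)
  out <- inv[[1]]
  for (t in inv[-1]) out <- composeTransforms(out, t)
  out
})

#' @rdname invertTransform
setMethod("invertTransform", "BasisWarp", function(transform) {
  stop("basis warps are not invertible in closed form")
})

#' Serialize / restore transforms as JSON
#'
#' @param transform a RigidTransform, BasisWarp or TransformChain.
#' @param path JSON file path.
#' @return \code{readTransform}: the restored transform.
#' @export
writeTransform <- function(transform, path) {
  enc <- function(t) {
    if (is(t, "RigidTransform"))
      list(type = "rigid", translation = t@translation,
           rotation = t@rotation, center = t@center)
    else if (is(t, "BasisWarp"))
      list(type = "warp", coef = as.numeric(t@coef), cutoff = t@cutoff,
           regWeight = t@regWeight, domainDim = t@domainDim,
           domainAffine = as.numeric(t@domainAffine))
    else list(type = "chain", transforms = lapply(t@transforms, enc))
  }
  jsonlite::write_json(enc(transform), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname writeTransform
#' @export
readTransform <- function(path) {
  dec <- function(x) {
    if (x$type == "rigid")
      rigidTransform(unlist(x$translation), unlist(x$rotation),
                     unlist(x$center))
    else if (x$type == "warp")
      new("BasisWarp", coef = matrix(unlist(x$coef), ncol = 3),
          cutoff = as.integer(x$cutoff), regWeight = x$regWeight,
          domainDim = as.integer(unlist(x$domainDim)),
          domainAffine = matrix(unlist(x$domainAffine), 4, 4))
    else new("TransformChain", transforms = lapply(x$transforms, dec))
  }
  dec(jsonlite::read_json(path, simplifyVector = FALSE))
}
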