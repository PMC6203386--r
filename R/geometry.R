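# Internal grid geometry and interpolation machinery.
# Conventions: RAS world axes, mm units, voxel centers at integer 0-based
# indices, affine maps (i, j, k, 1) -> (x, y, z, 1).

imgGeometry <- function(dim, affine)
  list(dim = as.integer(dim[1:3]), affine = affine)

geometryOf <- function(x) {
  if (is(x, "ImageVolume")) return(imgGeometry(dim(x@data), x@affine))
  if (is(x, "LabelMap")) return(imgGeometry(dim(x@labels), x@affine))
  stopifnot(is.list(x), all(c("dim", "affine") %in% names(x)))
  x
}

sameGeometry <- function(a, b, tol = 1e-6) {
  a <- geometryOf(a); b <- geometryOf(b)
  all(a$dim == b$dim) && max(abs(a$affine - b$affine)) < tol
}

# N x 3 matrix of 0-based voxel indices for every voxel, x fastest
gridIndices <- function(dim) {
  dim <- as.integer(dim[1:3])
  cbind(rep.int(seq_len(dim[1]) - 1L, dim[2] * dim[3]),
        rep.int(rep(seq_len(dim[2]) - 1L, each = dim[1]), dim[3]),
        rep(seq_len(dim[3]) - 1L, each = dim[1] * dim[2]))
}

voxelToWorld <- function(affine, idx) {
  out <- idx %*% t(affine[1:3, 1:3])
  out[, 1] <- out[, 1] + affine[1, 4]
  out[, 2] <- out[, 2] + affine[2, 4]
  out[, 3] <- out[, 3] + affine[3, 4]
  out
}

worldToVoxel <- function(affine, pts) {
  voxelToWorld(solve(affine), pts)
}

# world coordinates of all voxel centers of a geometry
gridWorld <- function(geom) {
  geom <- geometryOf(geom)
  voxelToWorld(geom$affine, gridIndices(geom$dim))
}

worldCenter <- function(x) {
  geom <- geometryOf(x)
  voxelToWorld(geom$affine, matrix((geom$dim - 1) / 2, 1, 3))[1, ]
}

# Precompute a trilinear sampling plan for continuous 0-based voxel
# coordinates `idx` (N x 3) into an array of dims `d`. The plan can be
# applied to any 3D array of those dims (reused across dynamic frames).
trilinearPlan <- function(idx, d) {
  stopifnot(ncol(idx) == 3L, length(d) >= 3L)
  d <- as.integer(d[1:3])
  # snap near-integer coordinates so identity resampling is exact
  idx <- round(idx * 2^20) / 2^20
  i0 <- floor(idx)
  f <- idx - i0
  n <- nrow(idx)
  li <- matrix(0L, n, 8L)
  w <- matrix(0, n, 8L)
  oob <- matrix(FALSE, n, 8L)
  fx <- f[, 1]; fy <- f[, 2]; fz <- f[, 3]
  wx <- cbind(1 - fx, fx); wy <- cbind(1 - fy, fy); wz <- cbind(1 - fz, fz)
  corner <- 0L
  for (cz in 0:1) for (cy in 0:1) for (cx in 0:1) {
    corner <- corner + 1L
    ix <- i0[, 1] + cx; iy <- i0[, 2] + cy; iz <- i0[, 3] + cz
    bad <- ix < 0 | ix > d[1] - 1 | iy < 0 | iy > d[2] - 1 |
      iz < 0 | iz > d[3] - 1
    ixc <- pmin.int(pmax.int(ix, 0), d[1] - 1)
    iyc <- pmin.int(pmax.int(iy, 0), d[2] - 1)
    izc <- pmin.int(pmax.int(iz, 0), d[3] - 1)
    li[, corner] <- as.integer(1 + ixc + d[1] * (iyc + d[2] * izc))
    w[, corner] <- wx[, cx + 1] * wy[, cy + 1] * wz[, cz + 1]
    oob[, corner] <- bad
  }
  list(li = li, w = w, oob = oob, n = n)
}

applyPlan <- function(plan, arr, fill = 0) {
  v <- numeric(plan$n)
  for (k in 1:8) {
    wk <- plan$w[, k]
    active <- wk != 0
    if (!any(active)) next
    vk <- arr[plan$li[, k]]
    vk[plan$oob[, k]] <- fill
    # 0-weight corners contribute exactly nothing (keeps identity exact)
    v[active] <- v[active] + wk[active] * vk[active]
  }
  v
}

# pad a 3D array with a 1-voxel fill border; with .fastSample this yields
# trilinear interpolation with out-of-field fill at much lower allocation
# cost than a full sampling plan (used in registration inner loops)
.padArr <- function(arr, fill = 0) {
  d <- dim(arr)
  out <- array(fill, d + 2L)
  out[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- arr
  out
}

# trilinear sample of padded array `pad` (original dims d) at continuous
# 0-based voxel coords idx; returns list(values, infield)
.fastSample <- function(pad, d, idx) {
  i0x <- floor(idx[, 1]); i0y <- floor(idx[, 2]); i0z <- floor(idx[, 3])
  fx <- idx[, 1] - i0x; fy <- idx[, 2] - i0y; fz <- idx[, 3] - i0z
  np1 <- d[1] + 2L; np2 <- d[2] + 2L
  cx0 <- pmin.int(pmax.int(i0x, -1), d[1]) + 2
  cx1 <- pmin.int(pmax.int(i0x + 1, -1), d[1]) + 2
  cy0 <- pmin.int(pmax.int(i0y, -1), d[2]) + 2
  cy1 <- pmin.int(pmax.int(i0y + 1, -1), d[2]) + 2
  cz0 <- (pmin.int(pmax.int(i0z, -1), d[3]) + 1) * (np1 * np2)
  cz1 <- (pmin.int(pmax.int(i0z + 1, -1), d[3]) + 1) * (np1 * np2)
  ry0 <- (cy0 - 1) * np1; ry1 <- (cy1 - 1) * np1
  gx0 <- 1 - fx; gy0 <- 1 - fy; gz0 <- 1 - fz
  v <- gz0 * (gy0 * (gx0 * pad[cx0 + ry0 + cz0] + fx * pad[cx1 + ry0 + cz0]) +
              fy * (gx0 * pad[cx0 + ry1 + cz0] + fx * pad[cx1 + ry1 + cz0])) +
    fz * (gy0 * (gx0 * pad[cx0 + ry0 + cz1] + fx * pad[cx1 + ry0 + cz1]) +
          fy * (gx0 * pad[cx0 + ry1 + cz1] + fx * pad[cx1 + ry1 + cz1]))
  infield <- idx[, 1] >= 0 & idx[, 1] <= d[1] - 1 &
    idx[, 2] >= 0 & idx[, 2] <= d[2] - 1 &
    idx[, 3] >= 0 & idx[, 3] <= d[3] - 1
  list(values = v, infield = infield)
}

trilinearSampleWorld <- function(vol3d, affine, pts, fill = 0) {
  idx <- worldToVoxel(affine, pts)
  plan <- trilinearPlan(idx, dim(vol3d))
  applyPlan(plan, vol3d, fill)
}

# separable Gaussian blur; sigma in voxels per axis, edge-renormalized
gaussBlur3d <- function(arr, sigmaVox) {
  d <- dim(arr)
  sigmaVox <- rep_len(sigmaVox, 3L)
  for (ax in 1:3) {
    s <- sigmaVox[ax]
    if (s <= 1e-8) next
    n <- d[ax]
    r <- max(1L, ceiling(3 * s))
    K <- outer(seq_len(n), seq_len(n),
               function(i, j) ifelse(abs(i - j) <= r,
                                     exp(-((i - j)^2) / (2 * s^2)), 0))
    K <- K / rowSums(K)
    if (ax == 1) {
      arr <- array(K %*% matrix(arr, d[1]), d)
    } else if (ax == 2) {
      m <- matrix(aperm(arr, c(2, 1, 3)), d[2])
      arr <- aperm(array(K %*% m, d[c(2, 1, 3)]), c(2, 1, 3))
    } else {
      m <- matrix(aperm(arr, c(3, 1, 2)), d[3])
      arr <- aperm(array(K %*% m, d[c(3, 1, 2)]), c(2, 3, 1))
    }
  }
  arr
}

# central-difference spatial gradient arrays (per mm) of a 3D volume
imageGradient <- function(arr, voxelSize) {
  d <- dim(arr)
  shift <- function(a, ax, by) {
    idx <- rep(list(quote(expr = )), 3)
    src <- pmin(pmax(seq_len(d[ax]) + by, 1L), d[ax])
    idx[[ax]] <- src
    do.call(`[`, c(list(a), idx))
  }
  lapply(1:3, function(ax)
    (shift(arr, ax, 1L) - shift(arr, ax, -1L)) / (2 * voxelSize[ax]))
}
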