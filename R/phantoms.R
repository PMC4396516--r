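## Geometric phantom masks for validating the radial morphometry:
## shapes whose medial curve and radial distances are known analytically.

phantomGrid <- function(dims) {
  g <- expand.grid(i = seq_len(dims[1]), j = seq_len(dims[2]),
                   k = seq_len(dims[3]))
  as.matrix(g)
}

#' Solid cylinder phantom
#'
#' Axis-aligned solid cylinder: every surface point on the lateral wall sits
#' exactly `radius` mm from the axis, so the mean radial distance is known
#' up to voxelization and end-cap effects.
#'
#' @param radius Cylinder radius, mm.
#' @param length Cylinder length, mm.
#' @param voxelSize Isotropic voxel edge, mm.
#' @param axis Cylinder axis (1-3, default 3).
#' @param margin Background padding in voxels around the shape.
#' @return A [binaryMask3D()].
#' @export
cylinderMask <- function(radius = 5, length = 40, voxelSize = 1, axis = 3,
                         margin = 2) {
  rv <- radius / voxelSize
  lv <- round(length / voxelSize)
  side <- ceiling(2 * rv) + 2 * margin + 1
  dims <- rep(side, 3)
  dims[axis] <- lv + 2 * margin
  idx <- phantomGrid(dims)
  centre <- (dims + 1) / 2
  other <- setdiff(1:3, axis)
  inPlane <- (idx[, other[1]] - 0.5 - (dims[other[1]] / 2))^2 +
    (idx[, other[2]] - 0.5 - (dims[other[2]] / 2))^2 <= rv^2
  along <- idx[, axis] > margin & idx[, axis] <= margin + lv
  vox <- array(FALSE, dims)
  vox[idx[inPlane & along, , drop = FALSE]] <- TRUE
  binaryMask3D(vox, voxelSize = rep(voxelSize, 3))
}

#' Solid sphere phantom
#'
#' @param radius Sphere radius, mm.
#' @param voxelSize Isotropic voxel edge, mm.
#' @param margin Background padding in voxels.
#' @return A [binaryMask3D()].
#' @export
sphereMask <- function(radius = 10, voxelSize = 1, margin = 2) {
  rv <- radius / voxelSize
  side <- ceiling(2 * rv) + 2 * margin + 1
  dims <- rep(side, 3)
  idx <- phantomGrid(dims)
  c0 <- dims / 2
  keep <- rowSums(sweep(idx - 0.5, 2, c0)^2) <= rv^2
  vox <- array(FALSE, dims)
  vox[idx[keep, , drop = FALSE]] <- TRUE
  binaryMask3D(vox, voxelSize = rep(voxelSize, 3))
}

#' Bent tube phantom
#'
#' Constant-radius tube around a sinusoidally bent centreline along the
#' z axis; its medial curve should track the bend, and its radial distances
#' stay close to `radius`.
#'
#' @param radius Tube radius, mm.
#' @param length Tube length along z, mm.
#' @param bend Peak lateral deflection of the centreline, mm.
#' @param voxelSize Isotropic voxel edge, mm.
#' @param margin Background padding in voxels.
#' @return A [binaryMask3D()] with the generating centreline (mm) attached
#'   as attribute `"centreline"`.
#' @export
bentTubeMask <- function(radius = 4, length = 50, bend = 8, voxelSize = 1,
                         margin = 2) {
  rv <- radius / voxelSize
  lv <- round(length / voxelSize)
  nx <- ceiling(2 * rv + bend / voxelSize) + 2 * margin + 1
  ny <- ceiling(2 * rv) + 2 * margin + 1
  dims <- c(nx, ny, lv + 2 * margin)
  ## centreline sampled every voxel along z
  zc <- seq(margin + 0.5, margin + lv - 0.5, by = 1)
  xc <- margin + rv + 0.5 + (bend / voxelSize) *
    sin(pi * (zc - zc[1]) / (zc[length(zc)] - zc[1]))
  yc <- rep(ny / 2, length(zc))
  line <- cbind(xc, yc, zc) * voxelSize
  idx <- phantomGrid(dims)
  pts <- (idx - 0.5) * voxelSize
  keep <- rep(FALSE, nrow(pts))
  zIdx <- idx[, 3]
  inZ <- zIdx > margin & zIdx <= margin + lv
  seg <- pmin(pmax(zIdx - margin, 1), length(zc))  # nearest centreline sample
  dd <- sqrt((pts[, 1] - line[seg, 1])^2 + (pts[, 2] - line[seg, 2])^2)
  keep <- inZ & dd <= radius
  vox <- array(FALSE, dims)
  vox[idx[keep, , drop = FALSE]] <- TRUE
  m <- binaryMask3D(vox, voxelSize = rep(voxelSize, 3))
  attr(m, "centreline") <- line
  m
}
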