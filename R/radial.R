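## Radial morphometry of 3D binary masks: a medial curve traced by the
## per-slice boundary centroids, and the 3D distance from every surface
## point to that curve.  Surfaces are voxel-based (6-connectivity); 2D
## slice boundaries use 4-connectivity, so counts are reproducible.

## Logical 3-d array -> n x 3 matrix of foreground voxel indices.
fgIndices <- function(vox) which(vox, arr.ind = TRUE)

## Voxel index -> physical mm coordinate of the voxel centre.
voxelCentres <- function(idx, voxelSize)
  sweep(idx - 0.5, 2, voxelSize, `*`)

## Count of foreground 6-neighbours for every voxel (edge = background).
neighbourCount6 <- function(vox) {
  d <- dim(vox)
  p <- array(FALSE, d + 2)
  p[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- vox
  cnt <- array(0L, d)
  shifts <- list(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0),
                 c(0, 1, 0), c(0, 0, -1), c(0, 0, 1))
  for (s in shifts) {
    i <- (2 + s[1]):(d[1] + 1 + s[1])
    j <- (2 + s[2]):(d[2] + 1 + s[2])
    k <- (2 + s[3]):(d[3] + 1 + s[3])
    cnt <- cnt + p[i, j, k]
  }
  cnt
}

## Number of 6-connected foreground components (flood fill).
countComponents6 <- function(vox) {
  d <- dim(vox)
  if (!any(vox)) return(0L)
  comp <- 0L
  remaining <- vox
  while (any(remaining)) {
    comp <- comp + 1L
    seed <- which(remaining)[1]
    frontier <- seed
    remaining[seed] <- FALSE
    while (length(frontier)) {
      ar <- arrayInd(frontier, d)
      nxt <- integer(0)
      for (s in list(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0),
                     c(0, 1, 0), c(0, 0, -1), c(0, 0, 1))) {
        nb <- sweep(ar, 2, s, `+`)
        ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 &
          nb[, 2] <= d[2] & nb[, 3] >= 1 & nb[, 3] <= d[3]
        if (!any(ok)) next
        lin <- nb[ok, 1] + d[1] * (nb[ok, 2] - 1) + d[1] * d[2] * (nb[ok, 3] - 1)
        hit <- lin[remaining[lin]]
        if (length(hit)) {
          remaining[hit] <- FALSE
          nxt <- c(nxt, hit)
        }
      }
      frontier <- unique(nxt)
    }
  }
  comp
}

## Default slicing axis: the grid axis most aligned with the longest
## principal axis of the foreground point cloud (the structure of interest
## is elongated; the acquisition slice plane is scanner-dependent, so the
## intrinsic axis is used instead).
principalAxis <- function(mask) {
  pts <- voxelCentres(fgIndices(mask@voxels), mask@voxelSize)
  if (nrow(pts) < 2) return(3L)
  pc <- stats::prcomp(pts, center = TRUE, scale. = FALSE)
  which.max(abs(pc$rotation[, 1]))
}

#' Medial curve of a 3D mask from per-slice boundary centroids
#'
#' For every slice (along the chosen axis) that contains foreground, takes
#' the centroid of that slice's 2D boundary pixels (foreground pixels with a
#' background 4-neighbour within the slice; slice edges count as
#' background), in mm coordinates, ordered by slice index.
#'
#' @param mask A [binaryMask3D()].
#' @param axis Slicing axis 1-3; default: the grid axis closest to the
#'   longest principal axis of the foreground.
#' @return Matrix of ordered 3D centroids (one row per occupied slice), mm;
#'   the slicing axis is attached as attribute `"axis"`.
#' @export
medialCurve <- function(mask, axis = NULL) {
  stopifnot(is(mask, "BinaryMask3D"))
  vox <- mask@voxels
  if (!any(vox)) stop("empty mask")
  if (is.null(axis)) axis <- principalAxis(mask)
  axis <- as.integer(axis)
  stopifnot(axis %in% 1:3)
  d <- dim(vox)
  other <- setdiff(1:3, axis)
  pts <- matrix(NA_real_, 0, 3)
  for (s in seq_len(d[axis])) {
    sl <- switch(axis, vox[s, , ], vox[, s, ], vox[, , s])
    if (!any(sl)) next
    ds <- dim(sl)
    p <- matrix(FALSE, ds[1] + 2, ds[2] + 2)
    p[2:(ds[1] + 1), 2:(ds[2] + 1)] <- sl
    interior <- sl &
      p[1:ds[1], 2:(ds[2] + 1)] & p[3:(ds[1] + 2), 2:(ds[2] + 1)] &
      p[2:(ds[1] + 1), 1:ds[2]] & p[2:(ds[1] + 1), 3:(ds[2] + 2)]
    bd <- sl & !interior
    ij <- which(bd, arr.ind = TRUE)
    cen3 <- numeric(3)
    cen3[axis] <- s
    cen3[other] <- colMeans(ij)
    pts <- rbind(pts, (cen3 - 0.5) * mask@voxelSize)
  }
  attr(pts, "axis") <- axis
  pts
}

#' Surface (boundary) points of a 3D mask
#'
#' Foreground voxels having at least one background 6-neighbour (grid edges
#' count as background), converted to mm voxel-centre coordinates.
#'
#' @param mask A [binaryMask3D()].
#' @return Matrix of boundary point coordinates (points x 3), mm.
#' @export
boundaryPoints <- function(mask) {
  stopifnot(is(mask, "BinaryMask3D"))
  vox <- mask@voxels
  if (!any(vox)) stop("empty mask")
  bd <- vox & (neighbourCount6(vox) < 6L)
  voxelCentres(fgIndices(bd), mask@voxelSize)
}

#' Radial distances from surface points to the medial curve
#'
#' Euclidean distance from every boundary point to the nearest point of the
#' piecewise-linear medial curve (distance to the polyline's segments, not
#' just its vertices, which damps slice-discretization artifacts).
#'
#' @param boundary Points x 3 matrix (mm), e.g. from [boundaryPoints()].
#' @param curve Ordered medial points (mm), e.g. from [medialCurve()].
#' @return List with `distances` (one value per boundary point, mm),
#'   `meanDistance`, and `flags` (contains `"degenerate-curve"` when the
#'   curve collapses to a single point).
#' @export
radialDistances <- function(boundary, curve) {
  boundary <- as.matrix(boundary)
  curve <- as.matrix(curve)
  if (!nrow(boundary) || !nrow(curve))
    stop("boundary and curve must be non-empty")
  flags <- character()
  if (nrow(curve) == 1) {
    flags <- "degenerate-curve"
    d <- sqrt(rowSums(sweep(boundary, 2, curve[1, ])^2))
  } else {
    d <- rep(Inf, nrow(boundary))
    for (s in seq_len(nrow(curve) - 1)) {
      a <- curve[s, ]
      ab <- curve[s + 1, ] - a
      l2 <- sum(ab^2)
      rel <- sweep(boundary, 2, a)
      tpar <- if (l2 == 0) rep(0, nrow(boundary))
              else pmin(1, pmax(0, as.vector(rel %*% ab) / l2))
      diff <- rel - tpar %o% ab
      d <- pmin(d, sqrt(rowSums(diff^2)))
    }
  }
  list(distances = d, meanDistance = mean(d), flags = flags)
}

#' Full radial profile of a segmentation mask
#'
#' Runs [medialCurve()], [boundaryPoints()] and [radialDistances()] and adds
#' the exact voxel-count volume.
#'
#' @param mask A [binaryMask3D()].
#' @param axis Optional slicing axis override (see [medialCurve()]).
#' @return A `RadialProfile`.
#' @examples
#' pr <- radialProfile(cylinderMask(radius = 5, length = 30))
#' meanRadialDistance(pr)
#' @export
radialProfile <- function(mask, axis = NULL) {
  curve <- medialCurve(mask, axis = axis)
  bd <- boundaryPoints(mask)
  rd <- radialDistances(bd, curve)
  new("RadialProfile", medialCurve = curve, boundaryPoints = bd,
      radialDistances = rd$distances, meanRadialDistance = rd$meanDistance,
      volume = sum(mask@voxels) * prod(mask@voxelSize), flags = rd$flags)
}

setMethod("maskVolume", "BinaryMask3D", function(object)
  sum(object@voxels) * prod(object@voxelSize))
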