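test_that("cylinder centroids sit on the cylinder axis", {
  m <- cylinderMask(radius = 5, length = 30)
  cur <- medialCurve(m)
  ## in-plane coordinates constant and central within half a voxel
  expect_lt(max(abs(cur[, 1] - mean(cur[, 1]))), 0.5)
  expect_lt(max(abs(cur[, 2] - mean(cur[, 2]))), 0.5)
  expect_identical(nrow(cur), 30L)   # one centroid per occupied slice
})

test_that("a single-slice disk yields one centroid at the disk centre", {
  vox <- array(FALSE, c(11, 11, 3))
  for (i in 1:11) for (j in 1:11)
    if ((i - 6)^2 + (j - 6)^2 <= 16) vox[i, j, 2] <- TRUE
  m <- binaryMask3D(vox)
  cur <- medialCurve(m, axis = 3)
  expect_identical(nrow(cur), 1L)
  expect_equal(cur[1, 1:2], c(5.5, 5.5), ignore_attr = TRUE)
})

test_that("boundary extraction matches brute-force 6-neighbour counting", {
  ## one voxel is its own boundary
  one <- array(FALSE, c(3, 3, 3)); one[2, 2, 2] <- TRUE
  expect_identical(nrow(boundaryPoints(binaryMask3D(one))), 1L)
  ## 3x3x3 solid cube: all but the centre voxel are boundary
  cube <- array(TRUE, c(3, 3, 3))
  m <- binaryMask3D(cube)
  expect_identical(nrow(boundaryPoints(m)), 26L)
  ## sphere: face-exposed voxel count ~ area times the mean maximal normal
  ## component (for a plane with unit normal n, exposed-voxel density is
  ## max|n_i| per unit area); the factor is estimated by Monte Carlo
  sp <- sphereMask(radius = 10)
  nb <- nrow(boundaryPoints(sp))
  set.seed(1)
  z <- matrix(rnorm(3 * 20000), ncol = 3)
  fac <- mean(apply(abs(z / sqrt(rowSums(z^2))), 1, max))
  expect_lt(abs(nb - fac * 4 * pi * 100) / (fac * 4 * pi * 100), 0.10)
})

test_that("volume is exactly foreground count times voxel volume", {
  sp <- sphereMask(radius = 7, voxelSize = 0.5)
  expect_equal(maskVolume(sp), sum(sp@voxels) * 0.5^3)
  expect_equal(maskVolume(radialProfile(sp)), maskVolume(sp))
})

test_that("cylinder radial distances equal the radius up to voxelization", {
  pr <- radialProfile(cylinderMask(radius = 5, length = 40))
  expect_lt(abs(meanRadialDistance(pr) - 5), sqrt(3))  # one voxel diagonal
  ## lateral-wall points individually close to the radius
  bd <- surfacePoints(pr)
  zmid <- abs(bd[, 3] - mean(bd[, 3])) < 15
  expect_lt(max(abs(radialValues(pr)[zmid] - 5)), sqrt(3))
})

test_that("a thinner cylinder has a strictly smaller mean radial distance", {
  thick <- radialProfile(cylinderMask(radius = 5, length = 40))
  thin <- radialProfile(cylinderMask(radius = 4, length = 40))
  expect_lt(meanRadialDistance(thin), meanRadialDistance(thick))
})

test_that("sphere distances match the radius near the equator, not the poles", {
  pr <- radialProfile(sphereMask(radius = 10), axis = 3)
  bd <- surfacePoints(pr)
  centreZ <- mean(medialPoints(pr)[, 3])
  nearEq <- abs(bd[, 3] - centreZ) < 2
  expect_lt(max(abs(radialValues(pr)[nearEq] - 10)), 2)
  ## polar bias: distances at the poles are far below the radius
  nearPole <- abs(bd[, 3] - centreZ) > 8
  expect_lt(mean(radialValues(pr)[nearPole]), 6)
})

test_that("doubling the voxel size doubles every distance exactly", {
  m1 <- cylinderMask(radius = 4, length = 20, voxelSize = 1)
  m2 <- binaryMask3D(m1@voxels, voxelSize = 2)
  d1 <- radialValues(radialProfile(m1, axis = 3))
  d2 <- radialValues(radialProfile(m2, axis = 3))
  expect_equal(d2, 2 * d1)
})

test_that("axis-aligned 90-degree rotation leaves the distance set unchanged", {
  m <- cylinderMask(radius = 4, length = 25, axis = 3)
  rot <- binaryMask3D(aperm(m@voxels, c(3, 1, 2)))
  d0 <- sort(radialValues(radialProfile(m, axis = 3)))
  d1 <- sort(radialValues(radialProfile(rot, axis = 1)))
  expect_equal(d1, d0)
})

test_that("the default slicing axis follows the longest principal axis", {
  m <- cylinderMask(radius = 4, length = 30, axis = 2)
  cur <- medialCurve(m)                 # no axis given
  expect_identical(attr(cur, "axis"), 2L)
})

test_that("the medial curve tracks a bent tube's generating centreline", {
  m <- bentTubeMask(radius = 4, length = 50, bend = 8)
  cur <- medialCurve(m, axis = 3)
  line <- attr(m, "centreline")
  ## compare at matching slice heights (interior slices, away from the caps)
  inner <- cur[, 3] > min(line[, 3]) + 5 & cur[, 3] < max(line[, 3]) - 5
  dev <- vapply(which(inner), function(i) {
    j <- which.min(abs(line[, 3] - cur[i, 3]))
    sqrt(sum((cur[i, 1:2] - line[j, 1:2])^2))
  }, numeric(1))
  expect_lt(max(dev), 1)                # < 1 voxel from the true centreline
  ## and the radial distances stay near the tube radius
  pr <- radialProfile(m, axis = 3)
  expect_lt(abs(meanRadialDistance(pr) - 4), sqrt(3))
})

test_that("a degenerate single-point curve is flagged, distances still defined", {
  one <- array(FALSE, c(5, 5, 5)); one[3, 3, 3] <- TRUE
  pr <- radialProfile(binaryMask3D(one), axis = 3)
  expect_true("degenerate-curve" %in% qualityFlags(pr))
  expect_equal(radialValues(pr), 0)
})

test_that("masks survive a NIfTI write/read round-trip", {
  m <- sphereMask(radius = 5, voxelSize = 0.8)
  path <- withr::local_tempfile(fileext = ".nii.gz")
  writeMaskNifti(m, path)
  back <- readMaskNifti(path)
  expect_identical(back@voxels, m@voxels)
  expect_equal(back@voxelSize, m@voxelSize, tolerance = 1e-6)
})

test_that("empty masks and multi-component masks are caught", {
  expect_error(binaryMask3D(array(FALSE, c(3, 3, 3))), "foreground")
  two <- array(FALSE, c(5, 5, 5)); two[1, 1, 1] <- TRUE; two[5, 5, 5] <- TRUE
  expect_warning(binaryMask3D(two), "connected")
})
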