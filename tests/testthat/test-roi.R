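test_that("tissueMask thresholds inclusively", {
  v <- imageVolume(array(10, c(3, 3, 3)), c(1, 1, 1))
  expect_true(all(imgData(tissueMask(v, 5))))
  expect_warning(m <- tissueMask(v, 11), "above the intensity maximum")
  expect_false(any(imgData(m)))
  half <- array(c(rep(2, 13), rep(20, 14)), c(3, 3, 3))
  hm <- tissueMask(imageVolume(half, c(1, 1, 1)), 10)
  expect_identical(imgData(hm), half >= 10)
})

test_that("concave hull leaves convex shapes unchanged and handles degenerates", {
  m <- matrix(FALSE, 20, 20); m[5:15, 5:15] <- TRUE
  expect_identical(sliceConcaveHull(m, 8, c(1, 1)), m)
  empty <- matrix(FALSE, 10, 10)
  expect_identical(sliceConcaveHull(empty, 5, c(1, 1)), empty)
  two <- matrix(FALSE, 10, 10); two[3, 3] <- TRUE; two[8, 8] <- TRUE
  expect_identical(sliceConcaveHull(two, 5, c(1, 1)), two)
})

test_that("alpha controls whether a U-shaped mouth is bridged", {
  # U shape: walls and floor 4 px wide, mouth 12 px wide
  m <- matrix(FALSE, 30, 30)
  m[5:25, 5:8] <- TRUE    # left wall
  m[5:25, 20:23] <- TRUE  # right wall
  m[22:25, 5:23] <- TRUE  # floor
  cavity <- c(10, 14)      # a point inside the U cavity
  big <- sliceConcaveHull(m, 12, c(1, 1))
  expect_true(big[cavity[1], cavity[2]]) # mouth bridged, cavity filled
  small <- sliceConcaveHull(m, 2, c(1, 1))
  expect_false(small[cavity[1], cavity[2]]) # mouth stays open
  expect_true(all(m[small] | !m[small])) # superset property
  expect_true(all(small[m]))
  expect_true(all(big[m]))
})

test_that("hull is idempotent and converges to the convex hull for large alpha", {
  set.seed(42)
  m <- matrix(FALSE, 26, 26)
  pts <- cbind(sample(4:23, 12, TRUE), sample(4:23, 12, TRUE))
  m[pts] <- TRUE
  h1 <- sliceConcaveHull(m, 7, c(1, 1))
  expect_identical(sliceConcaveHull(h1, 7, c(1, 1)), h1)
  # convex limit: compare against grDevices::chull rasterization
  hBig <- sliceConcaveHull(m, 500, c(1, 1))
  ch <- grDevices::chull(pts)
  poly <- pts[ch, , drop = FALSE]
  inHull <- function(p) {
    k <- nrow(poly); s <- 0
    for (i in seq_len(k)) {
      a <- poly[i, ]; b <- poly[(i %% k) + 1, ]
      cr <- (b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1])
      if (abs(cr) < 1e-9) next
      if (s == 0) s <- sign(cr)
      else if (sign(cr) != s) return(FALSE)
    }
    TRUE
  }
  grid <- as.matrix(expand.grid(1:26, 1:26))
  expected <- matrix(apply(grid, 1, inHull), 26, 26)
  agreement <- mean(hBig == expected)
  expect_gt(agreement, 0.97) # rasterization differs only at boundary pixels
})

test_that("erosion matches the brute-force Minkowski oracle exactly", {
  sp <- c(1, 1, 1)
  d <- c(21L, 21L, 21L)
  ball <- ballMask(d, sp, 8.2)
  got <- innerVolume(voxelMask(ball, sp), 3.6)
  expect_identical(imgData(got), oracleErode(ball, 3.6, sp))
  # anisotropic case
  sp2 <- c(2, 1, 1)
  d2 <- c(11L, 21L, 21L)
  ball2 <- ballMask(d2, sp2, 7.3)
  got2 <- innerVolume(voxelMask(ball2, sp2), 3.1)
  expect_identical(imgData(got2), oracleErode(ball2, 3.1, sp2))
})

test_that("erosion is monotone, subset-preserving, and identity at radius 0", {
  sp <- c(1, 1, 1)
  ball <- voxelMask(ballMask(c(25L, 25L, 25L), sp, 10.2), sp)
  expect_identical(imgData(innerVolume(ball, 0)), imgData(ball))
  e4 <- innerVolume(ball, 4.1)
  e6 <- innerVolume(ball, 6.1)
  expect_true(all(imgData(e6) <= imgData(e4)))
  expect_true(all(imgData(e4) <= imgData(ball)))
  # digital ball eroded by ~4 um: between balls of radius 5 and 6 (half-voxel slack)
  inner <- ballMask(c(25L, 25L, 25L), sp, 5)
  outer <- ballMask(c(25L, 25L, 25L), sp, 6.6)
  eros <- imgData(innerVolume(ball, 4.1))
  expect_true(all(eros[inner]))
  expect_true(all(outer[eros]))
})

test_that("erosion deeper than half-thickness empties a thin slab with warning", {
  m <- array(FALSE, c(9, 9, 9)); m[4:6, , ] <- TRUE
  expect_warning(out <- innerVolume(voxelMask(m, c(1, 1, 1)), 4),
                 "removed the entire mask")
  expect_false(any(imgData(out)))
})

test_that("roiMask composes threshold, slice hull and erosion", {
  # bright tissue block with a dark notch that the hull bridges
  v <- array(0, c(9, 40, 40))
  v[, 8:32, 8:32] <- 100
  v[, 15:25, 8:20] <- 0 # notch
  vol <- imageVolume(v, c(1, 1, 1))
  out <- roiMask(vol, roiParams(alpha = 20, erosionRadius = 2,
                                tissueThreshold = 50))
  expect_true(imgData(out)[5, 20, 15]) # inside bridged+eroded interior
  expect_false(imgData(out)[5, 9, 9])  # boundary eroded away
  expect_false(any(imgData(out)[1, , ])) # end slices eroded in z
})
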