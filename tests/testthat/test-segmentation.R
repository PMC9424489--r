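test_that("hysteresis boundary conventions are inclusive", {
  v <- imageVolume(array(5, c(3, 3, 3)), c(1, 1, 1))
  expect_true(all(imgData(hysteresisThreshold(v, 5, 5))))
  zeros <- imageVolume(array(0, c(3, 3, 3)), c(1, 1, 1))
  expect_false(any(imgData(hysteresisThreshold(zeros, 1, 1))))
  expect_error(hysteresisThreshold(v, 6, 5), "low must be <= high")
})

test_that("weak voxels survive only when connected to a strong voxel", {
  line <- function(vals) imageVolume(array(vals, c(5, 1, 1)), c(1, 1, 1))
  m1 <- imgData(hysteresisThreshold(line(c(1, 5, 1, 9, 1)), 4, 8, 6))
  expect_identical(which(m1), 4L)
  m2 <- imgData(hysteresisThreshold(line(c(1, 5, 9, 1, 1)), 4, 8, 6))
  expect_identical(which(m2), c(2L, 3L))
})

test_that("hysteresis equals the flood-fill oracle and is monotone in limits", {
  set.seed(7)
  for (rep in 1:12) {
    vals <- array(sample(0:12, 8 * 7 * 6, TRUE), c(8, 7, 6))
    vol <- imageVolume(vals, c(1, 1, 1))
    low <- sample(2:6, 1); high <- low + sample(0:4, 1)
    conn <- sample(c(6L, 18L, 26L), 1)
    got <- imgData(hysteresisThreshold(vol, low, high, conn))
    expect_identical(got, oracleHysteresis(vals, low, high, conn))
    # sandwich: high-mask subset of result subset of low-mask
    expect_true(all(got[vals >= high]))
    expect_true(all(vals[got] >= low))
    # monotonicity: raising either limit never adds foreground
    up1 <- imgData(hysteresisThreshold(vol, low + 1, high + 1, conn))
    expect_true(all(up1 <= got))
  }
})

test_that("every hysteresis component contains a strong voxel", {
  set.seed(11)
  vals <- array(sample(0:10, 10^3, TRUE), c(10, 10, 10))
  vol <- imageVolume(vals, c(1, 1, 1))
  got <- hysteresisThreshold(vol, 3, 8, 26)
  lab <- labelComponents(got, 26)
  k <- length(componentSizes(lab))
  if (k > 0) {
    strongLab <- unique(componentLabels(lab)[vals >= 8])
    expect_setequal(setdiff(strongLab, 0L), seq_len(k))
  }
})

test_that("connectivity distinguishes corner-touching voxels", {
  m <- array(FALSE, c(2, 2, 2)); m[1, 1, 1] <- TRUE; m[2, 2, 2] <- TRUE
  mk <- voxelMask(m, c(1, 1, 1))
  expect_length(componentSizes(labelComponents(mk, 26)), 1L)
  expect_length(componentSizes(labelComponents(mk, 6)), 2L)
  full <- voxelMask(array(TRUE, c(3, 3, 3)), c(1, 1, 1))
  expect_length(componentSizes(labelComponents(full, 6)), 1L)
  none <- voxelMask(array(FALSE, c(3, 3, 3)), c(1, 1, 1))
  expect_length(componentSizes(labelComponents(none, 26)), 0L)
})

test_that("labels are ordered by lexicographically smallest member voxel", {
  m <- array(FALSE, c(5, 5, 5))
  m[4, 4, 4] <- TRUE  # later in (z,y,x) order
  m[2, 1, 5] <- TRUE  # z=2 comes first
  lab <- labelComponents(voxelMask(m, c(1, 1, 1)), 6)
  expect_equal(componentLabels(lab)[2, 1, 5], 1L)
  expect_equal(componentLabels(lab)[4, 4, 4], 2L)
})

test_that("component filtering respects size, exclusions and conservation", {
  m <- array(FALSE, c(10, 10, 10))
  m[1:3, 1, 1] <- TRUE            # size 3
  m[6:10, 5, 5] <- TRUE; m[6:10, 6, 5] <- TRUE # size 10
  lab <- labelComponents(voxelMask(m, c(1, 1, 1)), 26)
  kept <- filterComponents(lab, minSize = 5)
  expect_equal(sum(imgData(kept)), 10)
  # excluding the largest keeps the rest
  sizes <- componentSizes(lab)
  biggest <- which.max(sizes)
  kept2 <- filterComponents(lab, minSize = 1, excludedLabels = biggest)
  expect_equal(sum(imgData(kept2)), sum(sizes[-biggest]))
  expect_warning(filterComponents(lab, minSize = 1, excludedLabels = 99L),
                 "not present")
  expect_warning(out <- filterComponents(lab, minSize = 100),
                 "mask is empty")
  expect_false(any(imgData(out)))
})

test_that("retained voxel count equals the sum of retained component sizes", {
  set.seed(5)
  for (rep in 1:20) {
    m <- array(runif(9 * 9 * 9) < 0.25, c(9, 9, 9))
    lab <- labelComponents(voxelMask(m, c(1, 1, 1)), sample(c(6L, 26L), 1))
    minSize <- sample(1:4, 1)
    sizes <- componentSizes(lab)
    excl <- if (length(sizes) && runif(1) < 0.5)
      sample(seq_along(sizes), 1) else integer()
    out <- suppressWarnings(filterComponents(lab, minSize, excl))
    retained <- setdiff(which(sizes >= minSize), excl)
    expect_equal(sum(imgData(out)), sum(sizes[retained]))
  }
})

test_that("component report carries sizes and physical centroids", {
  m <- array(FALSE, c(5, 5, 5)); m[2, 3, 4] <- TRUE
  lab <- labelComponents(voxelMask(m, c(2, 1, 1)), 26)
  tab <- componentTable(lab)
  expect_equal(tab$size_voxels, 1L)
  expect_equal(tab$centroid_z_um, (2 - 1) * 2)
  expect_equal(tab$centroid_y_um, 2)
  expect_equal(tab$centroid_x_um, 3)
  expect_equal(nrow(componentTable(labelComponents(
    voxelMask(array(FALSE, c(3, 3, 3)), c(1, 1, 1)), 26))), 0L)
})

test_that("automatic limits follow the mean + k SD rule", {
  set.seed(3)
  vals <- array(round(rnorm(4000, 50, 5)), c(10, 20, 20))
  vals[vals < 0] <- 0
  vol <- imageVolume(vals, c(1, 1, 1))
  thr <- suggestThresholds(vol)
  expect_equal(unname(thr["low"]), mean(vals) + 2 * sd(vals))
  expect_equal(unname(thr["high"]), mean(vals) + 4 * sd(vals))
})
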