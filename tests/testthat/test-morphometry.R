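test_that("a straight constant-radius edge gives closed-form features", {
  g <- LymphNetQuant:::demoStraightGraph(length_um = 10, radius_um = 2)
  fe <- extractFeatures(g, "demo")
  expect_equal(fe$length_um, 10)
  expect_equal(fe$avg_cross_section_um2, pi * 4)
  expect_equal(fe$volume_id, "demo")
})

test_that("arc length respects anisotropic spacing", {
  # path of 10 inter-voxel steps along z at dz = 2 um
  m <- array(FALSE, c(11, 3, 3)); m[1:11, 2, 2] <- TRUE
  g <- buildGraph(skeletonize(voxelMask(m, c(2, 1, 1))))
  expect_equal(edges(g)$length_um, 20)
})

test_that("interior-point averaging excludes inflated junction radii", {
  nodeDf <- data.frame(id = 1:2, kind = "endpoint", z = c(0, 4), y = 0,
                       x = 0, radius = 5)
  edgeList <- list(list(from = 1L, to = 2L,
                        poly = cbind(0:4, 0, 0),
                        radii = c(5, 2, 2, 2, 5)))
  g <- LymphNetQuant:::makeVesselGraph(nodeDf, edgeList, voxelSpacing(1, 1, 1))
  fe <- extractFeatures(g)
  expect_equal(fe$avg_cross_section_um2, pi * 4) # endpoints dropped
  # with only two points, both are used
  edgeList2 <- list(list(from = 1L, to = 2L, poly = cbind(c(0, 4), 0, 0),
                         radii = c(3, 1)))
  g2 <- LymphNetQuant:::makeVesselGraph(nodeDf, edgeList2, voxelSpacing(1, 1, 1))
  expect_equal(extractFeatures(g2)$avg_cross_section_um2, mean(pi * c(9, 1)))
})

test_that("full-pipeline area recovery on a rendered cylinder is accurate", {
  ph <- generatePhantom(tubeSpec(radius = 4))
  q <- quantifyVolume(ph$volume, segmentationParams(low = 100, high = 100,
                                                    minSize = 10))
  expect_equal(nrow(q$features), 1L)
  expect_lt(abs(q$features$avg_cross_section_um2 - pi * 16) / (pi * 16), 0.15)
})

test_that("per-volume aggregation reports the standard summaries", {
  r1 <- data.frame(volume_id = "a", edge_id = 1L, length_um = 10,
                   avg_cross_section_um2 = 3, n_points = 5L)
  expect_equal(aggregatePerVolume(r1)$mean_length_um, 10)
  r2 <- data.frame(volume_id = "a", edge_id = 1:2, length_um = c(10, 30),
                   avg_cross_section_um2 = c(3, 5), n_points = 5L)
  agg <- aggregatePerVolume(r2)
  expect_equal(agg$mean_length_um, 20)
  expect_equal(agg$median_length_um, 20)
  expect_equal(agg$total_length_um, 40)
  two <- rbind(r2, transform(r1, volume_id = "b"))
  agg2 <- aggregatePerVolume(two, branchCounts = c(a = 4L, b = 1L))
  expect_equal(agg2$volume_id, c("a", "b"))
  expect_equal(agg2$n_branchpoints, c(4L, 1L))
  expect_equal(nrow(aggregatePerVolume(r1[0, ])), 0L)
})

test_that("feature totals reconcile with the graph accounting", {
  ph <- generatePhantom(smallSpec(seed = 13L), render = FALSE)
  g <- truthGraph(ph$truth)
  fe <- extractFeatures(g, "v")
  expect_equal(sum(fe$length_um), totalNetworkLength(g))
})

test_that("features are invariant under translation and edge relabeling", {
  ph <- generatePhantom(smallSpec(seed = 4L), render = FALSE)
  m <- renderTruthMask(ph$truth, c(120L, 110L, 110L), c(2, 2, 2))
  q1 <- refineGraph(buildGraph(skeletonize(m)))
  f1 <- extractFeatures(q1, "v")
  v <- imgData(m)
  vt <- array(FALSE, dim(v)); vt[2:120, 3:110, 2:110] <- v[1:119, 1:108, 1:109]
  q2 <- refineGraph(buildGraph(skeletonize(voxelMask(vt, c(2, 2, 2)))))
  f2 <- extractFeatures(q2, "v")
  expect_equal(sort(f2$length_um), sort(f1$length_um), tolerance = 1e-8)
  expect_equal(sort(f2$avg_cross_section_um2),
               sort(f1$avg_cross_section_um2), tolerance = 1e-8)
  # relabeling edge ids leaves the feature multiset unchanged by construction
  perm <- sample(nrow(f1))
  expect_equal(sort(f1$length_um[perm]), sort(f1$length_um))
})
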