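straightPathGraph <- function(n = 10) {
  m <- array(FALSE, c(n + 2L, 3L, 3L))
  m[2:(n + 1), 2, 2] <- TRUE
  buildGraph(skeletonize(voxelMask(m, c(1, 1, 1))))
}

yMask <- function(armShort = 3L) {
  m <- array(FALSE, c(15, 15, 3))
  m[1:15, 8, 2] <- TRUE            # long bar
  m[8, 9:(8 + armShort), 2] <- TRUE # short arm
  voxelMask(m, c(1, 1, 1))
}

test_that("a straight voxel path becomes one edge between two endpoints", {
  g <- straightPathGraph(10)
  expect_equal(nrow(nodes(g)), 2L)
  expect_equal(nrow(edges(g)), 1L)
  expect_setequal(nodes(g)$kind, "endpoint")
  expect_equal(edges(g)$length_um, 9)
})

test_that("neighbour-count classification matches the explicit oracle on a Y", {
  g <- buildGraph(skeletonize(yMask(4L)))
  # oracle: arms of 26-neighbour count 1 are endpoints, the meeting voxel
  # has three neighbours
  expect_equal(endpointCount(g), 3L)
  expect_equal(branchpointCount(g), 1L)
  expect_equal(nrow(edges(g)), 3L)
  bp <- nodes(g)[nodes(g)$kind == "branchpoint", ]
  # junction near voxel (8,8), i.e. (7,7) um; the branch blob spans a voxel
  expect_lt(max(abs(c(bp$z, bp$y) - c(7, 7))), 1.5)
})

test_that("empty skeleton yields an empty graph", {
  sk <- skeletonize(voxelMask(array(FALSE, c(4, 4, 4)), c(1, 1, 1)))
  g <- buildGraph(sk)
  expect_equal(nrow(nodes(g)), 0L)
  expect_equal(nrow(edges(g)), 0L)
  expect_identical(refineGraph(g), g)
})

test_that("polyline ends coincide with node coordinates everywhere", {
  ph <- generatePhantom(smallSpec(seed = 21L), render = FALSE)
  g <- truthGraph(ph$truth)
  expect_true(validObject(g))
  q <- buildGraph(skeletonize(renderTruthMask(ph$truth, c(120L, 110L, 110L),
                                              c(2, 2, 2))))
  expect_true(validObject(q))
})

test_that("refinement is a no-op on graphs already at fixpoint", {
  g <- straightPathGraph(20)
  r <- refineGraph(g, refineParams(spurLength = 5, nodeMergeRadius = 3))
  expect_equal(totalNetworkLength(r), totalNetworkLength(g))
  expect_equal(nrow(edges(r)), nrow(edges(g)))
})

test_that("a short Y arm is pruned and the remaining chain fused", {
  g <- buildGraph(skeletonize(yMask(2L))) # arm of ~2 um
  r <- refineGraph(g, refineParams(spurLength = 5))
  expect_equal(nrow(edges(r)), 1L)
  expect_equal(branchpointCount(r), 0L)
  expect_equal(endpointCount(r), 2L)
  # fused chain passes through the former junction centroid: length is the
  # 14 um bar give or take the sub-voxel node placement
  expect_equal(r@edges$length_um, 14, tolerance = 0.1)
})

test_that("the last edge of a component survives pruning", {
  m <- array(FALSE, c(4, 3, 3)); m[2:3, 2, 2] <- TRUE
  g <- buildGraph(skeletonize(voxelMask(m, c(1, 1, 1))))
  expect_equal(nrow(edges(g)), 1L)
  expect_lt(edges(g)$length_um, 5)
  r <- refineGraph(g, refineParams(spurLength = 5))
  expect_equal(nrow(edges(r)), 1L)
})

test_that("close branchpoints are merged into one junction", {
  # H-shape: two crossbars 2 um apart -> two degree-3 nodes joined by a
  # short edge, merged under a 5 um radius
  m <- array(FALSE, c(21, 9, 3))
  m[1:21, 5, 2] <- TRUE
  m[10, 1:5, 2] <- TRUE
  m[12, 5:9, 2] <- TRUE
  g <- buildGraph(skeletonize(voxelMask(m, c(1, 1, 1))))
  expect_equal(branchpointCount(g), 2L)
  r <- refineGraph(g, refineParams(spurLength = 0.5, nodeMergeRadius = 5))
  expect_equal(branchpointCount(r), 1L)
  bp <- nodes(r)[nodes(r)$kind == "branchpoint", ]
  deg <- sum(edges(r)$from == bp$id) + sum(edges(r)$to == bp$id)
  expect_gte(deg, 4L)
})

test_that("refinement is idempotent and never increases the edge count", {
  params <- refineParams(spurLength = 8, nodeMergeRadius = 4)
  for (seed in 1:100) {
    g <- randomVesselGraph(seed, n = sample(5:14, 1))
    r1 <- refineGraph(g, params)
    expect_lte(nrow(edges(r1)), nrow(edges(g)))
    r2 <- refineGraph(r1, params)
    expect_equal(r2@nodes, r1@nodes)
    expect_equal(r2@edges, r1@edges)
    expect_equal(r2@polylines, r1@polylines)
  }
})

test_that("refined graphs satisfy the degree invariants", {
  for (seed in c(2, 17, 33)) {
    ph <- generatePhantom(smallSpec(seed = seed))
    q <- quantifyVolume(ph$volume, segmentationParams(minSize = 300))
    nd <- nodes(q$graph); ed <- edges(q$graph)
    deg <- tabulate(c(ed$from, ed$to), nrow(nd))
    selfLoops <- tabulate(ed$from[ed$from == ed$to], nrow(nd))
    expect_true(all(deg[nd$kind == "endpoint"] == 1L))
    # branchpoints have degree >= 3, except anchors of pure cycles
    bpdeg <- deg[nd$kind == "branchpoint"]
    bploop <- selfLoops[nd$kind == "branchpoint"]
    expect_true(all(bpdeg >= 3L | bploop > 0L))
  }
})

test_that("total length is invariant under translation and axis permutation", {
  ph <- generatePhantom(smallSpec(seed = 8L), render = FALSE)
  m <- renderTruthMask(ph$truth, c(120L, 110L, 110L), c(2, 2, 2))
  len0 <- totalNetworkLength(refineGraph(buildGraph(skeletonize(m))))
  # translation by whole voxels
  v <- imgData(m)
  vt <- array(FALSE, dim(v))
  vt[3:120, 2:110, 1:110] <- v[1:118, 1:109, 1:110]
  lent <- totalNetworkLength(refineGraph(buildGraph(skeletonize(
    voxelMask(vt, c(2, 2, 2))))))
  expect_equal(lent, len0, tolerance = 1e-8)
  # axis permutation with matching spacing permutation
  vp <- aperm(v, c(2, 3, 1))
  lenp <- totalNetworkLength(refineGraph(buildGraph(skeletonize(
    voxelMask(vp, c(2, 2, 2))))))
  # directional subiteration order makes permutation near- but not
  # bit-invariant
  expect_lt(abs(lenp - len0) / len0, 0.05)
})

test_that("graphs round-trip losslessly through JSON and GraphML", {
  g <- refineGraph(buildGraph(skeletonize(yMask(4L))))
  fj <- tempfile(fileext = ".json")
  writeGraph(g, fj)
  gj <- readGraph(fj)
  expect_equal(gj@nodes, g@nodes)
  expect_equal(gj@edges, g@edges)
  expect_equal(gj@polylines, g@polylines, tolerance = 1e-12)
  fg <- tempfile(fileext = ".graphml")
  writeGraph(g, fg)
  gg <- readGraph(fg)
  expect_equal(nrow(nodes(gg)), nrow(nodes(g)))
  expect_equal(sort(edges(gg)$length_um), sort(edges(g)$length_um),
               tolerance = 1e-6)
  # empty graph round trip
  e <- LymphNetQuant:::emptyVesselGraph(voxelSpacing(2, 2, 2))
  fe <- tempfile(fileext = ".json")
  writeGraph(e, fe)
  expect_equal(nrow(nodes(readGraph(fe))), 0L)
  expect_error(readGraph(tempfile(fileext = ".json")), "no such file")
})

test_that("a large synthetic graph keeps its feature table across round trip", {
  ph <- generatePhantom(phantomSpec(seed = 5L), render = FALSE)
  g <- truthGraph(ph$truth)
  f <- tempfile(fileext = ".json")
  writeGraph(g, f)
  back <- readGraph(f)
  expect_equal(extractFeatures(back, "v"), extractFeatures(g, "v"),
               tolerance = 1e-12)
})
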