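test_that("density zero yields only the longitudinal vessels", {
  sp <- smallSpec(seed = 2L, initialDensityFactor = 0, discontinuityProb = 0)
  ph <- generatePhantom(sp, render = FALSE)
  g <- truthGraph(ph$truth)
  expect_equal(branchpointCount(g), 0L)
  expect_equal(nrow(edges(g)), 2L) # nLongitudinal
  expect_setequal(truthTubes(ph$truth)$type, "longitudinal")
})

test_that("generation is bit-identical for a fixed spec and seed", {
  sp <- smallSpec(seed = 6L)
  a <- generatePhantom(sp)
  b <- generatePhantom(sp)
  expect_identical(imgData(a$volume), imgData(b$volume))
  expect_equal(truthGraph(a$truth)@nodes, truthGraph(b$truth)@nodes)
  expect_equal(truthGraph(a$truth)@edges, truthGraph(b$truth)@edges)
})

test_that("mutantSpec copies the control except the rarefaction fields and seed", {
  ctrl <- smallSpec(seed = 9L)
  mut <- mutantSpec(ctrl, densityFactor = 1, discontinuityProb = 0)
  for (sl in setdiff(slotNames("PhantomSpec"), "seed"))
    expect_equal(slot(mut, sl), slot(ctrl, sl), info = sl)
  expect_false(mut@seed == ctrl@seed)
  mut2 <- mutantSpec(ctrl, 0.4, 0.1)
  expect_equal(mut2@initialDensityFactor, 0.4)
  expect_equal(mut2@discontinuityProb, 0.1)
  expect_error(mutantSpec(ctrl, 1.4), "densityFactor")
})

test_that("initial counts follow the declared paired-Poisson placement", {
  # rungs are opposite-side pairs at Poisson positions: the initial count is
  # 2 * Poisson(axisLength / (2 * spacing)); check its 95% interval
  sp <- phantomSpec(seed = 1L) # axis 600, spacing 30 -> lambda 10, E = 20
  counts <- vapply(1:12, function(k) {
    s <- sp; s@seed <- as.integer(100 + k)
    ph <- generatePhantom(s, render = FALSE)
    sum(truthTubes(ph$truth)$type == "initial")
  }, numeric(1))
  lam <- 600 / (2 * 30)
  lo <- 2 * qpois(0.025, lam); hi <- 2 * qpois(0.975, lam)
  expect_gte(mean(counts >= lo & counts <= hi), 10 / 12)
  expect_lt(abs(mean(counts) - 20), 6)
})

test_that("ground-truth network length shrinks monotonically with density", {
  meanLen <- vapply(c(1, 0.6, 0.3), function(dens) {
    coh <- generateCohort(smallSpec(initialDensityFactor = dens), 6,
                          seed = 400, render = FALSE)
    mean(vapply(coh, function(p) totalNetworkLength(truthGraph(p$truth)),
                numeric(1)))
  }, numeric(1))
  expect_true(all(diff(meanLen) < 0))
})

test_that("rarefied cohorts have longer ground-truth segments pairwise", {
  ctrl <- generateCohort(phantomSpec(), 8, seed = 600, render = FALSE)
  mut <- generateCohort(mutantSpec(phantomSpec(), 0.4, 0.1), 8, seed = 700,
                        render = FALSE)
  meanSeg <- function(p) mean(edges(truthGraph(p$truth))$length_um)
  wins <- sum(vapply(1:8, function(k) meanSeg(mut[[k]]) > meanSeg(ctrl[[k]]),
                     logical(1)))
  expect_gte(wins, 7)
})

test_that("noise-free rendering is recovered exactly by hysteresis", {
  sp <- smallSpec(seed = 14L, noiseSd = 0, psfSigma = 0)
  ph <- generatePhantom(sp)
  rec <- hysteresisThreshold(ph$volume, sp@signalLevel, sp@signalLevel)
  tm <- renderTruthMask(ph$truth, sp@volumeDim, sp@spacing)
  expect_identical(imgData(rec), imgData(tm))
})

test_that("noisy rendering at 10 percent of signal keeps Dice above 0.9", {
  sp <- smallSpec(seed = 15L, noiseSd = 0.1 * 200)
  ph <- generatePhantom(sp)
  q <- quantifyVolume(ph$volume, segmentationParams(minSize = 300))
  tm <- renderTruthMask(ph$truth, sp@volumeDim, sp@spacing)
  expect_gte(diceCoef(imgData(q$mask), imgData(tm)), 0.9)
})

test_that("recovered radii rank-correlate with true tube radii", {
  radii <- seq(2, 8, by = 1)
  rec <- vapply(radii, function(r) {
    dimL <- as.integer(c(50, 2 * ceiling(r) + 13, 2 * ceiling(r) + 13))
    ph <- generatePhantom(tubeSpec(radius = r, len = 30, dim = dimL,
                                   seed = 30 + r))
    q <- quantifyVolume(ph$volume,
                        segmentationParams(low = 100, high = 100,
                                           minSize = 10))
    mean(edges(q$graph)$mean_radius_um)
  }, numeric(1))
  expect_gte(cor(radii, rec, method = "spearman"), 0.8)
})

test_that("cohorts are reproducible and members distinct", {
  c1 <- generateCohort(smallSpec(), 3, seed = 50)
  c2 <- generateCohort(smallSpec(), 3, seed = 50)
  for (k in 1:3)
    expect_identical(imgData(c1[[k]]$volume), imgData(c2[[k]]$volume))
  expect_false(identical(imgData(c1[[1]]$volume), imgData(c1[[2]]$volume)))
  single <- generateCohort(smallSpec(), 1, seed = 50)
  expect_identical(imgData(single[[1]]$volume), imgData(c1[[1]]$volume))
})

test_that("infeasible geometry is rejected with the violated margin named", {
  expect_error(generatePhantom(smallSpec(axisLength = 500)), "z extent")
  expect_error(generatePhantom(smallSpec(initialLength = 120)),
               "lateral reach")
})
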