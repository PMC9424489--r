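# Independent oracles and fixture builders. Each oracle uses a different
# algorithm than the implementation it checks.

connOffsets <- function(conn) {
  o <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  o <- o[rowSums(abs(o)) > 0, , drop = FALSE]
  s <- rowSums(abs(o))
  if (conn == 6) o <- o[s == 1, , drop = FALSE]
  if (conn == 18) o <- o[s <= 2, , drop = FALSE]
  o
}

# hysteresis oracle: iterative dilation from strong voxels over weak voxels
oracleHysteresis <- function(vol, low, high, conn = 26) {
  d <- dim(vol)
  weak <- vol >= low
  fg <- vol >= high
  offs <- connOffsets(conn)
  repeat {
    idx <- which(fg)
    if (!length(idx)) break
    co <- arrayInd(idx, d)
    added <- FALSE
    for (k in seq_len(nrow(offs))) {
      nb <- sweep(co, 2, offs[k, ], "+")
      ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
        nb[, 3] >= 1 & nb[, 3] <= d[3]
      lin <- nb[ok, 1] + d[1] * (nb[ok, 2] - 1) + d[1] * d[2] * (nb[ok, 3] - 1)
      new <- lin[weak[lin] & !fg[lin]]
      if (length(new)) { fg[new] <- TRUE; added <- TRUE }
    }
    if (!added) break
  }
  array(fg, d)
}

# brute-force Minkowski erosion by the digital ellipsoid of radius r (um);
# outside the grid counts as background
oracleErode <- function(mask, r, sp) {
  d <- dim(mask)
  rng <- floor(r / sp)
  offs <- as.matrix(expand.grid(dz = -rng[1]:rng[1], dy = -rng[2]:rng[2],
                                dx = -rng[3]:rng[3]))
  dist <- sqrt((offs[, 1] * sp[1])^2 + (offs[, 2] * sp[2])^2 +
                 (offs[, 3] * sp[3])^2)
  offs <- offs[dist <= r, , drop = FALSE]
  out <- array(FALSE, d)
  idx <- which(mask)
  if (!length(idx)) return(out)
  co <- arrayInd(idx, d)
  keep <- rep(TRUE, nrow(co))
  for (k in seq_len(nrow(offs))) {
    nb <- sweep(co, 2, offs[k, ], "+")
    inside <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    lin <- nb[inside, 1] + d[1] * (nb[inside, 2] - 1) +
      d[1] * d[2] * (nb[inside, 3] - 1)
    ok <- logical(nrow(co))
    ok[inside] <- mask[lin]
    keep <- keep & ok
    if (!any(keep)) break
  }
  out[idx[keep]] <- TRUE
  out
}

# two-sided Mann-Whitney p by direct enumeration, counting greater/equal
# pairs (never touching rank sums)
oracleUTwoSided <- function(a, b) {
  vals <- c(a, b)
  N <- length(vals); n1 <- length(a)
  uOf <- function(av, bv)
    sum(outer(av, bv, ">")) + 0.5 * sum(outer(av, bv, "=="))
  u <- uOf(a, b)
  mu <- n1 * (N - n1) / 2
  picks <- combn(N, n1)
  us <- apply(picks, 2, function(ix) uOf(vals[ix], vals[-ix]))
  mean(abs(us - mu) >= abs(u - mu) - 1e-9)
}

# random spatial tree graph with 3-point polylines (valid VesselGraph)
randomVesselGraph <- function(seed, n = 10) {
  set.seed(seed)
  coords <- matrix(runif(3 * n, 0, 60), n, 3)
  edgeList <- list()
  for (i in 2:n) {
    j <- sample(seq_len(i - 1), 1)
    a <- coords[j, ]; b <- coords[i, ]
    mid <- (a + b) / 2 + runif(3, -2, 2)
    edgeList[[length(edgeList) + 1L]] <-
      list(from = j, to = i, poly = rbind(a, mid, b),
           radii = rep(runif(1, 1, 4), 3))
  }
  deg <- tabulate(unlist(lapply(edgeList, function(e) c(e$from, e$to))), n)
  nodeDf <- data.frame(id = seq_len(n),
                       kind = ifelse(deg == 1, "endpoint", "branchpoint"),
                       z = coords[, 1], y = coords[, 2], x = coords[, 3],
                       radius = runif(n, 1, 4))
  LymphNetQuant:::makeVesselGraph(nodeDf, edgeList, voxelSpacing(1, 1, 1))
}

# digital ball mask of physical radius r (um) centred in a grid
ballMask <- function(d, sp, r) {
  centre <- (d - 1) / 2 * sp
  co <- as.matrix(expand.grid(z = seq_len(d[1]), y = seq_len(d[2]),
                              x = seq_len(d[3])))
  um <- sweep(co - 1, 2, sp, "*")
  dist <- sqrt(rowSums(sweep(um, 2, centre, "-")^2))
  array(dist <= r, d)
}

# small, fast phantom spec for unit tests (reduced geometry, same model)
smallSpec <- function(seed = 1L, ...) {
  args <- list(volumeDim = c(120L, 110L, 110L), spacing = c(2, 2, 2),
               axisLength = 180, axisCurveAmplitude = 5,
               nLongitudinal = 2L, longitudinalRadius = 6,
               longitudinalOffset = 20,
               initialSpacing = 30, initialLength = 25, initialLengthSd = 5,
               tipRate = 1.5, tipLength = 14, tipLengthSd = 2,
               seed = seed)
  do.call(phantomSpec, utils::modifyList(args, list(...)))
}

# straight tube phantom for geometry tests
tubeSpec <- function(radius, spacing = c(1, 1, 1), len = 50,
                     dim = c(70L, 21L, 21L), seed = 1L, ...) {
  phantomSpec(volumeDim = dim, spacing = spacing, axisLength = len,
              axisCurveAmplitude = 0, nLongitudinal = 1L,
              longitudinalRadius = radius, longitudinalOffset = 0,
              initialDensityFactor = 0, signalLevel = 100,
              backgroundLevel = 0, noiseSd = 0, psfSigma = 0, seed = seed,
              ...)
}

diceCoef <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))
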