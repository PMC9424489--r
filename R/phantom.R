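#' Construct a phantom specification
#'
#' Declares the generative model of a synthetic hepatic-lymphatic phantom:
#' a gently curved portal-tract axis with parallel longitudinal lymph
#' vessels, perpendicular blind-ending initials attached to the longitudinal
#' vessels as opposite-side ladder rungs at Poisson axial positions, and
#' short finger-like tips ramifying from the initials. Radii taper from
#' longitudinal vessels to initials to tips. \code{initialDensityFactor}
#' rarefies both the rung rate and the ramification (the mutant-like
#' phenotype); \code{discontinuityProb} breaks longitudinal vessels with a
#' gap. Intensities are integer photon-like counts: a tube field at
#' \code{signalLevel} is blurred with a Gaussian of \code{psfSigma},
#' shifted by \code{backgroundLevel}, and Gaussian noise of sd
#' \code{noiseSd} is added and clipped at zero.
#'
#' The default geometry places a 600 um axis in a 301 x 256 x 256 grid at
#' 2 um isotropic spacing (the z extent of 600 um between first and last
#' voxel centres holds the axis exactly), two longitudinal vessels of
#' radius 6 um at 30 um offset, initials of radius 3 um and length
#' 40 +/- 10 um every 30 um on average, and tips of radius 2 um and length
#' 18 +/- 4 um at an average of 2 per initial.
#'
#' @param volumeDim integer(3) grid size (z, y, x)
#' @param spacing numeric(3) or \linkS4class{VoxelSpacing} (um)
#' @param axisLength portal-tract axis length (um)
#' @param axisCurveAmplitude lateral sinusoidal amplitude of the axis (um)
#' @param nLongitudinal number of longitudinal vessels
#' @param longitudinalRadius,longitudinalOffset radius and radial offset (um)
#' @param initialSpacing mean axial distance between initials (um)
#' @param initialLength,initialLengthSd initial length distribution (um)
#' @param initialRadius initial radius (um)
#' @param tipRate mean tips per initial at density 1
#' @param tipLength,tipLengthSd tip length distribution (um)
#' @param tipRadius tip radius (um)
#' @param initialDensityFactor density multiplier in [0, 1]; 1 = control
#' @param discontinuityProb per-vessel probability of a gap
#' @param gapLength gap length (um)
#' @param signalLevel,backgroundLevel,noiseSd intensity model (counts)
#' @param psfSigma blur scale (um)
#' @param seed integer seed; fixed seed implies a bit-identical phantom
#' @return A \linkS4class{PhantomSpec}.
#' @examples
#' phantomSpec(volumeDim = c(60, 48, 48), axisLength = 100, seed = 7)
#' @export
phantomSpec <- function(volumeDim = c(301L, 256L, 256L),
                        spacing = c(2, 2, 2),
                        axisLength = 600, axisCurveAmplitude = 8,
                        nLongitudinal = 2L,
                        longitudinalRadius = 6, longitudinalOffset = 30,
                        initialSpacing = 30,
                        initialLength = 40, initialLengthSd = 10,
                        initialRadius = 3,
                        tipRate = 2, tipLength = 18, tipLengthSd = 4,
                        tipRadius = 2,
                        initialDensityFactor = 1, discontinuityProb = 0,
                        gapLength = 30,
                        signalLevel = 200, backgroundLevel = 20,
                        noiseSd = 10, psfSigma = 0.5, seed = 1L) {
  if (!is(spacing, "VoxelSpacing")) spacing <- voxelSpacing(spacing)
  new("PhantomSpec", volumeDim = as.integer(volumeDim), spacing = spacing,
      axisLength = axisLength, axisCurveAmplitude = axisCurveAmplitude,
      nLongitudinal = as.integer(nLongitudinal),
      longitudinalRadius = longitudinalRadius,
      longitudinalOffset = longitudinalOffset,
      initialSpacing = initialSpacing, initialLength = initialLength,
      initialLengthSd = initialLengthSd, initialRadius = initialRadius,
      tipRate = tipRate, tipLength = tipLength, tipLengthSd = tipLengthSd,
      tipRadius = tipRadius, initialDensityFactor = initialDensityFactor,
      discontinuityProb = discontinuityProb, gapLength = gapLength,
      signalLevel = signalLevel, backgroundLevel = backgroundLevel,
      noiseSd = noiseSd, psfSigma = psfSigma, seed = as.integer(seed))
}

#' Derive a mutant specification from a control
#'
#' Copy of the control with the rarefaction and discontinuity parameters
#' replaced and a fresh seed stream (control seed + 500000).
#'
#' @param control a \linkS4class{PhantomSpec}
#' @param densityFactor replacement \code{initialDensityFactor} in [0, 1]
#' @param discontinuityProb replacement gap probability in [0, 1]
#' @return A \linkS4class{PhantomSpec}.
#' @examples
#' mutantSpec(phantomSpec(), densityFactor = 0.4, discontinuityProb = 0.1)
#' @export
mutantSpec <- function(control, densityFactor, discontinuityProb = 0) {
  stopifnot(is(control, "PhantomSpec"))
  if (densityFactor < 0 || densityFactor > 1)
    stop("densityFactor must lie in [0, 1]", call. = FALSE)
  if (discontinuityProb < 0 || discontinuityProb > 1)
    stop("discontinuityProb must lie in [0, 1]", call. = FALSE)
  out <- control
  out@initialDensityFactor <- densityFactor
  out@discontinuityProb <- discontinuityProb
  out@seed <- control@seed + 500000L
  validObject(out)
  out
}

# truncated normal draw (vectorized), truncation at mean +/- 3.9 sd and lo
truncNorm <- function(n, mean, sd, lo) {
  v <- rnorm(n, mean, sd)
  pmax(lo, pmin(mean + 3.9 * sd, pmax(mean - 3.9 * sd, v)))
}

# sample a polyline at ~step spacing: returns function z -> (z, y, x) samples
# The axis runs along z from z0 to z0+len with sinusoidal lateral curvature.
axisCurve <- function(z0, len, yc, xc, amp, phase) {
  function(z) {
    t <- (z - z0) / len
    cbind(z = z,
          y = yc + amp * sin(2 * pi * t + phase[1]),
          x = xc + amp * sin(2 * pi * t + phase[2]))
  }
}

#' Generate a synthetic phantom volume with exact ground truth
#'
#' Draws the network geometry from the spec's seed, builds the exact
#' ground-truth \linkS4class{VesselGraph}, and (unless \code{render =
#' FALSE}) renders the intensity volume: solid tubes at
#' \code{signalLevel}, Gaussian blur of \code{psfSigma}, plus
#' \code{backgroundLevel} and Gaussian noise, clipped at zero and rounded
#' to integer counts. Identical spec and seed give a bit-identical volume.
#'
#' @param spec a \linkS4class{PhantomSpec}
#' @param render generate the intensity volume (set \code{FALSE} to obtain
#'   only the ground truth, e.g. for fast cohort statistics)
#' @return A list with elements \code{volume} (an
#'   \linkS4class{ImageVolume}, or NULL when \code{render = FALSE}) and
#'   \code{truth} (a \linkS4class{GroundTruth}).
#' @examples
#' ph <- generatePhantom(phantomSpec(volumeDim = c(80, 64, 64),
#'                                   axisLength = 120, seed = 3),
#'                       render = FALSE)
#' ph$truth
#' @export
generatePhantom <- function(spec, render = TRUE) {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  sp <- spacingVec(spec)
  d <- spec@volumeDim
  ext <- (d - 1L) * sp
  # feasibility: the axis must fit along z, and the widest possible reach
  # (offset + initial + tip, each at truncation bound) must fit laterally
  if (spec@axisLength > ext[1] + 1e-9)
    stop("infeasible geometry: axis length ", spec@axisLength,
         " um exceeds the z extent of ", ext[1], " um", call. = FALSE)
  reach <- spec@axisCurveAmplitude + spec@longitudinalOffset +
    spec@longitudinalRadius +
    (if (spec@initialDensityFactor > 0)
      (spec@initialLength + 3.9 * spec@initialLengthSd) +
        (if (spec@tipRate > 0)
          spec@tipLength + 3.9 * spec@tipLengthSd else 0)
     else 0)
  if (reach > min(ext[2], ext[3]) / 2)
    stop("infeasible geometry: lateral reach ", round(reach, 1),
         " um exceeds the half-extent ", min(ext[2], ext[3]) / 2,
         " um; enlarge the y/x grid or shorten initials", call. = FALSE)

  step <- min(sp) / 2
  geom <- withSeed(spec@seed, {
    z0 <- (ext[1] - spec@axisLength) / 2
    phase <- runif(2, 0, 2 * pi)
    ax <- axisCurve(z0, spec@axisLength, ext[2] / 2, ext[3] / 2,
                    spec@axisCurveAmplitude, phase)
    theta0 <- runif(1, 0, 2 * pi)
    nL <- spec@nLongitudinal
    thetas <- theta0 + 2 * pi * (seq_len(nL) - 1) / nL

    # longitudinal vessel centrelines, sampled along z
    zs <- seq(z0, z0 + spec@axisLength, by = step)
    if (zs[length(zs)] < z0 + spec@axisLength)
      zs <- c(zs, z0 + spec@axisLength)
    vesselLines <- lapply(thetas, function(th) {
      base <- ax(zs)
      base[, "y"] <- base[, "y"] + spec@longitudinalOffset * sin(th)
      base[, "x"] <- base[, "x"] + spec@longitudinalOffset * cos(th)
      base
    })

    # discontinuity gaps, one decision per longitudinal vessel
    gaps <- lapply(seq_len(nL), function(j) {
      if (runif(1) < spec@discontinuityProb) {
        centre <- runif(1, 0.25, 0.75) * spec@axisLength + z0
        c(centre - spec@gapLength / 2, centre + spec@gapLength / 2)
      } else NULL
    })

    # rung pairs: Poisson count, uniform axial positions avoiding gaps
    lambda <- spec@axisLength / (2 * spec@initialSpacing) *
      spec@initialDensityFactor
    nPairs <- if (lambda > 0) rpois(1, lambda) else 0L
    margin <- 0.03 * spec@axisLength
    drawPos <- function() {
      for (k in 1:50) {
        p <- runif(1, z0 + margin, z0 + spec@axisLength - margin)
        inGap <- any(vapply(gaps, function(g)
          !is.null(g) && p > g[1] - margin && p < g[2] + margin, logical(1)))
        if (!inGap) return(p)
      }
      p
    }
    pairPos <- sort(vapply(seq_len(nPairs), function(i) drawPos(), numeric(1)))

    # initials: one per side per pair, attached to alternating vessels
    initials <- list()
    for (i in seq_len(nPairs)) {
      for (s in 1:2) {
        j <- ((i * 2 + s) %% nL) + 1L
        th <- thetas[j]
        attach <- ax(pairPos[i])
        attach[, "y"] <- attach[, "y"] + spec@longitudinalOffset * sin(th)
        attach[, "x"] <- attach[, "x"] + spec@longitudinalOffset * cos(th)
        outAngle <- th + (if (nL == 1L && s == 2L) pi else 0) +
          rnorm(1, 0, pi / 12)
        tilt <- rnorm(1, 0, pi / 18)
        dir <- c(sin(tilt),
                 cos(tilt) * sin(outAngle), cos(tilt) * cos(outAngle))
        len <- truncNorm(1, spec@initialLength, spec@initialLengthSd, 15)
        nTips <- if (spec@tipRate * spec@initialDensityFactor > 0)
          rpois(1, spec@tipRate * spec@initialDensityFactor) else 0L
        tipFrac <- sort(runif(nTips, 0.15, 0.6))
        tipLen <- truncNorm(nTips, spec@tipLength, spec@tipLengthSd, 12)
        tipRot <- runif(nTips, 0, 2 * pi)
        initials[[length(initials) + 1L]] <-
          list(vessel = j, z = pairPos[i], attach = as.numeric(attach),
               dir = dir, len = len, tipFrac = tipFrac, tipLen = tipLen,
               tipRot = tipRot)
      }
    }
    list(z0 = z0, zs = zs, vesselLines = vesselLines, gaps = gaps,
         initials = initials)
  })

  gt <- buildGroundTruth(spec, geom, step)
  volume <- NULL
  if (render) {
    volume <- withSeed(spec@seed + 100003L, renderPhantomVolume(spec, gt))
  }
  list(volume = volume, truth = gt)
}

# sample points of a straight segment from a to a+dir*len at ~step spacing
lineSamples <- function(a, dir, len, step) {
  ts <- seq(0, len, by = step)
  if (ts[length(ts)] < len) ts <- c(ts, len)
  cbind(z = a[1] + dir[1] * ts, y = a[2] + dir[2] * ts,
        x = a[3] + dir[3] * ts)
}

# Assemble the exact ground-truth graph: longitudinal vessels split at rung
# attachments and gaps, initials split at tip attachments, tips as leaves.
buildGroundTruth <- function(spec, geom, step) {
  nodes <- list(); edges <- list(); tubes <- list(); centerlines <- list()
  addNode <- function(coord, radius) {
    nodes[[length(nodes) + 1L]] <<- list(coord = coord, radius = radius)
    length(nodes)
  }
  addEdge <- function(from, to, poly, radius) {
    edges[[length(edges) + 1L]] <<- list(from = from, to = to, poly = poly,
                                         radii = rep(radius, nrow(poly)))
  }
  addTube <- function(type, radius, cl) {
    tubes[[length(tubes) + 1L]] <<- list(type = type, radius = radius)
    centerlines[[length(centerlines) + 1L]] <<- cl
  }

  for (j in seq_along(geom$vesselLines)) {
    line <- geom$vesselLines[[j]]
    g <- geom$gaps[[j]]
    pieces <- if (is.null(g)) list(line) else {
      list(line[line[, "z"] <= g[1], , drop = FALSE],
           line[line[, "z"] >= g[2], , drop = FALSE])
    }
    pieces <- Filter(function(p) nrow(p) >= 2L, pieces)
    att <- Filter(function(ii) geom$initials[[ii]]$vessel == j,
                  seq_along(geom$initials))
    attZ <- vapply(att, function(ii) geom$initials[[ii]]$z, numeric(1))
    for (p in pieces) {
      addTube("longitudinal", spec@longitudinalRadius, p)
      inPiece <- which(attZ >= p[1, "z"] & attZ <= p[nrow(p), "z"])
      cutIdx <- sort(unique(vapply(inPiece, function(k)
        which.min(abs(p[, "z"] - attZ[k])), integer(1))))
      cutIdx <- cutIdx[cutIdx > 1 & cutIdx < nrow(p)]
      bounds <- c(1L, cutIdx, nrow(p))
      nodeIds <- integer(length(bounds))
      for (b in seq_along(bounds))
        nodeIds[b] <- addNode(p[bounds[b], ], spec@longitudinalRadius)
      for (b in seq_len(length(bounds) - 1L)) {
        seg <- p[bounds[b]:bounds[b + 1L], , drop = FALSE]
        addEdge(nodeIds[b], nodeIds[b + 1L], seg, spec@longitudinalRadius)
      }
      # remember which graph node carries each attachment on this piece
      for (k in inPiece) {
        ci <- which.min(abs(p[, "z"] - attZ[k]))
        bi <- which(bounds == ci)
        if (length(bi)) # interior cut: reuse its node
          geom$initials[[att[k]]]$node <- nodeIds[bi[1]]
      }
    }
  }

  for (ini in geom$initials) {
    # attachment node: reuse the vessel's cut node if one was created,
    # otherwise the initial dangles in a gap region and is skipped
    if (is.null(ini$node)) next
    a <- ini$attach
    cl <- lineSamples(a, ini$dir, ini$len, step)
    # re-anchor the first sample to the exact node coordinate
    startNode <- ini$node
    nodeCoord <- nodes[[startNode]]$coord
    cl[1, ] <- nodeCoord
    addTube("initial", spec@initialRadius, cl)
    nTips <- length(ini$tipFrac)
    cutIdx <- if (nTips) sort(unique(pmin(nrow(cl) - 1L, pmax(2L,
      round(ini$tipFrac * nrow(cl)))))) else integer()
    bounds <- c(1L, cutIdx, nrow(cl))
    bounds <- unique(bounds)
    nodeIds <- integer(length(bounds))
    nodeIds[1] <- startNode
    if (length(bounds) > 1)
      for (b in 2:length(bounds))
        nodeIds[b] <- addNode(cl[bounds[b], ], spec@initialRadius)
    for (b in seq_len(length(bounds) - 1L)) {
      seg <- cl[bounds[b]:bounds[b + 1L], , drop = FALSE]
      addEdge(nodeIds[b], nodeIds[b + 1L], seg, spec@initialRadius)
    }
    # tips branch from the interior cut nodes
    if (nTips) {
      stemDir <- ini$dir
      # two unit vectors orthogonal to the stem
      u <- c(-stemDir[2], stemDir[1], 0)
      if (sum(u^2) < 1e-12) u <- c(0, -stemDir[3], stemDir[2])
      u <- u / sqrt(sum(u^2))
      v <- c(u[2] * stemDir[3] - u[3] * stemDir[2],
             u[3] * stemDir[1] - u[1] * stemDir[3],
             u[1] * stemDir[2] - u[2] * stemDir[1])
      for (t in seq_len(nTips)) {
        ci <- pmin(nrow(cl) - 1L, pmax(2L, round(ini$tipFrac[t] * nrow(cl))))
        bi <- which(bounds == ci)
        if (!length(bi)) next
        tdir <- cos(ini$tipRot[t]) * u + sin(ini$tipRot[t]) * v
        tcl <- lineSamples(cl[ci, ], tdir, ini$tipLen[t], step)
        tcl[1, ] <- nodes[[nodeIds[bi[1]]]]$coord
        addTube("tip", spec@tipRadius, tcl)
        endN <- addNode(tcl[nrow(tcl), ], spec@tipRadius)
        addEdge(nodeIds[bi[1]], endN, tcl, spec@tipRadius)
      }
    }
  }

  nodeDf <- data.frame(
    id = seq_along(nodes),
    kind = "endpoint",
    z = vapply(nodes, function(n) n$coord[1], numeric(1)),
    y = vapply(nodes, function(n) n$coord[2], numeric(1)),
    x = vapply(nodes, function(n) n$coord[3], numeric(1)),
    radius = vapply(nodes, function(n) n$radius, numeric(1)))
  deg <- integer(length(nodes))
  for (e in edges) {
    deg[e$from] <- deg[e$from] + 1L
    deg[e$to] <- deg[e$to] + 1L
  }
  nodeDf$kind <- ifelse(deg >= 3L, "branchpoint", "endpoint")
  # a cut node whose initial was skipped has degree 2; fuse is not needed for
  # ground truth bookkeeping, but kind must reflect the degree invariant
  graph <- makeVesselGraph(nodeDf, edges, spec@spacing)
  graph <- fuseDegreeTwoTruth(graph)
  tubesDf <- data.frame(
    tube_id = seq_along(tubes),
    type = vapply(tubes, function(t) t$type, character(1)),
    radius_um = vapply(tubes, function(t) t$radius, numeric(1)))
  new("GroundTruth", graph = graph, tubes = tubesDf,
      centerlines = centerlines)
}

# fuse chains through degree-2 nodes of the analytic truth graph (arising
# when an attachment was dropped); reuses the refinement machinery with
# pruning and merging disabled
fuseDegreeTwoTruth <- function(graph) {
  refineGraph(graph, refineParams(spurLength = 0, nodeMergeRadius = 0,
                                  maxIterations = 5L))
}

# render the intensity volume for a ground truth (RNG state managed by caller)
renderPhantomVolume <- function(spec, gt) {
  sp <- spacingVec(spec)
  d <- spec@volumeDim
  pts <- do.call(rbind, gt@centerlines)
  rad <- rep(gt@tubes$radius_um,
             vapply(gt@centerlines, nrow, integer(1)))
  field <- cpp_stamp_tubes(d, sp[1], sp[2], sp[3], pts, rad)
  vol <- array(0, d)
  vol[field] <- spec@signalLevel
  if (spec@psfSigma > 0)
    vol <- cpp_blur_sep(vol, d, spec@psfSigma / sp[1], spec@psfSigma / sp[2],
                        spec@psfSigma / sp[3])
  vol <- cpp_finalize_volume(vol, spec@backgroundLevel, spec@noiseSd, 65535)
  imageVolume(array(vol, d), spec@spacing)
}

#' Render the exact tube mask of a ground truth
#'
#' Re-stamps the stored centrelines into a binary mask on the stated grid,
#' exactly as the generator rendered them (voxel centres within the tube
#' radius), giving the noise-free reference segmentation.
#'
#' @param truth a \linkS4class{GroundTruth}
#' @param volumeDim integer(3) grid size (z, y, x)
#' @param spacing numeric(3) or \linkS4class{VoxelSpacing}
#' @return A \linkS4class{VoxelMask}.
#' @export
renderTruthMask <- function(truth, volumeDim, spacing) {
  stopifnot(is(truth, "GroundTruth"))
  if (!is(spacing, "VoxelSpacing")) spacing <- voxelSpacing(spacing)
  sp <- spacingVec(spacing)
  pts <- do.call(rbind, truth@centerlines)
  rad <- rep(truth@tubes$radius_um,
             vapply(truth@centerlines, nrow, integer(1)))
  m <- cpp_stamp_tubes(as.integer(volumeDim), sp[1], sp[2], sp[3], pts, rad)
  voxelMask(array(m, volumeDim), spacing)
}

#' Generate a cohort of phantoms
#'
#' Member k of the cohort uses the base spec with seed \code{seed + k}, so
#' a cohort is exactly reproducible from its single seed and members are
#' mutually independent.
#'
#' @param spec base \linkS4class{PhantomSpec}
#' @param n cohort size (>= 1)
#' @param seed cohort seed
#' @param render generate intensity volumes (see [generatePhantom()])
#' @return List of \code{n} phantom lists (\code{volume}, \code{truth}).
#' @examples
#' coh <- generateCohort(phantomSpec(volumeDim = c(80, 64, 64),
#'                                   axisLength = 120),
#'                       n = 2, seed = 10, render = FALSE)
#' length(coh)
#' @export
generateCohort <- function(spec, n, seed, render = TRUE) {
  stopifnot(is(spec, "PhantomSpec"), n >= 1)
  lapply(seq_len(n), function(k) {
    s <- spec
    s@seed <- as.integer(seed + k)
    generatePhantom(s, render = render)
  })
}

#' Ground-truth accessors
#'
#' @param truth a \linkS4class{GroundTruth}
#' @return \code{truthGraph}: the exact \linkS4class{VesselGraph};
#'   \code{truthTubes}: the per-tube provenance table.
#' @export
truthGraph <- function(truth) {
  stopifnot(is(truth, "GroundTruth"))
  truth@graph
}

#' @rdname truthGraph
#' @export
truthTubes <- function(truth) {
  stopifnot(is(truth, "GroundTruth"))
  truth@tubes
}
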