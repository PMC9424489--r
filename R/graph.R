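# Skeleton voxels are classified by their 26-neighbour count: 1 -> endpoint,
# 2 -> chain, >= 3 -> branch voxel. Maximal chains become edges; 26-adjacent
# branch voxels are grouped into one branchpoint node placed at their
# radius-weighted centroid. All scans run in lexicographic (z, y, x) order.

emptyNodeFrame <- function() {
  data.frame(id = integer(), kind = character(), z = numeric(),
             y = numeric(), x = numeric(), radius = numeric())
}

emptyEdgeFrame <- function() {
  data.frame(id = integer(), from = integer(), to = integer(),
             length_um = numeric(), mean_radius_um = numeric(),
             n_points = integer())
}

emptyVesselGraph <- function(spacing = voxelSpacing(1, 1, 1)) {
  new("VesselGraph", nodes = emptyNodeFrame(), edges = emptyEdgeFrame(),
      polylines = list(), pointRadii = list(), spacing = spacing)
}

# assemble a VesselGraph from node/edge building blocks, recomputing the
# derived edge columns from the polylines
makeVesselGraph <- function(nodeDf, edgeList, spacing) {
  if (!nrow(nodeDf)) return(emptyVesselGraph(spacing))
  nodeDf$id <- as.integer(nodeDf$id)
  if (!length(edgeList)) {
    g <- new("VesselGraph", nodes = nodeDf, edges = emptyEdgeFrame(),
             polylines = list(), pointRadii = list(), spacing = spacing)
    return(g)
  }
  ed <- data.frame(
    id = seq_along(edgeList),
    from = vapply(edgeList, function(e) as.integer(e$from), integer(1)),
    to = vapply(edgeList, function(e) as.integer(e$to), integer(1)),
    length_um = vapply(edgeList, function(e) polylineLength(e$poly), numeric(1)),
    mean_radius_um = vapply(edgeList, function(e) mean(e$radii), numeric(1)),
    n_points = vapply(edgeList, function(e) nrow(e$poly), integer(1)))
  new("VesselGraph", nodes = nodeDf, edges = ed,
      polylines = lapply(edgeList, function(e) {
        p <- e$poly; colnames(p) <- c("z", "y", "x"); p
      }),
      pointRadii = lapply(edgeList, function(e) as.numeric(e$radii)),
      spacing = spacing)
}

#' Convert a skeleton to a spatial vessel graph
#'
#' Skeleton voxels with one 26-neighbour become endpoint nodes, voxels with
#' two neighbours form edge polylines, and adjacent voxels with three or
#' more neighbours are grouped into a single branchpoint node at their
#' radius-weighted centroid. Polylines are expressed in physical coordinates
#' (um) and carry per-point radii from the skeleton's distance-transform
#' radius map. Isolated skeleton voxels (no neighbours) cannot form a
#' segment and are dropped; pure cycles are represented as a self-loop edge
#' anchored at their lexicographically smallest voxel.
#'
#' @param skeleton a \linkS4class{VesselSkeleton}
#' @return A \linkS4class{VesselGraph} (refine with [refineGraph()] before
#'   morphometry).
#' @examples
#' m <- array(FALSE, c(12, 3, 3)); m[2:11, 2, 2] <- TRUE
#' g <- buildGraph(skeletonize(voxelMask(m, c(1, 1, 1))))
#' nrow(nodes(g)); nrow(edges(g))
#' @export
buildGraph <- function(skeleton) {
  stopifnot(is(skeleton, "VesselSkeleton"))
  co <- skeleton@coords
  n <- nrow(co)
  sp <- spacingVec(skeleton)
  if (n == 0L) return(emptyVesselGraph(skeleton@spacing))
  d <- as.numeric(skeleton@dims)
  um <- voxelToUm(co, sp)
  rad <- skeleton@radii
  lin <- co[, 1] + d[1] * (co[, 2] - 1) + d[1] * d[2] * (co[, 3] - 1)

  offs <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  nbr <- matrix(NA_integer_, n, nrow(offs))
  for (k in seq_len(nrow(offs))) {
    zz <- co[, 1] + offs[k, 1]; yy <- co[, 2] + offs[k, 2]
    xx <- co[, 3] + offs[k, 3]
    ok <- zz >= 1 & zz <= d[1] & yy >= 1 & yy <= d[2] & xx >= 1 & xx <= d[3]
    nl <- zz + d[1] * (yy - 1) + d[1] * d[2] * (xx - 1)
    m <- rep(NA_integer_, n)
    m[ok] <- match(nl[ok], lin)
    nbr[, k] <- m
  }
  deg <- rowSums(!is.na(nbr))
  # compact sorted adjacency lists
  adj <- apply(nbr, 1, function(r) sort(r[!is.na(r)]), simplify = FALSE)

  type <- integer(n) # 0 isolated, 1 endpoint, 2 chain, 3 branch
  type[deg == 1L] <- 1L
  type[deg == 2L] <- 2L
  type[deg >= 3L] <- 3L

  # cluster adjacent branch voxels
  clusterOf <- rep(NA_integer_, n)
  bidx <- which(type == 3L)
  nClusters <- 0L
  if (length(bidx)) {
    bset <- logical(n); bset[bidx] <- TRUE
    seen <- logical(n)
    for (b in bidx) { # lex order => cluster ids ordered by smallest member
      if (seen[b]) next
      nClusters <- nClusters + 1L
      stack <- b; seen[b] <- TRUE
      while (length(stack)) {
        cur <- stack[length(stack)]; stack <- stack[-length(stack)]
        clusterOf[cur] <- nClusters
        nb <- adj[[cur]]
        nb <- nb[bset[nb] & !seen[nb]]
        seen[nb] <- TRUE
        stack <- c(stack, nb)
      }
    }
  }

  # node bookkeeping: endpoints and clusters, ordered by smallest member voxel
  nodeKey <- c(which(type == 1L),
               if (nClusters) vapply(seq_len(nClusters), function(k)
                 min(which(clusterOf == k)), integer(1)))
  nodeIsCluster <- c(rep(FALSE, sum(type == 1L)), rep(TRUE, nClusters))
  ordn <- order(nodeKey)
  nodeKey <- nodeKey[ordn]; nodeIsCluster <- nodeIsCluster[ordn]
  nNodes <- length(nodeKey)
  nodeCoord <- matrix(0, nNodes, 3)
  nodeRadius <- numeric(nNodes)
  nodeKind <- character(nNodes)
  nodeOf <- rep(NA_integer_, n)
  for (i in seq_len(nNodes)) {
    if (nodeIsCluster[i]) {
      mem <- which(clusterOf == clusterOf[nodeKey[i]])
      w <- rad[mem]
      if (sum(w) <= 0) w <- rep(1, length(mem))
      nodeCoord[i, ] <- colSums(um[mem, , drop = FALSE] * w) / sum(w)
      nodeRadius[i] <- max(rad[mem])
      nodeKind[i] <- "branchpoint"
      nodeOf[mem] <- i
    } else {
      v <- nodeKey[i]
      nodeCoord[i, ] <- um[v, ]
      nodeRadius[i] <- rad[v]
      nodeKind[i] <- "endpoint"
      nodeOf[v] <- i
    }
  }

  visited <- logical(n)
  edgeList <- list()
  nodevox <- which(!is.na(nodeOf))
  addEdge <- function(a, b, pathRows) {
    poly <- rbind(nodeCoord[a, ],
                  um[pathRows, , drop = FALSE],
                  nodeCoord[b, ])
    rr <- c(nodeRadius[a], rad[pathRows], nodeRadius[b])
    edgeList[[length(edgeList) + 1L]] <<- list(from = a, to = b,
                                               poly = poly, radii = rr)
  }
  for (v in nodevox) {
    for (u in adj[[v]]) {
      nu <- nodeOf[u]
      if (!is.na(nu)) {
        # direct node-node contact (2-voxel component or endpoint on cluster)
        if (nu != nodeOf[v] && nodeOf[v] < nu) addEdge(nodeOf[v], nu, integer())
        next
      }
      if (visited[u]) next
      path <- integer(); prev <- v; cur <- u
      repeat {
        visited[cur] <- TRUE
        path <- c(path, cur)
        nb <- adj[[cur]]
        nxt <- nb[nb != prev]
        if (length(nxt) != 1L) { # defensive; chain voxels have exactly 2 nbrs
          nxt <- nxt[1L]
        }
        prev <- cur; cur <- nxt
        if (!is.na(nodeOf[cur])) break
        if (visited[cur]) break
      }
      if (!is.na(nodeOf[cur])) addEdge(nodeOf[v], nodeOf[cur], path)
    }
  }
  # pure cycles: chain voxels never reached from any node
  repeat {
    rem <- which(type == 2L & !visited & is.na(nodeOf))
    if (!length(rem)) break
    r <- rem[1L]
    nNodes <- nNodes + 1L
    nodeCoord <- rbind(nodeCoord, um[r, ])
    nodeRadius <- c(nodeRadius, rad[r])
    nodeKind <- c(nodeKind, "branchpoint")
    nodeOf[r] <- nNodes
    prev <- r; cur <- adj[[r]][1L]
    path <- integer()
    while (is.na(nodeOf[cur])) {
      visited[cur] <- TRUE
      path <- c(path, cur)
      nb <- adj[[cur]]
      nxt <- nb[nb != prev]
      prev <- cur; cur <- nxt[1L]
    }
    visited[r] <- TRUE
    addEdge(nNodes, nNodes, path)
  }

  nodeDf <- data.frame(id = seq_len(nNodes), kind = nodeKind,
                       z = nodeCoord[, 1], y = nodeCoord[, 2],
                       x = nodeCoord[, 3], radius = nodeRadius)
  makeVesselGraph(nodeDf, edgeList, skeleton@spacing)
}
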