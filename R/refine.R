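#' Graph refinement parameters
#'
#' Thresholds of the iterative refinement: terminal twigs shorter than
#' \code{spurLength} are thinning artefacts and are pruned (a few voxels at
#' typical spacing), while true spiky initials, which are tens of
#' micrometres long, survive; branchpoints closer than \code{nodeMergeRadius}
#' belong to one anatomical junction and are collapsed; chains through
#' degree-2 nodes are fused. The three rules are applied repeatedly until a
#' fixpoint (or \code{maxIterations}).
#'
#' @param spurLength prune threshold for terminal twigs (um)
#' @param nodeMergeRadius collapse radius for clustered branchpoints (um)
#' @param maxIterations safety cap on refinement sweeps
#' @return A named list of class \code{RefineParams}.
#' @examples
#' refineParams()
#' @export
refineParams <- function(spurLength = 10, nodeMergeRadius = 5,
                         maxIterations = 10L) {
  stopifnot(spurLength >= 0, nodeMergeRadius >= 0, maxIterations >= 1)
  structure(list(spurLength = spurLength, nodeMergeRadius = nodeMergeRadius,
                 maxIterations = as.integer(maxIterations)),
            class = "RefineParams")
}

# internal working representation: nodes as parallel vectors, edges as a list
graphToWork <- function(graph) {
  nd <- graph@nodes
  ed <- graph@edges
  edges <- vector("list", nrow(ed))
  for (i in seq_len(nrow(ed)))
    edges[[i]] <- list(from = ed$from[i], to = ed$to[i],
                       poly = graph@polylines[[i]],
                       radii = graph@pointRadii[[i]])
  list(id = nd$id, coord = cbind(nd$z, nd$y, nd$x), radius = nd$radius,
       edges = edges)
}

workDegrees <- function(w) {
  deg <- integer(length(w$id))
  names(deg) <- w$id
  for (e in w$edges) {
    deg[as.character(e$from)] <- deg[as.character(e$from)] + 1L
    deg[as.character(e$to)] <- deg[as.character(e$to)] + 1L
  }
  deg
}

workComponents <- function(w) {
  if (!length(w$edges))
    return(stats::setNames(seq_along(w$id), w$id))
  el <- do.call(rbind, lapply(w$edges, function(e) c(e$from, e$to)))
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(el[, 1]), to = as.character(el[, 2])),
    directed = FALSE, vertices = data.frame(name = as.character(w$id)))
  memb <- igraph::components(g)$membership
  stats::setNames(as.integer(memb[as.character(w$id)]), w$id)
}

edgeLen <- function(e) polylineLength(e$poly)

# drop nodes that no longer carry edges
dropOrphans <- function(w, keepNodes = integer()) {
  used <- unique(c(unlist(lapply(w$edges, function(e) c(e$from, e$to))),
                   keepNodes))
  keep <- w$id %in% used
  w$id <- w$id[keep]; w$coord <- w$coord[keep, , drop = FALSE]
  w$radius <- w$radius[keep]
  w
}

#' Iteratively refine a vessel graph
#'
#' Repeats three rules until a fixpoint or \code{maxIterations}: (a) delete
#' terminal edges (one endpoint of degree 1) with arc length below
#' \code{spurLength}, unless the edge is the last edge of its connected
#' component; (b) collapse pairs of branchpoints joined by an edge shorter
#' than \code{nodeMergeRadius} into a single node at their radius-weighted
#' midpoint; (c) fuse the two edges through any node whose degree has
#' dropped to 2 into one edge, concatenating their polylines. The result
#' satisfies the degree invariants (endpoints degree 1, branchpoints degree
#' >= 3), except that a pure cycle keeps a degree-2 anchor node for its
#' self-loop. Refinement never increases the edge count and is idempotent.
#'
#' @param graph a \linkS4class{VesselGraph}
#' @param params a [refineParams()] list
#' @return A refined \linkS4class{VesselGraph}. If the fixpoint is not
#'   reached within \code{maxIterations} sweeps a warning is raised and the
#'   current state returned.
#' @examples
#' # a Y whose short arm is pruned, leaving one fused edge
#' m <- array(FALSE, c(9, 9, 3))
#' m[1:9, 5, 2] <- TRUE; m[5, 6:7, 2] <- TRUE
#' g <- buildGraph(skeletonize(voxelMask(m, c(1, 1, 1))))
#' refineGraph(g, refineParams(spurLength = 5))
#' @export
refineGraph <- function(graph, params = refineParams()) {
  stopifnot(is(graph, "VesselGraph"), inherits(params, "RefineParams"))
  if (!nrow(graph@edges)) return(graph)
  w <- graphToWork(graph)
  converged <- FALSE
  for (iter in seq_len(params$maxIterations)) {
    changed <- FALSE

    # (a) spur pruning, sequential with re-checking
    repeat {
      deg <- workDegrees(w)
      comp <- workComponents(w)
      compEdges <- table(vapply(w$edges, function(e)
        comp[as.character(e$from)], numeric(1)))
      cand <- NA_integer_
      for (i in seq_along(w$edges)) {
        e <- w$edges[[i]]
        d1 <- deg[as.character(e$from)]; d2 <- deg[as.character(e$to)]
        if (d1 != 1L && d2 != 1L) next
        if (edgeLen(e) >= params$spurLength) next
        if (compEdges[as.character(comp[as.character(e$from)])] <= 1L) next
        cand <- i; break
      }
      if (is.na(cand)) break
      e <- w$edges[[cand]]
      w$edges[[cand]] <- NULL
      w <- dropOrphans(w)
      changed <- TRUE
    }

    # (b) merge branchpoints joined by an edge shorter than the merge radius
    repeat {
      deg <- workDegrees(w)
      lens <- vapply(w$edges, edgeLen, numeric(1))
      cand <- NA_integer_
      if (length(lens)) {
        ok <- vapply(seq_along(w$edges), function(i) {
          e <- w$edges[[i]]
          e$from != e$to &&
            deg[as.character(e$from)] >= 3L && deg[as.character(e$to)] >= 3L &&
            lens[i] < params$nodeMergeRadius
        }, logical(1))
        if (any(ok)) cand <- which(ok)[which.min(lens[ok])]
      }
      if (is.na(cand)) break
      e <- w$edges[[cand]]
      a <- min(e$from, e$to); b <- max(e$from, e$to)
      ia <- match(a, w$id); ib <- match(b, w$id)
      wgt <- c(w$radius[ia], w$radius[ib])
      if (sum(wgt) <= 0) wgt <- c(1, 1)
      newCoord <- (w$coord[ia, ] * wgt[1] + w$coord[ib, ] * wgt[2]) / sum(wgt)
      w$coord[ia, ] <- newCoord
      w$radius[ia] <- max(w$radius[ia], w$radius[ib])
      w$edges[[cand]] <- NULL
      w$edges <- lapply(w$edges, function(e2) {
        if (e2$from == b) e2$from <- a
        if (e2$to == b) e2$to <- a
        e2
      })
      # re-anchor terminal polyline points of all edges touching the merged node
      w$edges <- lapply(w$edges, function(e2) {
        if (e2$from == a) e2$poly[1, ] <- newCoord
        if (e2$to == a) e2$poly[nrow(e2$poly), ] <- newCoord
        e2
      })
      w <- dropOrphans(w)
      changed <- TRUE
    }

    # (c) fuse chains through degree-2 nodes
    repeat {
      deg <- workDegrees(w)
      two <- as.integer(names(deg)[deg == 2L])
      fused <- FALSE
      for (nid in two) {
        inc <- which(vapply(w$edges, function(e)
          (e$from == nid) + (e$to == nid), numeric(1)) > 0)
        if (length(inc) != 2L) next # self-loop ring: leave
        e1 <- w$edges[[inc[1]]]; e2 <- w$edges[[inc[2]]]
        # orient e1 to end at nid and e2 to start at nid
        if (e1$to != nid) {
          e1 <- list(from = e1$to, to = e1$from,
                     poly = e1$poly[nrow(e1$poly):1, , drop = FALSE],
                     radii = rev(e1$radii))
        }
        if (e2$from != nid) {
          e2 <- list(from = e2$to, to = e2$from,
                     poly = e2$poly[nrow(e2$poly):1, , drop = FALSE],
                     radii = rev(e2$radii))
        }
        newE <- list(from = e1$from, to = e2$to,
                     poly = rbind(e1$poly, e2$poly[-1, , drop = FALSE]),
                     radii = c(e1$radii, e2$radii[-1]))
        w$edges[[inc[2]]] <- NULL
        w$edges[[inc[1]]] <- newE
        w <- dropOrphans(w)
        fused <- TRUE
        changed <- TRUE
        break
      }
      if (!fused) break
    }

    if (!changed) { converged <- TRUE; break }
  }
  if (!converged) {
    # one silent extra check: a final sweep may simply have had nothing to do
    warning("graph refinement did not reach a fixpoint within ",
            params$maxIterations, " iterations; returning current state")
  }

  # rebuild the S4 object with fresh ids and kinds
  deg <- workDegrees(w)
  oldIds <- w$id
  newId <- stats::setNames(seq_along(oldIds), oldIds)
  kind <- ifelse(deg[as.character(oldIds)] == 1L, "endpoint", "branchpoint")
  nodeDf <- data.frame(id = seq_along(oldIds), kind = as.character(kind),
                       z = w$coord[, 1], y = w$coord[, 2], x = w$coord[, 3],
                       radius = w$radius)
  edgeList <- lapply(w$edges, function(e)
    list(from = newId[as.character(e$from)], to = newId[as.character(e$to)],
         poly = e$poly, radii = e$radii))
  makeVesselGraph(nodeDf, edgeList, graph@spacing)
}
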