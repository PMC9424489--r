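#' Write and read vessel graphs
#'
#' Graphs are serialized either as JSON (the lossless reference format:
#' nodes, edges, full polylines and radii at full precision) or as GraphML
#' via igraph (node attributes kind and x/y/z in um; edge attributes
#' length_um, mean_radius_um, and the polyline/radii embedded as JSON
#' strings). The format follows the file extension (\code{.json} or
#' \code{.graphml}).
#'
#' @param graph a \linkS4class{VesselGraph}
#' @param path output path ending in \code{.json} or \code{.graphml}
#' @return \code{writeGraph} returns \code{path} invisibly; \code{readGraph}
#'   a \linkS4class{VesselGraph}.
#' @examples
#' g <- LymphNetQuant:::demoStraightGraph()
#' f <- tempfile(fileext = ".json")
#' writeGraph(g, f)
#' readGraph(f)
#' @export
writeGraph <- function(graph, path) {
  stopifnot(is(graph, "VesselGraph"))
  fmt <- graphFormat(path)
  if (fmt == "json") {
    obj <- list(
      spacing = as.numeric(spacingVec(graph)),
      nodes = graph@nodes,
      edges = graph@edges,
      polylines = lapply(graph@polylines, function(p) unname(as.matrix(p))),
      point_radii = graph@pointRadii)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns")
  } else {
    ig <- vesselGraphToIgraph(graph)
    igraph::write_graph(ig, path, format = "graphml")
  }
  invisible(path)
}

#' @rdname writeGraph
#' @export
readGraph <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  fmt <- graphFormat(path)
  if (fmt == "json") {
    obj <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                    error = function(e)
                      stop("malformed graph file: ", conditionMessage(e),
                           call. = FALSE))
    if (!all(c("spacing", "nodes", "edges") %in% names(obj)))
      stop("malformed graph file: missing nodes/edges/spacing",
           call. = FALSE)
    sp <- voxelSpacing(unlist(obj$spacing))
    cols2df <- function(x) as.data.frame(lapply(x, function(col)
      unlist(lapply(col, function(v) if (is.null(v)) NA else v))))
    if (!length(obj$nodes$id)) return(emptyVesselGraph(sp))
    nd <- cols2df(obj$nodes)
    if (!length(obj$edges$id)) {
      return(new("VesselGraph", nodes = normNodeFrame(nd),
                 edges = emptyEdgeFrame(), polylines = list(),
                 pointRadii = list(), spacing = sp))
    }
    ed <- cols2df(obj$edges)
    pls <- lapply(obj$polylines, function(p) {
      m <- matrix(unlist(p), ncol = 3, byrow = TRUE)
      colnames(m) <- c("z", "y", "x"); m
    })
    prs <- lapply(obj$point_radii, function(r) as.numeric(unlist(r)))
    new("VesselGraph", nodes = normNodeFrame(nd), edges = normEdgeFrame(ed),
        polylines = pls, pointRadii = prs, spacing = sp)
  } else {
    ig <- tryCatch(igraph::read_graph(path, format = "graphml"),
                   error = function(e)
                     stop("malformed graph file: ", conditionMessage(e),
                          call. = FALSE))
    igraphToVesselGraph(ig)
  }
}

graphFormat <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) "json"
  else if (grepl("\\.graphml$", path, ignore.case = TRUE)) "graphml"
  else stop("unsupported graph format (use .json or .graphml): ", path,
            call. = FALSE)
}

normNodeFrame <- function(nd) {
  data.frame(id = as.integer(nd$id), kind = as.character(nd$kind),
             z = as.numeric(nd$z), y = as.numeric(nd$y),
             x = as.numeric(nd$x), radius = as.numeric(nd$radius))
}

normEdgeFrame <- function(ed) {
  data.frame(id = as.integer(ed$id), from = as.integer(ed$from),
             to = as.integer(ed$to), length_um = as.numeric(ed$length_um),
             mean_radius_um = as.numeric(ed$mean_radius_um),
             n_points = as.integer(ed$n_points))
}

#' Convert a vessel graph to an igraph object
#'
#' Vertices carry kind, x/y/z (um) and radius; edges carry length_um,
#' mean_radius_um, n_points, and polyline/radii as JSON string attributes.
#'
#' @param graph a \linkS4class{VesselGraph}
#' @return An \link[igraph]{igraph} object (undirected).
#' @export
vesselGraphToIgraph <- function(graph) {
  nd <- graph@nodes; ed <- graph@edges
  vdf <- data.frame(name = as.character(nd$id), kind = nd$kind,
                    z = nd$z, y = nd$y, x = nd$x, radius = nd$radius)
  if (!nrow(ed))
    return(igraph::graph_from_data_frame(
      data.frame(from = character(), to = character()),
      directed = FALSE, vertices = vdf))
  edf <- data.frame(from = as.character(ed$from), to = as.character(ed$to),
                    eid = ed$id, length_um = ed$length_um,
                    mean_radius_um = ed$mean_radius_um,
                    n_points = ed$n_points,
                    polyline = vapply(graph@polylines, function(p)
                      as.character(jsonlite::toJSON(unname(as.matrix(p)),
                                                    digits = NA)),
                      character(1)),
                    radii = vapply(graph@pointRadii, function(r)
                      as.character(jsonlite::toJSON(r, digits = NA)),
                      character(1)))
  igraph::graph_from_data_frame(edf, directed = FALSE, vertices = vdf)
}

igraphToVesselGraph <- function(ig, spacing = voxelSpacing(1, 1, 1)) {
  nd <- data.frame(id = as.integer(igraph::V(ig)$name),
                   kind = igraph::V(ig)$kind,
                   z = igraph::V(ig)$z, y = igraph::V(ig)$y,
                   x = igraph::V(ig)$x, radius = igraph::V(ig)$radius)
  ord <- order(nd$id)
  nd <- nd[ord, ]; rownames(nd) <- NULL
  m <- igraph::ecount(ig)
  if (!m)
    return(new("VesselGraph", nodes = nd, edges = emptyEdgeFrame(),
               polylines = list(), pointRadii = list(), spacing = spacing))
  el <- igraph::as_edgelist(ig, names = TRUE)
  eid <- igraph::E(ig)$eid
  eord <- order(eid)
  pls <- lapply(igraph::E(ig)$polyline, function(s) {
    m2 <- jsonlite::fromJSON(s)
    colnames(m2) <- c("z", "y", "x"); m2
  })
  prs <- lapply(igraph::E(ig)$radii, function(s) as.numeric(jsonlite::fromJSON(s)))
  edgeList <- lapply(eord, function(i) {
    # written edge direction is recoverable from the polyline ends
    from <- as.integer(el[i, 1]); to <- as.integer(el[i, 2])
    pl <- pls[[i]]
    a <- unlist(nd[match(from, nd$id), c("z", "y", "x")])
    if (max(abs(pl[1, ] - a)) > 1e-6) { tmp <- from; from <- to; to <- tmp }
    list(from = from, to = to, poly = pl, radii = prs[[i]])
  })
  makeVesselGraph(nd, edgeList, spacing)
}
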