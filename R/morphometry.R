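#' Per-segment morphometric features
#'
#' One record per graph edge (inter-branchpoint segment): the arc length of
#' its centreline polyline and the average cross-section area, pi * r^2
#' averaged over the polyline's interior points. Polyline endpoints are
#' excluded from the radius average whenever the polyline has more than two
#' points, because distance-transform radii at junctions reflect the
#' junction blob rather than the vessel.
#'
#' @param graph a refined \linkS4class{VesselGraph}
#' @param volumeId identifier recorded in every row
#' @return data.frame with columns volume_id, edge_id, length_um,
#'   avg_cross_section_um2, n_points; empty for an empty graph.
#' @examples
#' g <- LymphNetQuant:::demoStraightGraph(length_um = 10, radius_um = 2)
#' extractFeatures(g, "demo")
#' @export
extractFeatures <- function(graph, volumeId = "volume") {
  stopifnot(is(graph, "VesselGraph"))
  ed <- graph@edges
  if (!nrow(ed))
    return(data.frame(volume_id = character(), edge_id = integer(),
                      length_um = numeric(), avg_cross_section_um2 = numeric(),
                      n_points = integer()))
  area <- vapply(seq_len(nrow(ed)), function(i) {
    r <- graph@pointRadii[[i]]
    if (length(r) > 2L) r <- r[-c(1L, length(r))]
    mean(pi * r^2)
  }, numeric(1))
  data.frame(volume_id = volumeId, edge_id = ed$id, length_um = ed$length_um,
             avg_cross_section_um2 = area, n_points = ed$n_points)
}

#' Per-volume aggregation of segment features
#'
#' Summarises segment records per volume: mean/median segment length,
#' mean/median average cross-section area, edge count and total network
#' length, optionally joined with per-volume branchpoint counts.
#'
#' @param records a feature table from [extractFeatures()] (rows from
#'   several volumes may be concatenated)
#' @param branchCounts optional named integer vector (names = volume ids)
#' @return One row per volume id, ordered by first appearance.
#' @export
aggregatePerVolume <- function(records, branchCounts = NULL) {
  cols <- c("volume_id", "length_um", "avg_cross_section_um2")
  stopifnot(all(cols %in% names(records)))
  if (!nrow(records)) {
    out <- data.frame(volume_id = character(), n_segments = integer(),
                      mean_length_um = numeric(), median_length_um = numeric(),
                      mean_area_um2 = numeric(), median_area_um2 = numeric(),
                      total_length_um = numeric(),
                      n_branchpoints = integer())
    return(out)
  }
  ids <- unique(records$volume_id)
  out <- do.call(rbind, lapply(ids, function(v) {
    r <- records[records$volume_id == v, ]
    data.frame(volume_id = v, n_segments = nrow(r),
               mean_length_um = mean(r$length_um),
               median_length_um = median(r$length_um),
               mean_area_um2 = mean(r$avg_cross_section_um2),
               median_area_um2 = median(r$avg_cross_section_um2),
               total_length_um = sum(r$length_um))
  }))
  out$n_branchpoints <- if (!is.null(branchCounts))
    as.integer(branchCounts[out$volume_id]) else NA_integer_
  rownames(out) <- NULL
  out
}

# tiny fixture used in examples: one straight edge along z
demoStraightGraph <- function(length_um = 10, radius_um = 2, n = 5) {
  zs <- seq(0, length_um, length.out = n)
  nodeDf <- data.frame(id = 1:2, kind = "endpoint",
                       z = c(0, length_um), y = 0, x = 0, radius = radius_um)
  edgeList <- list(list(from = 1L, to = 2L,
                        poly = cbind(zs, 0, 0),
                        radii = rep(radius_um, n)))
  makeVesselGraph(nodeDf, edgeList, voxelSpacing(1, 1, 1))
}
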