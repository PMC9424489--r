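#' @import methods
NULL

#' Physical voxel spacing
#'
#' Step between neighbouring voxel centres along each axis, in micrometres.
#' Axis order is fixed to (z, y, x), z being the light-sheet stepping axis.
#'
#' @slot dz,dy,dx numeric(1), step per axis in micrometres; strictly positive.
#' @exportClass VoxelSpacing
setClass("VoxelSpacing",
         representation(dz = "numeric", dy = "numeric", dx = "numeric"))

setValidity("VoxelSpacing", function(object) {
  v <- c(object@dz, object@dy, object@dx)
  if (length(v) != 3L || any(!is.finite(v)) || any(v <= 0))
    return("dz, dy, dx must each be a single finite positive number")
  TRUE
})

#' @param dz,dy,dx step per axis in micrometres
#' @return A \code{VoxelSpacing} object.
#' @rdname VoxelSpacing-class
#' @examples
#' voxelSpacing(2, 2, 2)
#' @export
voxelSpacing <- function(dz, dy, dx) {
  if (length(dz) == 3L && missing(dy)) { dx <- dz[3]; dy <- dz[2]; dz <- dz[1] }
  new("VoxelSpacing", dz = as.numeric(dz), dy = as.numeric(dy), dx = as.numeric(dx))
}

#' 3D intensity volume
#'
#' A scalar intensity grid in (z, y, x) axis order with physical voxel
#' spacing attached. Intensities must be finite and non-negative.
#'
#' @slot values 3D numeric array, axis order (z, y, x)
#' @slot spacing a \linkS4class{VoxelSpacing}
#' @exportClass ImageVolume
setClass("ImageVolume",
         representation(values = "array", spacing = "VoxelSpacing"))

setValidity("ImageVolume", function(object) {
  d <- dim(object@values)
  if (length(d) != 3L) return("values must be a 3D array (z, y, x)")
  if (any(d < 1L)) return("each axis must have at least one voxel")
  if (!is.numeric(object@values)) return("values must be numeric")
  rng <- suppressWarnings(range(object@values))
  if (anyNA(rng) || !all(is.finite(rng)))
    return("intensities must be finite")
  if (rng[1] < 0) return("intensities must be non-negative")
  TRUE
})

#' @param values 3D numeric array, axis order (z, y, x)
#' @param spacing a \linkS4class{VoxelSpacing} or numeric(3) of (dz, dy, dx)
#' @return An \code{ImageVolume}.
#' @rdname ImageVolume-class
#' @export
imageVolume <- function(values, spacing) {
  if (!is(spacing, "VoxelSpacing")) spacing <- voxelSpacing(spacing)
  new("ImageVolume", values = values, spacing = spacing)
}

#' Binary foreground mask
#'
#' A 3D logical grid sharing the geometry of its source volume.
#'
#' @slot values 3D logical array, axis order (z, y, x)
#' @slot spacing a \linkS4class{VoxelSpacing}
#' @exportClass VoxelMask
setClass("VoxelMask",
         representation(values = "array", spacing = "VoxelSpacing"))

setValidity("VoxelMask", function(object) {
  d <- dim(object@values)
  if (length(d) != 3L) return("values must be a 3D array (z, y, x)")
  if (!is.logical(object@values)) return("values must be logical")
  if (anyNA(object@values)) return("mask may not contain NA")
  TRUE
})

#' @param values 3D logical array
#' @param spacing a \linkS4class{VoxelSpacing} or numeric(3)
#' @return A \code{VoxelMask}.
#' @rdname VoxelMask-class
#' @export
voxelMask <- function(values, spacing) {
  if (!is(spacing, "VoxelSpacing")) spacing <- voxelSpacing(spacing)
  new("VoxelMask", values = values, spacing = spacing)
}

#' Labelled connected components
#'
#' Integer component labels (0 = background, k >= 1 a component) with the
#' voxel count of every component. Labels are assigned in lexicographic
#' (z, y, x) order of each component's smallest member voxel, so labelling
#' is deterministic.
#'
#' @slot labels 3D integer array
#' @slot spacing a \linkS4class{VoxelSpacing}
#' @slot sizes integer vector, \code{sizes[k]} = voxel count of component k
#' @exportClass LabeledMask
setClass("LabeledMask",
         representation(labels = "array", spacing = "VoxelSpacing",
                        sizes = "integer"))

setValidity("LabeledMask", function(object) {
  if (length(dim(object@labels)) != 3L) return("labels must be a 3D array")
  k <- length(object@sizes)
  if (k > 0) {
    tab <- tabulate(object@labels[object@labels > 0L], nbins = k)
    if (!identical(as.integer(tab), as.integer(object@sizes)))
      return("sizes inconsistent with the label grid")
  } else if (any(object@labels > 0L)) {
    return("label grid has components but sizes is empty")
  }
  TRUE
})

#' Skeleton of a binary mask
#'
#' Unit-width medial voxel set of a mask, with a per-voxel physical radius
#' taken from the spacing-aware Euclidean distance transform of the source
#' mask (distance to the nearest background voxel centre, micrometres).
#'
#' @slot coords integer matrix (n x 3), 1-based voxel coordinates (z, y, x)
#' @slot radii numeric vector of physical radii, one per skeleton voxel
#' @slot dims integer(3), grid dimensions of the source mask
#' @slot spacing a \linkS4class{VoxelSpacing}
#' @exportClass VesselSkeleton
setClass("VesselSkeleton",
         representation(coords = "matrix", radii = "numeric",
                        dims = "integer", spacing = "VoxelSpacing"))

setValidity("VesselSkeleton", function(object) {
  if (ncol(object@coords) != 3L) return("coords must have 3 columns (z, y, x)")
  if (nrow(object@coords) != length(object@radii))
    return("one radius per skeleton voxel required")
  if (length(object@radii) && any(object@radii < 0)) return("radii must be >= 0")
  if (length(object@dims) != 3L) return("dims must be integer(3)")
  if (nrow(object@coords)) {
    if (any(object@coords < 1L) ||
        any(sweep(object@coords, 2, object@dims, ">")))
      return("skeleton coordinates outside the grid")
  }
  TRUE
})

#' Spatial vessel graph
#'
#' Nodes are endpoints or branchpoints with physical coordinates; each edge
#' carries an ordered centreline polyline (micrometres) and per-point radii.
#'
#' @slot nodes data.frame with columns id, kind ("endpoint"/"branchpoint"),
#'   z, y, x (micrometres), radius
#' @slot edges data.frame with columns id, from, to, length_um,
#'   mean_radius_um, n_points
#' @slot polylines list of numeric matrices (n_points x 3, columns z, y, x)
#' @slot pointRadii list of numeric vectors matching the polylines
#' @slot spacing a \linkS4class{VoxelSpacing}
#' @exportClass VesselGraph
setClass("VesselGraph",
         representation(nodes = "data.frame", edges = "data.frame",
                        polylines = "list", pointRadii = "list",
                        spacing = "VoxelSpacing"))

setValidity("VesselGraph", function(object) {
  nd <- object@nodes; ed <- object@edges
  need_n <- c("id", "kind", "z", "y", "x", "radius")
  need_e <- c("id", "from", "to", "length_um", "mean_radius_um", "n_points")
  if (!all(need_n %in% names(nd))) return("nodes is missing required columns")
  if (!all(need_e %in% names(ed))) return("edges is missing required columns")
  if (nrow(ed) != length(object@polylines) ||
      nrow(ed) != length(object@pointRadii))
    return("one polyline and one radius vector per edge required")
  if (nrow(ed)) {
    if (!all(ed$from %in% nd$id) || !all(ed$to %in% nd$id))
      return("edge endpoints must be graph nodes")
    for (i in seq_len(nrow(ed))) {
      pl <- object@polylines[[i]]
      if (nrow(pl) < 2L) return("polylines need at least 2 points")
      if (nrow(pl) != length(object@pointRadii[[i]]))
        return("polyline/radii length mismatch")
      a <- unlist(nd[match(ed$from[i], nd$id), c("z", "y", "x")])
      b <- unlist(nd[match(ed$to[i], nd$id), c("z", "y", "x")])
      if (max(abs(pl[1, ] - a)) > 1e-6 || max(abs(pl[nrow(pl), ] - b)) > 1e-6)
        return("polyline ends must coincide with node coordinates")
    }
  }
  TRUE
})

#' Generative parameters of a synthetic lymphatic phantom
#'
#' Describes a portal-tract-style network: a gently curved axis, parallel
#' longitudinal vessels, and perpendicular blind-ending initials placed as
#' opposite-side ladder rungs, each initial optionally ramified into short
#' finger-like tips. Lengths are micrometres. The density factor rarefies
#' both the initials and their ramification (1 = control); discontinuityProb
#' breaks longitudinal vessels with gaps, emulating the mutant phenotype.
#'
#' @slot volumeDim integer(3) grid size (z, y, x)
#' @slot spacing a \linkS4class{VoxelSpacing}
#' @slot axisLength length of the portal-tract axis (um)
#' @slot axisCurveAmplitude lateral sinusoidal amplitude of the axis (um)
#' @slot nLongitudinal number of long vessels parallel to the axis
#' @slot longitudinalRadius radius of longitudinal vessels (um)
#' @slot longitudinalOffset radial offset of longitudinal vessels from the axis (um)
#' @slot initialSpacing mean axial distance between initials (um)
#' @slot initialLength,initialLengthSd mean and sd of initial length (um)
#' @slot initialRadius radius of initials (um)
#' @slot tipRate mean number of finger-like tips per initial (control)
#' @slot tipLength,tipLengthSd mean and sd of tip length (um)
#' @slot tipRadius radius of tips (um)
#' @slot initialDensityFactor multiplier in [0, 1] on initial and tip rates
#' @slot discontinuityProb probability a longitudinal vessel is broken by a gap
#' @slot gapLength length of such a gap (um)
#' @slot signalLevel,backgroundLevel,noiseSd intensity model (photon counts)
#' @slot psfSigma Gaussian blur scale (um)
#' @slot seed integer random seed
#' @exportClass PhantomSpec
setClass("PhantomSpec",
         representation(volumeDim = "integer", spacing = "VoxelSpacing",
                        axisLength = "numeric", axisCurveAmplitude = "numeric",
                        nLongitudinal = "integer",
                        longitudinalRadius = "numeric",
                        longitudinalOffset = "numeric",
                        initialSpacing = "numeric",
                        initialLength = "numeric", initialLengthSd = "numeric",
                        initialRadius = "numeric",
                        tipRate = "numeric", tipLength = "numeric",
                        tipLengthSd = "numeric", tipRadius = "numeric",
                        initialDensityFactor = "numeric",
                        discontinuityProb = "numeric", gapLength = "numeric",
                        signalLevel = "numeric", backgroundLevel = "numeric",
                        noiseSd = "numeric", psfSigma = "numeric",
                        seed = "integer"))

setValidity("PhantomSpec", function(object) {
  if (length(object@volumeDim) != 3L || any(object@volumeDim < 4L))
    return("volumeDim must be integer(3), each >= 4")
  pos <- c(axisLength = object@axisLength,
           longitudinalRadius = object@longitudinalRadius,
           initialSpacing = object@initialSpacing,
           initialLength = object@initialLength,
           initialRadius = object@initialRadius,
           tipRadius = object@tipRadius,
           signalLevel = object@signalLevel)
  if (any(pos <= 0)) return(paste("must be > 0:",
                                  paste(names(pos)[pos <= 0], collapse = ", ")))
  if (object@initialDensityFactor < 0 || object@initialDensityFactor > 1)
    return("initialDensityFactor must lie in [0, 1]")
  if (object@discontinuityProb < 0 || object@discontinuityProb > 1)
    return("discontinuityProb must lie in [0, 1]")
  if (object@noiseSd < 0 || object@psfSigma < 0 || object@backgroundLevel < 0)
    return("noiseSd, psfSigma and backgroundLevel must be >= 0")
  TRUE
})

#' Exact ground truth of a generated phantom
#'
#' The analytically known centreline network of all rendered tubes: a
#' \linkS4class{VesselGraph} plus per-tube provenance (longitudinal vessel,
#' initial, or tip) and the raw centrelines used for rendering.
#'
#' @slot graph the exact \linkS4class{VesselGraph}
#' @slot tubes data.frame with columns tube_id, type, radius_um
#' @slot centerlines list of centreline matrices (um) parallel to tubes
#' @exportClass GroundTruth
setClass("GroundTruth",
         representation(graph = "VesselGraph", tubes = "data.frame",
                        centerlines = "list"))

#' Mann-Whitney U test result
#'
#' @slot uStatistic U of the first sample
#' @slot n1,n2 sample sizes
#' @slot pTwoSided two-sided p value
#' @slot method "exact" (full enumeration) or "normal_approx_tie_corrected"
#' @exportClass UTestResult
setClass("UTestResult",
         representation(uStatistic = "numeric", n1 = "integer", n2 = "integer",
                        pTwoSided = "numeric", method = "character"))

setValidity("UTestResult", function(object) {
  if (object@uStatistic < 0 || object@uStatistic > object@n1 * object@n2)
    return("U must lie in [0, n1*n2]")
  if (object@pTwoSided <= 0 || object@pTwoSided > 1)
    return("p must lie in (0, 1]")
  if (!object@method %in% c("exact", "normal_approx_tie_corrected"))
    return("unknown method")
  TRUE
})
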