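#' @include AllClasses.R
NULL

#' Accessors for spatial image objects
#'
#' \code{spacing} returns the \linkS4class{VoxelSpacing}; \code{spacingVec}
#' the numeric (dz, dy, dx); \code{imgData} the underlying array;
#' \code{gridDim} the grid dimensions.
#'
#' @param x an object with spatial geometry
#' @return See the individual descriptions.
#' @examples
#' m <- voxelMask(array(TRUE, c(2, 2, 2)), c(2, 1, 1))
#' spacingVec(m)
#' @name geometry-accessors
NULL

#' @rdname geometry-accessors
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))

#' @rdname geometry-accessors
#' @export
setGeneric("spacingVec", function(x) standardGeneric("spacingVec"))

#' @rdname geometry-accessors
#' @export
setGeneric("imgData", function(x) standardGeneric("imgData"))

#' @rdname geometry-accessors
#' @export
setGeneric("gridDim", function(x) standardGeneric("gridDim"))

#' Accessors for vessel graphs
#'
#' @param x a \linkS4class{VesselGraph}
#' @return \code{nodes}/\code{edges} return data.frames, \code{polylines} and
#'   \code{pointRadii} lists parallel to the edge table,
#'   \code{totalNetworkLength} the summed polyline arc length (micrometres),
#'   \code{branchpointCount} and \code{endpointCount} node tallies.
#' @name graph-accessors
NULL

#' @rdname graph-accessors
#' @export
setGeneric("nodes", function(x) standardGeneric("nodes"))

#' @rdname graph-accessors
#' @export
setGeneric("edges", function(x) standardGeneric("edges"))

#' @rdname graph-accessors
#' @export
setGeneric("polylines", function(x) standardGeneric("polylines"))

#' @rdname graph-accessors
#' @export
setGeneric("pointRadii", function(x) standardGeneric("pointRadii"))

#' @rdname graph-accessors
#' @export
setGeneric("totalNetworkLength", function(x) standardGeneric("totalNetworkLength"))

#' @rdname graph-accessors
#' @export
setGeneric("branchpointCount", function(x) standardGeneric("branchpointCount"))

#' @rdname graph-accessors
#' @export
setGeneric("endpointCount", function(x) standardGeneric("endpointCount"))

#' Component label accessors
#'
#' @param x a \linkS4class{LabeledMask}
#' @return \code{componentLabels} the integer label array,
#'   \code{componentSizes} the per-component voxel counts.
#' @name component-accessors
NULL

#' @rdname component-accessors
#' @export
setGeneric("componentLabels", function(x) standardGeneric("componentLabels"))

#' @rdname component-accessors
#' @export
setGeneric("componentSizes", function(x) standardGeneric("componentSizes"))
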