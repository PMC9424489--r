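#' @include AllGenerics.R
NULL

#' @rdname geometry-accessors
#' @export
setMethod("spacing", "VoxelSpacing", function(x) x)

#' @rdname geometry-accessors
#' @export
setMethod("spacingVec", "VoxelSpacing", function(x) c(dz = x@dz, dy = x@dy, dx = x@dx))

#' @rdname geometry-accessors
#' @export
setMethod("spacing", "ImageVolume", function(x) x@spacing)
#' @rdname geometry-accessors
#' @export
setMethod("spacing", "VoxelMask", function(x) x@spacing)
#' @rdname geometry-accessors
#' @export
setMethod("spacing", "LabeledMask", function(x) x@spacing)
#' @rdname geometry-accessors
#' @export
setMethod("spacing", "VesselSkeleton", function(x) x@spacing)
#' @rdname geometry-accessors
#' @export
setMethod("spacing", "VesselGraph", function(x) x@spacing)
#' @rdname geometry-accessors
#' @export
setMethod("spacing", "PhantomSpec", function(x) x@spacing)
#' @rdname geometry-accessors
#' @export
setMethod("spacingVec", "ImageVolume", function(x) spacingVec(x@spacing))
#' @rdname geometry-accessors
#' @export
setMethod("spacingVec", "VoxelMask", function(x) spacingVec(x@spacing))
#' @rdname geometry-accessors
#' @export
setMethod("spacingVec", "LabeledMask", function(x) spacingVec(x@spacing))
#' @rdname geometry-accessors
#' @export
setMethod("spacingVec", "VesselSkeleton", function(x) spacingVec(x@spacing))
#' @rdname geometry-accessors
#' @export
setMethod("spacingVec", "VesselGraph", function(x) spacingVec(x@spacing))
#' @rdname geometry-accessors
#' @export
setMethod("spacingVec", "PhantomSpec", function(x) spacingVec(x@spacing))

#' @rdname geometry-accessors
#' @export
setMethod("imgData", "ImageVolume", function(x) x@values)

#' @rdname geometry-accessors
#' @export
setMethod("imgData", "VoxelMask", function(x) x@values)

#' @rdname geometry-accessors
#' @export
setMethod("gridDim", "ImageVolume", function(x) dim(x@values))

#' @rdname geometry-accessors
#' @export
setMethod("gridDim", "VoxelMask", function(x) dim(x@values))

#' @rdname geometry-accessors
#' @export
setMethod("gridDim", "LabeledMask", function(x) dim(x@labels))

#' @rdname geometry-accessors
#' @export
setMethod("gridDim", "VesselSkeleton", function(x) x@dims)

#' @rdname component-accessors
#' @export
setMethod("componentLabels", "LabeledMask", function(x) x@labels)

#' @rdname component-accessors
#' @export
setMethod("componentSizes", "LabeledMask", function(x) x@sizes)

#' @rdname graph-accessors
#' @export
setMethod("nodes", "VesselGraph", function(x) x@nodes)

#' @rdname graph-accessors
#' @export
setMethod("edges", "VesselGraph", function(x) x@edges)

#' @rdname graph-accessors
#' @export
setMethod("polylines", "VesselGraph", function(x) x@polylines)

#' @rdname graph-accessors
#' @export
setMethod("pointRadii", "VesselGraph", function(x) x@pointRadii)

#' @rdname graph-accessors
#' @export
setMethod("totalNetworkLength", "VesselGraph", function(x) {
  if (!nrow(x@edges)) return(0)
  sum(x@edges$length_um)
})

#' @rdname graph-accessors
#' @export
setMethod("branchpointCount", "VesselGraph", function(x)
  sum(x@nodes$kind == "branchpoint"))

#' @rdname graph-accessors
#' @export
setMethod("endpointCount", "VesselGraph", function(x)
  sum(x@nodes$kind == "endpoint"))

setMethod("show", "VoxelSpacing", function(object) {
  cat(sprintf("VoxelSpacing (um): dz=%g dy=%g dx=%g\n",
              object@dz, object@dy, object@dx))
})

setMethod("show", "ImageVolume", function(object) {
  d <- dim(object@values)
  cat(sprintf("ImageVolume %d x %d x %d (z,y,x), range [%g, %g]\n",
              d[1], d[2], d[3], min(object@values), max(object@values)))
  show(object@spacing)
})

setMethod("show", "VoxelMask", function(object) {
  d <- dim(object@values)
  cat(sprintf("VoxelMask %d x %d x %d (z,y,x), %d foreground voxels\n",
              d[1], d[2], d[3], sum(object@values)))
  show(object@spacing)
})

setMethod("show", "LabeledMask", function(object) {
  d <- dim(object@labels)
  cat(sprintf("LabeledMask %d x %d x %d (z,y,x), %d components\n",
              d[1], d[2], d[3], length(object@sizes)))
})

setMethod("show", "VesselSkeleton", function(object) {
  cat(sprintf("VesselSkeleton: %d voxels in a %s grid\n",
              nrow(object@coords), paste(object@dims, collapse = " x ")))
})

setMethod("show", "VesselGraph", function(object) {
  cat(sprintf(paste0("VesselGraph: %d nodes (%d endpoints, %d branchpoints),",
                     " %d edges, total length %.1f um\n"),
              nrow(object@nodes), endpointCount(object),
              branchpointCount(object), nrow(object@edges),
              totalNetworkLength(object)))
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf(paste0("PhantomSpec: %s voxels, axis %g um, %d longitudinal",
                     " vessels, density factor %.2f, seed %d\n"),
              paste(object@volumeDim, collapse = " x "), object@axisLength,
              object@nLongitudinal, object@initialDensityFactor, object@seed))
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth: %d tubes (%s)\n", nrow(object@tubes),
              paste(sprintf("%d %s", table(object@tubes$type),
                            names(table(object@tubes$type))), collapse = ", ")))
  show(object@graph)
})

setMethod("show", "UTestResult", function(object) {
  cat(sprintf("Mann-Whitney U: U = %g (n1 = %d, n2 = %d), two-sided p = %.4g [%s]\n",
              object@uStatistic, object@n1, object@n2, object@pTwoSided,
              object@method))
})
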