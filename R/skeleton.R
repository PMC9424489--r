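#' Skeletonize a binary mask
#'
#' Homotopy-preserving 3D thinning of the mask to a unit-width medial voxel
#' set. Thinning removes simple border points in six directional
#' subiterations per pass, deleting sequentially with re-testing, so the
#' number of connected components (and all topology) of the mask is
#' preserved exactly and curve endpoints are retained. Anisotropic spacing
#' is handled by measuring every length and radius in physical units rather
#' than by resampling the grid. Each skeleton voxel carries a radius: the
#' spacing-aware Euclidean distance (um) from the voxel centre to the
#' nearest background voxel centre of the source mask (the grid boundary
#' counts as background). This estimate carries a positive bias of up to one
#' voxel step; no half-voxel correction is applied.
#'
#' @param mask a \linkS4class{VoxelMask}
#' @return A \linkS4class{VesselSkeleton}; empty for an empty mask.
#' @examples
#' m <- array(FALSE, c(10, 5, 5)); m[2:9, 3, 3] <- TRUE
#' sk <- skeletonize(voxelMask(m, c(1, 1, 1)))
#' nrow(skeletonCoords(sk))
#' @export
skeletonize <- function(mask) {
  stopifnot(is(mask, "VoxelMask"))
  v <- mask@values
  d <- dim(v)
  sp <- spacingVec(mask)
  if (!any(v)) {
    return(new("VesselSkeleton",
               coords = matrix(integer(), 0, 3,
                               dimnames = list(NULL, c("z", "y", "x"))),
               radii = numeric(), dims = d, spacing = mask@spacing))
  }
  sk <- cpp_skeletonize(v, d)
  idx <- which(sk)
  z <- (idx - 1L) %% d[1] + 1L
  y <- ((idx - 1L) %/% d[1]) %% d[2] + 1L
  x <- (idx - 1L) %/% (d[1] * d[2]) + 1L
  ord <- order(z, y, x) # lexicographic (z, y, x) for reproducible downstream scans
  co <- cbind(z = z[ord], y = y[ord], x = x[ord])
  edt <- sqrt(cpp_edt_sq(v, d, sp[1], sp[2], sp[3], TRUE))
  new("VesselSkeleton", coords = co, radii = edt[idx][ord], dims = d,
      spacing = mask@spacing)
}

#' Skeleton voxel accessors
#'
#' @param x a \linkS4class{VesselSkeleton}
#' @return \code{skeletonCoords}: integer matrix of 1-based (z, y, x) voxel
#'   coordinates; \code{skeletonRadii}: physical radii (um).
#' @export
skeletonCoords <- function(x) {
  stopifnot(is(x, "VesselSkeleton"))
  x@coords
}

#' @rdname skeletonCoords
#' @export
skeletonRadii <- function(x) {
  stopifnot(is(x, "VesselSkeleton"))
  x@radii
}

#' Export a skeleton as a mask
#'
#' @param x a \linkS4class{VesselSkeleton}
#' @return A \linkS4class{VoxelMask} with the skeleton voxels set.
#' @export
skeletonMask <- function(x) {
  stopifnot(is(x, "VesselSkeleton"))
  v <- array(FALSE, x@dims)
  if (nrow(x@coords)) v[x@coords] <- TRUE
  voxelMask(v, x@spacing)
}
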