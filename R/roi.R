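#' ROI masking parameters
#'
#' Parameters of the tissue region-of-interest stage: a slice-wise concave
#' hull of the tissue at scale \code{alpha} followed by a global erosion of
#' physical depth \code{erosionRadius}, so that analysis is restricted to the
#' interior of the sample, away from its cut or cleared surface. Neither
#' value is dictated by the acquisition; the defaults are sized to the
#' portal-tract scale (tract diameters of roughly 60-400 um).
#'
#' @param alpha concave-hull tightness (um, radius-like); larger bridges
#'   wider indentations, `Inf`-like values approach the convex hull
#' @param erosionRadius physical erosion depth (um)
#' @param tissueThreshold intensity separating tissue from the empty bath
#' @return A named list of class \code{RoiParams}.
#' @examples
#' roiParams(alpha = 100, erosionRadius = 50, tissueThreshold = 10)
#' @export
roiParams <- function(alpha = 100, erosionRadius = 50, tissueThreshold = 0) {
  if (alpha <= 0) stop("alpha must be > 0", call. = FALSE)
  if (erosionRadius < 0) stop("erosionRadius must be >= 0", call. = FALSE)
  structure(list(alpha = alpha, erosionRadius = erosionRadius,
                 tissueThreshold = tissueThreshold), class = "RoiParams")
}

#' Threshold a volume into a crude tissue mask
#'
#' Foreground wherever intensity >= \code{threshold}; the starting point for
#' the slice-wise hull.
#'
#' @param volume an \linkS4class{ImageVolume}
#' @param threshold intensity level within the volume's range
#' @return A \linkS4class{VoxelMask}.
#' @export
tissueMask <- function(volume, threshold) {
  stopifnot(is(volume, "ImageVolume"))
  rng <- range(volume@values)
  if (threshold > rng[2] + 1e-9)
    warning("threshold ", threshold, " above the intensity maximum ",
            rng[2], "; the tissue mask is empty")
  voxelMask(volume@values >= threshold, volume@spacing)
}

# distance (um) from each voxel to the nearest background voxel centre
distanceToBackground <- function(values, sp, padOutside = TRUE) {
  sqrt(cpp_edt_sq(values, dim(values), sp[1], sp[2], sp[3], padOutside))
}

# distance (um) from each voxel to the nearest foreground voxel centre
distanceToForeground <- function(values, sp) {
  sqrt(cpp_edt_sq(!values, dim(values), sp[1], sp[2], sp[3], FALSE))
}

# fill bounded background cavities of a (1, ny, nx) slice (4-connectivity)
fillHoles2D <- function(m3) {
  cc <- cpp_label_components(!m3, dim(m3), 6L)
  lab <- cc$labels
  border <- unique(c(lab[1, 1, ], lab[1, dim(m3)[2], ], lab[1, , 1],
                     lab[1, , dim(m3)[3]]))
  border <- border[border > 0L]
  m3 | (lab > 0L & !(lab %in% border))
}

#' Concave hull of one mask slice
#'
#' Filled concave hull (alpha-hull) of the foreground pixel centres of a 2D
#' slice, computed as morphological closing with a disc of physical radius
#' \code{alpha} followed by filling of enclosed cavities. By the
#' union-of-balls characterization of the alpha-hull, the closing is exactly
#' the filled hull at scale alpha: indentations narrower than a radius-alpha
#' disc are bridged, wider ones stay open, and as alpha grows the result
#' converges to the filled convex hull. The output is always a superset of
#' the input; slices with fewer than 3 foreground pixels are returned
#' unchanged.
#'
#' @param sliceMask 2D logical matrix (y, x)
#' @param alpha hull scale in um
#' @param spacing numeric(2) pixel size (dy, dx) in um, or a
#'   \linkS4class{VoxelSpacing}
#' @return A 2D logical matrix.
#' @examples
#' m <- matrix(FALSE, 20, 20); m[5:15, 5:15] <- TRUE
#' identical(sliceConcaveHull(m, 10, c(1, 1)), m)  # convex input unchanged
#' @export
sliceConcaveHull <- function(sliceMask, alpha, spacing = c(1, 1)) {
  if (is(spacing, "VoxelSpacing")) spacing <- spacingVec(spacing)[2:3]
  stopifnot(is.matrix(sliceMask), is.logical(sliceMask), alpha > 0)
  if (sum(sliceMask) < 3L) return(sliceMask)
  dy <- spacing[1]; dx <- spacing[2]
  pad <- ceiling(alpha / min(dy, dx)) + 2L
  ny <- nrow(sliceMask); nx <- ncol(sliceMask)
  big <- matrix(FALSE, ny + 2L * pad, nx + 2L * pad)
  big[pad + seq_len(ny), pad + seq_len(nx)] <- sliceMask
  m3 <- array(big, c(1L, dim(big)))
  # huge dz keeps the single-slice embedding two-dimensional: the padded
  # z-neighbours sit effectively at infinity
  sp <- c(1e9, dy, dx)
  dil <- distanceToForeground(m3, sp) <= alpha + 1e-9
  ero <- distanceToBackground(dil, sp, padOutside = TRUE) > alpha + 1e-9
  out <- fillHoles2D(ero | m3)
  out[1, pad + seq_len(ny), pad + seq_len(nx)] | sliceMask
}

#' Stacked slice-wise concave hull of a tissue mask
#'
#' Applies [sliceConcaveHull()] to every z-slice of a mask, reproducing the
#' slice-wise hull of an imaged tissue block.
#'
#' @param mask a \linkS4class{VoxelMask}
#' @param alpha hull scale in um
#' @return A \linkS4class{VoxelMask}.
#' @export
tissueHull <- function(mask, alpha) {
  stopifnot(is(mask, "VoxelMask"))
  sp <- spacingVec(mask)
  v <- mask@values
  out <- v
  for (z in seq_len(dim(v)[1]))
    out[z, , ] <- sliceConcaveHull(v[z, , ], alpha, sp[2:3])
  voxelMask(out, mask@spacing)
}

#' Erode a mask by a physical depth
#'
#' Morphological erosion with a spacing-aware ellipsoidal structuring element
#' of physical radius \code{erosionRadius}, so anisotropic grids erode by the
#' same depth in micrometres along every axis. Implemented as thresholding of
#' the Euclidean distance transform, which is exactly Minkowski erosion by
#' the digital ellipsoid. The grid boundary counts as background.
#'
#' @param mask a \linkS4class{VoxelMask} (typically the stacked tissue hull)
#' @param erosionRadius physical erosion depth in um; 0 is the identity
#' @return A \linkS4class{VoxelMask}, always a subset of the input. A warning
#'   is raised when the erosion empties the mask.
#' @export
innerVolume <- function(mask, erosionRadius) {
  stopifnot(is(mask, "VoxelMask"), erosionRadius >= 0)
  if (erosionRadius == 0) return(mask)
  sp <- spacingVec(mask)
  keep <- distanceToBackground(mask@values, sp, padOutside = TRUE) >
    erosionRadius + 1e-9
  out <- mask@values & keep
  if (!any(out) && any(mask@values))
    warning("erosion by ", erosionRadius, " um removed the entire mask")
  voxelMask(out, mask@spacing)
}

#' Apply the full ROI stage to a volume
#'
#' Tissue threshold, slice-wise concave hull, then global erosion; returns
#' the inner-volume mask used to zero voxels outside the tissue interior
#' before segmentation.
#'
#' @param volume an \linkS4class{ImageVolume}
#' @param params a [roiParams()] list
#' @return A \linkS4class{VoxelMask}.
#' @export
roiMask <- function(volume, params) {
  stopifnot(inherits(params, "RoiParams"))
  m <- tissueMask(volume, params$tissueThreshold)
  h <- tissueHull(m, params$alpha)
  innerVolume(h, params$erosionRadius)
}
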