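#' Segmentation parameters
#'
#' Hysteresis limits, component size threshold, foreground connectivity and
#' the curated exclusion list. The hysteresis limits are a per-volume choice
#' (set manually per volume in the original workflow); \code{low = NA} /
#' \code{high = NA} requests the declared automatic rule
#' (mean + 2 SD / mean + 4 SD of the analysed intensities, see
#' [suggestThresholds()]), intended for the synthetic experiments.
#'
#' @param low,high lower and upper hysteresis limits (intensity units),
#'   \code{low <= high}; NA for the automatic rule
#' @param minSize component size threshold in voxels (>= 1)
#' @param connectivity foreground connectivity: 6, 18 or 26
#' @param excludedLabels integer component labels removed by curation
#' @return A named list of class \code{SegmentationParams}.
#' @examples
#' segmentationParams(low = 60, high = 110, minSize = 500)
#' @export
segmentationParams <- function(low = NA_real_, high = NA_real_,
                               minSize = 500L, connectivity = 26L,
                               excludedLabels = integer()) {
  if (!is.na(low) && !is.na(high) && low > high)
    stop("low must be <= high", call. = FALSE)
  if (minSize < 1) stop("minSize must be >= 1", call. = FALSE)
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("connectivity must be 6, 18 or 26", call. = FALSE)
  structure(list(low = low, high = high, minSize = as.integer(minSize),
                 connectivity = as.integer(connectivity),
                 excludedLabels = as.integer(excludedLabels)),
            class = "SegmentationParams")
}

#' Automatic hysteresis limits
#'
#' The declared default rule for synthetic volumes: the upper limit is
#' mean + kHigh standard deviations and the lower limit mean + kLow standard
#' deviations of the intensities (optionally restricted to an ROI mask).
#'
#' @param volume an \linkS4class{ImageVolume}
#' @param roi optional \linkS4class{VoxelMask} restricting the statistics
#' @param kLow,kHigh SD multiples for the lower/upper limit
#' @return Named numeric \code{c(low = , high = )}.
#' @export
suggestThresholds <- function(volume, roi = NULL, kLow = 2, kHigh = 4) {
  stopifnot(is(volume, "ImageVolume"))
  v <- volume@values
  if (!is.null(roi)) {
    stopifnot(is(roi, "VoxelMask"))
    checkSameGeometry(v, roi@values)
    v <- v[roi@values]
  }
  m <- mean(v); s <- sd(v)
  c(low = m + kLow * s, high = m + kHigh * s)
}

#' Hysteresis thresholding of a volume
#'
#' A voxel is foreground iff its intensity is >= \code{low} and it is
#' connected, through voxels of intensity >= \code{low}, to at least one
#' voxel of intensity >= \code{high} (both limits inclusive). Keeps dim
#' vessel stretches only when anchored to a bright core, which suits thin
#' bright tubes over dim parenchymal background.
#'
#' @param volume an \linkS4class{ImageVolume}
#' @param low,high hysteresis limits, \code{low <= high}
#' @param connectivity 6, 18 or 26 (default 26, keeping diagonal runs of
#'   thin vessels connected)
#' @return A \linkS4class{VoxelMask}.
#' @examples
#' v <- imageVolume(array(c(1, 5, 1, 9, 1), c(5, 1, 1)), c(1, 1, 1))
#' sum(imgData(hysteresisThreshold(v, low = 4, high = 8)))  # only the 9
#' @export
hysteresisThreshold <- function(volume, low, high, connectivity = 26L) {
  stopifnot(is(volume, "ImageVolume"))
  if (low > high) stop("low must be <= high", call. = FALSE)
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("connectivity must be 6, 18 or 26", call. = FALSE)
  v <- volume@values
  out <- cpp_hysteresis(v, dim(v), low, high, as.integer(connectivity))
  voxelMask(out, volume@spacing)
}

#' Connected component labelling
#'
#' Maximal connected components of a binary mask under the stated
#' connectivity. Labels are deterministic: components are numbered by the
#' lexicographic (z, y, x) order of their smallest member voxel.
#'
#' @param mask a \linkS4class{VoxelMask}
#' @param connectivity 6, 18 or 26
#' @return A \linkS4class{LabeledMask}.
#' @export
labelComponents <- function(mask, connectivity = 26L) {
  stopifnot(is(mask, "VoxelMask"))
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("connectivity must be 6, 18 or 26", call. = FALSE)
  v <- mask@values
  cc <- cpp_label_components(v, dim(v), as.integer(connectivity))
  new("LabeledMask", labels = cc$labels, spacing = mask@spacing,
      sizes = cc$sizes)
}

#' Per-component report for curation
#'
#' Sizes and physical centroids of all components, the audit table from
#' which incorrectly segmented structures (for example blood vessels picked
#' up by the stain) are selected for exclusion.
#'
#' @param labeled a \linkS4class{LabeledMask}
#' @return data.frame with columns id, size_voxels, centroid_z_um,
#'   centroid_y_um, centroid_x_um.
#' @seealso [filterComponents()]
#' @export
componentTable <- function(labeled) {
  stopifnot(is(labeled, "LabeledMask"))
  k <- length(labeled@sizes)
  if (k == 0L)
    return(data.frame(id = integer(), size_voxels = integer(),
                      centroid_z_um = numeric(), centroid_y_um = numeric(),
                      centroid_x_um = numeric()))
  sp <- spacingVec(labeled)
  idx <- which(labeled@labels > 0L)
  lab <- labeled@labels[idx]
  d <- dim(labeled@labels)
  z <- (idx - 1L) %% d[1] + 1L
  y <- ((idx - 1L) %/% d[1]) %% d[2] + 1L
  x <- (idx - 1L) %/% (d[1] * d[2]) + 1L
  data.frame(
    id = seq_len(k),
    size_voxels = as.integer(labeled@sizes),
    centroid_z_um = as.numeric(tapply((z - 1) * sp[1], lab, mean)),
    centroid_y_um = as.numeric(tapply((y - 1) * sp[2], lab, mean)),
    centroid_x_um = as.numeric(tapply((x - 1) * sp[3], lab, mean)))
}

#' Filter components by size and curated exclusions
#'
#' Keeps the voxels of components whose size is >= \code{minSize} and whose
#' label is not in \code{excludedLabels}; the reproducible counterpart of
#' expert removal of incorrectly segmented structures.
#'
#' @param labeled a \linkS4class{LabeledMask}
#' @param minSize minimum component size in voxels
#' @param excludedLabels integer labels to drop; labels that do not exist
#'   raise a warning, not an error
#' @return A \linkS4class{VoxelMask}.
#' @export
filterComponents <- function(labeled, minSize = 1L,
                             excludedLabels = integer()) {
  stopifnot(is(labeled, "LabeledMask"), minSize >= 1)
  k <- length(labeled@sizes)
  excludedLabels <- as.integer(excludedLabels)
  absent <- setdiff(excludedLabels, seq_len(k))
  if (length(absent))
    warning("excluded labels not present: ", paste(absent, collapse = ", "))
  keep <- which(labeled@sizes >= minSize)
  keep <- setdiff(keep, excludedLabels)
  out <- array(labeled@labels %in% keep, dim(labeled@labels))
  if (!any(out) && k > 0L)
    warning("no component survived size/exclusion filtering; mask is empty")
  voxelMask(out, labeled@spacing)
}
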