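#' Read a 3D image volume from a multi-page TIFF stack
#'
#' One z-slice per page, axis order (z, y, x) with z the light-sheet stepping
#' axis. Integer TIFFs (8/16 bit) are read bit-exactly; 32-bit float TIFFs
#' are read as stored. The physical voxel spacing is not carried by TIFF and
#' must be supplied; the paper-style acquisition steps 2 um in z while the
#' lateral pixel size depends on magnification, so all three are explicit.
#'
#' @param path path to an existing multi-page TIFF stack
#' @param spacing a \linkS4class{VoxelSpacing} or numeric(3) (dz, dy, dx) in um
#' @param channel channel to select when pages carry several (default 1)
#' @return An \linkS4class{ImageVolume}.
#' @examples
#' vol <- imageVolume(array(1:24, c(2, 3, 4)), c(2, 2, 2))
#' f <- tempfile(fileext = ".tif")
#' writeVolume(vol, f)
#' identical(imgData(readVolume(f, c(2, 2, 2))), imgData(vol))
#' @seealso [writeVolume()], [readMask()]
#' @export
readVolume <- function(path, spacing, channel = 1L) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) {
      if (dim(p)[3] < channel)
        stop("page has ", dim(p)[3], " channels; cannot select channel ",
             channel, call. = FALSE)
      p <- p[, , channel]
    }
    if (length(dim(p)) != 2L)
      stop("TIFF pages must be 2D slices (got ", length(dim(p)),
           " dimensions): not a 3D volume", call. = FALSE)
    p
  })
  d2 <- dim(pages[[1]])
  if (!all(vapply(pages, function(p) identical(dim(p), d2), logical(1))))
    stop("TIFF pages differ in shape; not a single 3D dataset", call. = FALSE)
  vals <- array(0, c(length(pages), d2))
  for (z in seq_along(pages)) {
    p <- pages[[z]]
    if (!is.numeric(p)) stop("non-numeric pixel data in ", path, call. = FALSE)
    vals[z, , ] <- p
  }
  imageVolume(vals, spacing)
}

#' Write a 3D image volume as a multi-page TIFF stack
#'
#' Non-negative integer-valued volumes up to 65535 are stored as 16-bit
#' (lossless round trip); other volumes must lie in [0, 1] and are stored as
#' 32-bit float.
#'
#' @param volume an \linkS4class{ImageVolume}
#' @param path output path
#' @return \code{path}, invisibly.
#' @seealso [readVolume()]
#' @export
writeVolume <- function(volume, path) {
  stopifnot(is(volume, "ImageVolume"))
  v <- volume@values
  is_int <- all(v == round(v))
  if (is_int && max(v) <= 65535) {
    pages <- lapply(seq_len(dim(v)[1]), function(z) v[z, , ] / 65535)
    suppressWarnings(tiff::writeTIFF(pages, path, bits.per.sample = 16L,
                                     reduce = FALSE, compression = "deflate"))
  } else if (max(v) <= 1) {
    pages <- lapply(seq_len(dim(v)[1]), function(z) v[z, , ])
    tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  } else {
    stop("volumes must be integer counts (<= 65535) or lie in [0, 1] ",
         "to be stored losslessly as TIFF", call. = FALSE)
  }
  invisible(path)
}

#' Read and write binary masks as TIFF
#'
#' Masks are stored as 8-bit stacks of 0/255, one z-slice per page, and
#' round-trip losslessly.
#'
#' @param mask a \linkS4class{VoxelMask}
#' @param path file path
#' @param spacing a \linkS4class{VoxelSpacing} or numeric(3) in um
#' @return \code{writeMask} returns \code{path} invisibly; \code{readMask}
#'   returns a \linkS4class{VoxelMask}.
#' @examples
#' m <- voxelMask(array(c(TRUE, FALSE), c(2, 2, 2)), c(2, 2, 2))
#' f <- tempfile(fileext = ".tif")
#' writeMask(m, f)
#' identical(imgData(readMask(f, c(2, 2, 2))), imgData(m))
#' @export
writeMask <- function(mask, path) {
  stopifnot(is(mask, "VoxelMask"))
  v <- mask@values
  pages <- lapply(seq_len(dim(v)[1]), function(z) v[z, , ] * 1.0)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L, reduce = FALSE,
                  compression = "deflate")
  invisible(path)
}

#' @rdname writeMask
#' @export
readMask <- function(path, spacing) {
  vol <- readVolume(path, spacing)
  voxelMask(vol@values > 0, vol@spacing)
}
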