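# internal helpers

# evaluate expr under a local RNG seed, restoring the caller's RNG state
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# arc length of a polyline given as n x 3 matrix of um coordinates
polylineLength <- function(pl) {
  if (nrow(pl) < 2L) return(0)
  sum(sqrt(rowSums((pl[-1L, , drop = FALSE] - pl[-nrow(pl), , drop = FALSE])^2)))
}

# voxel (z,y,x) 1-based -> physical um coordinates (voxel centres)
voxelToUm <- function(coords, sp) {
  sweep(coords - 1, 2, sp, "*")
}

stopIfNot3D <- function(a, what) {
  if (length(dim(a)) != 3L)
    stop(what, " must be a 3D array (z, y, x)", call. = FALSE)
}

checkSameGeometry <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop("grids have different shapes: ", paste(dim(a), collapse = "x"),
         " vs ", paste(dim(b), collapse = "x"), call. = FALSE)
}
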