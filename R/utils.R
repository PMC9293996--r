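#' Evaluate code with a temporary RNG seed
#'
#' Sets the seed, runs `code`, and restores the caller's RNG state, so that
#' seeded package internals never disturb the user's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Reflect a 1-based index vector into [1, n] by symmetric (edge-including)
# mirroring; handles offsets larger than the extent by repeated folding.
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  j <- (i - 1L) %% (2L * n)
  j <- ifelse(j < 0L, j + 2L * n, j)
  as.integer(ifelse(j < n, j + 1L, 2L * n - j))
}

# Read a window [lo, hi] (1-based, inclusive, per axis) from a 3D array,
# mirror-padding where the window exceeds the array.
read_window <- function(arr, lo, hi) {
  d <- dim(arr)
  ix <- reflect_index(seq.int(lo[1], hi[1]), d[1])
  iy <- reflect_index(seq.int(lo[2], hi[2]), d[2])
  iz <- reflect_index(seq.int(lo[3], hi[3]), d[3])
  arr[ix, iy, iz, drop = FALSE]
}

# Bounding box of nonzero voxels; NULL if empty.
mask_bbox <- function(m) {
  idx <- which(m != 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(NULL)
  list(lo = apply(idx, 2, min), hi = apply(idx, 2, max))
}

round_half_up <- function(x) floor(x + 0.5)
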