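#' 3D scalar volume with voxel spacing
#'
#' A `Volume` couples a 3D numeric array with its voxel spacing and world
#' origin (both in mm). Arrays are indexed `(x, y, z)`: the first two axes are
#' in-plane, the third runs across slices. Voxels are voxel-centered and
#' 0-based in world coordinates: `world = origin + index * spacing`.
#'
#' @param data 3D numeric array, finite values only.
#' @param spacing numeric length-3, per-axis voxel spacing in mm, all > 0.
#' @param origin numeric length-3, world position of voxel (0,0,0) in mm.
#' @return An object of class `volume`.
#' @export
volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(dim(data)) != 3L)
    stop("volume data must have exactly 3 axes, got ", length(dim(data)))
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive finite values")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be 3 finite values")
  if (anyNA(data) || any(!is.finite(data)))
    stop("volume data contains non-finite values")
  structure(list(data = data, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "volume")
}

#' Binary mask on a volume grid
#'
#' A `mask_volume` is a `volume` whose voxels are restricted to {0, 1}. Masks
#' are used for the liver, for lesion references (one per rater), and for
#' predictions.
#'
#' @inheritParams volume
#' @return An object of classes `mask_volume` and `volume`.
#' @export
mask_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  storage.mode(data) <- "integer"
  if (!all(data %in% c(0L, 1L)))
    stop("mask values must be 0 or 1")
  v <- volume(data, spacing, origin)
  class(v) <- c("mask_volume", "volume")
  v
}

#' @export
print.volume <- function(x, ...) {
  cat(sprintf("<%s> %s voxels, spacing %s mm, origin %s mm\n",
              class(x)[1], paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              paste(signif(x$origin, 4), collapse = ",")))
  invisible(x)
}

#' Check that two volumes share one grid
#'
#' Same shape, and spacing/origin equal within `tol` mm.
#'
#' @param a,b `volume` objects.
#' @param tol tolerance in mm.
#' @keywords internal
same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$data), dim(b$data)) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

stop_if_grid_mismatch <- function(a, b) {
  if (!same_grid(a, b)) stop("volumes do not share a grid")
  invisible(TRUE)
}

#' Read a volume from a NIfTI file
#'
#' Reads a 3D NIfTI image (`.nii` or `.nii.gz`); spacing is taken from the
#' header `pixdim`, the origin from the qform/sform translation.
#'
#' @param path path to a NIfTI file.
#' @param mask logical; if `TRUE` return a [mask_volume()].
#' @return A [volume()] (or [mask_volume()]).
#' @export
read_volume <- function(path, mask = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path, internal = FALSE)
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) {
    img2 <- as.array(img)
    dim(img2) <- d[1:3]
  } else if (length(d) == 3L) {
    img2 <- as.array(img)
  } else {
    stop("expected a 3D image, got ", length(d), " dimensions: ", path)
  }
  attributes(img2) <- list(dim = dim(img2))
  if (anyNA(img2) || any(!is.finite(img2)))
    stop("image contains non-finite voxels: ", path)
  sp <- RNifti::pixdim(img)[1:3]
  xf <- RNifti::xform(img)
  org <- as.numeric(xf[1:3, 4])
  # our convention is axis-aligned LAS-agnostic storage; keep header origin
  if (mask) mask_volume(round(img2), spacing = sp, origin = org)
  else volume(img2, spacing = sp, origin = org)
}

#' Write a volume to a NIfTI file
#'
#' Masks are written as unsigned 8-bit integers, scalar volumes as float64.
#' The header spacing equals `v$spacing`; the origin is stored in the qform.
#'
#' @param v a [volume()] or [mask_volume()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  stopifnot(inherits(v, "volume"))
  is_mask <- inherits(v, "mask_volume")
  dat <- v$data
  storage.mode(dat) <- if (is_mask) "integer" else "double"
  img <- RNifti::asNifti(dat)
  RNifti::pixdim(img) <- v$spacing
  m <- diag(4)
  m[1, 1] <- v$spacing[1]; m[2, 2] <- v$spacing[2]; m[3, 3] <- v$spacing[3]
  m[1:3, 4] <- v$origin
  img <- RNifti::`qform<-`(img, structure(m, code = 2L))
  tryCatch({
    RNifti::writeNifti(img, path,
                       datatype = if (is_mask) "uint8" else "double")
    TRUE
  }, error = function(e) stop("cannot write ", path, ": ", conditionMessage(e)))
  invisible(path)
}
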