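#' Post-processing configuration
#'
#' @param threshold probability threshold in (0, 1); comparison is strict
#'   (`prob > threshold`), so a voxel at exactly the threshold is background.
#' @param erosion_kernel odd extent of the per-slice square kernel eroding
#'   the liver to define the border region (default 7).
#' @param opening_kernel odd extent of the per-slice square opening applied
#'   to tumor voxels within the border region (default 3).
#' @return A `postprocess_config` list.
#' @export
postprocess_config <- function(threshold = 0.5, erosion_kernel = 7L,
                               opening_kernel = 3L) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must lie in (0, 1)")
  if (erosion_kernel %% 2L != 1L || opening_kernel %% 2L != 1L ||
      erosion_kernel < 1L || opening_kernel < 1L)
    stop("kernel extents must be odd and >= 1")
  structure(list(threshold = threshold,
                 erosion_kernel = as.integer(erosion_kernel),
                 opening_kernel = as.integer(opening_kernel)),
            class = "postprocess_config")
}

#' Binarize a probability volume within the liver
#'
#' Voxel is foreground iff `prob > threshold` and the liver mask is 1.
#'
#' @param prob probability [volume()].
#' @param liver liver [mask_volume()] on the same grid.
#' @param threshold probability threshold (strict).
#' @return A [mask_volume()].
#' @export
binarize_in_liver <- function(prob, liver, threshold = 0.5) {
  stop_if_grid_mismatch(prob, liver)
  mask_volume(((prob$data > threshold) & (liver$data == 1L)) + 0L,
              spacing = prob$spacing, origin = prob$origin)
}

#' Remove thin false positives at the liver border
#'
#' The liver mask is eroded with a per-slice square kernel (default 7x7); the
#' border region is the original minus the eroded mask. Tumor voxels inside
#' the border region are filtered with a per-slice opening (default 3x3),
#' which removes thin structures; interior tumor voxels are never modified:
#' `out = (tumor & !border) | opening(tumor & border)`. Kernels act per
#' slice (z extent 1) because slices are thick relative to the in-plane
#' spacing.
#'
#' @param tumor binary tumor [mask_volume()].
#' @param liver liver [mask_volume()] on the same grid.
#' @param cfg a [postprocess_config()].
#' @return Cleaned [mask_volume()], always a subset of the input.
#' @export
border_cleanup <- function(tumor, liver, cfg = postprocess_config()) {
  stop_if_grid_mismatch(tumor, liver)
  eroded <- erode_square_slices(liver$data, cfg$erosion_kernel)
  border <- (liver$data == 1L) & (eroded == 0L)
  inner <- tumor$data * (1L - border)
  at_border <- tumor$data * (border + 0L)
  opened <- open_square_slices(at_border, cfg$opening_kernel)
  # opening is anti-extensive, so `opened` stays inside the border tumor part
  mask_volume(((inner == 1L) | (opened == 1L)) + 0L,
              spacing = tumor$spacing, origin = tumor$origin)
}

#' Full post-processing of a raw model output
#'
#' Thresholding within the liver followed by [border_cleanup()].
#'
#' @inheritParams binarize_in_liver
#' @param cfg a [postprocess_config()].
#' @return A [mask_volume()].
#' @export
postprocess_prediction <- function(prob, liver, cfg = postprocess_config()) {
  border_cleanup(binarize_in_liver(prob, liver, cfg$threshold), liver, cfg)
}
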