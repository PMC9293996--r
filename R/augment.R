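#' Augmentation configuration
#'
#' On-the-fly patch augmentation: independent axis flips (probability 0.5 per
#' axis), contrast rescaling of the voxel-value distance from the patch mean
#' by a factor `a` drawn uniformly from `[0.75, 1.25)`, and a shift of the
#' gray-value mean by `b` drawn from a normal with mean 0 and standard
#' deviation 0.25. Fresh draws are made each time a patch is served.
#'
#' @param flip_prob per-axis flip probability in \[0, 1\].
#' @param contrast_range half-open interval for the contrast factor.
#' @param shift_sd standard deviation of the mean shift, >= 0.
#' @return An `augment_config` list.
#' @export
augment_config <- function(flip_prob = 0.5, contrast_range = c(0.75, 1.25),
                           shift_sd = 0.25) {
  if (flip_prob < 0 || flip_prob > 1) stop("flip_prob must lie in [0, 1]")
  if (contrast_range[1] >= contrast_range[2]) stop("contrast interval empty")
  if (shift_sd < 0) stop("shift_sd must be >= 0")
  structure(list(flip_prob = flip_prob, contrast_range = contrast_range,
                 shift_sd = shift_sd), class = "augment_config")
}

flip_array <- function(a, flips) {
  if (flips[1]) a <- a[rev(seq_len(dim(a)[1])), , , drop = FALSE]
  if (flips[2]) a <- a[, rev(seq_len(dim(a)[2])), , drop = FALSE]
  if (flips[3]) a <- a[, , rev(seq_len(dim(a)[3])), drop = FALSE]
  a
}

#' Augment one training patch
#'
#' Flips are applied identically to image, label, and weight patches; the
#' intensity transform `v' = m + a * (v - m) + b` (with `m` the image-patch
#' mean before the transform) is applied to the image only, so the label
#' stays binary and the weight untouched.
#'
#' @param image,label,weight 3D arrays of one shape.
#' @param cfg an [augment_config()].
#' @param draw optional list with fixed `flips` (logical length 3),
#'   `contrast`, `shift`; when `NULL` they are drawn from the RNG.
#' @return List with transformed `image`, `label`, `weight` and the `draw`
#'   actually used.
#' @export
augment_patch <- function(image, label, weight, cfg = augment_config(),
                          draw = NULL) {
  if (!identical(dim(image), dim(label)) || !identical(dim(image), dim(weight)))
    stop("image, label and weight patches must share one shape")
  if (is.null(draw)) {
    draw <- list(
      flips = stats::runif(3) < cfg$flip_prob,
      contrast = stats::runif(1, cfg$contrast_range[1], cfg$contrast_range[2]),
      shift = stats::rnorm(1, 0, cfg$shift_sd)
    )
  }
  image <- flip_array(image, draw$flips)
  label <- flip_array(label, draw$flips)
  weight <- flip_array(weight, draw$flips)
  if (draw$contrast != 1 || draw$shift != 0) {
    m <- mean(image)
    image <- m + draw$contrast * (image - m) + draw$shift
  }
  list(image = image, label = label, weight = weight, draw = draw)
}
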