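# In-plane resampling to a target spacing and liver-percentile gray-value
# normalization. Slices are never resampled: slice count and slice spacing
# pass through unchanged, so the working voxel size is target x target x z mm.

# 1D linear-interpolation weight matrix mapping n_in samples at spacing
# sp_in onto n_out samples at spacing sp_out, same world origin, clamped at
# the edges. Exact identity when the grids coincide.
resample_weights <- function(n_in, sp_in, n_out, sp_out) {
  pos <- (seq_len(n_out) - 1) * sp_out / sp_in  # continuous 0-based index
  lo <- pmin(pmax(floor(pos), 0), n_in - 1)
  hi <- pmin(lo + 1, n_in - 1)
  w <- pos - lo
  w[hi == lo] <- 0
  W <- matrix(0, n_out, n_in)
  W[cbind(seq_len(n_out), lo + 1)] <- W[cbind(seq_len(n_out), lo + 1)] + (1 - w)
  W[cbind(seq_len(n_out), hi + 1)] <- W[cbind(seq_len(n_out), hi + 1)] + w
  W
}

#' Resample a volume in-plane
#'
#' Resamples the first two axes to `target_mm` (default 1 mm); there is no
#' resampling between slices, so the output spacing is
#' `(target_mm, target_mm, z)` with `z` unchanged. The image is interpolated
#' linearly, masks by nearest neighbor (they stay binary). The new in-plane
#' shape is `round(old_shape * old_spacing / target_mm)` (round half up) and
#' the output grid is anchored at the same world origin.
#'
#' @param v a [volume()].
#' @param target_mm target in-plane spacing in mm, > 0.
#' @param masks optional named list of [mask_volume()]s on `v`'s grid.
#' @return List with `image` and `masks` (resampled).
#' @export
resample_inplane <- function(v, target_mm = 1.0, masks = list()) {
  stopifnot(inherits(v, "volume"))
  if (target_mm <= 0) stop("target_mm must be > 0")
  for (m in masks) stop_if_grid_mismatch(v, m)
  d <- dim(v$data); sp <- v$spacing
  n_out <- as.integer(round_half_up(d[1:2] * sp[1:2] / target_mm))
  Wx <- resample_weights(d[1], sp[1], n_out[1], target_mm)
  Wy <- resample_weights(d[2], sp[2], n_out[2], target_mm)
  out <- array(0, c(n_out, d[3]))
  for (z in seq_len(d[3])) out[, , z] <- Wx %*% v$data[, , z] %*% t(Wy)
  new_sp <- c(target_mm, target_mm, sp[3])
  rimg <- volume(out, spacing = new_sp, origin = v$origin)
  # nearest-neighbor index maps for masks
  ix <- pmin(pmax(round_half_up((seq_len(n_out[1]) - 1) * target_mm / sp[1]) + 1, 1), d[1])
  iy <- pmin(pmax(round_half_up((seq_len(n_out[2]) - 1) * target_mm / sp[2]) + 1, 1), d[2])
  rmasks <- lapply(masks, function(m) {
    mask_volume(m$data[ix, iy, , drop = FALSE], spacing = new_sp,
                origin = m$origin)
  })
  list(image = rimg, masks = rmasks)
}

#' Fit gray-value normalization parameters
#'
#' Computes the low/high gray-value percentiles (defaults 2 and 98) of the
#' voxels inside the liver mask, using linear interpolation between order
#' statistics ([stats::quantile()] type 7).
#'
#' @param v a [volume()].
#' @param liver liver [mask_volume()] on the same grid, nonempty.
#' @param low_rank,high_rank percentile ranks in (0, 100), `low < high`.
#' @return A `normalization_params` list with `low`, `high`, and the ranks.
#' @export
fit_normalization <- function(v, liver, low_rank = 2, high_rank = 98) {
  stop_if_grid_mismatch(v, liver)
  if (low_rank <= 0 || high_rank >= 100 || low_rank >= high_rank)
    stop("percentile ranks must satisfy 0 < low < high < 100")
  vals <- v$data[liver$data == 1L]
  if (length(vals) == 0L) stop("liver mask is empty")
  q <- stats::quantile(vals, c(low_rank, high_rank) / 100,
                       names = FALSE, type = 7)
  if (q[2] <= q[1])
    stop("degenerate gray-value percentiles: case cannot be normalized")
  structure(list(low = q[1], high = q[2],
                 low_rank = low_rank, high_rank = high_rank),
            class = "normalization_params")
}

#' Apply gray-value normalization
#'
#' Linearly maps the fitted low/high percentiles to 0 and 1 over the whole
#' volume, without clipping: values below the low percentile map below 0 and
#' values above the high percentile map above 1.
#'
#' @param v a [volume()].
#' @param p a `normalization_params` object from [fit_normalization()].
#' @return Normalized [volume()].
#' @export
apply_normalization <- function(v, p) {
  stopifnot(inherits(v, "volume"), inherits(p, "normalization_params"))
  volume((v$data - p$low) / (p$high - p$low),
         spacing = v$spacing, origin = v$origin)
}

#' Preprocess one case
#'
#' Resamples in-plane to the configured target spacing, then fits and applies
#' liver-percentile normalization (percentiles are taken on the resampled
#' grid).
#'
#' @param case list with `image`, `liver`, and optionally `lesions` and
#'   `raters` (list of masks).
#' @param cfg `preprocess` block of [default_config()].
#' @return The case with resampled, normalized `image`, resampled masks, and
#'   the fitted `norm` parameters attached.
#' @export
preprocess_case <- function(case, cfg = default_config()$preprocess) {
  masks <- list(liver = case$liver)
  if (!is.null(case$lesions)) masks$lesions <- case$lesions
  extra <- if (!is.null(case$raters)) case$raters else list()
  if (length(extra)) names(extra) <- paste0("rater", seq_along(extra))
  res <- resample_inplane(case$image, cfg$target_mm, c(masks, extra))
  p <- fit_normalization(res$image, res$masks$liver,
                         cfg$low_rank, cfg$high_rank)
  out <- list(image = apply_normalization(res$image, p),
              liver = res$masks$liver,
              lesions = res$masks$lesions,
              norm = p)
  if (length(extra))
    out$raters <- res$masks[names(extra)]
  out
}
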