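#' Specification of a synthetic liver phantom
#'
#' Describes a late-hepatocellular-phase-like test volume: a bright, smooth
#' liver blob containing darker (hypointense) ellipsoidal lesions, on an
#' anisotropic grid, with additive Gaussian noise and an arbitrary global
#' intensity scale/offset emulating the non-standardized gray-value scale of
#' liver MRI. Defaults place the grid in the middle of the published
#' acquisition range (in-plane 0.74-1.76 mm, slices 2-5 mm).
#'
#' @param shape image extent in voxels `(x, y, z)`.
#' @param spacing voxel spacing in mm; in-plane and slice spacing.
#' @param n_lesions number of lesions (>= 0).
#' @param lesion_radius range (mm) of lesion radii; the minimum must exceed
#'   the largest spacing component so every lesion spans >= 1 voxel per axis.
#' @param parenchyma mean gray value of liver parenchyma.
#' @param lesion_fraction lesion intensity as a fraction of parenchyma, in
#'   (0, 1) (hypointense).
#' @param background gray value outside the liver.
#' @param noise_sd standard deviation of additive Gaussian noise.
#' @param scale,offset global affine intensity transform applied last.
#' @param rater_magnitude default per-lesion boundary perturbation (mm) for
#'   [simulate_raters()].
#' @param seed integer seed; identical seeds reproduce identical phantoms.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(shape = c(96L, 96L, 28L),
                         spacing = c(1.2, 1.2, 3.0),
                         n_lesions = 3L,
                         lesion_radius = c(4, 12),
                         parenchyma = 400,
                         lesion_fraction = 0.45,
                         background = 100,
                         noise_sd = 20,
                         scale = 1,
                         offset = 0,
                         rater_magnitude = 2,
                         seed = 1L) {
  if (n_lesions < 0) stop("n_lesions must be >= 0")
  if (lesion_fraction <= 0 || lesion_fraction >= 1)
    stop("lesion_fraction must lie in (0, 1)")
  if (lesion_radius[1] > lesion_radius[2]) stop("lesion_radius range reversed")
  if (lesion_radius[1] <= max(spacing))
    stop("minimum lesion radius must exceed the largest spacing component")
  if (any(spacing <= 0)) stop("spacing must be positive")
  structure(list(shape = as.integer(shape), spacing = as.numeric(spacing),
                 n_lesions = as.integer(n_lesions),
                 lesion_radius = as.numeric(lesion_radius),
                 parenchyma = parenchyma, lesion_fraction = lesion_fraction,
                 background = background, noise_sd = noise_sd,
                 scale = scale, offset = offset,
                 rater_magnitude = rater_magnitude, seed = as.integer(seed)),
            class = "phantom_spec")
}

# Ellipsoid voxel set (logical array) around a center (mm), radius (mm).
ellipsoid_mask <- function(shape, spacing, center_mm, radii_mm) {
  x <- (seq_len(shape[1]) - 1) * spacing[1]
  y <- (seq_len(shape[2]) - 1) * spacing[2]
  z <- (seq_len(shape[3]) - 1) * spacing[3]
  dx2 <- ((x - center_mm[1]) / radii_mm[1])^2
  dy2 <- ((y - center_mm[2]) / radii_mm[2])^2
  dz2 <- ((z - center_mm[3]) / radii_mm[3])^2
  r2 <- outer(outer(dx2, dy2, `+`), dz2, `+`)
  r2 <= 1
}

#' Generate a synthetic liver phantom
#'
#' Builds the image, the liver mask, and the ground-truth lesion mask for a
#' [phantom_spec()]. The liver is an ellipsoid with a low-frequency random
#' boundary perturbation; lesions are ellipsoids placed fully inside the liver
#' by rejection sampling (cap 1000 retries per lesion), pairwise disjoint with
#' a one-voxel gap so each is a separate 6-connected component.
#'
#' @param spec a [phantom_spec()].
#' @return List with elements `image` ([volume()]), `liver`, `lesions`
#'   (both [mask_volume()]).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, {
    d <- spec$shape; sp <- spec$spacing
    ext <- (d - 1) * sp
    ctr <- ext / 2
    semi <- ext * c(0.36, 0.33, 0.38)
    x <- (seq_len(d[1]) - 1) * sp[1] - ctr[1]
    y <- (seq_len(d[2]) - 1) * sp[2] - ctr[2]
    z <- (seq_len(d[3]) - 1) * sp[3] - ctr[3]
    X <- array(x, d)
    Y <- aperm(array(y, d[c(2, 1, 3)]), c(2, 1, 3))
    Z <- aperm(array(z, d[c(3, 1, 2)]), c(2, 3, 1))
    R <- sqrt((X / semi[1])^2 + (Y / semi[2])^2 + (Z / semi[3])^2)
    theta <- atan2(Y / semi[2], X / semi[1])
    u <- ifelse(R > 0, (Z / semi[3]) / pmax(R, 1e-9), 0)
    cf <- stats::runif(5, -1, 1)
    pert <- 0.06 * (cf[1] * cos(theta) + cf[2] * sin(theta) +
                      cf[3] * cos(2 * theta) + cf[4] * sin(2 * theta) +
                      cf[5] * u)
    liver <- (R <= 1 + pert) + 0L
    dim(liver) <- d

    lesions <- array(0L, d)
    blocked <- array(0L, d)  # lesions dilated by one voxel: separation zone
    placed <- 0L
    if (spec$n_lesions > 0L) {
      liver_idx <- which(liver == 1L)
      for (i in seq_len(spec$n_lesions)) {
        ok <- FALSE
        for (try in seq_len(1000L)) {
          r_mm <- stats::runif(1, spec$lesion_radius[1], spec$lesion_radius[2])
          # mild anisotropy of the lesion shape
          rad <- r_mm * stats::runif(3, 0.8, 1.2)
          cvox <- liver_idx[sample.int(length(liver_idx), 1L)]
          ci <- arrayInd(cvox, d)
          cmm <- (ci - 1) * sp
          les <- ellipsoid_mask(d, sp, cmm, rad)
          if (any(les & liver == 0L)) next
          if (any(les & blocked == 1L)) next
          lesions[les] <- 1L
          blocked <- blocked | dilate_offsets(les + 0L, ellipsoid_offsets(c(1, 1, 1)))
          ok <- TRUE
          placed <- placed + 1L
          break
        }
        if (!ok) stop("could not place lesion ", i,
                      " disjointly after 1000 retries")
      }
    }
    img <- array(spec$background, d)
    img[liver == 1L] <- spec$parenchyma
    img[lesions == 1L] <- spec$lesion_fraction * spec$parenchyma
    img <- img + stats::rnorm(length(img), 0, spec$noise_sd)
    img <- spec$scale * img + spec$offset
    dim(img) <- d
    list(image = volume(img, spacing = sp),
         liver = mask_volume(liver, spacing = sp),
         lesions = mask_volume(lesions + 0L, spacing = sp))
  })
}

#' Simulate disagreeing raters from a lesion mask
#'
#' Produces `n_raters` independent variants of a reference lesion mask by
#' perturbing each lesion with a random morphological dilation or erosion of
#' physical radius up to `magnitude` mm (converted to per-axis voxel radii, so
#' anisotropic grids perturb plausibly), and by randomly dropping small
#' lesions (equivalent radius below `drop_radius` mm) with probability
#' `drop_prob`. Deterministic for a given `seed`.
#'
#' @param lesions reference lesion [mask_volume()].
#' @param n_raters number of variants (>= 1).
#' @param magnitude maximal boundary shift in mm.
#' @param seed integer seed.
#' @param drop_prob probability of dropping a small lesion.
#' @param drop_radius size threshold (mm, equivalent sphere radius) below
#'   which a lesion may be dropped.
#' @param liver optional liver [mask_volume()]; dilations are clipped to it.
#' @return List of `n_raters` [mask_volume()] objects.
#' @export
simulate_raters <- function(lesions, n_raters, magnitude = 2, seed = 1L,
                            drop_prob = 0.1, drop_radius = 5, liver = NULL) {
  stopifnot(inherits(lesions, "mask_volume"), n_raters >= 1)
  sp <- lesions$spacing
  lab <- label_lesions(lesions)
  k <- max(lab)
  voxvol <- prod(sp)
  with_seed(seed, {
    lapply(seq_len(n_raters), function(rr) {
      out <- array(0L, dim(lesions$data))
      for (l in seq_len(k)) {
        comp <- (lab == l) + 0L
        vol_mm3 <- sum(comp) * voxvol
        eq_r <- (3 * vol_mm3 / (4 * pi))^(1 / 3)
        if (eq_r < drop_radius && stats::runif(1) < drop_prob) next
        delta <- stats::runif(1, -magnitude, magnitude)
        rv <- round(abs(delta) / sp)
        if (any(rv >= 1)) {
          offs <- ellipsoid_offsets(rv)
          comp <- if (delta > 0) dilate_offsets(comp, offs)
                  else erode_offsets(comp, offs)
        }
        out <- out | comp
      }
      out <- out + 0L
      if (!is.null(liver)) out <- out * liver$data
      mask_volume(out, spacing = sp, origin = lesions$origin)
    })
  })
}

#' Generate a batch of phantom study cases
#'
#' Produces `n` reproducible cases. Per case the global intensity scale and
#' offset are drawn (scale in \[0.7, 1.3\], offset in \[-60, 60\]) to emulate
#' the non-standardized gray-value scale across acquisitions; lesion count,
#' radii, spacing and noise come from `spec`. Optionally simulates raters
#' and runs the standard preprocessing (1 mm in-plane resampling, 2/98
#' percentile normalization).
#'
#' @param n number of cases.
#' @param base_seed seed of case 1; case i uses `base_seed + i - 1`.
#' @param n_raters rater variants to simulate per case (0 for none).
#' @param spec template [phantom_spec()].
#' @param preprocess run [preprocess_case()] on each case.
#' @return List of cases (`image`, `liver`, `lesions`, optionally `raters`).
#' @export
phantom_cases <- function(n, base_seed = 1L, n_raters = 0L,
                          spec = phantom_spec(), preprocess = TRUE) {
  lapply(seq_len(n), function(i) {
    seed_i <- base_seed + i - 1L
    sp <- spec
    sp$seed <- seed_i
    with_seed(seed_i + 900000L, {
      sp$scale <- stats::runif(1, 0.7, 1.3)
      sp$offset <- stats::runif(1, -60, 60)
    })
    ph <- generate_phantom(sp)
    case <- list(image = ph$image, liver = ph$liver, lesions = ph$lesions)
    if (n_raters > 0L)
      case$raters <- simulate_raters(ph$lesions, n_raters,
                                     magnitude = sp$rater_magnitude,
                                     seed = seed_i + 500000L,
                                     liver = ph$liver)
    if (preprocess) preprocess_case(case) else case
  })
}
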