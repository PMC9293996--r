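test_that("in-plane resampling halves 2 mm spacing to the expected grid", {
  set.seed(3)
  v <- volume(array(rnorm(64 * 64 * 20), c(64, 64, 20)),
              spacing = c(2, 2, 3.5))
  m <- mask_volume(array(rbinom(64 * 64 * 20, 1, 0.2), c(64, 64, 20)),
                   spacing = c(2, 2, 3.5))
  r <- resample_inplane(v, 1.0, list(m = m))
  expect_identical(dim(r$image$data), c(128L, 128L, 20L))
  expect_equal(r$image$spacing, c(1, 1, 3.5))
  expect_identical(dim(r$masks$m$data), c(128L, 128L, 20L))
  expect_true(all(r$masks$m$data %in% c(0L, 1L)))
  # the slice axis is never resampled
  expect_identical(dim(r$image$data)[3], dim(v$data)[3])
  expect_equal(r$image$spacing[3], v$spacing[3])
})

test_that("resampling an already-1mm grid is the identity", {
  set.seed(4)
  v <- volume(array(rnorm(20 * 18 * 6), c(20, 18, 6)), spacing = c(1, 1, 4))
  m <- mask_volume(array(rbinom(20 * 18 * 6, 1, 0.3), c(20, 18, 6)),
                   spacing = c(1, 1, 4))
  r <- resample_inplane(v, 1.0, list(m = m))
  expect_equal(r$image$data, v$data, tolerance = 1e-12)
  expect_identical(r$masks$m$data, m$data)
})

test_that("mask voxel count scales roughly with resampled area", {
  ph <- generate_phantom(small_phantom_spec(seed = 8))
  r <- resample_inplane(ph$image, 1.0, list(liver = ph$liver))
  scale_factor <- prod(ph$liver$spacing[1:2]) / 1.0
  expected <- sum(ph$liver$data) * scale_factor
  got <- sum(r$masks$liver$data)
  expect_gt(got, 0.5 * expected)
  expect_lt(got, 2.0 * expected)
})

test_that("percentile fit matches the linear-interpolation definition", {
  d <- c(101L, 1L, 1L)
  v <- volume(array(as.numeric(0:100), d))
  liver <- mask_volume(array(1L, d))
  p <- fit_normalization(v, liver, 2, 98)
  expect_equal(p$low, 2.0)
  expect_equal(p$high, 98.0)
  # degenerate constant region cannot be normalized
  vc <- volume(array(5, d))
  expect_error(fit_normalization(vc, liver), "degenerate")
  empty <- mask_volume(array(0L, d))
  expect_error(fit_normalization(v, empty), "empty")
})

test_that("normalization maps percentiles to 0/1 without clipping", {
  d <- c(101L, 1L, 1L)
  v <- volume(array(as.numeric(0:100), d))
  liver <- mask_volume(array(1L, d))
  p <- fit_normalization(v, liver)
  n <- apply_normalization(v, p)
  expect_equal(n$data[v$data == p$low], 0)
  expect_equal(n$data[v$data == p$high], 1)
  # a voxel one full range below the low percentile maps to exactly -1
  v2 <- v; v2$data[1] <- p$low - (p$high - p$low)
  expect_equal(apply_normalization(v2, p)$data[1], -1)
  expect_lt(min(n$data), 0)  # values below the 2nd percentile stay below 0
})

test_that("normalization is invariant to affine gray-value transforms", {
  set.seed(5)
  d <- c(30L, 30L, 5L)
  v <- volume(array(rnorm(prod(d), 100, 25), d))
  liver <- mask_volume(array(rbinom(prod(d), 1, 0.5), d))
  n1 <- apply_normalization(v, fit_normalization(v, liver))
  v2 <- volume(3.7 * v$data - 42, spacing = v$spacing)
  n2 <- apply_normalization(v2, fit_normalization(v2, liver))
  expect_equal(n1$data, n2$data, tolerance = 1e-10)
})

test_that("normalization is idempotent after refit", {
  ph <- generate_phantom(small_phantom_spec(seed = 9))
  case <- preprocess_case(list(image = ph$image, liver = ph$liver,
                               lesions = ph$lesions))
  p2 <- fit_normalization(case$image, case$liver)
  expect_equal(p2$low, 0, tolerance = 1e-10)
  expect_equal(p2$high, 1, tolerance = 1e-10)
})
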