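# Binary morphology helpers. Per-slice square-kernel operations use integral
# images (exact, zero-padded outside the image, so structures touching the
# image edge erode there). Offset-brush operations serve the phantom rater
# simulation and the liver loss-mask dilation.

# Count of ones in a k x k window around every pixel of a binary matrix,
# with zeros assumed outside. k odd.
box_count2d <- function(m, k) {
  r <- (k - 1L) %/% 2L
  nx <- nrow(m); ny <- ncol(m)
  p <- matrix(0, nx + 2L * r, ny + 2L * r)
  p[(r + 1L):(r + nx), (r + 1L):(r + ny)] <- m
  # integral image with a leading zero row/column
  I <- matrix(0, nx + 2L * r + 1L, ny + 2L * r + 1L)
  I[-1L, -1L] <- apply(apply(p, 2L, cumsum), 1L, cumsum) |> t()
  i1 <- 1L:nx; j1 <- 1L:ny
  I[i1 + 2L * r + 1L, j1 + 2L * r + 1L, drop = FALSE] -
    I[i1, j1 + 2L * r + 1L, drop = FALSE] -
    I[i1 + 2L * r + 1L, j1, drop = FALSE] +
    I[i1, j1, drop = FALSE]
}

apply_slices <- function(a, f) {
  out <- a
  for (z in seq_len(dim(a)[3])) out[, , z] <- f(a[, , z])
  out
}

# Per-slice erosion/dilation/opening with a k x k square structuring element.
erode_square_slices <- function(a, k) {
  if (k == 1L) return(a)
  apply_slices(a, function(s) (box_count2d(s, k) == k * k) + 0L)
}

dilate_square_slices <- function(a, k) {
  if (k == 1L) return(a)
  apply_slices(a, function(s) (box_count2d(s, k) > 0) + 0L)
}

open_square_slices <- function(a, k) {
  dilate_square_slices(erode_square_slices(a, k), k)
}

# Integer offsets covering an ellipsoid with per-axis voxel radii r (>= 0).
ellipsoid_offsets <- function(r) {
  r <- pmax(as.integer(round(r)), 0L)
  g <- expand.grid(dx = -r[1]:r[1], dy = -r[2]:r[2], dz = -r[3]:r[3])
  rr <- pmax(r, 1e-9)
  keep <- (g$dx / rr[1])^2 + (g$dy / rr[2])^2 + (g$dz / rr[3])^2 <= 1 + 1e-9
  as.matrix(g[keep, , drop = FALSE])
}

# Shift a 3D binary array by an integer offset, zero-filled.
shift3d <- function(a, off) {
  d <- dim(a)
  out <- array(0L, d)
  sx <- max(1L, 1L + off[1]):min(d[1], d[1] + off[1])
  sy <- max(1L, 1L + off[2]):min(d[2], d[2] + off[2])
  sz <- max(1L, 1L + off[3]):min(d[3], d[3] + off[3])
  if (length(sx) < 1L || length(sy) < 1L || length(sz) < 1L) return(out)
  out[sx, sy, sz] <- a[sx - off[1], sy - off[2], sz - off[3], drop = FALSE]
  out
}

dilate_offsets <- function(a, offs) {
  out <- array(0L, dim(a))
  for (i in seq_len(nrow(offs))) {
    out <- out | shift3d(a, offs[i, ])
  }
  out + 0L
}

erode_offsets <- function(a, offs) {
  out <- array(1L, dim(a))
  for (i in seq_len(nrow(offs))) {
    out <- out & shift3d(a, -offs[i, ])
  }
  out + 0L
}

# Disk offsets in-plane (z radius 0).
disk_offsets <- function(r_xy) {
  g <- expand.grid(dx = -r_xy:r_xy, dy = -r_xy:r_xy, dz = 0L)
  keep <- g$dx^2 + g$dy^2 <= r_xy^2 + 1e-9
  as.matrix(g[keep, , drop = FALSE])
}

# Dilate the liver mask for the loss weight: per-slice disk of radius r_xy
# voxels, then +/- r_z slices in z.
dilate_liver_weight <- function(liver, r_xy = 5L, r_z = 1L) {
  out <- dilate_offsets(liver, disk_offsets(r_xy))
  if (r_z > 0L) {
    zoffs <- cbind(0L, 0L, -r_z:r_z)
    out <- dilate_offsets(out, zoffs)
  }
  out
}
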