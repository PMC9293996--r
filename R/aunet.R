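#' Anisotropic U-Net configuration
#'
#' Describes the encoder-decoder segmentation network: `levels` resolution
#' levels, unpadded (valid) 3x3x1 in-plane convolutions (two per block),
#' in-plane-only 2x2x1 max pooling and transposed-convolution upsampling,
#' crop-and-concatenate skip connections, batch normalization + ReLU after
#' every convolutional block except the last, and a single-channel sigmoid
#' output. Through-plane context enters via unpadded 1x1x3 convolutions in
#' the three lowest-resolution levels only; each in-plane convolution there
#' is followed by `z_convs_per_conv` of them. With the default of 2 this
#' places 20 z-convolutions on the encoder-bottom-decoder path, which
#' reproduces the published patch geometry 236x236x72 -> 52x52x32 (symmetric
#' margin 92x92x20) exactly.
#'
#' @param levels number of resolution levels (>= 2), default 5.
#' @param base_features feature count of the first level; doubled per level.
#' @param max_features cap on the per-level feature count.
#' @param z_levels integer vector of levels carrying 1x1x3 convolutions;
#'   `NULL` means the three lowest-resolution levels.
#' @param z_convs_per_conv number of 1x1x3 convolutions appended after each
#'   in-plane convolution at those levels.
#' @param dropout dropout rate in \[0, 1), applied after the deepest encoder
#'   block.
#' @return A `network_config` list.
#' @export
network_config <- function(levels = 5L, base_features = 32L,
                           max_features = 512L, z_levels = NULL,
                           z_convs_per_conv = 2L, dropout = 0.1) {
  levels <- as.integer(levels)
  if (levels < 2L) stop("levels must be >= 2")
  if (base_features < 1L) stop("base_features must be positive")
  if (dropout < 0 || dropout >= 1) stop("dropout must lie in [0, 1)")
  if (is.null(z_levels))
    z_levels <- if (levels >= 3L) (levels - 2L):levels else integer(0)
  widths <- pmin(base_features * 2L^(0:(levels - 1L)), max_features)
  structure(list(levels = levels, widths = as.integer(widths),
                 z_levels = as.integer(z_levels),
                 z_convs_per_conv = as.integer(z_convs_per_conv),
                 dropout = dropout),
            class = "network_config")
}

# Ordered conv units of one block. Each unit: name, kernel, cin, cout.
block_units <- function(prefix, level, cin, cout, cfg, zk = c(1L, 1L, 3L),
                        inplane_k = c(3L, 3L, 1L)) {
  units <- list()
  add <- function(u) units[[length(units) + 1L]] <<- u
  nzi <- if (level %in% cfg$z_levels) cfg$z_convs_per_conv else 0L
  for (j in 1:2) {
    add(list(name = sprintf("%s.c%d", prefix, j), k = inplane_k,
             cin = if (j == 1) cin else cout, cout = cout))
    if (nzi > 0L) for (m in seq_len(nzi))
      add(list(name = sprintf("%s.z%d.%d", prefix, j, m), k = zk,
               cin = cout, cout = cout))
  }
  units
}

# Full layer plan: encoder blocks, bottom, decoder blocks, final conv.
layer_plan <- function(cfg, full3d = FALSE) {
  L <- cfg$levels; w <- cfg$widths
  zk <- if (full3d) c(3L, 3L, 3L) else c(1L, 1L, 3L)
  enc <- lapply(seq_len(L), function(i) {
    cin <- if (i == 1L) 1L else w[i - 1L]
    block_units(if (i == L) "bottom" else sprintf("enc%d", i), i, cin, w[i],
                cfg, zk = zk)
  })
  dec <- lapply(seq_len(L - 1L), function(i) {
    list(up = list(name = sprintf("up%d", i), cin = w[i + 1L], cout = w[i]),
         units = block_units(sprintf("dec%d", i), i, 2L * w[i], w[i], cfg,
                             zk = zk))
  })
  list(enc = enc, dec = dec,
       final = list(name = "final", k = c(1L, 1L, 1L), cin = w[1L], cout = 1L))
}

#' Count trainable parameters of a network configuration
#'
#' Convolution weights and biases plus batch-normalization scale/shift.
#' With `full3d = TRUE` the through-plane 1x1x3 convolutions are replaced by
#' 3x3x3 convolutions, as in a full 3D U-Net, for comparison.
#'
#' @param cfg a [network_config()].
#' @param full3d replace 1x1x3 kernels by 3x3x3.
#' @return Integer parameter count.
#' @export
count_parameters <- function(cfg, full3d = FALSE) {
  plan <- layer_plan(cfg, full3d = full3d)
  n <- 0
  conv_n <- function(u) prod(u$k) * u$cin * u$cout + u$cout + 2L * u$cout
  for (bl in plan$enc) for (u in bl) n <- n + conv_n(u)
  for (d in plan$dec) {
    n <- n + 4L * d$up$cin * d$up$cout + d$up$cout + 2L * d$up$cout
    for (u in d$units) n <- n + conv_n(u)
  }
  f <- plan$final
  n <- n + prod(f$k) * f$cin * f$cout + f$cout  # final conv: no BN
  n
}

glorot <- function(k_prod, cin, cout) {
  fan_in <- k_prod * cin; fan_out <- k_prod * cout
  lim <- sqrt(6 / (fan_in + fan_out))
  stats::runif(k_prod * cin * cout, -lim, lim)
}

#' Build (initialize) an anisotropic U-Net
#'
#' Allocates all parameters with Glorot-uniform convolution weights, zero
#' biases, and unit-scale batch normalization. Different seeds give
#' differently initialized networks.
#'
#' @param cfg a [network_config()].
#' @param seed integer seed for the weight initialization.
#' @return A `aunet` object (configuration + flat parameter/state lists).
#' @export
build_network <- function(cfg = network_config(), seed = 1L) {
  plan <- layer_plan(cfg)
  params <- list(); state <- list()
  add_conv <- function(u) {
    params[[paste0(u$name, ".W")]] <<-
      array(glorot(prod(u$k), u$cin, u$cout), c(prod(u$k), u$cin, u$cout))
    params[[paste0(u$name, ".b")]] <<- numeric(u$cout)
    params[[paste0(u$name, ".g")]] <<- rep(1, u$cout)
    params[[paste0(u$name, ".be")]] <<- numeric(u$cout)
    state[[paste0(u$name, ".rm")]] <<- numeric(u$cout)
    state[[paste0(u$name, ".rv")]] <<- rep(1, u$cout)
  }
  with_seed(seed, {
    for (bl in plan$enc) for (u in bl) add_conv(u)
    for (d in plan$dec) {
      up <- d$up
      params[[paste0(up$name, ".W")]] <-
        array(glorot(4L, up$cin, up$cout), c(4L, up$cin, up$cout))
      params[[paste0(up$name, ".b")]] <- numeric(up$cout)
      params[[paste0(up$name, ".g")]] <- rep(1, up$cout)
      params[[paste0(up$name, ".be")]] <- numeric(up$cout)
      state[[paste0(up$name, ".rm")]] <- numeric(up$cout)
      state[[paste0(up$name, ".rv")]] <- rep(1, up$cout)
      for (u in d$units) add_conv(u)
    }
    f <- plan$final
    params[[paste0(f$name, ".W")]] <-
      array(glorot(1L, f$cin, f$cout), c(1L, f$cin, f$cout))
    params[[paste0(f$name, ".b")]] <- numeric(f$cout)
  })
  structure(list(cfg = cfg, plan = plan, params = params, state = state,
                 bn_eps = 1e-5, bn_momentum = 0.9, version = 1L),
            class = "aunet")
}

#' Propagate the patch geometry through the network
#'
#' Symbolic shape propagation through every layer of the configuration:
#' returns the exact output extent for a given input extent and the symmetric
#' per-side margin `(input - output) / 2`. For a pure-convolutional valid
#' network the margin is the same for every admissible input extent. Errors
#' name the offending layer when an extent becomes non-positive or an odd
#' extent reaches a pooling step.
#'
#' @param cfg a [network_config()].
#' @param input_extent integer length-3 input patch extent `(x, y, z)`.
#' @return List with `input`, `output`, `margin` (each length 3).
#' @export
compute_patch_geometry <- function(cfg, input_extent) {
  plan <- layer_plan(cfg)
  L <- cfg$levels
  shrink <- function(ext, u) {
    out <- ext - (u$k - 1L)
    if (any(out < 1L))
      stop(sprintf("feature map extent %s too small for layer %s",
                   paste(ext, collapse = "x"), u$name))
    out
  }
  ext <- as.integer(input_extent)
  if (any(ext < 1L)) stop("input extent must be positive")
  skips <- vector("list", L - 1L)
  for (i in seq_len(L)) {
    for (u in plan$enc[[i]]) ext <- shrink(ext, u)
    if (i < L) {
      skips[[i]] <- ext
      if (any(ext[1:2] %% 2L != 0L))
        stop(sprintf("odd in-plane extent %s before pooling at level %d",
                     paste(ext, collapse = "x"), i))
      ext <- c(ext[1:2] %/% 2L, ext[3])
    }
  }
  for (i in rev(seq_len(L - 1L))) {
    ext <- c(2L * ext[1:2], ext[3])  # transposed conv
    d <- skips[[i]] - ext
    if (any(d < 0L) || any(d %% 2L != 0L))
      stop(sprintf(
        "cannot center-crop skip %s to %s at level %d",
        paste(skips[[i]], collapse = "x"), paste(ext, collapse = "x"), i))
    for (u in plan$dec[[i]]$units) ext <- shrink(ext, u)
  }
  margin <- (as.integer(input_extent) - ext)
  if (any(margin %% 2L != 0L))
    stop("asymmetric margin; invalid input extent")
  list(input = as.integer(input_extent), output = ext,
       margin = margin %/% 2L)
}

# ---- forward / backward machinery ----------------------------------------
# Activations are (B*nx*ny*nz) x C matrices; `dims` = c(nx, ny, nz, B).

# Row indices of the centered sub-window `len` within `dims`.
crop_rows <- function(dims, len) {
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]; B <- dims[4]
  lo <- (dims[1:3] - len) %/% 2L
  xs <- lo[1] + seq_len(len[1])
  ys <- lo[2] + seq_len(len[2])
  zs <- lo[3] + seq_len(len[3])
  plane <- outer(xs, (ys - 1L) * nx, `+`)
  vol <- outer(as.vector(plane), (zs - 1L) * nx * ny, `+`)
  nv <- nx * ny * nz
  as.vector(outer(as.vector(vol), (seq_len(B) - 1L) * nv, `+`))
}

# Small channel products are faster with the direct conv loop; large ones
# with the per-offset GEMM path.
conv_fwd <- function(X, dims, W, k, b) {
  if (dim(W)[2] * dim(W)[3] <= 64L && k[1] <= 8L)
    cpp_conv3d_fwd_direct(X, dims, W, k, b)
  else cpp_conv3d_fwd(X, dims, W, k, b)
}

conv_bwd <- function(X, dims, W, k, dOut) {
  if (dim(W)[2] * dim(W)[3] <= 64L && k[1] <= 8L)
    cpp_conv3d_bwd_direct(X, dims, W, k, dOut)
  else cpp_conv3d_bwd(X, dims, W, k, dOut)
}

# Batch norm statistics + fused normalize/scale/ReLU; shared by conv and
# transposed-conv units.
bn_relu <- function(net, name, out, train) {
  g <- net$params[[paste0(name, ".g")]]
  be <- net$params[[paste0(name, ".be")]]
  if (train) {
    st <- cpp_colstats(out)
    mom <- net$bn_momentum
    net$state[[paste0(name, ".rm")]] <-
      mom * net$state[[paste0(name, ".rm")]] + (1 - mom) * st$mu
    net$state[[paste0(name, ".rv")]] <-
      mom * net$state[[paste0(name, ".rv")]] + (1 - mom) * st$va
  } else {
    st <- list(mu = net$state[[paste0(name, ".rm")]],
               va = net$state[[paste0(name, ".rv")]])
  }
  inv <- 1 / sqrt(st$va + net$bn_eps)
  r <- cpp_bn_relu_fwd(out, st$mu, inv, g, be)
  list(act = r$act, xhat = r$xhat, inv = inv, net = net)
}

# conv -> BN -> ReLU unit; returns activation and (optionally) a cache.
unit_fwd <- function(net, u, X, dims, train, keep) {
  p <- net$params
  out <- conv_fwd(X, dims, p[[paste0(u$name, ".W")]], u$k,
                  p[[paste0(u$name, ".b")]])
  odims <- c(dims[1:3] - (u$k - 1L), dims[4])
  bn <- bn_relu(net, u$name, out, train)
  cache <- NULL
  if (keep)
    cache <- list(X = X, dims = dims, xhat = bn$xhat, inv = bn$inv,
                  act = bn$act)
  list(act = bn$act, dims = odims, cache = cache, net = bn$net)
}

unit_bwd <- function(net, u, dAct, cache, grads) {
  g <- net$params[[paste0(u$name, ".g")]]
  bb <- cpp_bn_relu_bwd(dAct, cache$act, cache$xhat, cache$inv, g)
  res <- conv_bwd(cache$X, cache$dims,
                  net$params[[paste0(u$name, ".W")]], u$k, bb$dx)
  grads[[paste0(u$name, ".W")]] <- array(res$dw, dim(net$params[[paste0(u$name, ".W")]]))
  grads[[paste0(u$name, ".b")]] <- res$db
  grads[[paste0(u$name, ".g")]] <- bb$dg
  grads[[paste0(u$name, ".be")]] <- bb$dbe
  list(dX = res$dx, grads = grads)
}

up_fwd <- function(net, d, X, dims, train, keep) {
  p <- net$params; nm <- d$up$name
  out <- cpp_upconv_fwd(X, dims, p[[paste0(nm, ".W")]], p[[paste0(nm, ".b")]])
  odims <- c(2L * dims[1:2], dims[3], dims[4])
  bn <- bn_relu(net, nm, out, train)
  cache <- NULL
  if (keep)
    cache <- list(X = X, dims = dims, xhat = bn$xhat, inv = bn$inv,
                  act = bn$act)
  list(act = bn$act, dims = odims, cache = cache, net = bn$net)
}

up_bwd <- function(net, d, dAct, cache, grads) {
  nm <- d$up$name
  g <- net$params[[paste0(nm, ".g")]]
  bb <- cpp_bn_relu_bwd(dAct, cache$act, cache$xhat, cache$inv, g)
  dg <- bb$dg; dbe <- bb$dbe
  res <- cpp_upconv_bwd(cache$X, cache$dims,
                        net$params[[paste0(nm, ".W")]], bb$dx)
  grads[[paste0(nm, ".W")]] <- array(res$dw, dim(net$params[[paste0(nm, ".W")]]))
  grads[[paste0(nm, ".b")]] <- res$db
  grads[[paste0(nm, ".g")]] <- dg
  grads[[paste0(nm, ".be")]] <- dbe
  list(dX = res$dx, grads = grads)
}

#' Forward pass of the network
#'
#' @param net an `aunet` from [build_network()].
#' @param X activation matrix `(batch * prod(extent)) x 1`.
#' @param dims integer `(nx, ny, nz, batch)`.
#' @param train use batch statistics and dropout (and update running stats).
#' @param keep_cache retain intermediate activations for [unet_backward()].
#' @return List with `prob` (output activation matrix), `dims` of the output,
#'   `cache`, and the updated `net` (running statistics).
#' @keywords internal
unet_forward <- function(net, X, dims, train = FALSE, keep_cache = FALSE) {
  plan <- net$plan; L <- net$cfg$levels
  cache <- list()
  skips <- vector("list", L - 1L)
  cur <- X; cdims <- dims
  for (i in seq_len(L)) {
    for (u in plan$enc[[i]]) {
      r <- unit_fwd(net, u, cur, cdims, train, keep_cache)
      net <- r$net; cur <- r$act; cdims <- r$dims
      if (keep_cache) cache[[u$name]] <- r$cache
    }
    if (i < L) {
      skips[[i]] <- list(act = cur, dims = cdims)
      pr <- cpp_maxpool_fwd(cur, cdims)
      if (keep_cache) cache[[sprintf("pool%d", i)]] <-
        list(idx = pr$idx, dims = cdims)
      cur <- pr$out
      cdims <- c(cdims[1:2] %/% 2L, cdims[3], cdims[4])
    }
  }
  if (train && net$cfg$dropout > 0) {
    keepp <- 1 - net$cfg$dropout
    dmask <- matrix(stats::rbinom(length(cur), 1L, keepp) / keepp,
                    nrow(cur), ncol(cur))
    cur <- cur * dmask
    if (keep_cache) cache[["dropout"]] <- dmask
  }
  for (i in rev(seq_len(L - 1L))) {
    dblock <- plan$dec[[i]]
    r <- up_fwd(net, dblock, cur, cdims, train, keep_cache)
    net <- r$net; cur <- r$act; cdims <- r$dims
    if (keep_cache) cache[[dblock$up$name]] <- r$cache
    sk <- skips[[i]]
    rows <- crop_rows(sk$dims, cdims[1:3])
    if (length(rows) != nrow(cur))
      stop(sprintf("skip crop mismatch at level %d", i))
    cur <- cbind(sk$act[rows, , drop = FALSE], cur)
    if (keep_cache) cache[[sprintf("concat%d", i)]] <-
      list(rows = rows, skip_dims = sk$dims, nskip = ncol(sk$act))
    for (u in dblock$units) {
      r <- unit_fwd(net, u, cur, cdims, train, keep_cache)
      net <- r$net; cur <- r$act; cdims <- r$dims
      if (keep_cache) cache[[u$name]] <- r$cache
    }
  }
  f <- plan$final
  pre <- conv_fwd(cur, cdims, net$params[[paste0(f$name, ".W")]], f$k,
                        net$params[[paste0(f$name, ".b")]])
  prob <- 1 / (1 + exp(-pre))
  if (keep_cache) cache[["final"]] <- list(X = cur, dims = cdims, prob = prob)
  list(prob = prob, dims = cdims, cache = cache, net = net)
}

#' Backward pass of the network
#'
#' @param net an `aunet`.
#' @param cache forward cache from [unet_forward()] with `keep_cache = TRUE`.
#' @param dProb gradient of the loss with respect to the output probability.
#' @return Flat named list of parameter gradients.
#' @keywords internal
unet_backward <- function(net, cache, dProb) {
  plan <- net$plan; L <- net$cfg$levels
  grads <- list()
  fc <- cache[["final"]]
  dPre <- dProb * fc$prob * (1 - fc$prob)
  f <- plan$final
  res <- conv_bwd(fc$X, fc$dims, net$params[[paste0(f$name, ".W")]],
                        f$k, dPre)
  grads[[paste0(f$name, ".W")]] <- array(res$dw, dim(net$params[[paste0(f$name, ".W")]]))
  grads[[paste0(f$name, ".b")]] <- res$db
  dCur <- res$dx
  pending_skip <- vector("list", L - 1L)
  for (i in seq_len(L - 1L)) {
    dblock <- plan$dec[[i]]
    for (u in rev(dblock$units)) {
      r <- unit_bwd(net, u, dCur, cache[[u$name]], grads)
      grads <- r$grads; dCur <- r$dX
    }
    cc <- cache[[sprintf("concat%d", i)]]
    nskip <- cc$nskip
    dSkip <- dCur[, seq_len(nskip), drop = FALSE]
    dUp <- dCur[, nskip + seq_len(ncol(dCur) - nskip), drop = FALSE]
    full <- matrix(0, prod(cc$skip_dims[1:3]) * cc$skip_dims[4], nskip)
    full[cc$rows, ] <- dSkip
    pending_skip[[i]] <- full
    r <- up_bwd(net, dblock, dUp, cache[[dblock$up$name]], grads)
    grads <- r$grads; dCur <- r$dX
  }
  if (!is.null(cache[["dropout"]])) dCur <- dCur * cache[["dropout"]]
  for (i in rev(seq_len(L))) {
    if (i < L) {
      pc <- cache[[sprintf("pool%d", i)]]
      dCur <- cpp_maxpool_bwd(pc$idx, pc$dims, dCur)
      dCur <- dCur + pending_skip[[i]]
    }
    units <- plan$enc[[i]]
    for (u in rev(units)) {
      r <- unit_bwd(net, u, dCur, cache[[u$name]], grads)
      grads <- r$grads; dCur <- r$dX
    }
  }
  grads
}

#' Predict a probability volume by tiled inference
#'
#' Tiles the liver bounding box with non-overlapping output windows of the
#' given patch geometry, reads each corresponding input window (output window
#' plus the symmetric margin) with mirror padding where it exceeds the
#' volume, and runs the network in inference mode (batch-norm running
#' statistics, no dropout). Voxels outside all tiles are 0. The result does
#' not depend on the tile traversal order.
#'
#' @param net trained or initialized `aunet`.
#' @param v normalized [volume()].
#' @param liver liver [mask_volume()] on the same grid.
#' @param geometry from [compute_patch_geometry()]; must belong to `net`'s
#'   configuration.
#' @return Probability [volume()] on `v`'s grid.
#' @export
predict_volume <- function(net, v, liver, geometry) {
  stop_if_grid_mismatch(v, liver)
  chk <- compute_patch_geometry(net$cfg, geometry$input)
  if (!identical(chk$output, geometry$output))
    stop("geometry inconsistent with network configuration")
  d <- dim(v$data)
  out <- array(0, d)
  bb <- mask_bbox(liver$data)
  if (is.null(bb)) return(volume(out, v$spacing, v$origin))
  oext <- geometry$output; marg <- geometry$margin
  starts <- lapply(1:3, function(a) seq(bb$lo[a], bb$hi[a], by = oext[a]))
  for (sx in starts[[1]]) for (sy in starts[[2]]) for (sz in starts[[3]]) {
    lo_out <- c(sx, sy, sz)
    hi_out <- lo_out + oext - 1L
    patch <- read_window(v$data, lo_out - marg, hi_out + marg)
    X <- matrix(as.numeric(patch), ncol = 1L)
    r <- unet_forward(net, X, c(dim(patch), 1L), train = FALSE)
    pr <- array(r$prob, oext)
    keep_hi <- pmin(hi_out, d)
    len <- keep_hi - lo_out + 1L
    if (any(len < 1L)) next
    out[lo_out[1]:keep_hi[1], lo_out[2]:keep_hi[2], lo_out[3]:keep_hi[3]] <-
      pr[seq_len(len[1]), seq_len(len[2]), seq_len(len[3])]
  }
  volume(out, v$spacing, v$origin)
}
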