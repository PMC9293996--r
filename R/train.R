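#' Training configuration
#'
#' @param batch_size patches per iteration (default 2).
#' @param learning_rate Adam learning rate (default 1e-4).
#' @param iterations total training iterations.
#' @param val_interval validation-Jaccard interval in iterations (default 500).
#' @param tumor_fraction fraction of patches required to contain a tumor
#'   voxel (default 0.9); the remainder must contain a liver voxel.
#' @param liver_dilate_xy,liver_dilate_z dilation of the liver mask used as
#'   loss weight: per-slice disk radius in voxels, plus slices in z.
#' @param patch_input input patch extent for training.
#' @param infer_input input patch extent used for full-volume validation
#'   inference (larger tiles amortize the margin).
#' @param augment an [augment_config()] or `NULL` to disable augmentation.
#' @param seed integer seed driving sampling, augmentation and dropout.
#' @return A `train_config` list.
#' @export
train_config <- function(batch_size = 2L, learning_rate = 1e-4,
                         iterations = 80000L, val_interval = 500L,
                         tumor_fraction = 0.9,
                         liver_dilate_xy = 5L, liver_dilate_z = 1L,
                         patch_input = c(236L, 236L, 72L),
                         infer_input = c(236L, 236L, 72L),
                         augment = augment_config(), seed = 1L) {
  if (batch_size < 1L) stop("batch_size must be >= 1")
  if (tumor_fraction < 0 || tumor_fraction > 1)
    stop("tumor_fraction must lie in [0, 1]")
  if (val_interval < 1L) stop("val_interval must be >= 1")
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 iterations = as.integer(iterations),
                 val_interval = as.integer(val_interval),
                 tumor_fraction = tumor_fraction,
                 liver_dilate_xy = as.integer(liver_dilate_xy),
                 liver_dilate_z = as.integer(liver_dilate_z),
                 patch_input = as.integer(patch_input),
                 infer_input = as.integer(infer_input),
                 augment = augment, seed = as.integer(seed)),
            class = "train_config")
}

# Precompute per-case sampling aids: lesion/liver voxel indices and the
# dilated liver weight mask.
prepare_case <- function(case, cfg) {
  if (is.null(case$weight))
    case$weight <- dilate_liver_weight(case$liver$data, cfg$liver_dilate_xy,
                                       cfg$liver_dilate_z)
  if (is.null(case$tumor_idx))
    case$tumor_idx <- which(case$lesions$data == 1L)
  if (is.null(case$liver_idx))
    case$liver_idx <- which(case$liver$data == 1L)
  case
}

#' Sample one training patch
#'
#' Draws an output window whose central (loss-contributing) region contains
#' at least one tumor voxel (`tumor_biased = TRUE`) or at least one liver
#' voxel (`FALSE`), then reads the input-sized window (output window plus
#' margin) with mirror padding at the volume borders. The weight patch is the
#' dilated liver mask restricted to the output region. A tumor-biased request
#' on a case without lesions falls back to liver-biased.
#'
#' @param case prepared case (image, liver, lesions, weight).
#' @param geometry a patch geometry from [compute_patch_geometry()].
#' @param tumor_biased logical.
#' @return List with `image` (input extent), `label`, `weight` (output
#'   extent), and the window position.
#' @export
sample_patch <- function(case, geometry, tumor_biased = TRUE) {
  d <- dim(case$image$data)
  oext <- geometry$output; marg <- geometry$margin
  idx <- if (tumor_biased && length(case$tumor_idx) > 0L) case$tumor_idx
         else case$liver_idx
  if (tumor_biased && length(case$tumor_idx) == 0L)
    message("tumor-biased patch requested on a case without lesions; ",
            "falling back to liver-biased sampling")
  v <- idx[sample.int(length(idx), 1L)]
  pos <- as.integer(arrayInd(v, d))
  # place the output window uniformly among positions containing `pos`
  lo <- pos - (vapply(seq_len(3), function(a)
    sample.int(oext[a], 1L), integer(1)) - 1L)
  lo_out <- lo; hi_out <- lo + oext - 1L
  img <- read_window(case$image$data, lo_out - marg, hi_out + marg)
  lab <- read_window(case$lesions$data, lo_out, hi_out)
  wgt <- read_window(case$weight, lo_out, hi_out)
  list(image = img, label = lab, weight = wgt, lo = lo_out)
}

#' Liver-masked smoothed Dice loss
#'
#' `1 - (2 * sum(w p t) + s) / (sum(w p) + sum(w t) + s)` with smoothing
#' constant `s = 1`; only voxels with weight 1 contribute. An all-zero weight
#' patch is a degenerate batch: the loss is 0 by the smoothing convention.
#'
#' @param pred probability array/vector.
#' @param target binary array/vector, same shape.
#' @param weight binary array/vector, same shape.
#' @param smooth smoothing constant.
#' @return List with `loss` and the gradient `dpred`.
#' @export
masked_dice_loss <- function(pred, target, weight, smooth = 1.0) {
  if (length(pred) != length(target) || length(pred) != length(weight))
    stop("pred, target and weight must have equal shapes")
  wp <- weight * pred
  wt <- weight * target
  num <- 2 * sum(wp * target) + smooth
  den <- sum(wp) + sum(wt) + smooth
  loss <- 1 - num / den
  # d/dp_i = -(2 w t_i * den - num * w_i) / den^2
  dpred <- -(2 * weight * target * den - num * weight) / den^2
  list(loss = loss, dpred = dpred)
}

#' Jaccard coefficient of two binary masks
#'
#' Intersection over union; defined as 1 when both masks are empty.
#'
#' @param pred,ref binary arrays of one shape.
#' @return Scalar in \[0, 1\].
#' @export
jaccard <- function(pred, ref) {
  if (!identical(dim(pred), dim(ref))) stop("shape mismatch")
  i <- sum(pred & ref)
  u <- sum(pred | ref)
  if (u == 0) 1 else i / u
}

# Mean validation Jaccard: binarize full-volume predictions at 0.5 within
# the (undilated) liver mask, per case, then average.
validation_jaccard <- function(net, val_cases, geometry) {
  js <- vapply(val_cases, function(ca) {
    prob <- predict_volume(net, ca$image, ca$liver, geometry)
    pred <- (prob$data > 0.5) & (ca$liver$data == 1L)
    jaccard(pred + 0L, ca$lesions$data)
  }, numeric(1))
  mean(js)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1L
  c1 <- 1 - beta1^opt$t; c2 <- 1 - beta2^opt$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (opt$m[[nm]] / c1) / (sqrt(opt$v[[nm]] / c2) + eps)
  }
  list(params = params, opt = opt)
}

#' Train a network
#'
#' Runs the optimization loop: per iteration a batch of patches is sampled
#' (a deterministic 9:1 tumor/liver cycle at the default 0.9 tumor fraction),
#' optionally augmented, pushed through the network, and the liver-masked
#' Dice loss (averaged over the batch) is backpropagated into an Adam step.
#' Every `val_interval` iterations the mean validation Jaccard is recorded
#' (full-volume predictions binarized at 0.5 within the liver mask); the
#' parameter state with the highest validation Jaccard is kept (ties resolve
#' to the earliest iteration).
#'
#' @param net an `aunet` from [build_network()], or a `train_state` to resume.
#' @param cases list of training cases (each: `image`, `liver`, `lesions`).
#' @param val_cases list of validation cases.
#' @param cfg a [train_config()].
#' @param state optional `train_state` to resume from (overrides `net`).
#' @return A `train_state`: the current `net`, `best` checkpoint (params,
#'   state, iteration, jaccard), `history` data frame (iteration, loss,
#'   val_jaccard), optimizer state, and RNG snapshot.
#' @export
train_model <- function(net, cases, val_cases, cfg = train_config(),
                        state = NULL) {
  if (length(cases) < 1L || length(val_cases) < 1L)
    stop("need at least one training and one validation case")
  geom <- compute_patch_geometry(net$cfg, cfg$patch_input)
  igeom <- compute_patch_geometry(net$cfg, cfg$infer_input)
  cases <- lapply(cases, prepare_case, cfg = cfg)
  val_cases <- lapply(val_cases, prepare_case, cfg = cfg)
  cycle_len <- 10L
  n_tumor <- round(cfg$tumor_fraction * cycle_len)
  if (is.null(state)) {
    state <- list(net = net, opt = adam_init(net$params), iter = 0L,
                  history = data.frame(iteration = integer(),
                                       loss = numeric(),
                                       val_jaccard = numeric()),
                  best = NULL, draw = 0L, rng = NULL)
    with_seed(cfg$seed, state$rng <- .Random.seed)
  }
  net <- state$net
  old_rng <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  assign(".Random.seed", state$rng, envir = globalenv())
  on.exit({
    if (!is.null(old_rng)) assign(".Random.seed", old_rng, globalenv())
  })
  start <- state$iter
  if (cfg$iterations < start)
    stop("target iteration count lies before the resumed state")
  for (it in seq_len(cfg$iterations - start) + start) {
    Xs <- vector("list", cfg$batch_size)
    Ls <- vector("list", cfg$batch_size)
    Ws <- vector("list", cfg$batch_size)
    for (b in seq_len(cfg$batch_size)) {
      tumor <- (state$draw %% cycle_len) < n_tumor
      state$draw <- state$draw + 1L
      ca <- cases[[sample.int(length(cases), 1L)]]
      p <- sample_patch(ca, geom, tumor_biased = tumor)
      if (!is.null(cfg$augment)) {
        # flips commute with the symmetric central crop, so the
        # output-sized label/weight can be flipped directly
        acfg <- cfg$augment
        draw <- list(flips = stats::runif(3) < acfg$flip_prob,
                     contrast = stats::runif(1, acfg$contrast_range[1],
                                             acfg$contrast_range[2]),
                     shift = stats::rnorm(1, 0, acfg$shift_sd))
        p$image <- flip_array(p$image, draw$flips)
        if (draw$contrast != 1 || draw$shift != 0) {
          m <- mean(p$image)
          p$image <- m + draw$contrast * (p$image - m) + draw$shift
        }
        p$label <- flip_array(p$label, draw$flips)
        p$weight <- flip_array(p$weight, draw$flips)
      }
      Xs[[b]] <- as.numeric(p$image)
      Ls[[b]] <- as.numeric(p$label)
      Ws[[b]] <- as.numeric(p$weight)
    }
    X <- matrix(unlist(Xs), ncol = 1L)
    dims <- c(geom$input, cfg$batch_size)
    fw <- unet_forward(net, X, dims, train = TRUE, keep_cache = TRUE)
    net <- fw$net
    nvox <- prod(geom$output)
    loss <- 0
    dprob <- numeric(nvox * cfg$batch_size)
    for (b in seq_len(cfg$batch_size)) {
      rows <- (b - 1L) * nvox + seq_len(nvox)
      dl <- masked_dice_loss(fw$prob[rows, 1L], Ls[[b]], Ws[[b]])
      if (all(Ws[[b]] == 0))
        message("degenerate batch element: all-zero weight patch")
      loss <- loss + dl$loss / cfg$batch_size
      dprob[rows] <- dl$dpred / cfg$batch_size
    }
    if (!is.finite(loss))
      stop("non-finite loss at iteration ", it,
           "; aborting (check inputs and learning rate)")
    grads <- unet_backward(net, fw$cache, matrix(dprob, ncol = 1L))
    st <- adam_step(net$params, grads, state$opt, cfg$learning_rate)
    net$params <- st$params
    state$opt <- st$opt
    vj <- NA_real_
    if (it %% cfg$val_interval == 0L) {
      vj <- validation_jaccard(net, val_cases, igeom)
      if (is.null(state$best) || vj > state$best$jaccard) {
        state$best <- list(params = net$params, bn_state = net$state,
                           iteration = it, jaccard = vj)
      }
    }
    state$history <- rbind(state$history,
                           data.frame(iteration = it, loss = loss,
                                      val_jaccard = vj))
    state$iter <- it
  }
  state$rng <- get(".Random.seed", globalenv())
  state$net <- net
  class(state) <- "train_state"
  state
}

#' Extract the best checkpoint of a training run as a usable network
#'
#' Returns the network at the recorded best-validation-Jaccard iteration
#' (argmax of the history; earliest iteration on ties).
#'
#' @param state a `train_state` from [train_model()].
#' @return An `aunet`.
#' @export
best_network <- function(state) {
  net <- state$net
  if (!is.null(state$best)) {
    net$params <- state$best$params
    net$state <- state$best$bn_state
  }
  net
}
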