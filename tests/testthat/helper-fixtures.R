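# Shared fixtures: small networks and phantoms sized for fast unit tests,
# plus an exhaustive (brute-force) oracle for the lesion correspondence
# matcher.

# Tiny purely in-plane network: 3 levels, width 2, no 1x1x3 convolutions,
# so small patches are admissible and one iteration costs milliseconds.
tiny_net_config <- function(dropout = 0.1) {
  network_config(levels = 3L, base_features = 2L, max_features = 4L,
                 z_levels = integer(0), dropout = dropout)
}

tiny_train_config <- function(iterations, seed = 1L, val_interval = 50L,
                              learning_rate = 3e-3, batch_size = 2L,
                              augment = augment_config()) {
  train_config(batch_size = batch_size, learning_rate = learning_rate,
               iterations = iterations, val_interval = val_interval,
               patch_input = c(44L, 44L, 8L), infer_input = c(76L, 76L, 12L),
               augment = augment, seed = seed)
}

# Small phantom: quick to generate, lesions still several voxels across.
small_phantom_spec <- function(seed = 1L, n_lesions = 3L) {
  phantom_spec(shape = c(64L, 64L, 20L), spacing = c(1.5, 1.5, 3.0),
               n_lesions = n_lesions, lesion_radius = c(4, 9), seed = seed)
}

small_cases <- function(n, base_seed = 1L, n_raters = 0L) {
  phantom_cases(n, base_seed = base_seed, n_raters = n_raters,
                spec = small_phantom_spec())
}

# --- brute-force correspondence oracle ------------------------------------
# Enumerates every subset of the initial overlap edges; groups are the
# connected components of the kept edges; per-group Dice uses all voxel
# overlaps between members. Returns the maximal mean per-group Dice.

bf_components <- function(n, edges) {
  comp <- seq_len(n)
  changed <- TRUE
  while (changed) {
    changed <- FALSE
    if (length(edges)) for (e in seq_len(nrow(edges))) {
      a <- edges[e, 1]; b <- edges[e, 2]
      m <- min(comp[a], comp[b])
      if (comp[a] != m || comp[b] != m) {
        comp[comp == comp[a] | comp == comp[b]] <- m
        changed <- TRUE
      }
    }
  }
  comp
}

# Objective of one kept-edge subset: mean Dice over ALL groups (connected
# components of the kept edges), where components without a counterpart are
# zero-Dice singleton groups.
bf_mean_dice <- function(overlap, ref_sizes, pred_sizes, eg, nr, np) {
  comp <- bf_components(nr + np, eg)
  ds <- vapply(unique(comp), function(g) {
    mem <- which(comp == g)
    refs <- mem[mem <= nr]; preds <- mem[mem > nr] - nr
    inter <- if (length(refs) && length(preds))
      sum(overlap[refs, preds, drop = FALSE]) else 0
    2 * inter / (sum(ref_sizes[refs]) + sum(pred_sizes[preds]))
  }, numeric(1))
  mean(ds)
}

bf_best_mean_dice <- function(overlap, ref_sizes, pred_sizes) {
  nr <- length(ref_sizes); np <- length(pred_sizes)
  edges <- which(overlap > 0, arr.ind = TRUE)
  ne <- nrow(edges)
  best <- -Inf
  for (mask in 0:(2^ne - 1L)) {
    kept <- as.logical(bitwAnd(mask, 2^(seq_len(ne) - 1L)))
    ek <- edges[kept, , drop = FALSE]
    eg <- if (nrow(ek)) cbind(ek[, 1], nr + ek[, 2]) else
      matrix(integer(0), 0, 2)
    best <- max(best, bf_mean_dice(overlap, ref_sizes, pred_sizes, eg, nr, np))
  }
  best
}

# The matcher's value of the same objective, recovered from its result.
matcher_mean_dice <- function(cs) {
  ds <- vapply(cs$correspondences, `[[`, numeric(1), "dice")
  n_groups <- length(ds) + length(cs$unmatched_ref) +
    length(cs$unmatched_pred)
  sum(ds) / n_groups
}

# Random small matching instance: a pair of binary arrays with a bounded
# number of components and overlap edges.
random_match_instance <- function(seed, max_components = 8L, max_edges = 10L) {
  with_seed(seed, {
    repeat {
      d <- c(14L, 14L, 4L)
      ref <- array(0L, d); pred <- array(0L, d)
      for (k in seq_len(sample(1:3, 1))) {
        lo <- c(sample(1:10, 1), sample(1:10, 1), sample(1:3, 1))
        sz <- c(sample(2:5, 1), sample(2:5, 1), sample(1:2, 1))
        hi <- pmin(lo + sz - 1L, d)
        ref[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- 1L
      }
      for (k in seq_len(sample(1:3, 1))) {
        lo <- c(sample(1:10, 1), sample(1:10, 1), sample(1:3, 1))
        sz <- c(sample(2:5, 1), sample(2:5, 1), sample(1:2, 1))
        hi <- pmin(lo + sz - 1L, d)
        pred[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- 1L
      }
      lr <- label_lesions(ref); lp <- label_lesions(pred)
      nr <- max(lr); np <- max(lp)
      if (nr + np > max_components || nr == 0L || np == 0L) next
      both <- lr > 0L & lp > 0L
      ne <- if (any(both)) nrow(unique(cbind(lr[both], lp[both]))) else 0L
      if (ne < 1L || ne > max_edges) next
      return(list(
        ref = mask_volume(ref, spacing = c(1, 1, 1)),
        pred = mask_volume(pred, spacing = c(1, 1, 1))
      ))
    }
  })
}

# Overlap matrix and component sizes for the oracle, computed directly.
overlap_table <- function(ref, pred) {
  lr <- label_lesions(ref); lp <- label_lesions(pred)
  nr <- max(lr); np <- max(lp)
  ov <- matrix(0, nr, np)
  both <- lr > 0L & lp > 0L
  if (any(both)) {
    tb <- table(factor(lr[both], levels = seq_len(nr)),
                factor(lp[both], levels = seq_len(np)))
    ov <- matrix(as.numeric(tb), nr, np)
  }
  list(overlap = ov,
       ref_sizes = tabulate(lr[lr > 0L], nr),
       pred_sizes = tabulate(lp[lp > 0L], np))
}

with_seed <- aunetseg:::with_seed
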