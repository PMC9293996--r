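#' Scoring configuration
#'
#' @param alpha weight of the uncertainty-aware score (default 0.1).
#' @param corr_dice_threshold per-correspondence Dice above which a
#'   correspondence counts as a true positive (strict `>`, default 0.2).
#' @param significance_level Wilcoxon test level (default 0.05).
#' @param fdr Benjamini-Hochberg false discovery rate (default 0.05).
#' @return A `score_config` list.
#' @export
score_config <- function(alpha = 0.1, corr_dice_threshold = 0.2,
                         significance_level = 0.05, fdr = 0.05) {
  if (alpha <= 0) stop("alpha must be > 0")
  if (corr_dice_threshold <= 0 || corr_dice_threshold >= 1)
    stop("corr_dice_threshold must lie in (0, 1)")
  structure(list(alpha = alpha, corr_dice_threshold = corr_dice_threshold,
                 significance_level = significance_level, fdr = fdr),
            class = "score_config")
}

#' Dice score of two binary masks
#'
#' `2|A & B| / (|A| + |B|)`; defined as 1 when both masks are empty.
#'
#' @param a,b [mask_volume()]s on one grid, or plain binary arrays of one
#'   shape.
#' @return Scalar in \[0, 1\].
#' @export
dice <- function(a, b) {
  if (inherits(a, "volume")) {
    stop_if_grid_mismatch(a, b)
    a <- a$data; b <- b$data
  }
  if (!identical(dim(a), dim(b))) stop("shape mismatch")
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a * b) / (sa + sb)
}

#' Uncertainty-aware segmentation score
#'
#' `phi = max(1 - alpha * eps_hat / eps_bar, 0)` with the algorithm
#' discrepancy `eps_hat = 1 - mean_algo_dice` (mean Dice of the algorithm
#' against the raters) and the inter-rater discrepancy
#' `eps_bar = 1 - mean_rater_dice` (mean pairwise Dice between raters).
#' At `alpha = 0.1`, a value of 0.9 or above marks a segmentation considered
#' as good as the manual ones given the observer disagreement.
#'
#' @param mean_algo_dice mean Dice of algorithm vs. raters.
#' @param mean_rater_dice mean pairwise inter-rater Dice, < 1.
#' @param alpha score weight.
#' @return Scalar in \[0, 1\].
#' @export
uncertainty_aware_score <- function(mean_algo_dice, mean_rater_dice,
                                    alpha = 0.1) {
  if (mean_rater_dice >= 1)
    stop("perfect inter-rater agreement: uncertainty-aware score undefined")
  eps_hat <- 1 - mean_algo_dice
  eps_bar <- 1 - mean_rater_dice
  max(1 - alpha * eps_hat / eps_bar, 0)
}

#' Label lesions as connected components
#'
#' 6-connectivity (face neighbors) in 3D, the package-wide convention for
#' what constitutes one lesion. Labels 1..k are assigned deterministically
#' in column-major scan order of the first voxel of each component.
#'
#' @param m a [mask_volume()] or binary 3D array.
#' @return Integer array of labels, 0 = background.
#' @export
label_lesions <- function(m) {
  dat <- if (inherits(m, "volume")) m$data else m
  storage.mode(dat) <- "integer"
  cpp_label6(dat, dim(dat))
}

# Union-find partition of components 1..n given an edge matrix (2 columns).
cc_partition <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  if (length(edges)) for (e in seq_len(nrow(edges))) {
    a <- find(edges[e, 1]); b <- find(edges[e, 2])
    if (a != b) parent[a] <- b
  }
  vapply(seq_len(n), find, integer(1))
}

# Mean per-correspondence Dice for a kept-edge subset. Groups are the
# connected components of the bipartite graph over ALL lesion components
# under the kept edges; per-group Dice uses all voxel overlaps between
# member components (the grouping decides membership, the voxels decide the
# score). Components without a counterpart form zero-Dice singleton groups,
# so detaching a genuine overlap never "improves" the mean by discarding it.
matching_objective <- function(overlap, ref_sizes, pred_sizes, edges, kept) {
  nr <- length(ref_sizes); np <- length(pred_sizes)
  if (nr + np == 0L) return(list(mean = NA_real_, groups = list()))
  ek <- edges[kept, , drop = FALSE]
  eg <- if (nrow(ek)) cbind(ek[, 1], nr + ek[, 2]) else
    matrix(integer(0), 0, 2)
  comp <- cc_partition(nr + np, eg)
  groups <- lapply(unique(comp), function(g) {
    mem <- which(comp == g)
    refs <- mem[mem <= nr]
    preds <- mem[mem > nr] - nr
    inter <- if (length(refs) && length(preds))
      sum(overlap[refs, preds]) else 0
    d <- 2 * inter / (sum(ref_sizes[refs]) + sum(pred_sizes[preds]))
    list(refs = refs, preds = preds, dice = d)
  })
  matched <- vapply(groups, function(g)
    length(g$refs) > 0L && length(g$preds) > 0L && g$dice > 0, logical(1))
  list(mean = mean(vapply(groups, `[[`, numeric(1), "dice")),
       groups = groups[matched])
}

#' Establish N:M lesion correspondences between two masks
#'
#' Builds the bipartite overlap graph between 6-connected lesion components
#' of the reference and the prediction. Initial correspondences are the
#' connected components of that graph; a greedy refinement then removes, one
#' at a time, the overlap edge whose removal most increases the mean
#' per-correspondence Dice (the Dice of a correspondence is computed on the
#' union of its member components' voxels), until no single removal improves
#' it. Components with no overlap, or detached by the refinement, are
#' unmatched. On small instances the refinement attains the brute-force
#' optimum over all edge subsets.
#'
#' @param ref,pred binary [mask_volume()]s on one grid.
#' @param cfg a [score_config()].
#' @return A `correspondence_set`: list of correspondences (`refs`, `preds`,
#'   `dice`), `unmatched_ref`, `unmatched_pred`, and component counts.
#' @export
match_lesions <- function(ref, pred, cfg = score_config()) {
  stop_if_grid_mismatch(ref, pred)
  lr <- label_lesions(ref); lp <- label_lesions(pred)
  nr <- max(lr); np <- max(lp)
  ref_sizes <- if (nr) tabulate(lr[lr > 0L], nr) else integer(0)
  pred_sizes <- if (np) tabulate(lp[lp > 0L], np) else integer(0)
  overlap <- matrix(0, max(nr, 1L), max(np, 1L))
  both <- lr > 0L & lp > 0L
  if (any(both)) {
    tab <- table(factor(lr[both], levels = seq_len(nr)),
                 factor(lp[both], levels = seq_len(np)))
    overlap <- matrix(as.numeric(tab), nr, np)
  }
  edges <- which(overlap > 0, arr.ind = TRUE)
  kept <- rep(TRUE, nrow(edges))
  if (nrow(edges) > 0L) {
    repeat {
      cur <- matching_objective(overlap, ref_sizes, pred_sizes, edges, kept)
      best_gain <- 0; best_e <- NA
      for (e in which(kept)) {
        trial <- kept; trial[e] <- FALSE
        alt <- matching_objective(overlap, ref_sizes, pred_sizes, edges, trial)
        if (!is.na(alt$mean) && alt$mean > cur$mean + 1e-12 &&
            alt$mean - cur$mean > best_gain) {
          best_gain <- alt$mean - cur$mean; best_e <- e
        }
      }
      if (is.na(best_e)) break
      kept[best_e] <- FALSE
    }
  }
  fin <- matching_objective(overlap, ref_sizes, pred_sizes, edges, kept)
  matched_r <- unlist(lapply(fin$groups, `[[`, "refs"))
  matched_p <- unlist(lapply(fin$groups, `[[`, "preds"))
  structure(list(correspondences = fin$groups,
                 unmatched_ref = setdiff(seq_len(nr), matched_r),
                 unmatched_pred = setdiff(seq_len(np), matched_p),
                 n_ref = nr, n_pred = np),
            class = "correspondence_set")
}

#' Lesion detection counts and rates from a correspondence set
#'
#' A correspondence with Dice above the threshold is one true positive; a
#' sub-threshold correspondence contributes one false positive and one false
#' negative; every unmatched reference lesion is a false negative and every
#' unmatched predicted lesion a false positive. Degenerate conventions: with
#' no reference lesions recall is 1, with no predicted lesions precision
#' is 1. FPC (false positives per case) equals FP.
#'
#' @param cs a `correspondence_set` from [match_lesions()].
#' @param cfg a [score_config()].
#' @return List with `tp`, `fp`, `fn`, `recall`, `precision`, `f1`, `fpc`.
#' @export
detection_metrics <- function(cs, cfg = score_config()) {
  d <- vapply(cs$correspondences, `[[`, numeric(1), "dice")
  tp <- sum(d > cfg$corr_dice_threshold)
  sub <- sum(d <= cfg$corr_dice_threshold)
  fp <- sub + length(cs$unmatched_pred)
  fn <- sub + length(cs$unmatched_ref)
  recall <- if (tp + fn > 0) tp / (tp + fn) else 1
  precision <- if (tp + fp > 0) tp / (tp + fp) else 1
  f1 <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else 1
  list(tp = tp, fp = fp, fn = fn, recall = recall, precision = precision,
       f1 = f1, fpc = fp)
}

#' Segmentation scores of one case against multiple raters
#'
#' Computes the Dice of the prediction against each rater, its mean, all
#' pairwise inter-rater Dice scores and their mean, the discrepancies
#' `eps_hat = 1 - mean(D(pred, Ri))` and `eps_bar = 1 - mean(D(Ri, Rj))`,
#' and the uncertainty-aware score. With a single rater, or with perfect
#' inter-rater agreement (`eps_bar = 0`), the score is `NA` with a warning.
#'
#' @param pred predicted [mask_volume()].
#' @param raters list of >= 1 rater [mask_volume()]s.
#' @param cfg a [score_config()].
#' @return A `case_scores` list.
#' @export
score_case <- function(pred, raters, cfg = score_config()) {
  if (length(raters) < 1L) stop("need at least one rater")
  d_r <- vapply(raters, function(r) dice(pred, r), numeric(1))
  pair <- if (length(raters) >= 2L) {
    cmb <- utils::combn(length(raters), 2L)
    apply(cmb, 2L, function(ij) dice(raters[[ij[1]]], raters[[ij[2]]]))
  } else numeric(0)
  mean_algo <- mean(d_r)
  mean_rater <- if (length(pair)) mean(pair) else NA_real_
  phi <- NA_real_
  if (length(raters) < 2L) {
    warning("uncertainty-aware score needs >= 2 raters; phi is NA")
  } else if (mean_rater >= 1) {
    warning("perfect inter-rater agreement; phi undefined for this case")
  } else {
    phi <- uncertainty_aware_score(mean_algo, mean_rater, cfg$alpha)
  }
  structure(list(dice_per_rater = d_r, mean_dice = mean_algo,
                 pairwise_rater_dice = pair, mean_rater_dice = mean_rater,
                 eps_hat = 1 - mean_algo,
                 eps_bar = if (is.na(mean_rater)) NA_real_ else 1 - mean_rater,
                 phi = phi),
            class = "case_scores")
}

#' Paired significance tests with multiplicity correction
#'
#' Two-sided Wilcoxon signed-rank test per comparison (exact distribution for
#' fewer than 25 pairs, normal approximation with continuity correction
#' otherwise), followed by Benjamini-Hochberg step-up across the comparison
#' family. All-zero differences give p = 1 by convention.
#'
#' @param comparisons named list; each element a list with numeric vectors
#'   `a` and `b` of equal length (>= 6 pairs for a meaningful test).
#' @param fdr false discovery rate of the step-up procedure.
#' @return Data frame with `comparison`, `n`, `p`, `p_adj`, `reject`.
#' @export
paired_tests <- function(comparisons, fdr = 0.05) {
  p <- vapply(names(comparisons), function(nm) {
    a <- comparisons[[nm]]$a; b <- comparisons[[nm]]$b
    if (length(a) != length(b)) stop("unequal lengths in ", nm)
    d <- a - b
    if (all(d == 0)) {
      message("all paired differences zero in '", nm, "'; p = 1")
      return(1)
    }
    suppressWarnings(
      stats::wilcox.test(a, b, paired = TRUE,
                         exact = length(a) < 25, correct = TRUE)$p.value)
  }, numeric(1))
  p_adj <- stats::p.adjust(p, method = "BH")
  data.frame(comparison = names(comparisons),
             n = vapply(comparisons, function(x) length(x$a), integer(1)),
             p = p, p_adj = p_adj, reject = p_adj <= fdr,
             row.names = NULL)
}
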