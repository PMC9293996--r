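mk <- function(idx, d = c(6L, 6L, 2L)) {
  a <- array(0L, d); a[idx] <- 1L
  mask_volume(a)
}

test_that("dice matches counting and is symmetric", {
  a <- mk(1:4); b <- mk(3:6)
  expect_equal(dice(a, a), 1)
  expect_equal(dice(a, mk(10:13)), 0)
  expect_equal(dice(a, b), 0.5)      # |a|=|b|=4, overlap 2
  expect_equal(dice(a, b), dice(b, a))
  expect_equal(dice(mk(integer(0)), mk(integer(0))), 1)
})

test_that("uncertainty-aware score follows its defining formula", {
  # equal discrepancies at alpha 0.1 give the human-level threshold 0.9
  expect_equal(uncertainty_aware_score(0.8, 0.8, 0.1), 0.9)
  # perfect agreement of the algorithm gives 1
  expect_equal(uncertainty_aware_score(1, 0.8, 0.1), 1)
  # tenfold worse than the raters clamps at 0
  expect_equal(uncertainty_aware_score(1 - 10 * 0.2, 1 - 0.2, 0.1), 0)
  # the published summary Dice values: 1 - 0.1 * 0.262 / 0.219
  expect_equal(uncertainty_aware_score(0.738, 0.781, 0.1),
               1 - 0.1 * 0.262 / 0.219, tolerance = 1e-12)
  expect_equal(uncertainty_aware_score(0.738, 0.781, 0.1), 0.8804,
               tolerance = 1e-4)
  # perfect rater agreement is undefined
  expect_error(uncertainty_aware_score(0.9, 1, 0.1), "undefined")
})

test_that("phi is monotone in algorithm Dice and in alpha", {
  phis <- vapply(seq(0.5, 1, by = 0.05),
                 function(d) uncertainty_aware_score(d, 0.8, 0.1), numeric(1))
  expect_true(all(diff(phis) >= 0))
  alphas <- vapply(c(0.05, 0.1, 0.2, 0.5),
                   function(a) uncertainty_aware_score(0.7, 0.8, a),
                   numeric(1))
  expect_true(all(diff(alphas) <= 0))
})

test_that("lesion labeling uses 6-connectivity", {
  d <- c(4L, 4L, 2L)
  m <- array(0L, d)
  m[1, 1, 1] <- 1L; m[2, 2, 1] <- 1L   # diagonal touch: two components
  expect_equal(max(label_lesions(mask_volume(m))), 2L)
  m2 <- array(0L, d)
  m2[1:2, 1, 1] <- 1L                   # face touch: one component
  expect_equal(max(label_lesions(mask_volume(m2))), 1L)
  expect_equal(max(label_lesions(mask_volume(array(0L, d)))), 0L)
  ph <- generate_phantom(small_phantom_spec(seed = 130))
  expect_equal(max(label_lesions(ph$lesions)), 3L)
})

test_that("identity matching yields 1:1 correspondences with Dice 1", {
  ph <- generate_phantom(small_phantom_spec(seed = 131))
  cs <- match_lesions(ph$lesions, ph$lesions)
  expect_equal(length(cs$correspondences), 3L)
  for (g in cs$correspondences) {
    expect_equal(length(g$refs), 1L)
    expect_equal(length(g$preds), 1L)
    expect_equal(g$dice, 1)
  }
  expect_equal(length(cs$unmatched_ref), 0L)
  expect_equal(length(cs$unmatched_pred), 0L)
})

test_that("a split prediction forms one 1:2 correspondence", {
  d <- c(12L, 12L, 1L)
  ref <- array(0L, d); ref[2:11, 5, 1] <- 1L            # 10 voxels
  pred <- array(0L, d)
  pred[2:5, 5, 1] <- 1L; pred[8:11, 5, 1] <- 1L         # two 4-voxel pieces
  cs <- match_lesions(mask_volume(ref), mask_volume(pred))
  expect_equal(length(cs$correspondences), 1L)
  g <- cs$correspondences[[1]]
  expect_equal(length(g$refs), 1L)
  expect_equal(length(g$preds), 2L)
  expect_equal(g$dice, 2 * 8 / (10 + 8))
})

test_that("matching equals the brute-force optimum on random instances", {
  for (s in 1:30) {
    inst <- random_match_instance(1000 + s)
    cs <- match_lesions(inst$ref, inst$pred)
    got <- matcher_mean_dice(cs)
    tab <- overlap_table(inst$ref, inst$pred)
    opt <- bf_best_mean_dice(tab$overlap, tab$ref_sizes, tab$pred_sizes)
    expect_equal(got, opt, tolerance = 1e-12)
  }
})

test_that("detection metrics follow the counting rules", {
  # 3 TP, 1 FP, 2 FN constructed from dice values and unmatched lists
  cs <- structure(list(
    correspondences = list(
      list(refs = 1, preds = 1, dice = 0.9),
      list(refs = 2, preds = 2, dice = 0.8),
      list(refs = 3, preds = 3, dice = 0.5),
      list(refs = 4, preds = 4, dice = 0.15)),  # sub-threshold: FP + FN
    unmatched_ref = 5, unmatched_pred = integer(0),
    n_ref = 5L, n_pred = 4L), class = "correspondence_set")
  m <- detection_metrics(cs)
  expect_equal(c(m$tp, m$fp, m$fn), c(3, 1, 2))
  expect_equal(m$recall, 0.6)
  expect_equal(m$precision, 0.75)
  expect_equal(m$f1, 6 / 9)
  expect_equal(m$fpc, 1)
  # conservation: TP+FN covers references, TP+FP covers predictions
  expect_equal(m$tp + m$fn, 5)
  expect_equal(m$tp + m$fp, 4)
})

test_that("degenerate detection conventions", {
  ph <- generate_phantom(small_phantom_spec(seed = 132))
  empty <- mask_volume(array(0L, dim(ph$lesions$data)),
                       spacing = ph$lesions$spacing)
  cs <- match_lesions(ph$lesions, empty)
  m <- detection_metrics(cs)
  expect_equal(m$recall, 0)
  expect_equal(m$precision, 1)   # no positive calls
  expect_equal(m$fpc, 0)
  # perfect match
  m2 <- detection_metrics(match_lesions(ph$lesions, ph$lesions))
  expect_equal(c(m2$recall, m2$precision, m2$f1, m2$fpc), c(1, 1, 1, 0))
})

test_that("a sub-threshold correspondence is formed but not a true positive", {
  d <- c(20L, 20L, 1L)
  ref <- array(0L, d); ref[1:10, 1:10, 1] <- 1L     # 100 voxels
  pred <- array(0L, d); pred[10:12, 10:12, 1] <- 1L # 9 voxels, overlap 1
  cs <- match_lesions(mask_volume(ref), mask_volume(pred))
  expect_equal(length(cs$correspondences), 1L)
  expect_lt(cs$correspondences[[1]]$dice, 0.2)
  m <- detection_metrics(cs)
  expect_equal(c(m$tp, m$fp, m$fn), c(0, 1, 1))
})

test_that("case scoring aggregates raters and flags degenerate agreement", {
  ph <- generate_phantom(small_phantom_spec(seed = 133))
  raters <- simulate_raters(ph$lesions, 3, magnitude = 2, seed = 4,
                            drop_prob = 0, liver = ph$liver)
  sc <- score_case(raters[[1]], raters)
  expect_equal(sc$dice_per_rater[1], 1)
  expect_equal(sc$eps_hat, 1 - sc$mean_dice)
  expect_equal(sc$eps_bar, 1 - sc$mean_rater_dice)
  expect_gt(sc$phi, 0.9)   # matching one rater beats the inter-rater spread
  # identical raters: phi undefined by perfect agreement
  expect_warning(sc2 <- score_case(ph$lesions,
                                   list(ph$lesions, ph$lesions, ph$lesions)),
                 "perfect")
  expect_true(is.na(sc2$phi))
  # single rater: Dice available, phi NA
  expect_warning(sc3 <- score_case(raters[[1]], raters[1]), "2 raters")
  expect_equal(sc3$dice_per_rater[[1]], 1)
  expect_true(is.na(sc3$phi))
  # hand-evaluated composition
  expect_equal(uncertainty_aware_score(0.7, 0.8, 0.1),
               1 - 0.1 * (0.3 / 0.2))
})

test_that("paired tests apply BH step-up over the family", {
  set.seed(50)
  base <- rnorm(20, 0.7, 0.1)
  cmp <- list(
    strong = list(a = base + 0.2, b = base),
    medium = list(a = base + 0.05 + rnorm(20, 0, 0.02), b = base),
    null1 = list(a = base + rnorm(20, 0, 0.001), b = base),
    null2 = list(a = base, b = base)
  )
  expect_message(res <- paired_tests(cmp), "p = 1")
  expect_equal(res$p[res$comparison == "null2"], 1)
  expect_true(res$reject[res$comparison == "strong"])
  expect_false(res$reject[res$comparison == "null2"])
  # BH decision equals the hand-applied step-up rule
  m <- nrow(res)
  ord <- order(res$p)
  k <- max(c(0, which(res$p[ord] <= seq_len(m) / m * 0.05)))
  manual <- rep(FALSE, m)
  if (k > 0) manual[ord[seq_len(k)]] <- TRUE
  expect_identical(res$reject, manual)
  # a single comparison reduces to p <= alpha
  one <- paired_tests(list(only = list(a = base + 0.2, b = base)))
  expect_identical(one$reject, one$p <= 0.05)
})

test_that("end-to-end phantom recovery: rater variant scores near-perfect", {
  ph <- generate_phantom(small_phantom_spec(seed = 134))
  pred <- simulate_raters(ph$lesions, 1, magnitude = 2, seed = 11,
                          drop_prob = 0, liver = ph$liver)[[1]]
  cs <- match_lesions(ph$lesions, pred)
  m <- detection_metrics(cs)
  expect_gt(m$recall, 0.9)
  expect_gt(m$precision, 0.9)
})
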