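test_that("masked Dice loss matches hand-evaluated cases", {
  n <- 1000
  t <- c(rep(1, 500), rep(0, 500))
  w <- rep(1, n)
  # perfect prediction
  expect_lte(masked_dice_loss(t, t, w)$loss, 1e-3)
  # total miss
  p <- 1 - t
  expect_gte(masked_dice_loss(p, t, w)$loss, 0.99)
  # half overlap, smoothing off: loss = 0.5 exactly
  t2 <- c(rep(1, 100), rep(0, 100))
  p2 <- c(rep(0, 50), rep(1, 100), rep(0, 50))
  expect_equal(masked_dice_loss(p2, t2, rep(1, 200), smooth = 0)$loss, 0.5)
  # voxels outside the weight mask cannot change the loss
  w3 <- c(rep(1, 600), rep(0, 400))
  base <- masked_dice_loss(p, t, w3)$loss
  t_perturbed <- t; t_perturbed[601:1000] <- 1 - t_perturbed[601:1000]
  expect_equal(masked_dice_loss(p, t_perturbed, w3)$loss, base)
  # all-zero weights: smoothing convention gives loss 0
  expect_equal(masked_dice_loss(p, t, rep(0, n))$loss, 0)
  # loss stays in [0, 1]
  set.seed(20)
  for (i in 1:20) {
    l <- masked_dice_loss(runif(50), rbinom(50, 1, 0.5),
                          rbinom(50, 1, 0.8))$loss
    expect_gte(l, 0); expect_lte(l, 1)
  }
})

test_that("dice-loss gradient matches finite differences", {
  set.seed(21)
  p <- runif(40); t <- rbinom(40, 1, 0.4); w <- rbinom(40, 1, 0.8)
  r <- masked_dice_loss(p, t, w)
  eps <- 1e-6
  for (i in c(1, 7, 20, 40)) {
    p1 <- p; p1[i] <- p[i] + eps
    p2 <- p; p2[i] <- p[i] - eps
    num <- (masked_dice_loss(p1, t, w)$loss -
              masked_dice_loss(p2, t, w)$loss) / (2 * eps)
    expect_equal(r$dpred[i], num, tolerance = 1e-5)
  }
})

test_that("jaccard handles the standard and degenerate cases", {
  a <- array(0L, c(4, 4, 1)); a[1:2, 1:2, 1] <- 1L
  b <- array(0L, c(4, 4, 1)); b[2:3, 1:2, 1] <- 1L
  expect_equal(jaccard(a, a), 1)
  expect_equal(jaccard(a, 1L - a), 0)
  expect_equal(jaccard(a, b), 2 / 6)
  empty <- array(0L, c(4, 4, 1))
  expect_equal(jaccard(empty, empty), 1)
  # jaccard <= dice always
  set.seed(22)
  for (i in 1:20) {
    x <- array(rbinom(64, 1, 0.4), c(4, 4, 4))
    y <- array(rbinom(64, 1, 0.4), c(4, 4, 4))
    expect_lte(jaccard(x, y), dice(x, y) + 1e-12)
  }
})

test_that("tumor-biased patches always contain a lesion voxel", {
  case <- small_cases(1, base_seed = 51)[[1]]
  cfg <- tiny_train_config(10L)
  case <- aunetseg:::prepare_case(case, cfg)
  geom <- compute_patch_geometry(tiny_net_config(), cfg$patch_input)
  set.seed(30)
  for (i in 1:100) {
    p <- sample_patch(case, geom, tumor_biased = TRUE)
    expect_gt(sum(p$label), 0)
    expect_identical(dim(p$image), as.integer(geom$input))
    expect_identical(dim(p$label), as.integer(geom$output))
  }
  # unbiased patches contain liver in the output region
  liver_patch <- aunetseg:::read_window(case$liver$data, c(1, 1, 1),
                                        dim(case$liver$data))
  for (i in 1:20) {
    p <- sample_patch(case, geom, tumor_biased = FALSE)
    expect_gt(sum(p$weight), 0)
  }
})

test_that("tumor-biased sampling falls back on lesion-free cases", {
  ph <- generate_phantom(small_phantom_spec(seed = 52, n_lesions = 0L))
  case <- preprocess_case(list(image = ph$image, liver = ph$liver,
                               lesions = ph$lesions))
  cfg <- tiny_train_config(10L)
  case <- aunetseg:::prepare_case(case, cfg)
  geom <- compute_patch_geometry(tiny_net_config(), cfg$patch_input)
  set.seed(31)
  expect_message(p <- sample_patch(case, geom, tumor_biased = TRUE),
                 "falling back")
  expect_equal(sum(p$label), 0)
})

test_that("the 90/10 scheduler cycle hits the configured mix exactly", {
  draws <- vapply(0:999, function(d) (d %% 10L) < 9L, logical(1))
  expect_equal(mean(draws), 0.9, tolerance = 0.03)
})

test_that("training bookkeeping: validation entries and best checkpoint", {
  cases <- small_cases(2, base_seed = 61)
  val <- small_cases(1, base_seed = 63)
  cfg <- tiny_train_config(50L, val_interval = 25L, seed = 7L)
  net <- build_network(tiny_net_config(), seed = 7L)
  st <- train_model(net, cases, val, cfg)
  h <- st$history[!is.na(st$history$val_jaccard), ]
  expect_identical(h$iteration, c(25L, 50L))
  expect_equal(st$best$jaccard, max(h$val_jaccard))
  # ties/argmax rule: best iteration is the earliest achieving the max
  expect_equal(st$best$iteration,
               h$iteration[which.max(h$val_jaccard)])
  expect_true(all(is.finite(st$history$loss)))
  expect_true(all(st$history$loss >= 0 & st$history$loss <= 1))
})

test_that("training with a fixed seed is exactly reproducible", {
  cases <- small_cases(2, base_seed = 71)
  val <- small_cases(1, base_seed = 73)
  cfg <- tiny_train_config(20L, val_interval = 10L, seed = 5L,
                           augment = NULL)
  a <- train_model(build_network(tiny_net_config(), seed = 5L),
                   cases, val, cfg)
  b <- train_model(build_network(tiny_net_config(), seed = 5L),
                   cases, val, cfg)
  expect_identical(a$history$loss, b$history$loss)
  expect_identical(a$history$val_jaccard, b$history$val_jaccard)
})

test_that("loss decreases and validation improves on the phantom task", {
  cases <- small_cases(4, base_seed = 81)
  val <- small_cases(1, base_seed = 86)
  wins_loss <- 0L; wins_val <- 0L
  for (s in 1:5) {
    cfg <- tiny_train_config(300L, val_interval = 100L, seed = s)
    st <- train_model(build_network(tiny_net_config(), seed = s),
                      cases, val, cfg)
    h <- st$history
    if (mean(tail(h$loss, 10)) < mean(head(h$loss, 10))) wins_loss <- wins_loss + 1L
    v <- h$val_jaccard[!is.na(h$val_jaccard)]
    if (max(v) > v[1] || v[1] > 0.5) wins_val <- wins_val + 1L
  }
  expect_gte(wins_loss, 4L)
  expect_gte(wins_val, 4L)
})
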