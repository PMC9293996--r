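test_that("schedule accounting matches the published budget", {
  s <- training_schedule()
  expect_equal(total_iterations(s), 240000)
  single <- training_schedule(1L, 80000L)
  expect_equal(total_iterations(single), 80000)
  expect_equal(total_iterations(s) / total_iterations(single), 3)
  toy <- training_schedule(c(4L, 2L, 1L), c(10L, 20L, 40L))
  expect_equal(total_iterations(toy), 4 * 10 + 2 * 10 + 1 * 20)
})

test_that("schedule validation enforces its invariants", {
  expect_error(training_schedule(c(4L, 4L, 1L), c(10L, 20L, 30L)),
               "decreasing")
  expect_error(training_schedule(c(4L, 2L), c(10L, 20L)), "last stage")
  expect_error(training_schedule(c(4L, 2L, 1L), c(10L, 10L, 30L)),
               "increasing")
})

test_that("survivor selection keeps the top Jaccards with id tie-breaks", {
  rec <- data.frame(id = 1:4, alive = TRUE,
                    jaccard = c(0.2, 0.5, 0.4, 0.3))
  out <- select_survivors(rec, 2L)
  expect_identical(out$id[out$alive], c(2L, 3L))
  # ties resolve toward the lower run id
  rec2 <- data.frame(id = 1:4, alive = TRUE, jaccard = rep(0.4, 4))
  out2 <- select_survivors(rec2, 2L)
  expect_identical(out2$id[out2$alive], c(1L, 2L))
  # keeping everyone is a warning no-op
  expect_warning(out3 <- select_survivors(rec, 4L), "nothing to eliminate")
  expect_true(all(out3$alive))
})

test_that("toy successive halving obeys the selection invariant", {
  cases <- small_cases(3, base_seed = 91)
  val <- small_cases(1, base_seed = 95)
  sched <- training_schedule(c(4L, 2L, 1L), c(50L, 100L, 200L))
  tc <- tiny_train_config(0L, val_interval = 50L)
  res <- run_multi_model(cases, val, tiny_net_config(), tc, sched,
                         base_seed = 3L, workers = 1L)
  rec <- res$records
  expect_equal(nrow(rec), 4L)
  expect_equal(sum(rec$alive), 1L)
  # the survivor reached the final milestone; the dead stopped at theirs
  expect_equal(rec$iterations[rec$alive], 200L)
  # the survivor was never worse than an eliminated run at its elimination
  # point (both were compared at that shared milestone)
  h <- res$state$history
  for (ms in sched$milestones[-length(sched$milestones)]) {
    surv_j <- h$val_jaccard[h$iteration == ms]
    dead_j <- rec$jaccard[!rec$alive & rec$iterations == ms]
    if (length(dead_j)) expect_gte(surv_j, max(dead_j))
  }
  # the non-degenerate seed spread shows up as differing scores
  expect_gt(length(unique(rec$jaccard)), 1L)
})

test_that("the worker count never changes the outcome", {
  cases <- small_cases(2, base_seed = 101)
  val <- small_cases(1, base_seed = 104)
  sched <- training_schedule(c(2L, 1L), c(30L, 60L))
  tc <- tiny_train_config(0L, val_interval = 30L)
  r1 <- run_multi_model(cases, val, tiny_net_config(), tc, sched,
                        base_seed = 9L, workers = 1L)
  r4 <- run_multi_model(cases, val, tiny_net_config(), tc, sched,
                        base_seed = 9L, workers = 4L)
  expect_identical(r1$survivor, r4$survivor)
  expect_identical(r1$records, r4$records)
})

test_that("a single-stage schedule reduces to one training run", {
  cases <- small_cases(1, base_seed = 111)
  val <- small_cases(1, base_seed = 113)
  sched <- training_schedule(1L, 40L)
  tc <- tiny_train_config(0L, val_interval = 20L)
  res <- run_multi_model(cases, val, tiny_net_config(), tc, sched,
                         base_seed = 6L)
  tc2 <- tc; tc2$iterations <- 40L; tc2$seed <- 6L
  st <- train_model(build_network(tiny_net_config(), seed = 6L),
                    cases, val, tc2)
  expect_identical(res$state$history$loss, st$history$loss)
})
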