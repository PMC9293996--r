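#' Successive-halving training schedule
#'
#' Ordered stages of (surviving run count, cumulative iteration milestone).
#' The default mirrors the published bracket: 16 differently seeded runs,
#' halved at 5k, 10k, 20k and 40k iterations on the validation Jaccard, the
#' survivor trained to 80k. Pure successive halving with a fixed bracket: no
#' hyper-parameters are searched, only initialization seeds differ.
#'
#' @param runs strictly decreasing run counts ending in 1.
#' @param milestones strictly increasing cumulative iteration milestones.
#' @return A `training_schedule` object.
#' @export
training_schedule <- function(runs = c(16L, 8L, 4L, 2L, 1L),
                              milestones = c(5000L, 10000L, 20000L,
                                             40000L, 80000L)) {
  runs <- as.integer(runs); milestones <- as.integer(milestones)
  if (length(runs) != length(milestones))
    stop("runs and milestones must have equal length")
  if (any(diff(runs) >= 0L) && length(runs) > 1L)
    stop("run counts must be strictly decreasing")
  if (utils::tail(runs, 1L) != 1L) stop("the last stage must keep 1 run")
  if (any(diff(milestones) <= 0L))
    stop("milestones must be strictly increasing")
  structure(list(runs = runs, milestones = milestones),
            class = "training_schedule")
}

#' Total number of training iterations of a schedule
#'
#' Sum over stages of (stage run count x iterations trained within the
#' stage). The default schedule totals 240,000 iterations, three times the
#' 80,000 of a single training.
#'
#' @param s a [training_schedule()].
#' @return Integer iteration count.
#' @export
total_iterations <- function(s) {
  stopifnot(inherits(s, "training_schedule"))
  seg <- diff(c(0L, s$milestones))
  sum(as.numeric(s$runs) * seg)
}

#' Select surviving runs at a milestone
#'
#' Keeps the `keep` alive runs with the highest validation Jaccard at the
#' milestone; ties break toward the lower run id. Eliminated runs are marked
#' dead with their iteration count frozen at the milestone. Runs that failed
#' (non-finite loss) carry a `-Inf` score and are eliminated first.
#'
#' @param records data frame with columns `id`, `alive`, `jaccard` (score at
#'   the shared milestone).
#' @param keep number of runs to keep.
#' @return The updated records.
#' @export
select_survivors <- function(records, keep) {
  alive <- which(records$alive)
  if (keep >= length(alive)) {
    warning("keep >= alive runs; nothing to eliminate")
    return(records)
  }
  sc <- records$jaccard[alive]
  ord <- alive[order(-sc, records$id[alive])]
  kill <- ord[(keep + 1L):length(ord)]
  records$alive[kill] <- FALSE
  records
}

#' Multi-model training by successive halving
#'
#' Launches the stage-1 runs with seeds `base_seed + run index - 1`, trains
#' every alive run to each milestone in turn, and halves the field by
#' validation Jaccard at the milestone (measured at equal budget, not each
#' run's historical best). The final survivor's best checkpoint (by its own
#' validation history) is returned. Runs execute sequentially; `workers` is
#' accepted for interface compatibility and never changes results.
#'
#' @param cases,val_cases training and validation case lists.
#' @param net_cfg a [network_config()].
#' @param train_cfg a [train_config()]; its `val_interval` must divide every
#'   milestone gap so a Jaccard measurement exists at each milestone.
#' @param schedule a [training_schedule()].
#' @param base_seed seed of run 1; run i uses `base_seed + i - 1`.
#' @param workers worker count (wall-time only; results are identical).
#' @return List with `net` (best checkpoint of the survivor), `survivor` run
#'   id, `records` (run table: id, seed, iterations, jaccard at last
#'   evaluated milestone, alive), and `states` (final `train_state` of the
#'   survivor).
#' @export
run_multi_model <- function(cases, val_cases, net_cfg = network_config(),
                            train_cfg = train_config(),
                            schedule = training_schedule(),
                            base_seed = 1L, workers = 1L) {
  if (workers < 1L) stop("need at least one worker")
  if (any(schedule$milestones %% train_cfg$val_interval != 0L))
    stop("val_interval must divide every milestone")
  n0 <- schedule$runs[1L]
  records <- data.frame(id = seq_len(n0), seed = base_seed + seq_len(n0) - 1L,
                        iterations = 0L, jaccard = NA_real_, alive = TRUE)
  states <- vector("list", n0)
  for (stage in seq_along(schedule$milestones)) {
    ms <- schedule$milestones[stage]
    for (i in which(records$alive)) {
      cfg_i <- train_cfg
      cfg_i$iterations <- ms
      cfg_i$seed <- records$seed[i]
      states[[i]] <- tryCatch(
        train_model(build_network(net_cfg, seed = records$seed[i]),
                    cases, val_cases, cfg_i, state = states[[i]]),
        error = function(e) {
          message("run ", i, " failed: ", conditionMessage(e),
                  "; eliminated with penalty score")
          st <- states[[i]]
          if (is.null(st)) st <- list(failed = TRUE)
          st$failed <- TRUE
          st
        })
      records$iterations[i] <- ms
      records$jaccard[i] <- if (isTRUE(states[[i]]$failed)) -Inf else {
        h <- states[[i]]$history
        h$val_jaccard[match(ms, h$iteration)]
      }
    }
    if (stage < length(schedule$milestones))
      records <- select_survivors(records, schedule$runs[stage + 1L])
  }
  surv <- which(records$alive)[1L]
  list(net = best_network(states[[surv]]), survivor = records$id[surv],
       records = records, state = states[[surv]])
}
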