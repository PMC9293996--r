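#' Default run configuration
#'
#' Returns the full nested configuration with every parameter at its default.
#' Defaults follow the published pipeline wherever a value is stated there:
#' in-plane resampling target 1 mm, normalization percentiles 2/98, patch
#' input 236x236x72, batch size 2, validation interval 500, tumor-patch
#' fraction 0.9, successive-halving schedule 16@5k/8@10k/4@20k/2@40k/1@80k,
#' threshold 0.5, 7x7 liver erosion, 3x3 opening, score weight alpha 0.1,
#' correspondence Dice threshold 0.2.
#'
#' @return Nested list of configuration blocks.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    paths = list(cases = NULL, out = NULL),
    preprocess = list(
      target_mm = 1.0,
      low_rank = 2,
      high_rank = 98
    ),
    augment = list(
      enabled = TRUE,
      flip_prob = 0.5,
      contrast_range = c(0.75, 1.25),
      shift_sd = 0.25
    ),
    network = list(
      levels = 5L,
      base_features = 32L,
      max_features = 512L,
      z_levels = NULL,        # NULL = the three lowest-resolution levels
      z_convs_per_conv = 2L,  # 1x1x3 convs appended after each in-plane conv
      dropout = 0.1
    ),
    train = list(
      batch_size = 2L,
      learning_rate = 1e-4,
      iterations = 80000L,
      val_interval = 500L,
      tumor_fraction = 0.9,
      liver_dilate_xy = 5L,
      liver_dilate_z = 1L,
      patch_input = c(236L, 236L, 72L),
      infer_input = c(236L, 236L, 72L)
    ),
    schedule = list(
      runs = c(16L, 8L, 4L, 2L, 1L),
      milestones = c(5000L, 10000L, 20000L, 40000L, 80000L)
    ),
    postprocess = list(
      threshold = 0.5,
      erosion_kernel = 7L,
      opening_kernel = 3L
    ),
    evaluate = list(
      alpha = 0.1,
      corr_dice_threshold = 0.2,
      significance_level = 0.05,
      fdr = 0.05
    )
  )
}

merge_config <- function(defaults, user, path = "") {
  if (is.null(user)) return(defaults)
  if (!is.list(user)) stop("config block '", path, "' must be a mapping")
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ",
         paste0(sub("^\\.", "", paste0(path, ".", unknown)), collapse = ", "))
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
      defaults[[k]] <- merge_config(defaults[[k]], user[[k]],
                                    paste0(path, ".", k))
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

#' Load a run configuration from YAML
#'
#' Reads a YAML file, fills absent keys with the defaults of
#' [default_config()], rejects unknown keys (typo safety), and echoes the
#' fully resolved configuration to the log.
#'
#' @param path YAML file; an empty file yields the full default config.
#' @param quiet suppress the resolved-config echo.
#' @return Nested configuration list.
#' @export
load_config <- function(path = NULL, quiet = TRUE) {
  user <- if (is.null(path)) NULL else yaml::read_yaml(path)
  cfg <- merge_config(default_config(), user)
  if (!quiet)
    message("resolved config:\n", yaml::as.yaml(cfg))
  cfg
}
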