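# YAML configuration. One file with sections [data, preprocess, train,
# cyclefit, evaluate]; every default in the package is overridable there.

#' Default pipeline configuration
#'
#' Returns the full default configuration as a nested list with sections
#' `data` (synthetic generator settings), `preprocess`, `train`, `cyclefit`
#' and `evaluate`. [load_config()] merges a user YAML file over these
#' defaults.
#'
#' @return Nested list of defaults.
#' @export
default_config <- function() {
  list(
    data = list(
      synthetic = list(
        image_size = 448,
        noise_sd = 0.02,
        stains = c("HE", "Shorr"),
        n_subjects = 6,
        clumping_strength = 0.7
      )
    ),
    preprocess = list(
      luminance_reference = 0.8,
      histogram_bins = 64,
      quadrisect = TRUE,
      fractions = c(0.8, 0.1, 0.1),
      strata_keys = c("stain", "species", "lab", "magnification"),
      augment = list(
        reflect = "both", reflect_prob = 0.5,
        rotation_range = 30, scale_range = c(0.9, 1.1),
        translate_range = 0.1
      )
    ),
    train = list(
      backbone = "smallcnn",
      n_stages = 4,
      # initial_lr and minibatch default per backbone (see training_config():
      # 1e-5 / 80 for pretrained zoo backbones, 0.1 / 20 for smallcnn)
      initial_lr = NULL,
      minibatch = NULL,
      optimizer = "rmsprop",
      squared_gradient_decay = 0.99,
      epochs = 3,
      shuffle_every_epoch = TRUE,
      lr_drop = 0.1,
      epochs_drop = 1,
      lr_floor = 0
    ),
    cyclefit = list(
      period_days = 4.8,
      stage_fractions = c(diestrus = 0.35, proestrus = 0.15,
                          estrus = 0.30, metestrus = 0.20),
      phase_increment = 0.1,
      deviation_threshold = 1.0,
      ci_threshold = 0.30,
      waveform = "interpolation",
      pseudopregnancy_factor = 1.5,
      anestrus_leukocyte_threshold = 0.9,
      anestrus_min_days = 2
    ),
    evaluate = list(
      bootstrap_iterations = 5000,
      kfold_groups = 6
    )
  )
}

#' Load a configuration file
#'
#' Reads a YAML file and deep-merges it over [default_config()]: any key
#' present in the file overrides the default, keys absent keep their default.
#'
#' @param path Path to a YAML config, or `NULL` for pure defaults.
#' @return Nested configuration list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) stopf("config file not found: %s", path)
  user <- yaml::read_yaml(path)
  merge_lists(cfg, user)
}

merge_lists <- function(base, override) {
  if (!is.list(override)) return(override)
  if (!is.list(base)) base <- list()
  for (k in names(override)) {
    base[[k]] <- if (is.list(override[[k]]) && !is.null(names(override[[k]]))) {
      merge_lists(base[[k]], override[[k]])
    } else {
      override[[k]]
    }
  }
  base
}
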