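# Declarative run configuration: a nested YAML document with strict schema
# checking (unknown keys are rejected) over defaults that encode the
# reference protocol (window 400/40, SE reduction 4, LeakyReLU slope 0.01,
# transformer M=4 H=8 h=4096 C3=512, Adam lr 1e-3 / wd 1e-4, poly power 0.9,
# batch 4, patch 32x256x256, 500 epochs).

#' Default run configuration
#'
#' @return A nested list with `preprocess`, `augment`, `network`,
#'   `transformer` and `train` sections.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    preprocess = list(window_width = 400, window_level = 40),
    augment = list(p_mirror = c(0.5, 0.5, 0.5), rotation_deg_max = 15,
                   scale_range = c(0.9, 1.1), translate_frac_max = 0.1,
                   noise_sd = 0.02, enabled = TRUE),
    network = list(variant = "transresseunet25d",
                   stage_channels = c(16L, 32L, 64L, 128L, 256L),
                   patch = c(32L, 256L, 256L), n_classes = 2L),
    transformer = list(M = 4L, H = 8L, h = 4096L, C3 = 512L),
    train = list(batch_size = 4L, lr0 = 1e-3, weight_decay = 1e-4,
                 poly_power = 0.9, epochs = 500L, crops_per_case = 1L)
  )
}

merge_strict <- function(base, override, path = "") {
  for (nm in names(override)) {
    key <- if (path == "") nm else paste0(path, ".", nm)
    if (!nm %in% names(base))
      stop_gtv("unknown configuration key: %s", key)
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_strict(base[[nm]], override[[nm]], key)
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Load a run configuration from YAML
#'
#' Missing keys take the defaults of [default_config()]; unknown keys are
#' rejected with the offending key path. An empty file yields the full
#' default configuration.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return The merged configuration list.
#' @export
load_config <- function(path = NULL) {
  base <- default_config()
  if (is.null(path)) return(base)
  if (!file.exists(path)) stop_gtv("config file not found: %s", path)
  y <- yaml::read_yaml(path)
  if (is.null(y)) return(base)
  if (!is.list(y)) stop_gtv("config file must be a YAML mapping")
  merge_strict(base, y)
}

config_to_objects <- function(cfg) {
  aug <- if (isTRUE(cfg$augment$enabled)) {
    augment_config(p_mirror = cfg$augment$p_mirror,
                   rotation_deg_max = cfg$augment$rotation_deg_max,
                   scale_range = cfg$augment$scale_range,
                   translate_frac_max = cfg$augment$translate_frac_max,
                   noise_sd = cfg$augment$noise_sd)
  } else NULL
  ncfg <- network_config(variant = cfg$network$variant,
                         stage_channels = cfg$network$stage_channels,
                         patch = cfg$network$patch,
                         n_classes = cfg$network$n_classes,
                         transformer = list(M = cfg$transformer$M,
                                            H = cfg$transformer$H,
                                            h = cfg$transformer$h,
                                            c3 = cfg$transformer$C3))
  tcfg <- train_config(batch_size = cfg$train$batch_size, lr0 = cfg$train$lr0,
                       weight_decay = cfg$train$weight_decay,
                       poly_power = cfg$train$poly_power,
                       epochs = cfg$train$epochs, patch = cfg$network$patch,
                       seed = cfg$seed, crops_per_case = cfg$train$crops_per_case,
                       augment = aug,
                       window_width = cfg$preprocess$window_width,
                       window_level = cfg$preprocess$window_level)
  list(network = ncfg, train = tcfg)
}
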