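# Declarative run configuration: a nested YAML file validated against the
# default schema. Defaults are the reference hyperparameters (pretraining
# batch 64, lr 0.005 with cosine decay over 500 epochs; probe lr 0.01 over
# 100 epochs with multistep decay, 5 folds; 128-d projector output).

#' Default pipeline configuration
#'
#' @return Nested named list with sections `synth`, `augment`, `encoder`,
#'   `projector`, `pretrain`, `probe`, `outlier` and `io`, plus the global
#'   `seed` and `outdir`.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    outdir = "clumm-output",
    synth = list(frames_per_class = 200L, noise_sd = 0.02,
                 dropout_rate = 0.05),
    augment = list(jitter_sd = 0.5, scale_sd = 0.2, scale_center = 1.0,
                   paper_literal_scaling = FALSE),
    encoder = list(kind = "resnet18", base_width = 64L, repr_dim = NULL,
                   hidden = 256L, pretrained_init = FALSE),
    projector = list(out_dim = 128L),
    pretrain = list(epochs = 500L, batch_size = 64L, lr = 0.005,
                    weight_decay = 1e-4, temperature = 0.5),
    probe = list(epochs = 100L, lr = 0.01, milestones = c(50L, 75L),
                 gamma = 0.1, folds = 5L),
    outlier = list(clusters = 3L, n_init = 10L, enabled = FALSE),
    io = list(features = NULL, labels = NULL))
}

# Recursive merge of user values into defaults; unknown keys are an error
# naming the offending key. `repr_dim` (and other NULL-default leaves) are
# declared in the schema even though their default is NULL.
merge_config <- function(defaults, user, path = character(),
                         nullable = c("repr_dim", "features", "labels")) {
  if (is.null(user)) return(defaults)
  if (!is.list(user))
    stop("config section '", paste(path, collapse = "."),
         "' must be a mapping", call. = FALSE)
  known <- names(defaults)
  unknown <- setdiff(names(user), known)
  if (length(unknown))
    stop("unknown config key(s): ",
         paste(paste(c(path, unknown[1]), collapse = "."), collapse = ", "),
         call. = FALSE)
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
      defaults[[k]] <- merge_config(defaults[[k]], user[[k]], c(path, k))
    } else {
      defaults[k] <- list(user[[k]])
    }
  }
  defaults
}

validate_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) stop("config: ", msg, call. = FALSE)
  chk(is.numeric(cfg$seed) && length(cfg$seed) == 1, "seed must be a number")
  chk(cfg$encoder$kind %in% c("mlp", "resnet18", "resnet50"),
      "encoder.kind must be one of mlp, resnet18, resnet50")
  chk(cfg$pretrain$epochs > 0, "pretrain.epochs must be positive")
  chk(cfg$pretrain$batch_size >= 2, "pretrain.batch_size must be >= 2")
  chk(cfg$pretrain$lr > 0, "pretrain.lr must be positive")
  chk(cfg$pretrain$temperature > 0, "pretrain.temperature must be positive")
  chk(cfg$augment$jitter_sd >= 0 && cfg$augment$scale_sd >= 0,
      "augment standard deviations must be non-negative")
  chk(cfg$probe$folds >= 2, "probe.folds must be >= 2")
  chk(cfg$synth$frames_per_class > 0,
      "synth.frames_per_class must be positive")
  chk(cfg$synth$dropout_rate >= 0 && cfg$synth$dropout_rate <= 1,
      "synth.dropout_rate must be in [0, 1]")
  chk(cfg$outlier$clusters >= 1, "outlier.clusters must be >= 1")
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

#' Parse and validate a run configuration
#'
#' Reads a YAML configuration file (or takes a list), fills every omitted
#' key with its default, rejects unknown keys by name, and validates ranges.
#' An empty file yields the full defaults.
#'
#' @param config Path to a YAML file, a named list of overrides, or NULL
#'   for pure defaults.
#' @return A validated configuration list.
#' @export
parse_and_validate <- function(config = NULL) {
  user <- if (is.null(config)) {
    list()
  } else if (is.character(config)) {
    yaml::read_yaml(config) %||% list()
  } else if (is.list(config)) {
    config
  } else stop("config must be a file path or a list", call. = FALSE)
  validate_config(merge_config(default_config(), user))
}
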