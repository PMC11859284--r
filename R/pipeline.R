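# End-to-end pipeline: (synthesize | load) features -> contrastive
# pretraining -> frozen-encoder probe cross-validation -> optional outlier
# audit. Every run is reproducible from (config, seed); artifacts are
# stamped with the configuration hash.

stage_encoder_config <- function(cfg) {
  encoder_config(kind = cfg$encoder$kind,
                 pretrained_init = cfg$encoder$pretrained_init,
                 repr_dim = cfg$encoder$repr_dim,
                 base_width = cfg$encoder$base_width,
                 hidden = cfg$encoder$hidden)
}

#' Run the full pipeline from a configuration
#'
#' Stages execute in order: data (synthetic generation, or loading the
#' feature/label files named in `io`), contrastive pretraining, probe
#' cross-validation, and — when `outlier$enabled` — the outlier audit of the
#' training features. Artifacts are written under `outdir`: the feature and
#' label CSVs, the encoder checkpoint, the loss-history CSV, a metrics JSON
#' and a manifest carrying the config hash for every artifact. Rerunning
#' with an identical configuration reproduces the metrics exactly.
#'
#' @param config A configuration accepted by [parse_and_validate()].
#' @param write_artifacts Logical; set FALSE to skip writing files.
#' @return Invisible list with the data, pretraining result, CV result,
#'   baseline result, optional outlier report, the metrics list and the
#'   config hash.
#' @export
run_pipeline <- function(config = NULL, write_artifacts = TRUE) {
  cfg <- parse_and_validate(config)
  hash <- config_hash(cfg)
  outdir <- cfg$outdir
  if (write_artifacts) dir.create(outdir, recursive = TRUE,
                                  showWarnings = FALSE)

  # --- data ---------------------------------------------------------------
  fm <- if (!is.null(cfg$io$features)) {
    read_feature_matrix(cfg$io$features, labels_path = cfg$io$labels)
  } else {
    classes <- default_motion_classes(noise_sd = cfg$synth$noise_sd,
                                      dropout_rate = cfg$synth$dropout_rate)
    generate_dataset(classes, frames_per_class = cfg$synth$frames_per_class,
                     seed = derive_seed(cfg$seed, "data"))
  }

  # --- contrastive pretraining ---------------------------------------------
  enc_cfg <- stage_encoder_config(cfg)
  aug <- augment_config(jitter_sd = cfg$augment$jitter_sd,
                        scale_sd = cfg$augment$scale_sd,
                        scale_center = cfg$augment$scale_center,
                        paper_literal_scaling = cfg$augment$paper_literal_scaling)
  pt_cfg <- pretrain_config(epochs = cfg$pretrain$epochs,
                            batch_size = cfg$pretrain$batch_size,
                            lr = cfg$pretrain$lr,
                            weight_decay = cfg$pretrain$weight_decay,
                            temperature = cfg$pretrain$temperature,
                            seed = derive_seed(cfg$seed, "pretrain"))
  prj_cfg <- projector_config(enc_cfg$repr_dim,
                              out_dim = cfg$projector$out_dim)
  pt <- pretrain(fm, encoder_config = enc_cfg, augment = aug,
                 projector = prj_cfg, config = pt_cfg)

  # --- probe cross-validation ----------------------------------------------
  pr_cfg <- probe_config(epochs = cfg$probe$epochs, lr = cfg$probe$lr,
                         milestones = cfg$probe$milestones,
                         gamma = cfg$probe$gamma, folds = cfg$probe$folds,
                         seed = derive_seed(cfg$seed, "probe"))
  cv <- if (!is.null(fm$labels)) cross_validate(pt$encoder, fm, pr_cfg)

  # --- outlier audit -------------------------------------------------------
  outl <- if (isTRUE(cfg$outlier$enabled))
    outlier_report(fm, c = cfg$outlier$clusters,
                   seed = derive_seed(cfg$seed, "outlier"),
                   n_init = cfg$outlier$n_init)

  metrics <- list(config_hash = hash, seed = cfg$seed,
                  n_frames = nrow(fm$x),
                  final_pretrain_loss = pt$loss_history$mean_loss[cfg$pretrain$epochs],
                  cv = if (!is.null(cv)) cv$mean,
                  outlier_fraction = if (!is.null(outl)) outl$outlier_fraction)

  paths <- NULL
  if (write_artifacts) {
    paths <- list(features = file.path(outdir, "features.csv"),
                  labels = file.path(outdir, "labels.csv"),
                  encoder = file.path(outdir, "encoder.rds"),
                  loss_history = file.path(outdir, "loss_history.csv"),
                  metrics = file.path(outdir, "metrics.json"),
                  manifest = file.path(outdir, "manifest.json"))
    write_feature_matrix(fm, paths$features, labels_path = paths$labels)
    save_encoder(pt$encoder, paths$encoder)
    utils::write.csv(pt$loss_history, paths$loss_history, row.names = FALSE)
    jsonlite::write_json(metrics, paths$metrics, auto_unbox = TRUE,
                         digits = NA, null = "null")
    jsonlite::write_json(list(config_hash = hash,
                              artifacts = basename(unlist(paths))),
                         paths$manifest, auto_unbox = TRUE)
  }

  invisible(list(data = fm, pretrain = pt, cv = cv, outliers = outl,
                 metrics = metrics, config = cfg, config_hash = hash,
                 paths = paths))
}
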