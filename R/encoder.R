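# Encoder f(.): maps a 30-element pose feature vector to a latent
# representation h. The reference configuration is a residual convolutional
# network (18- or 50-layer style) whose first convolution takes a single
# input channel: the 30-vector is arranged as a 1 x 10 x 3 grid (landmarks
# along rows, (x, y, z) along columns). An MLP variant is provided for fast
# CPU-scale experiments.

#' Encoder configuration
#'
#' For the convolutional encoders the stem uses a 3x3/stride-1 first
#' convolution and no initial max-pool: the input grid is only 10 x 3, and a
#' stride-2 stem would collapse it before any residual block runs. Stage
#' transitions downsample by stride 2 and global average pooling absorbs the
#' final feature map.
#'
#' @param kind One of `"mlp"`, `"resnet18"`, `"resnet50"`.
#' @param input_layout Grid shape (rows, cols) for the conv encoders; the
#'   product must be 30. Default `c(10, 3)`.
#' @param pretrained_init Logical; when TRUE, externally supplied pretrained
#'   first-conv weights must be provided to [build_encoder()] and are adapted
#'   to single-channel input via [adapt_first_conv()]. Default FALSE (random
#'   initialization; nothing is downloaded).
#' @param repr_dim Representation width. Defaults: 128 for `mlp`,
#'   `8 * base_width` for `resnet18` (512 at the standard width),
#'   `32 * base_width` for `resnet50` (2048).
#' @param base_width Channel width of the first convolutional stage,
#'   default 64. Reduce for quick tests.
#' @param hidden MLP hidden width, default 256.
#' @return An `encoder_config`.
#' @export
encoder_config <- function(kind = c("mlp", "resnet18", "resnet50"),
                           input_layout = c(10L, 3L),
                           pretrained_init = FALSE,
                           repr_dim = NULL, base_width = 64L, hidden = 256L) {
  kind <- match.arg(kind)
  input_layout <- as.integer(input_layout)
  if (prod(input_layout) != 30)
    stop("input_layout must multiply to 30", call. = FALSE)
  repr_dim <- as.integer(repr_dim %||% switch(kind,
    mlp = 128L, resnet18 = 8L * base_width, resnet50 = 32L * base_width))
  if (kind != "mlp" && repr_dim != switch(kind, resnet18 = 8L * base_width,
                                          resnet50 = 32L * base_width))
    stop("repr_dim of the residual encoders is fixed by base_width",
         call. = FALSE)
  stopifnot(repr_dim > 0)
  structure(list(kind = kind, input_layout = input_layout,
                 pretrained_init = isTRUE(pretrained_init),
                 repr_dim = repr_dim, base_width = as.integer(base_width),
                 hidden = as.integer(hidden)),
            class = "encoder_config")
}

#' Adapt pretrained 3-channel first-convolution weights to a single channel
#'
#' The single-channel kernel is the elementwise mean of the three input
#' channels; all other weights are untouched by the caller.
#'
#' @param pretrained_weights Array of dim `(out_ch, 3, k, k)`.
#' @return Array of dim `(out_ch, 1, k, k)`.
#' @export
adapt_first_conv <- function(pretrained_weights) {
  d <- dim(pretrained_weights)
  if (length(d) != 4 || d[2] != 3)
    stop("expected first-conv weights of dim (out_ch, 3, k, k)",
         call. = FALSE)
  w1 <- (pretrained_weights[, 1, , , drop = FALSE] +
         pretrained_weights[, 2, , , drop = FALSE] +
         pretrained_weights[, 3, , , drop = FALSE]) / 3
  dim(w1) <- c(d[1], 1L, d[3], d[4])
  w1
}

#' Build an encoder
#'
#' @param config An [encoder_config()].
#' @param seed Integer seed for weight initialization.
#' @param pretrained_first_conv Optional `(out_ch, 3, k, k)` pretrained
#'   first-conv weight array; required when `config$pretrained_init` is TRUE
#'   (the package never downloads weights itself).
#' @return A `clumm_encoder`: list with `config`, `net` and a format
#'   `version`.
#' @export
build_encoder <- function(config, seed = 1L, pretrained_first_conv = NULL) {
  stopifnot(inherits(config, "encoder_config"))
  w <- config$base_width
  layers <- with_seed(seed, switch(config$kind,
    mlp = list(nn_dense(30L, config$hidden), nn_relu(),
               nn_dense(config$hidden, config$hidden), nn_relu(),
               nn_dense(config$hidden, config$repr_dim)),
    resnet18 = c(
      list(nn_reshape(config$input_layout),
           nn_conv(1L, w, 3L, 1L), nn_relu()),
      list(nn_resblock(w, w), nn_resblock(w, w),
           nn_resblock(w, 2L * w, 2L), nn_resblock(2L * w, 2L * w),
           nn_resblock(2L * w, 4L * w, 2L), nn_resblock(4L * w, 4L * w),
           nn_resblock(4L * w, 8L * w, 2L), nn_resblock(8L * w, 8L * w),
           nn_gap())),
    resnet50 = c(
      list(nn_reshape(config$input_layout),
           nn_conv(1L, w, 3L, 1L), nn_relu()),
      lapply(seq_len(3), function(i)
        nn_bottleneck(if (i == 1) w else 4L * w, w)),
      lapply(seq_len(4), function(i)
        nn_bottleneck(if (i == 1) 4L * w else 8L * w, 2L * w,
                      stride = if (i == 1) 2L else 1L)),
      lapply(seq_len(6), function(i)
        nn_bottleneck(if (i == 1) 8L * w else 16L * w, 4L * w,
                      stride = if (i == 1) 2L else 1L)),
      lapply(seq_len(3), function(i)
        nn_bottleneck(if (i == 1) 16L * w else 32L * w, 8L * w,
                      stride = if (i == 1) 2L else 1L)),
      list(nn_gap()))))
  net <- nn_network(layers)
  if (config$pretrained_init) {
    if (is.null(pretrained_first_conv))
      stop(paste("pretrained_init = TRUE but no pretrained first-conv",
                 "weights were supplied; pass pretrained_first_conv or use",
                 "random initialization (pretrained_init = FALSE)"),
           call. = FALSE)
    if (config$kind == "mlp")
      stop("pretrained_init applies to the convolutional encoders",
           call. = FALSE)
    ci <- 2L  # first conv sits after the reshape layer
    w1 <- adapt_first_conv(pretrained_first_conv)
    if (!identical(dim(w1), dim(net$layers[[ci]]$W)))
      stop("pretrained first-conv weights do not match the configured stem",
           call. = FALSE)
    net$layers[[ci]]$W <- w1
  }
  structure(list(config = config, net = net, version = 1L),
            class = "clumm_encoder")
}

#' @export
print.clumm_encoder <- function(x, ...) {
  cat(sprintf("<clumm_encoder> kind=%s repr_dim=%d (%s parameters)\n",
              x$config$kind, x$config$repr_dim,
              format(nn_n_params(x$net), big.mark = ",")))
  invisible(x)
}

#' Arrange a 30-element feature vector as a single-channel grid
#'
#' Row j of the default 10 x 3 grid is the (x, y, z) triplet of the j-th
#' landmark of interest; [flatten_grid()] is the exact inverse.
#'
#' @param v Length-30 numeric vector.
#' @param layout Grid shape (rows, cols), product 30.
#' @return A rows x cols numeric matrix.
#' @export
reshape_input <- function(v, layout = c(10L, 3L)) {
  if (prod(layout) != length(v))
    stop("layout incompatible with vector length", call. = FALSE)
  matrix(v, layout[1], layout[2], byrow = TRUE)
}

#' @rdname reshape_input
#' @param g Grid produced by [reshape_input()].
#' @export
flatten_grid <- function(g) as.vector(t(g))

#' Encode feature vectors into latent representations
#'
#' Deterministic in evaluation: the encoder has no stochastic layers, so
#' identical inputs give identical representations and a batched call equals
#' stacked per-sample calls up to floating-point accumulation order.
#'
#' @param encoder A `clumm_encoder`.
#' @param x Length-30 vector, n x 30 matrix, or `feature_matrix`.
#' @return An n x repr_dim numeric matrix of representations.
#' @export
encode <- function(encoder, x) {
  stopifnot(inherits(encoder, "clumm_encoder"))
  xm <- feature_values(x)
  check_finite(xm, "encoder input")
  nn_forward(encoder$net, xm)
}

#' Save / load an encoder checkpoint
#'
#' Single-file checkpoint with a format version header.
#'
#' @param encoder A `clumm_encoder`.
#' @param path Checkpoint path (`.rds`).
#' @return `path` (save) or the restored `clumm_encoder` (load).
#' @export
save_encoder <- function(encoder, path) {
  stopifnot(inherits(encoder, "clumm_encoder"))
  saveRDS(encoder, path)
  invisible(path)
}

#' @rdname save_encoder
#' @export
load_encoder <- function(path) {
  enc <- readRDS(path)
  if (!inherits(enc, "clumm_encoder") || !identical(enc$version, 1L))
    stop("not a recognized encoder checkpoint", call. = FALSE)
  enc
}
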