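# Contrastive pretraining: projector head g(.), the normalized
# temperature-scaled cross-entropy (NT-Xent) loss, and the minibatch
# training loop that returns the encoder and discards the projector.

#' Projector head configuration
#'
#' Linear -> ReLU -> linear, mapping representations into the space where
#' the contrastive loss is applied.
#'
#' @param repr_dim Input width (the encoder's representation width).
#' @param hidden_dim Hidden width, default `repr_dim`.
#' @param out_dim Output (projection) width, default 128.
#' @return A `projector_config`.
#' @export
projector_config <- function(repr_dim, hidden_dim = repr_dim, out_dim = 128L) {
  stopifnot(repr_dim > 0, hidden_dim > 0, out_dim > 0)
  structure(list(repr_dim = as.integer(repr_dim),
                 hidden_dim = as.integer(hidden_dim),
                 out_dim = as.integer(out_dim)),
            class = "projector_config")
}

#' Build a projector head
#'
#' @param config A [projector_config()].
#' @param seed Seed for weight initialization.
#' @return A `clumm_projector`.
#' @export
build_projector <- function(config, seed = 1L) {
  stopifnot(inherits(config, "projector_config"))
  net <- with_seed(seed, nn_network(list(
    nn_dense(config$repr_dim, config$hidden_dim), nn_relu(),
    nn_dense(config$hidden_dim, config$out_dim))))
  structure(list(config = config, net = net), class = "clumm_projector")
}

#' Apply the projector head
#'
#' @param projector A `clumm_projector`.
#' @param h Representation vector or n x repr_dim matrix.
#' @return n x out_dim matrix of projections.
#' @export
project <- function(projector, h) {
  stopifnot(inherits(projector, "clumm_projector"))
  if (is.null(dim(h))) h <- matrix(h, nrow = 1)
  if (ncol(h) != projector$config$repr_dim)
    stop("representation width does not match projector input", call. = FALSE)
  nn_forward(projector$net, h)
}

#' Cosine similarity between two vectors
#'
#' Returns `u . v / (||u|| ||v||)`. When either vector is all-zero the
#' similarity is defined as 0 (with a warning): the direction of a zero
#' embedding is undefined and a neutral similarity avoids division by zero.
#'
#' @param u,v Numeric vectors of equal length.
#' @return A number in `[-1, 1]`.
#' @export
cosine_similarity <- function(u, v) {
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) {
    warning("zero-vector embedding: cosine similarity defined as 0",
            call. = FALSE)
    return(0)
  }
  sum(u * v) / (nu * nv)
}

# Row-normalize projections; all-zero rows stay zero (cosine-0 convention).
l2_normalize_rows <- function(z) {
  nrm <- sqrt(rowSums(z^2))
  if (any(nrm == 0)) {
    warning("zero-vector projection(s): treated with cosine similarity 0",
            call. = FALSE)
    nrm[nrm == 0] <- Inf
  }
  z / nrm
}

# Temperature-scaled cosine-similarity matrix with the self-similarity
# masked out (set to -Inf so it never enters a softmax denominator).
similarity_matrix <- function(z, temperature) {
  u <- l2_normalize_rows(z)
  s <- tcrossprod(u) / temperature
  diag(s) <- -Inf
  s
}

#' NT-Xent contrastive loss over a batch of positive pairs
#'
#' Projections are arranged as 2b rows: rows `1..b` are the first views and
#' rows `b+1..2b` the second views, row `i` pairing with row `i + b`. The
#' per-anchor loss is the negative log of the softmax weight of the positive
#' pair among the anchor's 2b - 1 other views; the batch loss averages over
#' all 2b anchors (both orderings of each pair).
#'
#' Degenerate cases follow the definition: with b = 1 the positive is the
#' only other view, so the loss is exactly 0; with all projections identical
#' every similarity ties and the loss is `log(2b - 1)`.
#'
#' @param projections 2b x d numeric matrix.
#' @param temperature Temperature tau > 0, default 0.5.
#' @return Non-negative scalar loss.
#' @export
nt_xent_loss <- function(projections, temperature = 0.5) {
  nt_xent(projections, temperature, grad = FALSE)$loss
}

# Loss and (optionally) the analytic gradient with respect to the
# unnormalized projections.
nt_xent <- function(z, temperature = 0.5, grad = TRUE) {
  stopifnot(is.matrix(z), temperature > 0)
  n2 <- nrow(z)
  if (n2 < 2 || n2 %% 2 != 0)
    stop("projections must form b >= 1 complete pairs (2b rows)",
         call. = FALSE)
  b <- n2 %/% 2
  pos <- c((b + 1):n2, 1:b)            # anchor i's positive is pos[i]
  u <- l2_normalize_rows(z)
  s <- tcrossprod(u) / temperature
  diag(s) <- -Inf
  logZ <- row_logsumexp(s)
  loss_i <- logZ - s[cbind(seq_len(n2), pos)]
  loss <- mean(loss_i)
  if (!grad) return(list(loss = loss))
  # dL/ds summed per anchor: softmax probabilities minus the positive
  # indicator, scaled by the 1/(2b) anchor average
  p <- exp(s - logZ)
  p[cbind(seq_len(n2), pos)] <- p[cbind(seq_len(n2), pos)] - 1
  g <- p / n2
  du <- ((g + t(g)) %*% u) / temperature
  # back through row normalization: d z_i = (du_i - (du_i . u_i) u_i)/||z_i||
  nrm <- sqrt(rowSums(z^2))
  proj <- rowSums(du * u)
  dz <- (du - proj * u)
  nz <- nrm > 0
  dz[nz, ] <- dz[nz, , drop = FALSE] / nrm[nz]
  dz[!nz, ] <- 0
  list(loss = loss, grad = dz)
}

#' Pretraining configuration
#'
#' Defaults follow the reference training recipe: AdamW with initial
#' learning rate 0.005 under cosine decay, 500 epochs, batch size 64.
#'
#' @param epochs Number of epochs, default 500.
#' @param batch_size Minibatch size (pairs per batch), default 64.
#' @param lr Initial learning rate, default 0.005.
#' @param weight_decay AdamW decoupled weight decay, default 1e-4.
#' @param temperature NT-Xent temperature, default 0.5.
#' @param seed Run seed, default 1.
#' @return A `pretrain_config`.
#' @export
pretrain_config <- function(epochs = 500L, batch_size = 64L, lr = 0.005,
                            weight_decay = 1e-4, temperature = 0.5,
                            seed = 1L) {
  stopifnot(epochs > 0, batch_size >= 2, lr > 0, temperature > 0)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 weight_decay = weight_decay, temperature = temperature,
                 seed = as.integer(seed)),
            class = "pretrain_config")
}

#' Contrastive pretraining of the encoder
#'
#' Runs SimCLR-style training on unlabeled feature vectors: each minibatch
#' row is augmented into a jittered view and a scaled view (a positive
#' pair), both views pass through the encoder and projector, and encoder and
#' projector are updated jointly to minimize the NT-Xent loss. The projector
#' is discarded from the returned artifact; downstream classification uses
#' the encoder representation.
#'
#' Epoch-level shuffling uses the run seed; augmentation draws use a
#' substream derived from (seed, epoch, step). The final incomplete
#' minibatch of an epoch is dropped (NT-Xent degenerates for a single pair).
#'
#' @param fm A `feature_matrix` (labels, if any, are ignored).
#' @param encoder_config An [encoder_config()].
#' @param augment An [augment_config()].
#' @param projector A [projector_config()]; default 128-d output on the
#'   encoder's width.
#' @param config A [pretrain_config()].
#' @return A `clumm_pretrain`: list with `encoder` (a `clumm_encoder`),
#'   `loss_history` (data.frame epoch, mean_loss) and the configurations.
#' @export
pretrain <- function(fm, encoder_config = clumm::encoder_config("mlp"),
                     augment = augment_config(),
                     projector = projector_config(encoder_config$repr_dim),
                     config = pretrain_config()) {
  x <- feature_values(fm)
  m <- nrow(x)
  b <- config$batch_size
  if (m < b)
    stop("batch_size exceeds the number of training rows", call. = FALSE)
  enc <- build_encoder(encoder_config,
                       seed = derive_seed(config$seed, "encoder-init"))
  prj <- build_projector(projector,
                         seed = derive_seed(config$seed, "projector-init"))
  # one composite network: encoder layers followed by projector layers
  n_enc <- length(enc$net$layers)
  full <- nn_network(c(enc$net$layers, prj$net$layers))
  params <- nn_params(full)
  opt <- adamw_init(params)
  history <- numeric(config$epochs)
  for (epoch in seq_len(config$epochs)) {
    lr <- lr_cosine(config$lr, epoch, config$epochs)
    order <- with_seed(derive_seed(config$seed, paste0("shuffle/", epoch)),
                       sample.int(m))
    n_steps <- m %/% b
    if (n_steps == 0) stop("no complete minibatch", call. = FALSE)
    losses <- numeric(n_steps)
    for (step in seq_len(n_steps)) {
      rows <- order[((step - 1) * b + 1):(step * b)]
      views <- with_seed(
        derive_seed(config$seed, paste0("augment/", epoch, "/", step)),
        augment_batch(x[rows, , drop = FALSE], augment))
      fwd <- nn_forward(full, views, keep = TRUE)
      lg <- nt_xent(fwd$out, config$temperature)
      if (!is.finite(lg$loss))
        stop(sprintf("non-finite contrastive loss at epoch %d step %d",
                     epoch, step), call. = FALSE)
      losses[step] <- lg$loss
      bwd <- nn_backward(full, fwd$caches, lg$grad)
      upd <- adamw_step(params, bwd$grads, opt, lr,
                        weight_decay = config$weight_decay)
      params <- upd$params
      opt <- upd$state
      full <- nn_set_params(full, params)
    }
    history[epoch] <- mean(losses)
  }
  enc$net <- nn_network(full$layers[seq_len(n_enc)])
  structure(list(encoder = enc,
                 loss_history = data.frame(epoch = seq_len(config$epochs),
                                           mean_loss = history),
                 encoder_config = encoder_config, augment = augment,
                 projector_config = projector, config = config),
            class = "clumm_pretrain")
}

#' @export
print.clumm_pretrain <- function(x, ...) {
  n <- nrow(x$loss_history)
  cat(sprintf("<clumm_pretrain> %s encoder, %d epochs; NT-Xent %.4f -> %.4f\n",
              x$encoder$config$kind, n,
              x$loss_history$mean_loss[1], x$loss_history$mean_loss[n]))
  invisible(x)
}
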