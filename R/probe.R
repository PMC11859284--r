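# Downstream motion classification: a multinomial logistic regression head
# trained on frozen encoder representations (softmax scores
# phi_k(v) = w_k' v + b_k, negative log-likelihood objective), evaluated
# with stratified k-fold cross-validation and
# accuracy/precision/recall/F1.

#' Probe training configuration
#'
#' Defaults follow the reference fine-tuning recipe: Adam with learning rate
#' 0.01 over 100 epochs under a multistep decay, 5-fold cross-validation.
#'
#' @param epochs Training epochs, default 100.
#' @param lr Initial learning rate, default 0.01.
#' @param milestones Epochs after which the learning rate is multiplied by
#'   `gamma`, default `c(50, 75)`.
#' @param gamma Multistep decay factor, default 0.1.
#' @param batch_size Minibatch size for Adam, default 64.
#' @param folds Cross-validation folds, default 5.
#' @param seed Seed for fold assignment and epoch shuffling, default 1.
#' @return A `probe_config`.
#' @export
probe_config <- function(epochs = 100L, lr = 0.01, milestones = c(50L, 75L),
                         gamma = 0.1, batch_size = 64L, folds = 5L,
                         seed = 1L) {
  stopifnot(epochs >= 0, lr > 0, folds >= 2, batch_size >= 1)
  structure(list(epochs = as.integer(epochs), lr = lr,
                 milestones = as.integer(milestones), gamma = gamma,
                 batch_size = as.integer(batch_size),
                 folds = as.integer(folds), seed = as.integer(seed)),
            class = "probe_config")
}

probe_scores <- function(X, W, b) X %*% t(W) + rep(b, each = nrow(X))

#' Class probabilities under the softmax model
#'
#' `p_k = exp(phi_k) / sum_j exp(phi_j)` with `phi_k = w_k' v + b_k`,
#' evaluated in a log-sum-exp-stabilized form.
#'
#' @param features Length-d vector or n x d matrix of representations.
#' @param weights List with `W` (K x d matrix) and `b` (length-K vector).
#' @return Probability vector (or n x K matrix); rows sum to 1.
#' @export
softmax_probabilities <- function(features, weights) {
  X <- if (is.null(dim(features))) matrix(features, nrow = 1) else features
  check_finite(X, "probe features")
  s <- probe_scores(X, weights$W, weights$b)
  p <- exp(s - row_logsumexp(s))
  if (nrow(p) == 1 && is.null(dim(features))) p[1, ] else p
}

#' Mean negative log-likelihood of true classes
#'
#' @param features n x d representation matrix.
#' @param y Integer class labels in `1..K`.
#' @param weights List with `W` (K x d) and `b` (length K).
#' @return Non-negative scalar.
#' @export
nll_loss <- function(features, y, weights) {
  X <- if (is.null(dim(features))) matrix(features, nrow = 1) else features
  K <- nrow(weights$W)
  stopifnot(all(y >= 1), all(y <= K), length(y) == nrow(X))
  s <- probe_scores(X, weights$W, weights$b)
  mean(row_logsumexp(s) - s[cbind(seq_len(nrow(X)), y)])
}

# Analytic gradient of nll_loss w.r.t. W and b.
nll_grad <- function(features, y, weights) {
  X <- features
  n <- nrow(X)
  s <- probe_scores(X, weights$W, weights$b)
  p <- exp(s - row_logsumexp(s))
  p[cbind(seq_len(n), y)] <- p[cbind(seq_len(n), y)] - 1
  g <- p / n
  list(W = crossprod(g, X), b = colSums(g))
}

#' Train the softmax probe on frozen encoder representations
#'
#' The encoder is used purely as a feature extractor (its weights are never
#' touched); only the probe weight matrix and biases are optimized, by
#' minibatch Adam under the multistep schedule (epoch order reshuffled from
#' the probe seed). Weights initialize at zero, so a zero-epoch run returns
#' the untouched initialization.
#'
#' @param encoder A `clumm_encoder` (frozen).
#' @param fm A labeled `feature_matrix` (at least two classes).
#' @param config A [probe_config()].
#' @param features Optional precomputed representation matrix (bypasses
#'   `encode`); used internally by cross-validation.
#' @param labels Optional label factor overriding `fm$labels`.
#' @return A `clumm_probe`: weights `W`, `b`, the class levels and a
#'   per-epoch training-loss log.
#' @export
train_probe <- function(encoder, fm, config = probe_config(),
                        features = NULL, labels = NULL) {
  labels <- labels %||% fm$labels
  if (is.null(labels)) stop("labeled data required", call. = FALSE)
  labels <- factor(labels)
  if (nlevels(labels) < 2)
    stop("at least two classes required, got: ",
         paste(levels(labels), collapse = ", "), call. = FALSE)
  X <- features %||% encode(encoder, fm)
  y <- as.integer(labels)
  K <- nlevels(labels)
  weights <- list(W = matrix(0, K, ncol(X)), b = numeric(K))
  opt <- adamw_init(weights)
  log_loss <- numeric(config$epochs)
  n <- nrow(X)
  bsz <- min(config$batch_size, n)
  for (epoch in seq_len(config$epochs)) {
    lr <- lr_multistep(config$lr, epoch, config$milestones, config$gamma)
    order <- with_seed(derive_seed(config$seed, paste0("probe-shuffle/", epoch)),
                       sample.int(n))
    for (start in seq(1, n, by = bsz)) {
      rows <- order[start:min(start + bsz - 1, n)]
      g <- nll_grad(X[rows, , drop = FALSE], y[rows], weights)
      upd <- adamw_step(weights, g, opt, lr)
      weights <- upd$params
      opt <- upd$state
    }
    log_loss[epoch] <- nll_loss(X, y, weights)
  }
  structure(list(W = weights$W, b = weights$b, classes = levels(labels),
                 loss = log_loss, config = config),
            class = "clumm_probe")
}

#' Predict class labels with a trained probe
#'
#' @param object A `clumm_probe`.
#' @param features Representation matrix (n x d).
#' @param ... Unused.
#' @return Factor of predicted classes.
#' @export
predict.clumm_probe <- function(object, features, ...) {
  p <- softmax_probabilities(features, list(W = object$W, b = object$b))
  if (is.null(dim(p))) p <- matrix(p, nrow = 1)
  factor(object$classes[max.col(p, ties.method = "first")],
         levels = object$classes)
}

#' Classification metrics from truth and predictions
#'
#' Accuracy, macro-averaged precision/recall/F1 (the per-class convention
#' 0/0 = 0 is used for empty denominators), a per-class breakdown and the
#' K x K confusion matrix (rows = truth, columns = prediction).
#'
#' @param truth,pred Factors over the same class levels.
#' @return A `classification_metrics` list.
#' @export
classification_metrics <- function(truth, pred) {
  classes <- levels(truth)
  pred <- factor(pred, levels = classes)
  cm <- table(truth = truth, pred = pred)
  tp <- diag(cm)
  prec <- ifelse(colSums(cm) > 0, tp / colSums(cm), 0)
  rec <- ifelse(rowSums(cm) > 0, tp / rowSums(cm), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  structure(list(accuracy = sum(tp) / sum(cm),
                 precision = mean(prec), recall = mean(rec), f1 = mean(f1),
                 per_class = data.frame(class = classes, precision = as.numeric(prec),
                                        recall = as.numeric(rec), f1 = as.numeric(f1),
                                        support = as.numeric(rowSums(cm))),
                 confusion = unclass(cm)),
            class = "classification_metrics")
}

#' @export
print.classification_metrics <- function(x, ...) {
  cat(sprintf("accuracy %.3f | macro precision %.3f recall %.3f F1 %.3f\n",
              x$accuracy, x$precision, x$recall, x$f1))
  invisible(x)
}

#' Evaluate a trained probe on held-out labeled data
#'
#' @param probe A `clumm_probe`.
#' @param encoder The frozen `clumm_encoder` used for training.
#' @param fm A labeled `feature_matrix`, disjoint from the training rows
#'   (caller contract).
#' @return A `classification_metrics`.
#' @export
evaluate_probe <- function(probe, encoder, fm) {
  labels <- fm$labels
  if (is.null(labels)) stop("labeled data required", call. = FALSE)
  if (!all(levels(factor(labels)) %in% probe$classes))
    stop("labels outside the probe's training classes", call. = FALSE)
  truth <- factor(as.character(labels), levels = probe$classes)
  pred <- predict(probe, encode(encoder, fm))
  classification_metrics(truth, pred)
}

# Stratified fold assignment: within each class, shuffled rows are dealt
# round-robin to folds.
stratified_folds <- function(labels, k, seed) {
  labels <- factor(labels)
  counts <- table(labels)
  if (any(counts < k))
    stop("class(es) with fewer samples than folds: ",
         paste(names(counts)[counts < k], collapse = ", "), call. = FALSE)
  fold <- integer(length(labels))
  with_seed(seed, for (cl in levels(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  })
  fold
}

#' Stratified k-fold cross-validation of the frozen-encoder probe
#'
#' Folds partition the data; each probe trains on k-1 folds and is scored on
#' the held-out fold only. Representations are computed once with the frozen
#' encoder.
#'
#' @param encoder A `clumm_encoder`.
#' @param fm A labeled `feature_matrix`.
#' @param config A [probe_config()] (supplies `folds` and `seed`).
#' @return A `clumm_cv`: per-fold `classification_metrics`, the fold
#'   assignment, and mean metrics across folds.
#' @export
cross_validate <- function(encoder, fm, config = probe_config()) {
  labels <- factor(fm$labels)
  if (is.null(fm$labels)) stop("labeled data required", call. = FALSE)
  X <- encode(encoder, fm)
  fold <- stratified_folds(labels, config$folds,
                           derive_seed(config$seed, "cv-folds"))
  per_fold <- lapply(seq_len(config$folds), function(k) {
    tr <- fold != k
    probe <- train_probe(encoder, fm, config,
                         features = X[tr, , drop = FALSE],
                         labels = labels[tr])
    pred <- predict(probe, X[!tr, , drop = FALSE])
    classification_metrics(labels[!tr], pred)
  })
  take <- function(f) vapply(per_fold, `[[`, numeric(1), f)
  structure(list(folds = per_fold, fold_assignment = fold,
                 mean = list(accuracy = mean(take("accuracy")),
                             precision = mean(take("precision")),
                             recall = mean(take("recall")),
                             f1 = mean(take("f1")))),
            class = "clumm_cv")
}

#' @export
print.clumm_cv <- function(x, ...) {
  cat(sprintf("<clumm_cv> %d folds | mean accuracy %.3f (P %.3f R %.3f F1 %.3f)\n",
              length(x$folds), x$mean$accuracy, x$mean$precision,
              x$mean$recall, x$mean$f1))
  invisible(x)
}

#' Baseline transfer: probe on a frozen non-contrastive encoder
#'
#' Applies the same frozen-encoder probe protocol to an encoder that was
#' never contrastively pretrained, for comparison tables. With
#' `pretrained_init = FALSE` (the default) the encoder is randomly
#' initialized and frozen; externally supplied pretrained first-conv weights
#' may be passed through.
#'
#' @param fm A labeled `feature_matrix`.
#' @param encoder_cfg An [encoder_config()].
#' @param config A [probe_config()].
#' @param seed Seed for the baseline encoder's initialization.
#' @param pretrained_first_conv Optional pretrained first-conv weights.
#' @return List with `encoder`, the cross-validation result `cv`, and
#'   `metrics` (the mean metrics).
#' @export
baseline_transfer <- function(fm, encoder_cfg = encoder_config("mlp"),
                              config = probe_config(), seed = 1L,
                              pretrained_first_conv = NULL) {
  enc <- build_encoder(encoder_cfg,
                       seed = derive_seed(seed, "baseline-encoder"),
                       pretrained_first_conv = pretrained_first_conv)
  cv <- cross_validate(enc, fm, config)
  list(encoder = enc, cv = cv, metrics = cv$mean)
}

#' Side-by-side comparison table for probe results
#'
#' @param results Named list of `classification_metrics`-like lists (each
#'   with accuracy/precision/recall/f1).
#' @return A data.frame, one row per model.
#' @export
comparison_table <- function(results) {
  data.frame(network = names(results),
             accuracy = vapply(results, `[[`, numeric(1), "accuracy"),
             precision = vapply(results, `[[`, numeric(1), "precision"),
             recall = vapply(results, `[[`, numeric(1), "recall"),
             f1 = vapply(results, `[[`, numeric(1), "f1"),
             row.names = NULL)
}
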