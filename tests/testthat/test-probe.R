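test_that("softmax probabilities are exact, stable and shift-invariant", {
  w2 <- list(W = matrix(c(log(3), 0), 2, 1), b = c(0, 0))
  expect_equal(softmax_probabilities(1, w2), c(0.75, 0.25))

  wK <- list(W = matrix(0, 4, 3), b = rep(2, 4))
  expect_equal(softmax_probabilities(c(1, 2, 3), wK), rep(0.25, 4))

  withr::with_seed(1, {
    W <- matrix(stats::rnorm(15), 3)
    b <- stats::rnorm(3)
    X <- matrix(stats::rnorm(50 * 5), 50)
    p <- softmax_probabilities(X, list(W = W, b = b))
    expect_true(all(abs(rowSums(p) - 1) < 1e-12))
    naive <- t(apply(X %*% t(W) + rep(b, each = 50), 1,
                     function(s) exp(s) / sum(exp(s))))
    expect_lt(max(abs(p - naive)), 1e-12)
    shifted <- softmax_probabilities(X, list(W = W, b = b + 100))
    expect_lt(max(abs(p - shifted)), 1e-12)
    # extreme scores do not overflow
    big <- softmax_probabilities(c(1000, 0, 0), list(W = diag(3), b = rep(0, 3)))
    expect_true(all(is.finite(big)) && abs(sum(big) - 1) < 1e-12)
  })
})

test_that("the NLL hits its closed forms and its gradient checks out", {
  # near-one-hot correct probabilities -> ~0 loss
  sure <- list(W = diag(100, 3), b = rep(0, 3))
  expect_lt(nll_loss(diag(3), 1:3, sure), 1e-10)
  # uniform probabilities -> log K for any labels
  unif <- list(W = matrix(0, 5, 4), b = rep(0, 5))
  X <- withr::with_seed(2, matrix(stats::rnorm(12 * 4), 12))
  expect_equal(nll_loss(X, rep(1:3, 4), unif), log(5))

  withr::with_seed(3, {
    Xb <- matrix(stats::rnorm(5 * 4), 5)
    y <- c(1, 3, 2, 3, 1)
    w <- list(W = matrix(stats::rnorm(12), 3), b = stats::rnorm(3))
    g <- clumm:::nll_grad(Xb, y, w)
    eps <- 1e-6
    for (nm in c("W", "b")) {
      num <- w[[nm]] * 0
      for (i in seq_along(num)) {
        wp <- w; wp[[nm]][i] <- wp[[nm]][i] + eps
        wm <- w; wm[[nm]][i] <- wm[[nm]][i] - eps
        num[i] <- (nll_loss(Xb, y, wp) - nll_loss(Xb, y, wm)) / (2 * eps)
      }
      expect_lt(max(abs(g[[nm]] - num)), 1e-5)
    }
  })
})

test_that("the probe fits separable features and freezes the encoder", {
  blobs <- blob_features()
  enc <- identity_encoder()
  before <- serialize(enc, NULL)
  fm <- build_feature_matrix(matrix(0, length(blobs$y), 30),
                             labels = blobs$y)
  probe <- train_probe(enc, fm, probe_config(seed = 1),
                       features = blobs$X, labels = blobs$y)
  acc <- mean(predict(probe, blobs$X) == blobs$y)
  expect_gte(acc, 0.99)
  expect_identical(serialize(enc, NULL), before)
  expect_true(all(diff(probe$loss[60:100]) <= 1e-8))  # settled after decay

  zero <- train_probe(enc, fm, probe_config(epochs = 0),
                      features = blobs$X, labels = blobs$y)
  expect_identical(zero$W, matrix(0, 3, ncol(blobs$X)))
  expect_identical(zero$b, rep(0, 3))

  ones <- build_feature_matrix(matrix(0, 10, 30), labels = rep("a", 10))
  expect_error(train_probe(enc, ones), "two classes")
})

test_that("probe predictions agree with an independent multinomial fit", {
  skip_if_not_installed("nnet")
  blobs <- blob_features(n_per = 40, sep = 4, sd = 0.8, seed = 7)
  fm <- build_feature_matrix(matrix(0, length(blobs$y), 30),
                             labels = blobs$y)
  probe <- train_probe(identity_encoder(), fm, probe_config(seed = 2),
                       features = blobs$X, labels = blobs$y)
  d <- data.frame(y = blobs$y, blobs$X)
  ref <- nnet::multinom(y ~ ., d, trace = FALSE, maxit = 300)
  agree <- mean(predict(probe, blobs$X) == predict(ref, d))
  expect_gte(agree, 0.98)
})

test_that("classification metrics match hand counts", {
  truth <- factor(c("a", "a", "b", "b", "c", "c"),
                  levels = c("a", "b", "c"))
  perfect <- classification_metrics(truth, truth)
  expect_identical(perfect$accuracy, 1)
  expect_identical(perfect$precision, 1)
  expect_identical(perfect$f1, 1)
  expect_identical(unname(diag(perfect$confusion)), rep(2L, 3))

  all_a <- classification_metrics(truth, factor(rep("a", 6),
                                                levels = levels(truth)))
  expect_equal(all_a$accuracy, 1 / 3)

  pred <- factor(c("a", "b", "b", "c", "c", "c"), levels = levels(truth))
  m <- classification_metrics(truth, pred)
  # hand-computed confusion: a->(a,b), b->(b,c), c->(c,c)
  expect_identical(unname(m$confusion),
                   matrix(c(1L, 0L, 0L, 1L, 1L, 0L, 0L, 1L, 2L), 3))
  expect_equal(m$accuracy, 4 / 6)
  expect_equal(m$per_class$recall, c(0.5, 0.5, 1))
  expect_equal(m$per_class$precision, c(1, 0.5, 2 / 3))
  expect_equal(m$recall, mean(c(0.5, 0.5, 1)))
})

test_that("cross-validation folds partition the data stratified by class", {
  fm <- generate_dataset(frames_per_class = 40, seed = 6)
  cfg <- probe_config(epochs = 10, folds = 5, seed = 4)
  fold <- clumm:::stratified_folds(fm$labels, 5, 99)
  expect_identical(sort(unique(fold)), 1:5)
  expect_true(all(table(fold) == 24))
  expect_true(all(table(fold, fm$labels) == 8))

  cv <- cross_validate(identity_encoder(), fm, cfg)
  expect_length(cv$folds, 5)
  expect_true(all(vapply(cv$folds, `[[`, numeric(1), "accuracy") >= 0))
  expect_identical(sort(unique(cv$fold_assignment)), 1:5)

  few <- build_feature_matrix(matrix(stats::runif(90), 3),
                              labels = c("a", "a", "b"))
  expect_error(cross_validate(identity_encoder(), few, cfg), "fewer samples")
})

test_that("duplicated data in different folds yields near-identical metrics", {
  fm <- generate_dataset(clean_classes(), frames_per_class = 30, seed = 8)
  dup <- build_feature_matrix(rbind(fm$x, fm$x),
                              labels = c(as.character(fm$labels),
                                         as.character(fm$labels)))
  cv <- cross_validate(identity_encoder(), dup,
                       probe_config(epochs = 40, folds = 2, seed = 5))
  accs <- vapply(cv$folds, `[[`, numeric(1), "accuracy")
  expect_lt(abs(accs[1] - accs[2]), 0.03)
})

test_that("held-out evaluation enforces label validity", {
  blobs <- blob_features(n_per = 20)
  fm <- build_feature_matrix(matrix(stats::runif(60 * 30), 60),
                             labels = blobs$y)
  enc <- identity_encoder()
  probe <- train_probe(enc, fm, probe_config(epochs = 20, seed = 1))
  m <- evaluate_probe(probe, enc, fm)
  expect_s3_class(m, "classification_metrics")
  bad <- build_feature_matrix(fm$x, labels = rep(c("a", "zz"), 30))
  expect_error(evaluate_probe(probe, enc, bad), "outside")
})

test_that("the baseline transfer run mirrors the probe protocol", {
  fm <- generate_dataset(frames_per_class = 25, seed = 10)
  bl <- baseline_transfer(fm, encoder_config("mlp", repr_dim = 16),
                          probe_config(epochs = 10, seed = 2), seed = 3)
  expect_named(bl$metrics, c("accuracy", "precision", "recall", "f1"))
  expect_true(all(unlist(bl$metrics) >= 0 & unlist(bl$metrics) <= 1))
  tab <- comparison_table(list(clumm = bl$metrics, baseline = bl$metrics))
  expect_identical(names(tab),
                   c("network", "accuracy", "precision", "recall", "f1"))
  expect_identical(nrow(tab), 2L)
})
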