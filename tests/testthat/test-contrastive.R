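test_that("projector maps representations as configured", {
  cfg <- projector_config(repr_dim = 8, out_dim = 4)
  prj <- build_projector(cfg, seed = 1)
  h <- withr::with_seed(2, matrix(stats::rnorm(5 * 8), 5))
  psi <- project(prj, h)
  expect_identical(dim(psi), c(5L, 4L))
  loop <- t(vapply(1:5, function(i) project(prj, h[i, ])[1, ], numeric(4)))
  expect_lt(max(abs(psi - loop)), 1e-5)
  expect_error(project(prj, matrix(0, 2, 7)), "width")

  # zero weights give zero output
  zero <- prj
  zero$net <- clumm:::nn_set_params(zero$net,
    clumm:::tree_map(function(p) p * 0, clumm:::nn_params(zero$net)))
  expect_identical(unname(project(zero, h)), matrix(0, 5, 4))

  # identity-configured single linear layer passes h through
  idp <- prj
  idp$net <- clumm:::nn_network(list(clumm:::nn_dense(8, 8,
                                                      init = "identity")))
  expect_equal(project(idp, h), h)
})

test_that("cosine similarity honors the zero-vector convention", {
  u <- c(1, 2, 3)
  expect_equal(cosine_similarity(u, u), 1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity(u, -u), -1)
  expect_warning(z <- cosine_similarity(c(0, 0), c(0, 0)), "zero-vector")
  expect_identical(z, 0)
})

test_that("NT-Xent matches its closed forms", {
  expect_identical(nt_xent_loss(withr::with_seed(1, matrix(stats::rnorm(10), 2))), 0)
  for (b in c(2, 4, 8)) {
    z <- matrix(rep(withr::with_seed(b, stats::rnorm(7)), each = 2 * b), 2 * b)
    expect_lt(abs(nt_xent_loss(z, 0.5) - log(2 * b - 1)), 1e-9)
  }
  expect_error(nt_xent_loss(matrix(0, 3, 4)), "pairs")
})

test_that("NT-Xent equals the brute-force enumeration on random batches", {
  withr::with_seed(99, {
    for (rep in 1:25) for (b in c(2, 3, 4, 8)) {
      z <- matrix(stats::rnorm(2 * b * 16), 2 * b)
      tau <- sample(c(0.1, 0.5, 1), 1)
      expect_lt(abs(nt_xent_loss(z, tau) - brute_nt_xent(z, tau)), 1e-6)
    }
  })
})

test_that("NT-Xent is invariant to permuting the pair order in the batch", {
  withr::with_seed(5, {
    b <- 4
    z <- matrix(stats::rnorm(2 * b * 8), 2 * b)
    perm <- sample(b)
    zp <- rbind(z[perm, ], z[perm + b, ])
    expect_equal(nt_xent_loss(z, 0.5), nt_xent_loss(zp, 0.5))
  })
})

test_that("sharper temperatures shrink the loss when positives dominate", {
  # pairs nearly aligned, negatives near-orthogonal
  base <- diag(1, 4, 8)
  z <- rbind(base, base + 0.01)
  losses <- vapply(c(1, 0.5, 0.2, 0.1, 0.05), function(tau)
    nt_xent_loss(z, tau), numeric(1))
  expect_true(all(diff(losses) < 0))
})

test_that("the NT-Xent gradient matches finite differences", {
  withr::with_seed(6, {
    z <- matrix(stats::rnorm(8 * 5), 8)
    g <- clumm:::nt_xent(z, 0.5)$grad
    eps <- 1e-6
    num <- z * 0
    for (i in seq_along(z)) {
      zp <- z; zp[i] <- zp[i] + eps
      zm <- z; zm[i] <- zm[i] - eps
      num[i] <- (nt_xent_loss(zp, 0.5) - nt_xent_loss(zm, 0.5)) / (2 * eps)
    }
    expect_lt(max(abs(g - num)), 1e-6)
  })
})

test_that("pretraining runs, logs losses, and is seed-deterministic", {
  fm <- generate_dataset(frames_per_class = 24, seed = 1)
  cfg <- pretrain_config(epochs = 2, batch_size = 16, seed = 3)
  pt <- pretrain(fm, encoder_config = encoder_config("mlp", repr_dim = 16),
                 config = cfg)
  expect_s3_class(pt$encoder, "clumm_encoder")
  expect_identical(nrow(pt$loss_history), 2L)
  expect_true(all(is.finite(pt$loss_history$mean_loss)))
  # projector weights are discarded from the artifact
  expect_false(any(vapply(pt, inherits, logical(1), "clumm_projector")))

  pt2 <- pretrain(fm, encoder_config = encoder_config("mlp", repr_dim = 16),
                  config = cfg)
  expect_identical(pt$loss_history, pt2$loss_history)
  expect_identical(pt$encoder, pt2$encoder)
  expect_error(pretrain(fm, config = pretrain_config(batch_size = 100)),
               "batch_size")
})

test_that("pretraining groups frames of the same motion type", {
  fm <- generate_dataset(frames_per_class = 60, seed = 21)
  holdout <- generate_dataset(frames_per_class = 25, seed = 22)
  pt <- pretrain(fm, encoder_config = encoder_config("mlp", repr_dim = 32),
                 config = pretrain_config(epochs = 20, batch_size = 32,
                                          seed = 2))
  H <- encode(pt$encoder, holdout)
  U <- H / sqrt(rowSums(H^2))
  S <- tcrossprod(U)
  y <- holdout$labels
  same <- outer(y, y, "==") & upper.tri(S)
  diff <- outer(y, y, "!=") & upper.tri(S)
  expect_gt(mean(S[same]), mean(S[diff]))
})
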