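test_that("k-means degenerate cases give zero WCSS", {
  x <- matrix(stats::runif(90), 3)
  m <- cluster_features(x, c = 3, seed = 1)
  expect_lt(m$wcss, 1e-12)
  expect_identical(sort(m$assignments), 1:3)

  same <- matrix(0.3, 10, 30)
  expect_lt(cluster_features(same, c = 2, seed = 1)$wcss, 1e-12)
  expect_error(cluster_features(x, c = 5), "fewer rows")
})

test_that("k-means recovers tight blob centers and stores a consistent WCSS", {
  withr::with_seed(4, {
    a <- matrix(stats::rnorm(40 * 30, 0, 0.01), 40) + rep(rep(0.2, 30), each = 40)
    b <- matrix(stats::rnorm(40 * 30, 0, 0.01), 40) + rep(rep(0.8, 30), each = 40)
  })
  m <- cluster_features(rbind(a, b), c = 2, seed = 2)
  centers <- m$centroids[order(m$centroids[, 1]), ]
  expect_lt(max(abs(centers[1, ] - colMeans(a))), 0.01)
  expect_lt(max(abs(centers[2, ] - colMeans(b))), 0.01)
  # stored WCSS equals its definition recomputed from centroids/assignments
  x <- rbind(a, b)
  recomputed <- sum((x - m$centroids[m$assignments, ])^2)
  expect_lt(abs(m$wcss - recomputed), 1e-9)
})

test_that("nearest-centroid distances match brute force", {
  model <- structure(list(c = 1L, centroids = matrix(0, 1, 30),
                          assignments = 1L, wcss = 0),
                     class = "clumm_clusters")
  p <- c(3, 4, rep(0, 28))
  expect_equal(nearest_centroid_distances(matrix(p, 1), model), 5)
  expect_equal(nearest_centroid_distances(model$centroids, model), 0)

  withr::with_seed(5, {
    x <- matrix(stats::rnorm(50 * 30), 50)
    mu <- matrix(stats::rnorm(4 * 30), 4)
  })
  m4 <- structure(list(c = 4L, centroids = mu,
                       assignments = rep(1L, 50), wcss = 0),
                  class = "clumm_clusters")
  d <- nearest_centroid_distances(x, m4)
  brute <- apply(x, 1, function(r)
    min(apply(mu, 1, function(c) sqrt(sum((r - c)^2)))))
  expect_lt(max(abs(d - brute)), 1e-12)
})

test_that("the threshold is mean plus two population standard deviations", {
  th <- outlier_threshold(c(1, 1, 1, 1, 5))
  expect_equal(th$mu_d, 1.8)
  expect_equal(th$sigma_d, 1.6)
  expect_equal(th$t, 5.0)
  expect_identical(sum(flag_outliers(c(1, 1, 1, 1, 5), th$t)$mask), 0L)

  const <- outlier_threshold(rep(2.5, 7))
  expect_equal(const$t, 2.5)
  expect_equal(const$sigma_d, 0)

  d <- c(0.2, 0.7, 1.1, 3)
  expect_equal(outlier_threshold(d + 10)$t, outlier_threshold(d)$t + 10)
})

test_that("outlier flagging uses a strict inequality", {
  d <- c(0.5, 1, 2)
  f <- flag_outliers(d, 2)
  expect_identical(f$mask, c(FALSE, FALSE, FALSE))  # boundary is an inlier
  expect_identical(flag_outliers(d, 1.9)$mask, c(FALSE, FALSE, TRUE))
  expect_equal(flag_outliers(d, 0.4)$fraction, 1)
})

test_that("per-cluster spread statistics match a direct loop", {
  x <- rbind(rep(0, 30), c(2, rep(0, 29)), rep(5, 30))
  model <- structure(list(c = 2L, centroids = rbind(c(1, rep(0, 29)),
                                                    rep(5, 30)),
                          assignments = c(1L, 1L, 2L), wcss = 0),
                     class = "clumm_clusters")
  st <- cluster_spread_stats(x, model)
  expect_equal(st$mean_distance, c(1, 0))  # symmetric pair; singleton at center
  expect_equal(st$max_distance, c(1, 0))

  withr::with_seed(6, xr <- matrix(stats::rnorm(60 * 30), 60))
  m <- cluster_features(xr, c = 4, seed = 3)
  st2 <- cluster_spread_stats(xr, m)
  for (i in 1:4) {
    rows <- which(m$assignments == i)
    dd <- vapply(rows, function(r) sqrt(sum((xr[r, ] - m$centroids[i, ])^2)),
                 numeric(1))
    expect_equal(st2$mean_distance[i], mean(dd))
    expect_equal(st2$max_distance[i], max(dd))
  }

  empty <- structure(list(c = 2L, centroids = matrix(0, 2, 30),
                          assignments = rep(1L, 3), wcss = 0),
                     class = "clumm_clusters")
  expect_warning(se <- cluster_spread_stats(matrix(0, 3, 30), empty), "empty")
  expect_identical(se$mean_distance[2], 0)
})

test_that("injected far outliers are flagged against reference clusters", {
  fm <- generate_dataset(frames_per_class = 80, seed = 12)
  far <- outlier_motion_spec(offset = 2, noise_sd = 0.02, dropout_rate = 0)
  inj <- inject_outliers(fm, far, n_outliers = 24, seed = 12)
  rep <- outlier_report(inj$matrix, c = 3, seed = 1, reference = fm)
  recall <- mean(rep$outlier_mask[inj$outlier_mask])
  expect_gte(recall, 0.95)
  expect_equal(rep$outlier_fraction, mean(rep$outlier_mask))
  expect_true(all(rep$distances >= 0))
  # self-fitted audit on clean data stays consistent
  self <- outlier_report(fm, c = 3, seed = 1)
  expect_identical(self$outlier_mask, self$distances > self$threshold)
})

test_that("the threshold keeps most unimodal inlier mass", {
  fm <- generate_dataset(frames_per_class = 100, seed = 13)
  rep <- outlier_report(fm, c = 3, seed = 2)
  expect_lt(rep$outlier_fraction, 0.08)
})

test_that("landmark-wise audit reports one row per landmark", {
  fm <- generate_dataset(frames_per_class = 40, seed = 14)
  la <- landmark_outlier_analysis(fm, seed = 3)
  expect_identical(nrow(la$per_landmark), 10L)
  expect_identical(la$per_landmark$landmark, unname(landmark_indices()))
  expect_true(all(la$per_landmark$fraction >= 0 &
                  la$per_landmark$fraction <= 1))
  expect_equal(la$pct_outlier_landmarks,
               100 * mean(la$per_landmark$fraction))
})

test_that("the penalized loss reduces to NT-Xent and strictly exceeds it", {
  withr::with_seed(7, z <- matrix(stats::rnorm(8 * 16), 8))
  base <- nt_xent_loss(z, 0.5)
  expect_equal(penalized_nt_xent(z, omega = rep(0, 8), lambda = 3,
                                 delta = 2, temperature = 0.5), base)
  pen <- penalized_nt_xent(z, omega = c(1, rep(0, 7)), lambda = 3,
                           delta = 2, temperature = 0.5)
  expect_gt(pen, base)

  # direct-formula oracle with a random mask
  withr::with_seed(8, {
    omega <- stats::rbinom(8, 1, 0.5)
    lambda <- stats::runif(1, 0, 5)
  })
  direct <- {
    b <- 4; pos <- c(5:8, 1:4)
    cs <- function(u, v) sum(u * v) / sqrt(sum(u^2) * sum(v^2))
    li <- vapply(1:8, function(i) {
      den <- sum(vapply((1:8)[-i], function(k)
        exp(cs(z[i, ], z[k, ]) / 0.5), numeric(1))) + lambda * 1.5 * omega[i]
      -log(exp(cs(z[i, ], z[pos[i], ]) / 0.5) / den)
    }, numeric(1))
    mean(li)
  }
  expect_lt(abs(penalized_nt_xent(z, omega, lambda, 1.5, 0.5) - direct),
            1e-9)
  # per-pair mask applies to both views
  expect_equal(penalized_nt_xent(z, c(1, 0, 0, 0), lambda, 1.5, 0.5),
               penalized_nt_xent(z, c(1, 0, 0, 0, 1, 0, 0, 0),
                                 lambda, 1.5, 0.5))
})

test_that("the outlier experiment emits a well-formed, reproducible report", {
  fm <- generate_dataset(frames_per_class = 40, seed = 15)
  run <- function() outlier_experiment(
    fm, counts = c(0L, 10L),
    encoder_cfg = encoder_config("mlp", repr_dim = 16),
    pretrain_cfg = pretrain_config(epochs = 2, batch_size = 32),
    probe_cfg = probe_config(epochs = 10, folds = 3),
    seed = 5)
  ex <- run()
  expect_identical(names(ex$report),
                   c("count", "pct_outlier_landmarks", "mean_outlier_distance",
                     "max_outlier_distance", "accuracy", "precision",
                     "recall", "f1"))
  expect_identical(ex$report$count, c(0L, 10L))
  expect_true(is.na(ex$report$pct_outlier_landmarks[1]))
  expect_true(all(ex$report$accuracy >= 0 & ex$report$accuracy <= 1))
  ex2 <- run()
  expect_identical(ex$report, ex2$report)
})
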