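# Training-data audit: K-means clustering of feature vectors,
# nearest-centroid Euclidean distances, the mean-plus-two-standard-deviation
# outlier threshold, per-cluster spread statistics, an outlier-penalized
# variant of the contrastive loss (diagnostic only), and the
# outlier-injection experiment.

#' K-means clustering of feature vectors
#'
#' Lloyd's algorithm with `n_init` random seeded restarts, keeping the
#' solution with the lowest within-cluster sum of squares (WCSS).
#'
#' @param fm A `feature_matrix` or numeric matrix.
#' @param c Number of clusters, default 3.
#' @param seed Seed for the restarts.
#' @param n_init Number of restarts, default 10.
#' @param iter_max Maximum Lloyd iterations, default 300.
#' @return A `clumm_clusters`: list with `c`, `centroids` (c x 30),
#'   `assignments` and `wcss`.
#' @export
cluster_features <- function(fm, c = 3L, seed = 1L, n_init = 10L,
                             iter_max = 300L) {
  x <- feature_values(fm)
  if (nrow(x) < c)
    stop("fewer rows than clusters", call. = FALSE)
  ux <- unique(x)
  if (nrow(ux) <= c) {
    # fewer distinct points than clusters: each distinct point is its own
    # centroid (WCSS exactly 0), surplus centroids duplicate the last point
    centroids <- ux[rep(seq_len(nrow(ux)), length.out = c), , drop = FALSE]
    assign <- match(apply(x, 1, paste, collapse = "\r"),
                    apply(ux, 1, paste, collapse = "\r"))
    return(structure(list(c = as.integer(c), centroids = unname(centroids),
                          assignments = as.integer(assign), wcss = 0),
                     class = "clumm_clusters"))
  }
  km <- with_seed(derive_seed(seed, "kmeans"),
                  suppressWarnings(stats::kmeans(x, centers = c,
                                                 iter.max = iter_max,
                                                 nstart = n_init,
                                                 algorithm = "Lloyd")))
  structure(list(c = as.integer(c), centroids = unname(km$centers),
                 assignments = as.integer(km$cluster),
                 wcss = km$tot.withinss),
            class = "clumm_clusters")
}

#' Euclidean distance of every row to its nearest centroid
#'
#' `d(V) = min_i sqrt(sum_j (V_j - mu_ij)^2)` over the fitted centroids.
#'
#' @param fm A `feature_matrix` or numeric matrix.
#' @param model A `clumm_clusters`.
#' @return Numeric vector of non-negative distances, one per row.
#' @export
nearest_centroid_distances <- function(fm, model) {
  x <- feature_values(fm)
  mu <- model$centroids
  d2 <- outer(rowSums(x^2), rep(1, nrow(mu))) - 2 * tcrossprod(x, mu) +
    rep(rowSums(mu^2), each = nrow(x))
  sqrt(pmax(apply(d2, 1, min), 0))
}

#' Outlier distance threshold
#'
#' `t = mu_d + 2 sigma_d` where `mu_d` is the mean nearest-centroid distance
#' and `sigma_d` its population standard deviation (a descriptive statistic
#' over the full training set, hence the population form).
#'
#' @param distances Non-empty numeric vector of nearest-centroid distances.
#' @return List with `t`, `mu_d` and `sigma_d`.
#' @export
outlier_threshold <- function(distances) {
  stopifnot(length(distances) > 0)
  mu <- mean(distances)
  sigma <- sqrt(mean((distances - mu)^2))
  list(t = mu + 2 * sigma, mu_d = mu, sigma_d = sigma)
}

#' Per-cluster spread statistics
#'
#' For each cluster: the mean and the maximum distance of member points to
#' their own centroid. Empty clusters report 0 with a warning.
#'
#' @param fm A `feature_matrix` or numeric matrix.
#' @param model A `clumm_clusters` fitted on the same rows.
#' @return data.frame with columns `cluster`, `size`, `mean_distance`,
#'   `max_distance`.
#' @export
cluster_spread_stats <- function(fm, model) {
  x <- feature_values(fm)
  stopifnot(length(model$assignments) == nrow(x))
  stats_df <- lapply(seq_len(model$c), function(i) {
    members <- model$assignments == i
    if (!any(members)) {
      warning("cluster ", i, " is empty; reporting 0 spread", call. = FALSE)
      return(data.frame(cluster = i, size = 0L, mean_distance = 0,
                        max_distance = 0))
    }
    d <- sqrt(rowSums((x[members, , drop = FALSE] -
                       rep(model$centroids[i, ], each = sum(members)))^2))
    data.frame(cluster = i, size = sum(members), mean_distance = mean(d),
               max_distance = max(d))
  })
  do.call(rbind, stats_df)
}

#' Flag outliers by strict threshold exceedance
#'
#' A point is an outlier iff its nearest-centroid distance strictly exceeds
#' the threshold; boundary points are inliers.
#'
#' @param distances Numeric vector of nearest-centroid distances.
#' @param t Threshold (see [outlier_threshold()]).
#' @return List with logical `mask` and scalar `fraction`.
#' @export
flag_outliers <- function(distances, t) {
  mask <- distances > t
  list(mask = mask, fraction = mean(mask))
}

# Assign rows of x to the nearest centroid of a fitted model.
assign_clusters <- function(x, model) {
  mu <- model$centroids
  d2 <- outer(rowSums(x^2), rep(1, nrow(mu))) - 2 * tcrossprod(x, mu) +
    rep(rowSums(mu^2), each = nrow(x))
  max.col(-d2, ties.method = "first")
}

#' Full outlier report for a dataset
#'
#' Clusters the rows, computes nearest-centroid distances, the threshold,
#' per-cluster spread statistics and the outlier mask.
#'
#' When heavy contamination is suspected, fitting the cluster model on the
#' audited data itself can hide outliers: a sufficiently tight foreign
#' motion attracts its own centroid and its frames become "inliers" of that
#' cluster. Passing a trusted `reference` dataset fits the centroids on the
#' reference and scores the audited rows against them.
#'
#' @inheritParams cluster_features
#' @param reference Optional trusted `feature_matrix` (or matrix) on which
#'   the cluster model is fitted; default is `fm` itself.
#' @return A `clumm_outlier_report`.
#' @export
outlier_report <- function(fm, c = 3L, seed = 1L, n_init = 10L,
                           reference = NULL) {
  model <- cluster_features(reference %||% fm, c = c, seed = seed,
                            n_init = n_init)
  model$assignments <- assign_clusters(feature_values(fm), model)
  d <- nearest_centroid_distances(fm, model)
  th <- outlier_threshold(d)
  fl <- flag_outliers(d, th$t)
  structure(list(model = model, distances = d, threshold = th$t,
                 mu_d = th$mu_d, sigma_d = th$sigma_d,
                 cluster_stats = cluster_spread_stats(fm, model),
                 outlier_mask = fl$mask, outlier_fraction = fl$fraction),
            class = "clumm_outlier_report")
}

#' @export
print.clumm_outlier_report <- function(x, ...) {
  cat(sprintf("<clumm_outlier_report> c=%d | t=%.4f (mu_d %.4f, sigma_d %.4f) | %.1f%% flagged\n",
              x$model$c, x$threshold, x$mu_d, x$sigma_d,
              100 * x$outlier_fraction))
  invisible(x)
}

#' Landmark-wise outlier analysis
#'
#' Some outlier motions resemble the regular classes at most joints, so the
#' audit is repeated on each landmark's (x, y, z) sub-vector separately:
#' each landmark's coordinates are clustered and thresholded on their own.
#' The aggregate percentage of outlier landmarks is the mean flagged
#' fraction across the ten landmarks.
#'
#' @inheritParams cluster_features
#' @return List with `per_landmark` (data.frame: landmark, fraction,
#'   threshold, mean/max flagged distance) and scalar `pct_outlier_landmarks`
#'   (in percent).
#' @export
landmark_outlier_analysis <- function(fm, c = 3L, seed = 1L, n_init = 10L) {
  x <- feature_values(fm)
  idx <- landmark_indices()
  rows <- lapply(1:10, function(j) {
    sub <- x[, (3 * j - 2):(3 * j), drop = FALSE]
    model <- cluster_features(sub, c = min(c, nrow(sub)),
                              seed = derive_seed(seed, paste0("lm/", j)),
                              n_init = n_init)
    d <- nearest_centroid_distances(sub, model)
    th <- outlier_threshold(d)
    fl <- flag_outliers(d, th$t)
    data.frame(landmark = idx[j], fraction = fl$fraction, threshold = th$t,
               mean_outlier_distance = if (any(fl$mask)) mean(d[fl$mask]) else NA_real_,
               max_outlier_distance = if (any(fl$mask)) max(d[fl$mask]) else NA_real_)
  })
  per_landmark <- do.call(rbind, rows)
  rownames(per_landmark) <- NULL
  list(per_landmark = per_landmark,
       pct_outlier_landmarks = 100 * mean(per_landmark$fraction))
}

#' Outlier-penalized contrastive loss (diagnostic)
#'
#' The NT-Xent denominator of an anchor flagged as an outlier is inflated by
#' `lambda * delta`, where `lambda` is the mean outlier-to-centroid distance
#' and `delta` a weight controlling the impact. With all flags zero this
#' reduces exactly to [nt_xent_loss()]; with `lambda * delta > 0` the loss
#' of every flagged anchor strictly increases. This evaluator quantifies how
#' outliers inflate the contrastive objective; training itself always uses
#' the unpenalized loss.
#'
#' @param projections 2b x d matrix of projections (pair convention as in
#'   [nt_xent_loss()]).
#' @param omega Logical/0-1 outlier flags, length 2b (per anchor) or length
#'   b (per pair, applied to both views).
#' @param lambda Mean outlier-to-centroid distance (>= 0).
#' @param delta Penalty weight, default 1.
#' @param temperature Temperature tau, default 0.5.
#' @return Scalar loss.
#' @export
penalized_nt_xent <- function(projections, omega, lambda, delta = 1,
                              temperature = 0.5) {
  stopifnot(is.matrix(projections), temperature > 0, is.finite(lambda),
            is.finite(delta), delta >= 0)
  n2 <- nrow(projections)
  if (n2 < 2 || n2 %% 2 != 0)
    stop("projections must form complete pairs", call. = FALSE)
  b <- n2 %/% 2
  omega <- as.numeric(omega)
  if (length(omega) == b) omega <- rep(omega, 2)
  stopifnot(length(omega) == n2)
  pos <- c((b + 1):n2, 1:b)
  s <- similarity_matrix(projections, temperature)
  # denominators are sums of exp(similarity / tau) with |cosine| <= 1, so
  # direct summation is safe for any reasonable temperature
  expn <- exp(s)
  diag(expn) <- 0
  denom <- rowSums(expn) + lambda * delta * omega
  loss_i <- log(denom) - s[cbind(seq_len(n2), pos)]
  mean(loss_i)
}

#' Outlier-injection experiment
#'
#' Quantifies how contaminating the unlabeled pretraining data with frames
#' of a foreign motion degrades downstream classification. For each
#' requested count: outlier frames are injected, the encoder is
#' contrastively pretrained on the contaminated data, the landmark-wise
#' outlier audit is run, and the probe is cross-validated on the clean
#' labeled rows using the contaminated encoder. The count-0 row is the
#' uncontaminated pipeline.
#'
#' @param fm Labeled `feature_matrix` of clean data (used for pretraining
#'   and, with its labels, for probe cross-validation).
#' @param counts Integer vector of outlier counts, e.g. `c(0, 100, 200, 500)`.
#' @param outlier_spec [motion_class_spec()] of the injected motion.
#' @param encoder_cfg,augment,pretrain_cfg,probe_cfg Stage configurations.
#' @param c Clusters for the audit, default 3.
#' @param seed Master seed.
#' @return A `clumm_outlier_experiment`: data.frame `report` with one row
#'   per count (count, pct_outlier_landmarks, mean/max outlier distance,
#'   accuracy, precision, recall, f1) plus the per-count details.
#' @export
outlier_experiment <- function(fm, counts = c(0L, 100L, 200L, 500L),
                               outlier_spec = outlier_motion_spec(),
                               encoder_cfg = encoder_config("mlp"),
                               augment = augment_config(),
                               pretrain_cfg = pretrain_config(),
                               probe_cfg = probe_config(),
                               c = 3L, seed = 1L) {
  stopifnot(inherits(fm, "feature_matrix"), !is.null(fm$labels))
  details <- vector("list", length(counts))
  rows <- vector("list", length(counts))
  for (i in seq_along(counts)) {
    n_out <- counts[i]
    inj <- inject_outliers(fm, outlier_spec, n_out,
                           seed = derive_seed(seed, paste0("inject/", n_out)))
    audit <- landmark_outlier_analysis(inj$matrix, c = c,
                                       seed = derive_seed(seed, "audit"))
    full <- outlier_report(inj$matrix, c = c,
                           seed = derive_seed(seed, "audit-full"))
    flagged <- full$distances[full$outlier_mask]
    pre_cfg <- pretrain_cfg
    pre_cfg$seed <- derive_seed(seed, paste0("pretrain/", n_out))
    pt <- pretrain(inj$matrix, encoder_config = encoder_cfg,
                   augment = augment, config = pre_cfg)
    pr_cfg <- probe_cfg
    pr_cfg$seed <- derive_seed(seed, paste0("probe/", n_out))
    cv <- cross_validate(pt$encoder, fm, pr_cfg)
    rows[[i]] <- data.frame(
      count = n_out,
      pct_outlier_landmarks = if (n_out > 0) audit$pct_outlier_landmarks else NA_real_,
      mean_outlier_distance = if (length(flagged)) mean(flagged) else NA_real_,
      max_outlier_distance = if (length(flagged)) max(flagged) else NA_real_,
      accuracy = cv$mean$accuracy, precision = cv$mean$precision,
      recall = cv$mean$recall, f1 = cv$mean$f1)
    details[[i]] <- list(count = n_out, audit = audit, report = full,
                         cv = cv, loss_history = pt$loss_history)
  }
  structure(list(report = do.call(rbind, rows), details = details),
            class = "clumm_outlier_experiment")
}

#' @export
print.clumm_outlier_experiment <- function(x, ...) {
  cat("<clumm_outlier_experiment>\n")
  print(x$report, digits = 3, row.names = FALSE)
  invisible(x)
}
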