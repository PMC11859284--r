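# Shared fixtures and independent oracles used across tests.

# Brute-force NT-Xent evaluation: enumerates every pairwise cosine
# similarity and softmax term independently of the package's vectorized
# implementation.
brute_nt_xent <- function(z, tau) {
  n2 <- nrow(z)
  b <- n2 / 2
  pos <- c((b + 1):n2, 1:b)
  cs <- function(u, v) sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  total <- 0
  for (i in seq_len(n2)) {
    num <- exp(cs(z[i, ], z[pos[i], ]) / tau)
    den <- 0
    for (k in seq_len(n2)) if (k != i) den <- den + exp(cs(z[i, ], z[k, ]) / tau)
    total <- total - log(num / den)
  }
  total / n2
}

# A full 33-landmark frame with deterministic coordinates.
full_frame <- function(offset = 0) {
  lapply(0:32, function(i)
    landmark(i, x = 0.01 * i + offset, y = 0.02 * i + offset, z = 0.001 * i))
}

# Small labeled dataset for probe tests: K well-separated Gaussian blobs in
# d dimensions (already "encoded" features).
blob_features <- function(n_per = 30, K = 3, d = 8, sep = 6, sd = 0.5,
                          seed = 42) {
  withr::with_seed(seed, {
    X <- do.call(rbind, lapply(seq_len(K), function(k) {
      center <- rep(0, d)
      center[k] <- sep
      matrix(stats::rnorm(n_per * d, 0, sd), n_per, d) +
        rep(center, each = n_per)
    }))
    list(X = X, y = factor(rep(letters[seq_len(K)], each = n_per)))
  })
}

# Tiny motion classes with zero noise/dropout for deterministic tests.
clean_classes <- function() default_motion_classes(noise_sd = 0,
                                                   dropout_rate = 0)

# The neutral standing pose as a 30-vector.
standing_pose_vec <- function() as.vector(t(clumm:::standing_pose()))

# An encoder whose representation is exactly the raw 30-d input (a single
# identity-initialized linear layer), for tests that need to isolate the
# probe from representation learning.
identity_encoder <- function() {
  enc <- build_encoder(encoder_config("mlp", repr_dim = 30), seed = 1)
  enc$net <- clumm:::nn_network(list(clumm:::nn_dense(30, 30,
                                                      init = "identity")))
  enc
}
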