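# Random-augmentation module for pose vectors: the two transforms that form
# a positive pair are an additive Gaussian jitter (t1) and a multiplicative
# Gaussian scaling (t2). Unlike image SimCLR the assignment is asymmetric:
# view 1 is always the jittered sample and view 2 the scaled one.

#' Augmentation configuration
#'
#' Jitter noise is drawn elementwise from N(0, `jitter_sd`^2); the scaling
#' factor is a single scalar per sample drawn from
#' N(`scale_center`, `scale_sd`^2).
#'
#' The scaling factor's published center is zero; a factor centered at zero
#' annihilates the signal in expectation and makes the positive pair carry no
#' information about the sample, so the default here is `scale_center = 1`
#' (scaling fluctuates around identity). The literal zero-centered behaviour
#' is available via `paper_literal_scaling = TRUE`. See the methods vignette.
#'
#' @param jitter_sd Jitter standard deviation, default 0.5.
#' @param scale_sd Scaling-factor standard deviation, default 0.2.
#' @param scale_center Scaling-factor mean, default 1.0.
#' @param paper_literal_scaling Logical; force the scaling-factor mean to 0.
#' @return An `augment_config`.
#' @export
augment_config <- function(jitter_sd = 0.5, scale_sd = 0.2, scale_center = 1.0,
                           paper_literal_scaling = FALSE) {
  stopifnot(jitter_sd >= 0, scale_sd >= 0)
  if (isTRUE(paper_literal_scaling)) scale_center <- 0
  structure(list(jitter_sd = jitter_sd, scale_sd = scale_sd,
                 scale_center = scale_center,
                 paper_literal_scaling = isTRUE(paper_literal_scaling)),
            class = "augment_config")
}

#' Random jitter augmentation (t1)
#'
#' Adds elementwise i.i.d. Gaussian noise to a feature vector or to each row
#' of a feature matrix.
#'
#' @param v Numeric vector (length 30) or matrix of feature rows.
#' @param jitter_sd Noise standard deviation.
#' @return Object of the same shape as `v`.
#' @export
jitter_view <- function(v, jitter_sd = 0.5) {
  check_finite(v, "jitter input")
  if (jitter_sd == 0) return(v)
  v + stats::rnorm(length(v), 0, jitter_sd)
}

#' Random scaling augmentation (t2)
#'
#' Multiplies a feature vector by a single random scalar (one factor per
#' sample; for a matrix, one factor per row).
#'
#' @param v Numeric vector or matrix of feature rows.
#' @param scale_sd Factor standard deviation.
#' @param scale_center Factor mean (0 when `paper_literal = TRUE`).
#' @param paper_literal Logical, see [augment_config()].
#' @return Object of the same shape as `v`.
#' @export
scale_view <- function(v, scale_sd = 0.2, scale_center = 1.0,
                       paper_literal = FALSE) {
  check_finite(v, "scale input")
  if (isTRUE(paper_literal)) scale_center <- 0
  if (is.matrix(v)) {
    eta <- stats::rnorm(nrow(v), scale_center, scale_sd)
    v * eta
  } else {
    v * stats::rnorm(1, scale_center, scale_sd)
  }
}

#' Build the positive pair of augmented views for one sample
#'
#' @param v Length-30 feature vector.
#' @param config An [augment_config()].
#' @param seed Optional seed for a reproducible pair.
#' @param source_row Row index of `v` in its dataset, carried through.
#' @return A `view_pair`: list with `view1` (jittered), `view2` (scaled) and
#'   `source_row`.
#' @export
make_view_pair <- function(v, config = augment_config(), seed = NULL,
                           source_row = NA_integer_) {
  draw <- function() list(
    view1 = jitter_view(v, config$jitter_sd),
    view2 = scale_view(v, config$scale_sd, config$scale_center),
    source_row = source_row)
  p <- if (is.null(seed)) draw() else with_seed(seed, draw())
  structure(p, class = "view_pair")
}

# Augment a whole minibatch: rows 1..b are jittered views, rows b+1..2b the
# scaled views (row i pairs with row i + b).
augment_batch <- function(x, config) {
  rbind(jitter_view(x, config$jitter_sd),
        scale_view(x, config$scale_sd, config$scale_center))
}
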