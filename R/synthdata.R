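# Synthetic pose-sequence generator. Emulates the statistical structure the
# framework assumes: a small number of separable motion classes whose frames
# are smooth phase-parameterized trajectories of the ten landmarks of
# interest, with additive Gaussian frame noise and per-landmark dropout
# (whole (x,y,z) triplets zeroed, mirroring how pose backends fail per
# joint). Also supports injecting frames of a foreign motion type as
# outliers for data-audit experiments.

#' Specify a synthetic motion class
#'
#' @param name Class name.
#' @param prototype Function of a phase in `[0, 1]` returning the 30-element
#'   landmark vector (or 10 x 3 matrix) of the noiseless pose at that phase.
#' @param noise_sd Standard deviation of i.i.d. Gaussian noise added to every
#'   coordinate (normalized image units). Default 0.02.
#' @param dropout_rate Probability that each landmark's (x, y, z) triplet is
#'   zeroed (recorded as missing). Default 0.05.
#' @return A `motion_class_spec`.
#' @export
motion_class_spec <- function(name, prototype, noise_sd = 0.02,
                              dropout_rate = 0.05) {
  stopifnot(is.character(name), is.function(prototype),
            noise_sd >= 0, dropout_rate >= 0, dropout_rate <= 1)
  p0 <- as.numeric(prototype(0.5))
  if (length(p0) != 30 || !all(is.finite(p0)))
    stop("prototype must return 30 finite coordinates", call. = FALSE)
  structure(list(name = name, prototype = prototype, noise_sd = noise_sd,
                 dropout_rate = dropout_rate),
            class = "motion_class_spec")
}

# Neutral standing pose in normalized image coordinates (y grows downward,
# subject centered at x = 0.5), rows in landmark-of-interest order.
standing_pose <- function() {
  rbind(
    c(0.42, 0.35, -0.02),  # left shoulder
    c(0.58, 0.35, -0.02),  # right shoulder
    c(0.38, 0.48, -0.01),  # left elbow
    c(0.62, 0.48, -0.01),  # right elbow
    c(0.36, 0.60,  0.00),  # left wrist
    c(0.64, 0.60,  0.00),  # right wrist
    c(0.45, 0.62,  0.00),  # left hip
    c(0.55, 0.62,  0.00),  # right hip
    c(0.45, 0.80,  0.01),  # left knee
    c(0.55, 0.80,  0.01))  # right knee
}

#' Default synthetic motion classes: idle, lift, bend
#'
#' `idle` is a near-static standing pose with a small lateral sway. `lift`
#' cycles between a partially raised and a fully overhead arm position;
#' `bend` cycles between a shallow and a deep forward bend. The moving
#' classes stay inside their motion envelope for the whole cycle (a subject
#' mid-task does not return to the exact neutral stance between frames), so
#' every frame carries class information — the separability the
#' representation learner is meant to exploit. Amplitudes are in normalized
#' image units on a standing pose.
#'
#' @inheritParams motion_class_spec
#' @return Named list of three `motion_class_spec`s.
#' @export
default_motion_classes <- function(noise_sd = 0.02, dropout_rate = 0.05) {
  base <- standing_pose()
  # smooth 0 -> 1 -> 0 cycle over one phase period
  cyc <- function(phase) 0.5 - 0.5 * cos(2 * pi * phase)

  idle <- function(phase) {
    p <- base
    p[, 1] <- p[, 1] + 0.01 * sin(2 * pi * phase)
    p
  }
  lift <- function(phase) {
    s <- cyc(phase)
    p <- base
    p[5:6, 2] <- p[5:6, 2] - (0.12 + 0.26 * s)  # wrists: raised to overhead
    p[3:4, 2] <- p[3:4, 2] - (0.08 + 0.14 * s)  # elbows follow
    p[3:4, 1] <- p[3:4, 1] + c(0.01, -0.01) * (1 + 2 * s)  # elbows tuck in
    p[1:2, 2] <- p[1:2, 2] - (0.01 + 0.02 * s)  # shoulders shrug slightly
    p
  }
  bend <- function(phase) {
    s <- cyc(phase)
    p <- base
    p[1:2, 2] <- p[1:2, 2] + (0.08 + 0.14 * s)  # shoulders drop toward hips
    p[1:2, 3] <- p[1:2, 3] - (0.05 + 0.10 * s)  # torso leans forward
    p[3:4, 2] <- p[3:4, 2] + (0.06 + 0.10 * s)  # elbows lower
    p[5:6, 2] <- p[5:6, 2] + (0.05 + 0.08 * s)  # wrists reach down
    p[7:8, 2] <- p[7:8, 2] + (0.02 + 0.03 * s)  # hips sink
    p[9:10, 2] <- p[9:10, 2] - (0.01 + 0.02 * s)  # knees flex
    p
  }
  list(idle = motion_class_spec("idle", idle, noise_sd, dropout_rate),
       lift = motion_class_spec("lift", lift, noise_sd, dropout_rate),
       bend = motion_class_spec("bend", bend, noise_sd, dropout_rate))
}

#' An outlier motion prototype: a deep squat-and-reach
#'
#' A motion type foreign to the default idle/lift/bend classes, used to
#' inject outlier frames into training data: the whole body drops, knees
#' flex strongly and the arms reach far forward.
#'
#' @param offset Extra uniform vertical displacement added to every landmark,
#'   to control how far the outlier motion sits from the inlier classes.
#' @inheritParams motion_class_spec
#' @return A `motion_class_spec`.
#' @export
outlier_motion_spec <- function(offset = 0.25, noise_sd = 0.02,
                                dropout_rate = 0.05) {
  base <- standing_pose()
  squat <- function(phase) {
    s <- 0.5 - 0.5 * cos(2 * pi * phase)
    p <- base
    p[, 2] <- p[, 2] + offset                 # whole body sits low
    p[1:6, 2] <- p[1:6, 2] + 0.10 * s
    p[5:6, 3] <- p[5:6, 3] - 0.30             # arms reach forward in depth
    p[9:10, 1] <- p[9:10, 1] + c(-0.08, 0.08) # knees splay outward
    p
  }
  motion_class_spec("squat_outlier", squat, noise_sd, dropout_rate)
}

#' Generate a noisy frame sequence for one motion class
#'
#' Frame `t` (t = 1..n) is `prototype(t / n)` plus elementwise Gaussian noise
#' of standard deviation `noise_sd`; each landmark triplet is then
#' independently zeroed with probability `dropout_rate`.
#'
#' @param spec A [motion_class_spec()].
#' @param n_frames Number of frames (> 0).
#' @param seed Optional integer; when supplied the sequence is drawn from
#'   `set.seed(seed)` without disturbing the caller's RNG state.
#' @return An `n_frames` x 30 numeric matrix.
#' @export
generate_sequence <- function(spec, n_frames, seed = NULL) {
  stopifnot(inherits(spec, "motion_class_spec"), n_frames > 0)
  gen <- function() {
    x <- t(vapply(seq_len(n_frames),
                  function(t) as.numeric(spec$prototype(t / n_frames)),
                  numeric(30)))
    if (spec$noise_sd > 0)
      x <- x + matrix(stats::rnorm(length(x), 0, spec$noise_sd), nrow(x))
    if (spec$dropout_rate > 0) {
      drop <- matrix(stats::runif(n_frames * 10) < spec$dropout_rate,
                     n_frames, 10)
      for (j in 1:10) x[drop[, j], (3 * j - 2):(3 * j)] <- 0
    }
    x
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

#' Generate a labeled synthetic dataset
#'
#' @param classes List of [motion_class_spec()]s (at least 2 for
#'   classification experiments); default [default_motion_classes()].
#' @param frames_per_class Frames per class, default 200.
#' @param seed Integer seed; output is byte-identical for identical
#'   `(classes, frames_per_class, seed)`.
#' @return A `feature_matrix` with per-row class labels.
#' @export
generate_dataset <- function(classes = default_motion_classes(),
                             frames_per_class = 200, seed = 1L) {
  stopifnot(length(classes) >= 1, frames_per_class > 0)
  parts <- lapply(seq_along(classes), function(i)
    generate_sequence(classes[[i]], frames_per_class,
                      seed = derive_seed(seed, paste0("synth/", i))))
  x <- do.call(rbind, parts)
  labels <- rep(vapply(classes, function(s) s$name, character(1)),
                each = frames_per_class)
  build_feature_matrix(x, labels = labels)
}

#' Inject outlier frames into a dataset
#'
#' Appends `n_outliers` frames drawn from a foreign motion type and returns
#' the augmented matrix together with a mask marking the injected rows.
#' Injected rows carry an `NA` label.
#'
#' @param fm A `feature_matrix`.
#' @param outlier_spec A [motion_class_spec()] for the outlier motion,
#'   default [outlier_motion_spec()].
#' @param n_outliers Number of frames to inject (>= 0).
#' @param seed Integer seed for the injected sequence.
#' @return List with `matrix` (the augmented `feature_matrix`) and
#'   `outlier_mask` (logical, TRUE on injected rows).
#' @export
inject_outliers <- function(fm, outlier_spec = outlier_motion_spec(),
                            n_outliers, seed = 1L) {
  stopifnot(inherits(fm, "feature_matrix"), n_outliers >= 0)
  if (n_outliers == 0)
    return(list(matrix = fm, outlier_mask = logical(nrow(fm$x))))
  extra <- generate_sequence(outlier_spec, n_outliers,
                             seed = derive_seed(seed, "outlier-inject"))
  labels <- if (!is.null(fm$labels))
    factor(c(as.character(fm$labels), rep(NA, n_outliers)),
           levels = levels(fm$labels))
  out <- build_feature_matrix(rbind(fm$x, extra), labels = labels)
  list(matrix = out,
       outlier_mask = c(logical(nrow(fm$x)), rep(TRUE, n_outliers)))
}
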