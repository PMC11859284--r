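# Landmark selection and per-frame quantization into 30-element feature
# vectors. Pose estimation itself is external: a pose backend is any callable
# mapping one image frame to a set of landmark records (BlazePose numbering,
# 33 points, any subset may be absent).

#' Landmark indices of interest
#'
#' The ten upper- and lower-limb landmarks used for motion features, in fixed
#' order: left/right shoulder (11, 12), left/right elbow (13, 14), left/right
#' wrist (15, 16), left/right hip (23, 24), left/right knee (25, 26). Indices
#' follow the 33-point BlazePose numbering.
#'
#' @return A named integer vector of length 10.
#' @export
landmark_indices <- function() {
  c(left_shoulder = 11L, right_shoulder = 12L,
    left_elbow = 13L, right_elbow = 14L,
    left_wrist = 15L, right_wrist = 16L,
    left_hip = 23L, right_hip = 24L,
    left_knee = 25L, right_knee = 26L)
}

#' Construct a single pose landmark record
#'
#' @param index Integer in `[0, 32]` (BlazePose numbering).
#' @param x,y,z Normalized image coordinates. Non-finite coordinates mark the
#'   landmark as missing.
#' @param present Logical; an absent landmark is stored with zero coordinates.
#' @return A `clumm_landmark` list.
#' @export
landmark <- function(index, x = 0, y = 0, z = 0, present = TRUE) {
  stopifnot(length(index) == 1, index >= 0, index <= 32)
  if (!present || !all(is.finite(c(x, y, z)))) {
    present <- FALSE
    x <- y <- z <- 0
  }
  structure(list(index = as.integer(index), x = x, y = y, z = z,
                 present = present),
            class = "clumm_landmark")
}

# Coerce a backend's frame output (list of landmark records, or a data.frame
# with columns index, x, y, z) into a list of clumm_landmark.
as_landmark_list <- function(frame_landmarks) {
  if (is.data.frame(frame_landmarks)) {
    frame_landmarks <- lapply(seq_len(nrow(frame_landmarks)), function(i)
      landmark(frame_landmarks$index[i], frame_landmarks$x[i],
               frame_landmarks$y[i], frame_landmarks$z[i] %||% 0))
  }
  lapply(frame_landmarks, function(l) {
    if (inherits(l, "clumm_landmark")) l
    else landmark(l$index, l$x %||% 0, l$y %||% 0, l$z %||% 0,
                  l$present %||% TRUE)
  })
}

#' Select the landmarks of interest from one frame's pose output
#'
#' Returns exactly ten landmark records in [landmark_indices()] order,
#' regardless of the arrival order of the backend output. Indices absent from
#' the input (or reported with non-finite coordinates) yield absent landmarks
#' with zero coordinates.
#'
#' @param frame_landmarks List of landmark records (see [landmark()]) or a
#'   data.frame with columns `index`, `x`, `y`, `z`; indices must be unique.
#' @param index_set Integer vector of indices to select, default
#'   [landmark_indices()].
#' @return List of `length(index_set)` `clumm_landmark` records.
#' @export
select_landmarks <- function(frame_landmarks, index_set = landmark_indices()) {
  lms <- as_landmark_list(frame_landmarks)
  idx <- vapply(lms, function(l) l$index, integer(1))
  if (anyDuplicated(idx))
    stop("duplicate landmark indices in frame: malformed pose backend output",
         call. = FALSE)
  lapply(index_set, function(i) {
    j <- match(i, idx)
    if (is.na(j)) landmark(i, present = FALSE) else lms[[j]]
  })
}

#' Quantize one frame's selected landmarks into a 30-element feature vector
#'
#' Coordinates are concatenated as (x, y, z) triplets in selection order;
#' missing landmarks contribute (0, 0, 0).
#'
#' @param selected List of exactly 10 landmark records, in index-set order.
#' @param frame_id Non-negative integer frame identifier.
#' @return Numeric vector of length 30 with a `frame_id` attribute.
#' @export
quantize_frame <- function(selected, frame_id = 0L) {
  if (length(selected) != 10)
    stop("expected exactly 10 selected landmarks, got ", length(selected),
         call. = FALSE)
  v <- unlist(lapply(selected, function(l) {
    if (isTRUE(l$present)) c(l$x, l$y, l$z) else c(0, 0, 0)
  }), use.names = FALSE)
  check_finite(v, "quantized feature vector")
  structure(v, frame_id = as.integer(frame_id))
}

feature_colnames <- function(index_set = landmark_indices()) {
  as.vector(t(outer(paste0("L", index_set), c("x", "y", "z"), paste, sep = "_")))
}

#' Assemble frame feature vectors into a dataset matrix
#'
#' @param frames A list of length-30 numeric vectors (one per frame, see
#'   [quantize_frame()]) or an m x 30 numeric matrix.
#' @param labels Optional per-frame class labels (factor or character),
#'   aligned 1:1 with frames.
#' @param frame_id Optional integer frame identifiers; defaults to the
#'   vectors' `frame_id` attributes or `0:(m-1)`.
#' @return A `feature_matrix` object: list with elements `x` (m x 30 numeric
#'   matrix with named coordinate columns), `labels` (factor or NULL) and
#'   `frame_id` (integer vector).
#' @export
build_feature_matrix <- function(frames, labels = NULL, frame_id = NULL) {
  if (is.matrix(frames)) {
    x <- frames
  } else {
    if (length(frames) == 0) stop("no frames supplied", call. = FALSE)
    lens <- lengths(frames)
    if (any(lens != 30))
      stop("ragged input: all feature vectors must have length 30",
           call. = FALSE)
    if (is.null(frame_id)) {
      ids <- vapply(frames, function(f) attr(f, "frame_id") %||% NA_integer_,
                    integer(1))
      if (!anyNA(ids)) frame_id <- ids
    }
    x <- do.call(rbind, lapply(frames, as.numeric))
  }
  if (ncol(x) != 30)
    stop("feature matrix must have 30 columns, got ", ncol(x), call. = FALSE)
  check_finite(x, "feature matrix")
  colnames(x) <- feature_colnames()
  if (is.null(frame_id)) frame_id <- seq_len(nrow(x)) - 1L
  if (!is.null(labels)) {
    if (length(labels) != nrow(x))
      stop("labels must align 1:1 with rows", call. = FALSE)
    labels <- factor(unname(labels))
  }
  structure(list(x = x, labels = labels, frame_id = as.integer(frame_id)),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d frames x %d coordinates\n",
              nrow(x$x), ncol(x$x)))
  if (!is.null(x$labels)) {
    tab <- table(x$labels)
    cat("labels:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' @export
as.matrix.feature_matrix <- function(x, ...) x$x

#' @export
dim.feature_matrix <- function(x) dim(x$x)

# Accept a feature_matrix or plain numeric matrix / vector.
feature_values <- function(x) {
  if (inherits(x, "feature_matrix")) return(x$x)
  if (is.numeric(x) && is.null(dim(x))) return(matrix(x, nrow = 1))
  if (is.matrix(x)) return(x)
  stop("expected a feature_matrix or numeric matrix", call. = FALSE)
}

#' Extract a feature matrix from image frames via a pose backend
#'
#' Runs the supplied pose-estimation backend on every frame, selects the
#' landmarks of interest and quantizes each frame. A backend failure on a
#' frame yields an all-missing (all-zero) row with a warning, so one corrupt
#' frame does not abort a long video.
#'
#' @param frame_source A list (or vector) of frames; elements are passed to
#'   `backend` unchanged.
#' @param backend A callable: `backend(frame)` returns up to 33 landmark
#'   records (see [landmark()]).
#' @param index_set Landmark indices to keep, default [landmark_indices()].
#' @return A `feature_matrix` with one row per frame, in source order.
#' @export
extract_from_frames <- function(frame_source, backend,
                                index_set = landmark_indices()) {
  stopifnot(is.function(backend))
  frames <- lapply(seq_along(frame_source), function(i) {
    lms <- tryCatch(backend(frame_source[[i]]), error = function(e) {
      warning(sprintf("pose backend failed on frame %d (%s); recording frame as all-missing",
                      i, conditionMessage(e)), call. = FALSE)
      list()
    })
    quantize_frame(select_landmarks(lms, index_set), frame_id = i - 1L)
  })
  build_feature_matrix(frames)
}

#' Write a feature matrix to disk
#'
#' CSV layout: a `frame_id` column followed by 30 named coordinate columns
#' (`L11_x,...,L26_z`); '.' decimal, UTF-8. `.rds` writes the binary twin.
#' Labels, when present, go to a separate two-column CSV (`frame_id,label`).
#'
#' @param fm A `feature_matrix`.
#' @param path Output path; format chosen by extension (`.csv` or `.rds`).
#' @param labels_path Optional path for the labels CSV.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(fm, path, labels_path = NULL) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (grepl("\\.rds$", path, ignore.case = TRUE)) {
    saveRDS(fm, path)
  } else {
    # %.17g guarantees an exact double round-trip through the text format
    num <- apply(fm$x, 2, function(col) sprintf("%.17g", col))
    df <- data.frame(frame_id = fm$frame_id, num, check.names = FALSE)
    colnames(df) <- c("frame_id", colnames(fm$x))
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  if (!is.null(labels_path) && !is.null(fm$labels)) {
    utils::write.csv(data.frame(frame_id = fm$frame_id,
                                label = as.character(fm$labels)),
                     labels_path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read a feature matrix written by [write_feature_matrix()]
#'
#' @param path CSV or RDS path.
#' @param labels_path Optional labels CSV (`frame_id,label`), joined on
#'   frame_id.
#' @return A `feature_matrix`.
#' @export
read_feature_matrix <- function(path, labels_path = NULL) {
  if (grepl("\\.rds$", path, ignore.case = TRUE)) {
    fm <- readRDS(path)
    stopifnot(inherits(fm, "feature_matrix"))
  } else {
    df <- utils::read.csv(path, check.names = FALSE)
    fm <- build_feature_matrix(as.matrix(df[, -1, drop = FALSE]),
                               frame_id = df$frame_id)
  }
  if (!is.null(labels_path)) {
    lab <- utils::read.csv(labels_path)
    fm$labels <- factor(lab$label[match(fm$frame_id, lab$frame_id)])
  }
  fm
}
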