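test_that("landmark selection returns the ten limb landmarks in fixed order", {
  sel <- select_landmarks(full_frame())
  expect_length(sel, 10)
  expect_identical(unname(vapply(sel, `[[`, integer(1), "index")),
                   unname(landmark_indices()))
  expect_true(all(vapply(sel, `[[`, logical(1), "present")))
  # arrival order must not matter
  shuffled <- full_frame()[sample(33)]
  sel2 <- select_landmarks(shuffled)
  expect_identical(quantize_frame(sel2), quantize_frame(sel))
})

test_that("absent landmarks come back as zeros, partial frames fill in place", {
  sel <- select_landmarks(list())
  expect_true(all(!vapply(sel, `[[`, logical(1), "present")))
  expect_identical(as.numeric(quantize_frame(sel)), rep(0, 30))

  one <- select_landmarks(list(landmark(23, 0.4, 0.5, 0.1)))
  v <- quantize_frame(one)
  expect_equal(as.numeric(v[19:21]), c(0.4, 0.5, 0.1))  # 7th triplet
  expect_identical(as.numeric(v[-(19:21)]), rep(0, 27))
})

test_that("malformed backend output is rejected", {
  dup <- list(landmark(11, 0.1, 0.1), landmark(11, 0.2, 0.2))
  expect_error(select_landmarks(dup), "duplicate")
  expect_error(quantize_frame(select_landmarks(full_frame())[1:9]),
               "10 selected landmarks")
})

test_that("non-finite backend coordinates are treated as missing", {
  lms <- list(landmark(11, NaN, 0.5), landmark(12, 0.3, Inf),
              landmark(13, 0.2, 0.4, 0.1))
  v <- quantize_frame(select_landmarks(lms))
  expect_true(all(is.finite(v)))
  expect_identical(as.numeric(v[1:6]), rep(0, 6))   # both bad landmarks zeroed
  expect_equal(as.numeric(v[7:9]), c(0.2, 0.4, 0.1))
})

test_that("quantized vectors stack into a dataset matrix preserving order", {
  frames <- lapply(1:5, function(i)
    quantize_frame(select_landmarks(full_frame(offset = i / 10)),
                   frame_id = i - 1L))
  fm <- build_feature_matrix(frames, labels = rep(c("a", "b"), c(2, 3)))
  expect_identical(dim(fm$x), c(5L, 30L))
  expect_identical(unname(fm$x), unname(do.call(rbind, lapply(frames, as.numeric))))
  expect_identical(as.character(fm$labels), rep(c("a", "b"), c(2, 3)))
  expect_error(build_feature_matrix(list(1:30, 1:29)), "ragged")
  expect_error(build_feature_matrix(list()), "no frames")
})

test_that("feature matrices round-trip through CSV and RDS bit-exactly", {
  fm <- generate_dataset(frames_per_class = 5, seed = 3)
  csv <- withr::local_tempfile(fileext = ".csv")
  lab <- withr::local_tempfile(fileext = ".csv")
  rds <- withr::local_tempfile(fileext = ".rds")
  write_feature_matrix(fm, csv, labels_path = lab)
  back <- read_feature_matrix(csv, labels_path = lab)
  expect_identical(back$x, fm$x)
  expect_identical(back$labels, fm$labels)
  expect_identical(back$frame_id, fm$frame_id)
  write_feature_matrix(fm, rds)
  expect_identical(read_feature_matrix(rds)$x, fm$x)
})

test_that("frame extraction runs the backend per frame and survives failures", {
  fixed <- function(frame) full_frame()
  fm <- extract_from_frames(1:4, fixed)
  expect_identical(dim(fm$x), c(4L, 30L))
  expect_true(all(fm$x == rep(fm$x[1, ], each = 4)))

  none <- function(frame) list()
  expect_identical(unname(extract_from_frames(1:3, none)$x),
                   matrix(0, 3, 30))

  scripted <- function(frame) list(landmark(15, frame / 10, 0.5))
  fm2 <- extract_from_frames(1:3, scripted)
  expect_equal(unname(fm2$x[, 13]), c(0.1, 0.2, 0.3))  # L15_x column

  flaky <- function(frame) if (frame == 2) stop("decode error") else full_frame()
  expect_warning(fm3 <- extract_from_frames(1:3, flaky), "frame 2")
  expect_identical(as.numeric(fm3$x[2, ]), rep(0, 30))
  expect_false(any(fm3$x[c(1, 3), ] == 0))
})
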