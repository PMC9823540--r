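test_that("8-bit rescaling maps linearly, rounds half-to-even, handles degenerate input", {
  # fixed HU-style range: endpoints map to 0 and 255
  v <- array(c(-1024, 3071, 1023.5), c(3, 1, 1))
  out <- rescale_to_8bit(v, "fixed_range", range = c(-1024, 3071))
  expect_identical(out[1, 1, 1], 0L)
  expect_identical(out[2, 1, 1], 255L)
  # identity on an already-8-bit volume
  v8 <- array(0:255, c(16, 16, 1))
  expect_equal(as.vector(rescale_to_8bit(v8, "fixed_range", range = c(0, 255))), 0:255)
  # constant volume: all-zero, not an error
  expect_equal(max(rescale_to_8bit(array(7, c(4, 4, 2)))), 0)
  expect_error(rescale_to_8bit(numeric(0)), "empty")
  expect_error(rescale_to_8bit(v, "fixed_range", range = c(5, 5)), "lo < hi")
  # monotone on random volumes
  set.seed(1)
  for (i in 1:5) {
    x <- array(rnorm(64), c(4, 4, 4))
    y <- rescale_to_8bit(x)
    o <- order(x)
    expect_true(all(diff(y[o]) >= 0))
    expect_true(min(y) >= 0 && max(y) <= 255)
  }
})

test_that("bounding boxes are tight, per-component, 0-based inclusive", {
  m <- matrix(0, 8, 8)
  m[4, 5] <- 1   # single pixel at 0-based (3, 4)
  bb <- fit_bounding_boxes(m)
  expect_equal(unlist(bb), c(row_min = 3, col_min = 4, row_max = 3, col_max = 4))
  expect_equal(nrow(fit_bounding_boxes(matrix(0, 4, 4))), 0)
  # two disjoint 2x2 blobs
  m2 <- matrix(0, 8, 8)
  m2[1:2, 1:2] <- 1
  m2[6:7, 5:6] <- 1
  bb2 <- fit_bounding_boxes(m2, per_component = TRUE)
  expect_equal(nrow(bb2), 2)
  expect_equal(bb2$row_max - bb2$row_min, c(1, 1))
  expect_equal(bb2$col_max - bb2$col_min, c(1, 1))
  expect_error(fit_bounding_boxes(matrix(2, 2, 2)), "binary")
})

test_that("bounding boxes agree with a brute-force component scan on random masks", {
  set.seed(42)
  for (i in 1:40) {
    m <- matrix(rbinom(256, 1, 0.2), 16, 16)
    got <- fit_bounding_boxes(m)
    want <- oracle_boxes(m)
    if (is.null(want)) {
      expect_equal(nrow(got), 0)
    } else {
      key <- function(b) do.call(order, as.list(b))
      got <- got[key(got), , drop = FALSE]
      want <- want[key(want), , drop = FALSE]
      expect_equal(unname(as.matrix(got)), unname(as.matrix(want)))
    }
    # one overall box is the envelope of the per-component boxes
    if (any(m > 0)) {
      all1 <- fit_bounding_boxes(m, per_component = FALSE)
      expect_equal(all1$row_min, min(want$row_min))
      expect_equal(all1$col_max, max(want$col_max))
    }
  }
})

test_that("slice filtering keeps exactly the ROI-bearing slices with their indices", {
  set.seed(3)
  img <- array(runif(16 * 16 * 10), c(16, 16, 10))
  msk <- array(0L, c(16, 16, 10))
  with_roi <- c(1, 2, 4, 6, 7, 8, 10)
  for (s in with_roi) msk[5:8, 5:8, s] <- 1L
  st <- patient_study("s1", img, msk)
  f <- filter_slices_with_roi(st)
  expect_equal(dim(f$slices)[3], 7)
  expect_equal(f$slice_indices, as.integer(with_roi - 1))
  # identity when all slices carry ROI
  all_roi <- patient_study("s2", img[, , with_roi], msk[, , with_roi])
  expect_equal(filter_slices_with_roi(all_roi)$slices, all_roi$slices)
  # all-empty study is unusable
  expect_error(filter_slices_with_roi(patient_study("s3", img, array(0L, dim(img)))),
               "unusable")
})

test_that("study invariants are enforced at construction", {
  img <- array(0, c(8, 8, 3))
  expect_error(patient_study("x", img, array(0, c(8, 8, 2))), "shape")
  expect_error(patient_study("x", img, array(2, c(8, 8, 3))), "binary")
  expect_error(patient_study("x", img, array(0, c(8, 8, 3)), slice_indices = c(2, 1, 3)),
               "increasing")
})

test_that("study IO round trips bit-exactly in both dialects", {
  set.seed(9)
  img <- array(sample(0:255, 16 * 16 * 5, replace = TRUE), c(16, 16, 5))
  msk <- array(0L, c(16, 16, 5))
  msk[4:9, 6:11, ] <- 1L
  st <- patient_study("rt01", img, msk, pixel_spacing = 0.7,
                      slice_indices = c(0L, 2L, 3L, 7L, 9L))
  for (fmt in c("nifti", "png_stack")) {
    d <- file.path(tempfile(), "study")
    write_study(st, d, fmt)
    back <- load_study(d, fmt)
    expect_equal(back$slices, st$slices, ignore_attr = TRUE)
    expect_equal(back$gt_masks, st$gt_masks, ignore_attr = TRUE)
    expect_equal(back$slice_indices, st$slice_indices)
    expect_equal(back$pixel_spacing, st$pixel_spacing)
    expect_equal(back$study_id, st$study_id)
  }
  # missing mask and non-binary mask are rejected
  d2 <- file.path(tempfile(), "broken")
  write_study(st, d2, "nifti")
  file.remove(file.path(d2, "mask.nii.gz"))
  expect_error(load_study(d2), "mask")
  d3 <- file.path(tempfile(), "nonbinary")
  st_bad <- st
  st_bad$gt_masks[1, 1, 1] <- 2L
  dir.create(d3, recursive = TRUE)
  img_i <- st_bad$slices; storage.mode(img_i) <- "integer"
  msk_i <- st_bad$gt_masks; storage.mode(msk_i) <- "integer"
  RNifti::writeNifti(RNifti::asNifti(img_i), file.path(d3, "image.nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(msk_i), file.path(d3, "mask.nii.gz"))
  jsonlite::write_json(list(study_id = "bad", pixel_spacing = 1,
                            slice_indices = 0:4),
                       file.path(d3, "study.json"), auto_unbox = TRUE)
  expect_error(load_study(d3), "binary")
})
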