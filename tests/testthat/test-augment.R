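make_test_study <- function(S = 10, L = 16, seed = 1) {
  set.seed(seed)
  img <- array(runif(L * L * S, 0, 255), c(L, L, S))
  msk <- array(0L, c(L, L, S))
  msk[5:9, 6:10, ] <- 1L
  patient_study("aug01", img, msk)
}

test_that("sequence building centers every slice once with correct padding", {
  st <- make_test_study(S = 10)
  maps <- lapply(1:10, function(s) attention_map(matrix(0.3, 16, 16)))
  for (N in c(3, 5, 7)) {
    seqs <- build_sequences(st, maps, N = N)
    expect_length(seqs, 10)
    h <- (N - 1) / 2
    for (s in seq_along(seqs)) {
      sq <- seqs[[s]]
      expect_length(sq$pairs, N)
      expect_equal(sq$target_index, h + 1)
      # the target pair is the slice itself
      expect_equal(sq$pairs[[sq$target_index]]$slice, st$slices[, , s])
      expect_equal(sq$target_gt, st$gt_masks[, , s])
      offs <- (s - h):(s + h)
      expect_equal(sq$padding_flags, offs < 1 | offs > 10)
    }
    # every slice is a target exactly once
    targets <- vapply(seqs, `[[`, integer(1), "slice_index")
    expect_equal(sort(targets), st$slice_indices)
  }
  # boundary replication at the volume start
  seqs5 <- build_sequences(st, maps, N = 5)
  first <- seqs5[[1]]
  expect_equal(first$padding_flags, c(TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(first$pairs[[1]]$slice, st$slices[, , 1])
  expect_equal(first$pairs[[2]]$slice, st$slices[, , 1])
  # reflect mirrors instead of clamping
  seqr <- build_sequences(st, maps, N = 5, boundary = "reflect")
  expect_equal(seqr[[1]]$pairs[[1]]$slice, st$slices[, , 3])
  expect_equal(seqr[[1]]$pairs[[2]]$slice, st$slices[, , 2])
  expect_error(build_sequences(st, maps, N = 4), "odd")
  expect_error(build_sequences(st, maps, N = -1), ">= 1")
  expect_error(build_sequences(st, maps[1:3], N = 3), "per slice")
})

test_that("elastic deformation is seeded, mask-safe, and identity at alpha 0", {
  st <- make_test_study(S = 1, L = 24, seed = 2)
  img <- st$slices[, , 1]; msk <- st$gt_masks[, , 1]
  id <- elastic_deform(img, msk, augmentation_spec(elastic_alpha = 0, seed = 1))
  expect_identical(id$image, img)
  expect_identical(id$mask, msk)
  sp <- augmentation_spec(elastic_alpha = 3, elastic_sigma = 2, seed = 7)
  a <- elastic_deform(img, msk, sp)
  b <- elastic_deform(img, msk, sp)
  expect_identical(a, b)
  expect_false(identical(a$image, img))
  # the warped mask stays binary over many random fields
  for (s in 1:100) {
    out <- elastic_deform(img, msk,
                          augmentation_spec(elastic_alpha = 4, elastic_sigma = 2,
                                            seed = s))
    expect_true(all(out$mask %in% c(0, 1)))
  }
})

test_that("rotation stays within the configured angle and round trips", {
  st <- make_test_study(S = 1, L = 32, seed = 3)
  img <- st$slices[, , 1]; msk <- st$gt_masks[, , 1]
  expect_identical(random_rotate(img, msk, augmentation_spec(rotation_max_deg = 0))$image,
                   img)
  # sampled angles over 1000 seeded draws all within +/- 10 degrees
  angles <- vapply(1:1000, function(s)
    random_rotate(img, msk, augmentation_spec(seed = s))$angle_deg, numeric(1))
  expect_true(all(abs(angles) <= 10))
  expect_gt(max(abs(angles)), 5)   # the range is actually exercised
  # rotating by theta then -theta restores the mask up to interpolation
  sp <- augmentation_spec(rotation_max_deg = 10, elastic_alpha = 0, seed = 21)
  fwd <- random_rotate(img, msk, sp)
  co <- thrombseg:::rotate_coords(-fwd$angle_deg * pi / 180, 32, 32)
  back_mask <- thrombseg:::warp_nearest(fwd$mask, co$r, co$c)
  expect_gte(compute_metrics(back_mask, msk)$Dice, 0.95)
})

test_that("image and mask always receive the identical geometric transform", {
  # transforming a coordinate grid through the image path and the mask path
  # must agree wherever both are defined
  L <- 24
  grid_r <- matrix(rep(1:L, L), L, L)
  sp <- augmentation_spec(rotation_max_deg = 8, elastic_alpha = 3,
                          elastic_sigma = 2, seed = 13)
  tr <- thrombseg:::sample_transform(sp, L, L)
  co_rot <- thrombseg:::rotate_coords(tr$theta, L, L)
  co_el <- thrombseg:::elastic_coords(tr, L, L)
  # same sampled parameters regardless of which op consumes them
  tr2 <- thrombseg:::sample_transform(sp, L, L)
  expect_identical(tr, tr2)
  # nearest-neighbour grid lookup equals rounded bilinear lookup of the grid
  nn <- thrombseg:::warp_nearest(grid_r, co_rot$r, co_rot$c)
  bl <- thrombseg:::warp_bilinear(grid_r, co_rot$r, co_rot$c)
  inside <- nn > 0 & bl > 0
  expect_lt(max(abs(nn[inside] - bl[inside])), 1)
})

test_that("whole-sequence augmentation shares one transform across all pairs", {
  st <- make_test_study(S = 5, L = 24, seed = 5)
  # constant-content slices: identical inputs must stay identical under a
  # shared warp, and differ under per-slice independent warps
  img <- st$slices[, , 1]
  for (s in 1:5) { st$slices[, , s] <- img }
  maps <- lapply(1:5, function(s) attention_map(matrix(0.5, 24, 24)))
  seqs <- build_sequences(st, maps, N = 5)
  aug <- augment_sequence(seqs[[3]], augmentation_spec(seed = 31))
  for (t in 2:5)
    expect_identical(aug$pairs[[t]]$slice, aug$pairs[[1]]$slice)
  expect_true(all(aug$target_gt %in% c(0, 1)))
  # disabled spec is the identity
  off <- augment_sequence(seqs[[3]], augmentation_spec(enabled = FALSE))
  expect_identical(off, seqs[[3]])
})
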