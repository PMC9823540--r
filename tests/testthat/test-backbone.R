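test_that("detector configuration validates its contract and serializes", {
  expect_error(detector_config(anchor_scales = c(32, 64)), "3 anchor scales")
  expect_error(detector_config(anchor_ratios = c(1, 2)), "aspect ratios")
  expect_error(detector_config(score_threshold = 1.4), "score_threshold")
  cfg <- detector_config(anchor_scales = c(16, 48, 96), score_threshold = 0.4)
  f <- tempfile(fileext = ".yaml")
  write_detector_config(cfg, f)
  expect_equal(read_detector_config(f), cfg)
})

test_that("an untrained detector yields no detections on a blank slice", {
  det <- configure_detector(detector_config(), seed = 1)
  blank <- matrix(0, 24, 24)
  out <- detect_instances(det, blank)
  expect_equal(nrow(out$boxes), 0)
  m <- extract_attention_map(blank, det, allow_untrained = TRUE)
  expect_true(all(attention_values(m) == 0))
  expect_equal(m$provider_tag, "detector")
})

test_that("attention maps respect the [0,1] clamp and provider contracts", {
  set.seed(6)
  img <- matrix(runif(24 * 24, 0, 255), 24, 24)
  bb <- lightweight_backbone(filters = 4, seed = 2)
  expect_error(extract_attention_map(img, bb), "untrained")
  m <- extract_attention_map(img, bb, allow_untrained = TRUE)
  expect_true(all(attention_values(m) >= 0 & attention_values(m) <= 1))
  expect_equal(dim(attention_values(m)), dim(img))
  expect_equal(m$provider_tag, "lightweight")
  # forcing the output bias far negative saturates the sigmoid to ~0
  bb_neg <- bb
  bb_neg$net$out$b <- -20
  m0 <- extract_attention_map(img, bb_neg, allow_untrained = TRUE)
  expect_lt(max(attention_values(m0)), 1e-6)
  # raw constructor clamps out-of-range values
  clamped <- attention_map(matrix(c(-0.5, 0.2, 1.7, 1), 2, 2))
  expect_equal(range(attention_values(clamped)), c(0, 1))
  # determinism for fixed provider parameters
  expect_identical(extract_attention_map(img, bb, allow_untrained = TRUE),
                   extract_attention_map(img, bb, allow_untrained = TRUE))
})

test_that("backbone training reduces loss, is seeded, and guards its inputs", {
  studies <- tiny_phantom_pair()
  bb <- lightweight_backbone(filters = 4, seed = 1)
  expect_error(train_backbone(bb, list()), "empty")
  # slices without ROI must be filtered out first
  bad <- studies[[1]]
  bad$gt_masks[, , 2] <- 0L
  expect_error(train_backbone(bb, list(bad)), "filter_slices_with_roi")
  # zero learning rate leaves the parameters untouched
  r0 <- train_backbone(bb, studies, lr = 0, steps = 5, seed = 1)
  expect_equal(r0$provider$net, bb$net)
  # a real run records a decreasing loss trend
  r <- train_backbone(bb, studies, lr = 2, steps = 120, alpha = 0.75, seed = 1)
  expect_length(r$trace, 120)
  expect_lt(mean(utils::tail(r$trace, 20)), mean(utils::head(r$trace, 20)))
  expect_identical(r$trace,
                   train_backbone(bb, studies, lr = 2, steps = 120,
                                  alpha = 0.75, seed = 1)$trace)
})

test_that("detector and lightweight providers are interchangeable downstream", {
  studies <- tiny_phantom_pair()
  st <- studies[[1]]
  bb <- lightweight_backbone(filters = 4, seed = 3)
  det <- configure_detector(detector_config(), seed = 3)
  cfg <- head_config(residual_filters = 3, clstm_filters = 4, fusion_filters = 3)
  model <- biclstm_head(cfg, seed = 4)
  for (prov in list(bb, det)) {
    maps <- lapply(seq_len(dim(st$slices)[3]), function(s)
      extract_attention_map(st$slices[, , s], prov, allow_untrained = TRUE))
    seqs <- build_sequences(st, maps, N = 3)
    pr <- predict(model, seqs[[2]])
    expect_equal(dim(pr$prob), dim(st$slices)[1:2])
  }
})

test_that("a trained detector pastes only its best instance into the map", {
  studies <- tiny_phantom_pair()
  det <- configure_detector(detector_config(), seed = 1)
  det <- train_backbone(det, studies, lr = 2, steps = 300, alpha = 0.75,
                        seed = 1)$provider
  st <- studies[[1]]
  out <- detect_instances(det, st$slices[, , 1])
  skip_if(nrow(out$boxes) == 0, "detector found no instance on this draw")
  m <- attention_values(extract_attention_map(st$slices[, , 1], det))
  best <- out$masks[[which.max(out$boxes$score)]]
  expect_equal(m, best)
  # nonzero support is a single connected candidate region
  lab <- thrombseg:::label_components((m > 0) * 1, 8L)
  expect_equal(max(lab), 1)
})
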