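test_that("residual blocks honor identity, shape and direct-convolution contracts", {
  # zero F-path on a non-negative 64-channel input is the identity
  set.seed(1)
  x <- array(abs(rnorm(5 * 5 * 4)), c(5, 5, 4))
  blk <- thrombseg:::new_res_block(3L, 4L, 4L)
  blk$conv1$W[] <- 0; blk$conv2$W[] <- 0
  expect_equal(residual_block(x, params = blk), x, tolerance = 1e-12)
  # channel projection: 2-channel input, 64-channel output, same spatial dims
  y <- residual_block(array(rnorm(6 * 7 * 2), c(6, 7, 2)), filters = 64)
  expect_equal(dim(y), c(6, 7, 64))
  # the block's convolution agrees with a direct triple-loop oracle
  xin <- array(rnorm(5 * 5 * 1), c(5, 5, 1))
  W <- array(rnorm(3 * 3 * 1 * 2, sd = 0.3), c(3, 3, 1, 2))
  b <- rnorm(2)
  got <- thrombseg:::conv2d(xin, W, b)$out
  expect_equal(thrombseg:::slice4(got, 1), naive_conv2d(xin, W, b), tolerance = 1e-5)
})

test_that("focal loss matches its closed forms", {
  set.seed(4)
  # gamma = 0, alpha = 0.5 is half the mean binary cross-entropy
  for (i in 1:20) {
    p <- matrix(runif(64, 0.01, 0.99), 8, 8)
    g <- matrix(rbinom(64, 1, 0.4), 8, 8)
    bce <- -mean(g * log(p) + (1 - g) * log(1 - p))
    expect_equal(focal_loss(p, g, alpha = 0.5, gamma = 0), 0.5 * bce,
                 tolerance = 1e-6)
  }
  # perfect prediction: loss vanishes (up to the epsilon clamp)
  g <- matrix(rbinom(64, 1, 0.3), 8, 8)
  expect_lt(focal_loss(g, g, alpha = 0.25, gamma = 2), 1e-5)
  # single-pixel hand evaluation: -alpha (1-p)^gamma log p
  expect_equal(focal_loss(matrix(0.9), matrix(1), alpha = 0.25, gamma = 2),
               -0.25 * 0.1^2 * log(0.9), tolerance = 1e-9)
  expect_error(focal_loss(matrix(1.2), matrix(1)), "\\[0, 1\\]")
})

test_that("prediction respects sigmoid range, tie rule and shape", {
  cfg <- head_config(residual_filters = 4, clstm_filters = 6, fusion_filters = 4)
  model <- biclstm_head(cfg, seed = 2)
  st <- generate_study(phantom_params(image_size = 32, n_slices = 5,
                                      center_drift = 1, seed = 3))
  maps <- lapply(1:5, function(s) attention_map(matrix(0.5, 32, 32)))
  seqs <- build_sequences(st, maps, N = 5)
  pr <- predict(model, seqs[[3]])
  expect_equal(dim(pr$prob), c(32, 32))
  expect_true(all(pr$prob >= 0 & pr$prob <= 1))
  expect_true(all(pr$mask %in% 0:1))
  # zero final conv: logits 0, probabilities exactly 1/2, and the >= tie
  # rule sends every pixel to foreground at threshold 0.5
  model0 <- model
  model0$params$out$W[] <- 0
  model0$params$out$b[] <- 0
  pr0 <- predict(model0, seqs[[3]])
  expect_true(all(pr0$prob == 0.5))
  expect_true(all(pr0$mask == 1))
  # all-slices scope yields one map per position
  pr_all <- predict(model, seqs[[3]], scope = "all_slices")
  expect_equal(dim(pr_all$prob), c(32, 32, 5))
})

test_that("head gradients match finite differences through every layer group", {
  set.seed(7)
  cfg <- head_config(residual_filters = 3, clstm_filters = 4, fusion_filters = 3,
                     focal_alpha = 0.3, focal_gamma = 2)
  model <- biclstm_head(cfg, seed = 3)
  H <- 6; W <- 5; N <- 3
  x <- array(runif(H * W * 2 * N), c(H, W, 2, N))
  gt <- matrix(rbinom(H * W, 1, 0.3), H, W)
  lossfun <- function(m) {
    fwd <- thrombseg:::head_fwd(m, x, train = TRUE, scope = "target_slice")
    p <- thrombseg:::sigmoid(fwd$logits)
    focal_loss(matrix(p, H, W), gt, cfg$focal_alpha, cfg$focal_gamma)
  }
  fwd <- thrombseg:::head_fwd(model, x, train = TRUE, scope = "target_slice")
  p <- thrombseg:::sigmoid(fwd$logits)
  dl <- thrombseg:::focal_grad_logit(p, array(gt, dim(p)), cfg$focal_alpha,
                                     cfg$focal_gamma)
  bwd <- thrombseg:::head_bwd(model, fwd, dl, train = TRUE)
  set_in <- function(params, path, val) {
    if (length(path) == 1) { params[[path]] <- val; return(params) }
    params[[path[1]]] <- set_in(params[[path[1]]], path[-1], val)
    params
  }
  for (path in list(c("res1", "conv1", "W"), c("res1", "bn1", "gamma"),
                    c("res1", "proj", "W"), c("res2", "conv2", "W"),
                    c("fwd", "W"), c("fwd", "pc"), c("bwd", "W"),
                    c("fus", "W"), c("out", "W"), c("out", "b"))) {
    g_an <- bwd$grads; p_cur <- model$params
    for (k in path) { g_an <- g_an[[k]]; p_cur <- p_cur[[k]] }
    ii <- if (length(p_cur) <= 4) seq_along(p_cur) else sort(sample(length(p_cur), 4))
    for (i in ii) {
      eps <- 1e-5
      m2 <- model
      val <- p_cur
      val[i] <- val[i] + eps
      m2$params <- set_in(model$params, path, val)
      lp <- lossfun(m2)
      val[i] <- val[i] - 2 * eps
      m2$params <- set_in(model$params, path, val)
      lm <- lossfun(m2)
      num <- (lp - lm) / (2 * eps)
      expect_equal(g_an[i], num, tolerance = 1e-4,
                   label = paste(paste(path, collapse = "$"), i))
    }
  }
})

test_that("head training is deterministic and a zero learning rate is a no-op", {
  studies <- tiny_phantom_pair()
  st <- studies[[1]]
  maps <- lapply(seq_len(dim(st$slices)[3]), function(s)
    attention_map(oracle_threshold_mask(st$slices[, , s],
                                        phantom_params()$intensity_levels)))
  seqs <- build_sequences(st, maps, N = 3)
  cfg <- head_config(residual_filters = 3, clstm_filters = 4, fusion_filters = 3)
  model <- biclstm_head(cfg, seed = 5)
  tr0 <- train_head(model, seqs, lr = 0, steps = 5, seed = 9)
  expect_equal(tr0$model$params, model$params)
  t1 <- train_head(model, seqs, lr = 0.1, steps = 5, seed = 9)
  t2 <- train_head(model, seqs, lr = 0.1, steps = 5, seed = 9)
  expect_identical(t1$trace, t2$trace)
  expect_identical(t1$model$params, t2$model$params)
  expect_error(train_head(model, list(), steps = 1), "empty")
})

test_that("checkpoints round trip the full model", {
  cfg <- head_config(residual_filters = 3, clstm_filters = 4, fusion_filters = 3)
  model <- biclstm_head(cfg, seed = 1)
  f <- tempfile(fileext = ".rds")
  save_checkpoint(model, f)
  back <- load_checkpoint(f)
  expect_equal(back, model)
  bad <- tempfile(fileext = ".rds")
  saveRDS(list(1), bad)
  expect_error(load_checkpoint(bad), "checkpoint")
})
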