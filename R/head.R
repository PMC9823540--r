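#' Configuration of the Bi-CLSTM segmentation head
#'
#' The head consumes a sequence of (slice, attention map) pairs stacked as
#' 2-channel inputs, encodes each pair with two residual blocks, runs a
#' bidirectional ConvLSTM over the encoded sequence, fuses the two
#' directions, and decodes the fused target-position features through a
#' fusion convolution and a final 1x1 logit convolution into a per-pixel
#' thrombus probability. Training uses focal loss to counter the heavy
#' foreground/background imbalance.
#'
#' @param residual_filters channels of the residual blocks (default 64).
#' @param clstm_filters hidden channels per ConvLSTM direction (default 128).
#' @param fusion_filters channels of the post-fusion convolution (default 64).
#' @param fusion_mode `"concat"` (default) or `"sum"`.
#' @param focal_alpha foreground weight of the focal loss, in `[0, 1]`.
#' @param focal_gamma focusing exponent, `>= 0`.
#' @param prediction_threshold probability cut for the binary mask; the
#'   comparison is `>=`, so exact ties go to foreground.
#' @param output_scope `"target_slice"` (default) segments only the central
#'   slice of each sequence; `"all_slices"` returns one map per position.
#' @param kernel_size odd convolution kernel extent (default 3).
#' @param peephole enable ConvLSTM cell-to-gate connections (default `TRUE`).
#' @return An object of class `head_config`.
#' @export
head_config <- function(residual_filters = 64L, clstm_filters = 128L,
                        fusion_filters = 64L, fusion_mode = c("concat", "sum"),
                        focal_alpha = 0.25, focal_gamma = 2,
                        prediction_threshold = 0.5,
                        output_scope = c("target_slice", "all_slices"),
                        kernel_size = 3L, peephole = TRUE) {
  fusion_mode <- match.arg(fusion_mode)
  output_scope <- match.arg(output_scope)
  if (focal_alpha < 0 || focal_alpha > 1) stop("focal_alpha must be in [0, 1]", call. = FALSE)
  if (focal_gamma < 0) stop("focal_gamma must be >= 0", call. = FALSE)
  if (prediction_threshold < 0 || prediction_threshold > 1)
    stop("prediction_threshold must be in [0, 1]", call. = FALSE)
  structure(list(residual_filters = as.integer(residual_filters),
                 clstm_filters = as.integer(clstm_filters),
                 fusion_filters = as.integer(fusion_filters),
                 fusion_mode = fusion_mode, focal_alpha = focal_alpha,
                 focal_gamma = focal_gamma,
                 prediction_threshold = prediction_threshold,
                 output_scope = output_scope,
                 kernel_size = as.integer(kernel_size),
                 peephole = isTRUE(peephole)),
            class = "head_config")
}

he_init <- function(k, cin, cout) {
  array(stats::rnorm(k * k * cin * cout, 0, sqrt(2 / (k * k * cin))),
        c(k, k, cin, cout))
}

new_conv <- function(k, cin, cout) list(W = he_init(k, cin, cout), b = numeric(cout))

new_res_block <- function(k, cin, cout) {
  list(conv1 = new_conv(k, cin, cout),
       bn1 = list(gamma = rep(1, cout), beta = numeric(cout)),
       conv2 = new_conv(k, cout, cout),
       bn2 = list(gamma = rep(1, cout), beta = numeric(cout)),
       proj = if (cin != cout) new_conv(1L, cin, cout) else NULL)
}

new_clstm_dir <- function(k, cin, L) {
  p <- convlstm_params(cin, L, k, peephole = TRUE, init = "random")
  pk <- pack_clstm(p)
  list(W = pk$W, b = pk$b, pc = pk$pc)
}

#' Create a Bi-CLSTM segmentation head
#'
#' Initializes all parameter tensors (He-scaled Gaussians for convolutions,
#' forget-gate biases at 1, peepholes at 0) deterministically from `seed`.
#'
#' @param config a [head_config()].
#' @param in_channels input channels per sequence element (2: image +
#'   attention map).
#' @param seed initialization seed.
#' @return An object of class `biclstm_head`.
#' @export
biclstm_head <- function(config = head_config(), in_channels = 2L, seed = 1L) {
  stopifnot(inherits(config, "head_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  k <- config$kernel_size
  r <- config$residual_filters
  L <- config$clstm_filters
  fu <- config$fusion_filters
  cf <- if (config$fusion_mode == "concat") 2L * L else L
  params <- list(
    res1 = new_res_block(k, in_channels, r),
    res2 = new_res_block(k, r, r),
    fwd = new_clstm_dir(k, r, L),
    bwd = new_clstm_dir(k, r, L),
    fus = new_conv(k, cf, fu),
    out = new_conv(1L, fu, 1L))
  stats <- list(
    res1 = list(bn1 = list(mean = numeric(r), var = rep(1, r)),
                bn2 = list(mean = numeric(r), var = rep(1, r))),
    res2 = list(bn1 = list(mean = numeric(r), var = rep(1, r)),
                bn2 = list(mean = numeric(r), var = rep(1, r))))
  structure(list(config = config, in_channels = as.integer(in_channels),
                 params = params, bn_stats = stats, trained = FALSE,
                 format_version = 1L),
            class = "biclstm_head")
}

#' @export
print.biclstm_head <- function(x, ...) {
  cat("<biclstm_head> filters ", x$config$residual_filters, "/",
      x$config$clstm_filters, "/", x$config$fusion_filters,
      ", fusion ", x$config$fusion_mode,
      if (x$trained) ", trained" else ", untrained", "\n", sep = "")
  invisible(x)
}

pk_from_dir <- function(d, k, Cx, L, peephole) {
  list(W = d$W, b = d$b, pc = d$pc, L = L, Cx = Cx, k = k, peephole = peephole)
}

# ---- residual block -------------------------------------------------------

res_fwd <- function(x, p, st, train) {
  c1 <- conv2d(x, p$conv1$W, p$conv1$b)
  b1 <- bn_fwd(c1$out, p$bn1$gamma, p$bn1$beta, st$bn1$mean, st$bn1$var, train)
  r1 <- relu(b1$out)
  c2 <- conv2d(r1, p$conv2$W, p$conv2$b)
  b2 <- bn_fwd(c2$out, p$bn2$gamma, p$bn2$beta, st$bn2$mean, st$bn2$var, train)
  if (is.null(p$proj)) {
    sc <- as_batch4(x)
    pj <- NULL
  } else {
    pj <- conv2d(x, p$proj$W, p$proj$b)
    sc <- pj$out
  }
  pre <- sc + b2$out
  out <- relu(pre)
  list(out = out,
       cache = list(c1 = c1, b1 = b1, r1 = r1, c2 = c2, b2 = b2, pj = pj,
                    pre = pre),
       stats = list(bn1 = list(mean = b1$run_mean, var = b1$run_var),
                    bn2 = list(mean = b2$run_mean, var = b2$run_var)))
}

res_bwd <- function(dout, cache, p, train) {
  dpre <- dout * (cache$pre > 0)
  g2 <- bn_bwd(dpre, cache$b2, p$bn2$gamma, train)
  k2 <- conv2d_bwd(g2$dx, cache$c2$cols, p$conv2$W)
  dr1 <- k2$dx * (cache$r1 > 0)
  g1 <- bn_bwd(dr1, cache$b1, p$bn1$gamma, train)
  k1 <- conv2d_bwd(g1$dx, cache$c1$cols, p$conv1$W)
  grads <- list(conv1 = list(W = k1$dW, b = k1$db),
                bn1 = list(gamma = g1$dgamma, beta = g1$dbeta),
                conv2 = list(W = k2$dW, b = k2$db),
                bn2 = list(gamma = g2$dgamma, beta = g2$dbeta))
  if (is.null(p$proj)) {
    dx <- k1$dx + dpre
    grads$proj <- NULL
  } else {
    kp <- conv2d_bwd(dpre, cache$pj$cols, p$proj$W)
    dx <- k1$dx + kp$dx
    grads$proj <- list(W = kp$dW, b = kp$db)
  }
  list(dx = dx, grads = grads)
}

#' Residual feature-extraction block
#'
#' `out = ReLU(project(x) + F(x))` with `F = Conv -> BN -> ReLU -> Conv ->
#' BN`; `project` is the identity when the input already has the block's
#' channel count, else a 1x1 channel projection. Spatial dimensions are
#' preserved.
#'
#' @param x input feature map `(H, W, C)` or batch `(H, W, C, N)`.
#' @param params block parameters as produced inside [biclstm_head()]; if
#'   `NULL`, a freshly initialized block with `filters` outputs is used.
#' @param filters output channels when `params` is `NULL` (default 64).
#' @param train use batch statistics (`TRUE`) or running statistics.
#' @param seed seed for fresh initialization.
#' @return Feature map with `filters` channels, same spatial size (batch
#'   axis preserved if the input had one).
#' @export
residual_block <- function(x, params = NULL, filters = 64L, train = FALSE,
                           seed = 1L) {
  xb <- as_batch4(x)
  cin <- dim(xb)[3]
  if (is.null(params)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
    params <- new_res_block(3L, cin, as.integer(filters))
  }
  cout <- length(params$bn1$gamma)
  st <- list(bn1 = list(mean = numeric(cout), var = rep(1, cout)),
             bn2 = list(mean = numeric(cout), var = rep(1, cout)))
  out <- res_fwd(xb, params, st, train)$out
  if (length(dim(x)) == 4L) out else slice4(out, 1L)
}

# ---- focal loss -----------------------------------------------------------

#' Focal loss for binary segmentation
#'
#' Mean over pixels of \eqn{-\alpha_t (1 - p_t)^\gamma \log(p_t)} with
#' \eqn{p_t = p} and \eqn{\alpha_t = \alpha} on foreground pixels and
#' \eqn{p_t = 1 - p}, \eqn{\alpha_t = 1 - \alpha} on background pixels.
#' Probabilities are clamped to `[1e-7, 1 - 1e-7]` for numerical stability.
#' At `gamma = 0`, `alpha = 0.5` the loss is exactly half the mean binary
#' cross-entropy.
#'
#' @param probs probability map in `[0, 1]`.
#' @param gt binary mask of the same shape.
#' @param alpha foreground weight in `[0, 1]`.
#' @param gamma focusing exponent `>= 0`.
#' @return Scalar loss.
#' @export
focal_loss <- function(probs, gt, alpha = 0.25, gamma = 2) {
  if (!identical(dim(probs), dim(gt)) && length(probs) != length(gt))
    stop("probability map and mask differ in shape", call. = FALSE)
  if (min(probs) < 0 || max(probs) > 1)
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  eps <- 1e-7
  p <- pmin(pmax(probs, eps), 1 - eps)
  fg <- gt > 0
  pt <- ifelse(fg, p, 1 - p)
  at <- ifelse(fg, alpha, 1 - alpha)
  mean(-at * (1 - pt)^gamma * log(pt))
}

# d(mean focal)/d(logit); p = sigmoid(z) already clamped
focal_grad_logit <- function(p, gt, alpha, gamma) {
  eps <- 1e-7
  p <- pmin(pmax(p, eps), 1 - eps)
  fg <- gt > 0
  dLdp <- ifelse(fg,
                 alpha * gamma * (1 - p)^(pmax(gamma - 1, 0)) * log(p) * (gamma > 0) -
                   alpha * (1 - p)^gamma / p,
                 -(1 - alpha) * gamma * p^(pmax(gamma - 1, 0)) * log(1 - p) * (gamma > 0) +
                   (1 - alpha) * p^gamma / (1 - p))
  dLdp * p * (1 - p) / length(p)
}

# ---- full head forward / backward ----------------------------------------

# xseq: (H, W, in_channels, N); returns logits and caches
head_fwd <- function(model, xseq, train = FALSE, scope = NULL) {
  cfg <- model$config
  if (is.null(scope)) scope <- cfg$output_scope
  k <- cfg$kernel_size
  r <- cfg$residual_filters
  L <- cfg$clstm_filters
  N <- dim(xseq)[4]
  tpos <- (N + 1L) %/% 2L
  r1 <- res_fwd(xseq, model$params$res1, model$bn_stats$res1, train)
  r2 <- res_fwd(r1$out, model$params$res2, model$bn_stats$res2, train)
  pkf <- pk_from_dir(model$params$fwd, k, r, L, cfg$peephole)
  pkb <- pk_from_dir(model$params$bwd, k, r, L, cfg$peephole)
  fw <- clstm_run(r2$out, pkf, reverse = FALSE, keep_cache = train)
  bw <- clstm_run(r2$out, pkb, reverse = TRUE, keep_cache = train)
  fused <- if (cfg$fusion_mode == "concat") {
    d <- dim(fw$Hs)
    af <- array(0, c(d[1], d[2], 2L * L, N))
    af[, , seq_len(L), ] <- fw$Hs
    af[, , L + seq_len(L), ] <- bw$Hs
    af
  } else fw$Hs + bw$Hs
  pos <- if (scope == "target_slice") tpos else seq_len(N)
  fin <- fused[, , , pos, drop = FALSE]
  fz <- conv2d(fin, model$params$fus$W, model$params$fus$b)
  fr <- relu(fz$out)
  oz <- conv2d(fr, model$params$out$W, model$params$out$b)
  logits <- oz$out   # (H, W, 1, length(pos))
  list(logits = logits, tpos = tpos, pos = pos,
       cache = list(r1 = r1, r2 = r2, fw = fw, bw = bw, fz = fz, fr = fr,
                    oz = oz, pkf = pkf, pkb = pkb, N = N, fused_dim = dim(fused)))
}

# dlogits matches fwd$logits; returns parameter gradients and new BN stats
head_bwd <- function(model, fwd, dlogits, train = TRUE) {
  cfg <- model$config
  ca <- fwd$cache
  L <- cfg$clstm_filters
  ko <- conv2d_bwd(dlogits, ca$oz$cols, model$params$out$W)
  dfr <- ko$dx * (ca$fr > 0)
  kf <- conv2d_bwd(dfr, ca$fz$cols, model$params$fus$W)
  dfused <- array(0, ca$fused_dim)
  dfused[, , , fwd$pos] <- kf$dx
  if (cfg$fusion_mode == "concat") {
    dHf <- dfused[, , seq_len(L), , drop = FALSE]
    dHb <- dfused[, , L + seq_len(L), , drop = FALSE]
  } else {
    dHf <- dfused
    dHb <- dfused
  }
  bf <- clstm_bptt(dHf, ca$fw$caches, ca$pkf, reverse = FALSE)
  bb <- clstm_bptt(dHb, ca$bw$caches, ca$pkb, reverse = TRUE)
  dr2 <- bf$dX + bb$dX
  r2b <- res_bwd(dr2, ca$r2$cache, model$params$res2, train)
  r1b <- res_bwd(r2b$dx, ca$r1$cache, model$params$res1, train)
  list(grads = list(
         res1 = r1b$grads, res2 = r2b$grads,
         fwd = list(W = bf$dW, b = bf$db, pc = bf$dpc),
         bwd = list(W = bb$dW, b = bb$db, pc = bb$dpc),
         fus = list(W = kf$dW, b = kf$db),
         out = list(W = ko$dW, b = ko$db)),
       stats = list(res1 = ca$r1$stats, res2 = ca$r2$stats))
}

seq_to_array <- function(seq) {
  stopifnot(inherits(seq, "pair_sequence"))
  N <- length(seq$pairs)
  d <- dim(seq$pairs[[1]]$slice)
  x <- array(0, c(d[1], d[2], 2L, N))
  for (t in seq_len(N)) {
    # 8-bit intensities on the unit scale, matching the attention channel,
    # so the unnormalized residual shortcut cannot saturate the gates
    x[, , 1L, t] <- seq$pairs[[t]]$slice / 255
    x[, , 2L, t] <- attention_values(seq$pairs[[t]]$attention)
  }
  x
}

#' Segment the target slice of a pair sequence
#'
#' Runs the full head: 2-channel pair encoding, residual blocks,
#' bidirectional ConvLSTM, fusion, fusion convolution and 1x1 logit
#' convolution, followed by a sigmoid. The binary mask applies the
#' configured threshold with a `>=` comparison (ties become foreground).
#'
#' @param object a [biclstm_head()].
#' @param seq a `pair_sequence` from [build_sequences()].
#' @param scope override the configured `output_scope`.
#' @param ... unused.
#' @return A list with `prob` (probability map, or `H x W x N` array for
#'   `all_slices` scope), `mask` (binary), and `target_index`.
#' @export
predict.biclstm_head <- function(object, seq, scope = NULL, ...) {
  if (!inherits(seq, "pair_sequence"))
    stop("predict expects a pair_sequence", call. = FALSE)
  x <- seq_to_array(seq)
  if (dim(x)[3] != object$in_channels)
    stop("model expects ", object$in_channels, "-channel inputs", call. = FALSE)
  fwd <- head_fwd(object, x, train = FALSE, scope = scope)
  pr <- sigmoid(fwd$logits)
  d <- dim(pr)
  prob <- if (d[4] == 1L) matrix(pr[, , 1L, 1L], d[1], d[2])
          else array(pr[, , 1L, ], c(d[1], d[2], d[4]))
  mask <- (prob >= object$config$prediction_threshold) * 1L
  list(prob = prob, mask = mask, target_index = seq$target_index)
}

#' Train the Bi-CLSTM head with SGD on focal loss
#'
#' Plain stochastic gradient descent (default learning rate 0.005) on
#' sequences sampled uniformly with replacement, one sequence per step; the
#' focal loss of the target-slice prediction is recorded per step. Fully
#' deterministic given `seed`.
#'
#' @param model a [biclstm_head()].
#' @param sequences nonempty list of `pair_sequence` objects carrying target
#'   ground truth (see [build_sequences()]).
#' @param lr learning rate.
#' @param steps number of SGD steps.
#' @param seed RNG seed for sequence sampling.
#' @return A list with the trained `model` and the per-step `trace`.
#' @export
train_head <- function(model, sequences, lr = 0.005, steps = 200L, seed = 1L) {
  stopifnot(inherits(model, "biclstm_head"))
  if (length(sequences) == 0) stop("empty training set", call. = FALSE)
  for (s in sequences) {
    if (!inherits(s, "pair_sequence")) stop("expected pair_sequence objects", call. = FALSE)
    if (is.null(s$target_gt))
      stop("training sequences must carry target ground truth", call. = FALSE)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  cfg <- model$config
  trace <- numeric(steps)
  arrays <- lapply(sequences, seq_to_array)
  gts <- lapply(sequences, `[[`, "target_gt")
  for (step in seq_len(steps)) {
    j <- sample.int(length(arrays), 1L)
    fwd <- head_fwd(model, arrays[[j]], train = TRUE, scope = "target_slice")
    p <- sigmoid(fwd$logits)
    gt <- gts[[j]]
    trace[step] <- focal_loss(matrix(p, nrow(gt), ncol(gt)), gt,
                              cfg$focal_alpha, cfg$focal_gamma)
    dl <- focal_grad_logit(p, array(gt, dim(p)), cfg$focal_alpha, cfg$focal_gamma)
    bwd <- head_bwd(model, fwd, dl, train = TRUE)
    model$params <- sgd_step(model$params, bwd$grads, lr)
    if (lr > 0) model$bn_stats <- bwd$stats
  }
  model$trained <- TRUE
  list(model = model, trace = trace)
}

#' Save / load a head checkpoint
#'
#' A checkpoint is a single-file archive holding every parameter tensor, the
#' batch-normalization running statistics, the [head_config()] and a format
#' version.
#'
#' @param model a [biclstm_head()].
#' @param path file path.
#' @return `path` (save) or the restored model (load).
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "biclstm_head"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "biclstm_head") || is.null(m$format_version))
    stop("not a head checkpoint: ", path, call. = FALSE)
  m
}
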