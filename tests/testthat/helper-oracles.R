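# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: plain loops and set arithmetic only.

# scalar (1x1 kernel, single channel, single pixel) LSTM cell with peepholes
scalar_lstm_step <- function(x, h, c, w) {
  sg <- function(z) 1 / (1 + exp(-z))
  i <- sg(w$W_xi * x + w$W_hi * h + w$w_ci * c + w$b_i)
  f <- sg(w$W_xf * x + w$W_hf * h + w$w_cf * c + w$b_f)
  g <- tanh(w$W_xg * x + w$W_hg * h + w$b_g)
  cn <- f * c + i * g
  o <- sg(w$W_xo * x + w$W_ho * h + w$w_co * cn + w$b_o)
  list(H = o * tanh(cn), C = cn)
}

# direct triple-loop same-padding convolution
naive_conv2d <- function(x, W, b) {
  H <- dim(x)[1]; Wd <- dim(x)[2]; Cin <- dim(x)[3]
  k <- dim(W)[1]; p <- (k - 1) / 2; Cout <- dim(W)[4]
  out <- array(0, c(H, Wd, Cout))
  for (o in 1:Cout) for (r in 1:H) for (cc in 1:Wd) {
    s <- b[o]
    for (ci in 1:Cin) for (i in 1:k) for (j in 1:k) {
      rr <- r + i - 1 - p; c2 <- cc + j - 1 - p
      if (rr >= 1 && rr <= H && c2 >= 1 && c2 <= Wd)
        s <- s + x[rr, c2, ci] * W[i, j, ci, o]
    }
    out[r, cc, o] <- s
  }
  out
}

# set-arithmetic metrics oracle
oracle_metrics <- function(pred, gt) {
  A <- which(pred > 0)
  B <- which(gt > 0)
  inter <- length(intersect(A, B))
  list(TO = inter / length(B),
       FN = length(setdiff(B, A)) / length(B),
       FP = if (length(A) == 0) 0 else length(setdiff(A, B)) / length(A),
       Dice = 2 * inter / (length(A) + length(B)),
       Jaccard = inter / length(union(A, B)))
}

# brute-force per-component bounding boxes by flood fill + min/max scan
oracle_boxes <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  seen <- matrix(FALSE, H, W)
  boxes <- NULL
  for (r0 in 1:H) for (c0 in 1:W) {
    if (mask[r0, c0] > 0 && !seen[r0, c0]) {
      queue <- list(c(r0, c0)); seen[r0, c0] <- TRUE; px <- NULL
      while (length(queue)) {
        p <- queue[[1]]; queue <- queue[-1]
        px <- rbind(px, p)
        for (dr in -1:1) for (dc in -1:1) {
          r <- p[1] + dr; c <- p[2] + dc
          if (r >= 1 && r <= H && c >= 1 && c <= W && mask[r, c] > 0 && !seen[r, c]) {
            seen[r, c] <- TRUE; queue <- c(queue, list(c(r, c)))
          }
        }
      }
      boxes <- rbind(boxes, data.frame(
        row_min = min(px[, 1]) - 1L, col_min = min(px[, 2]) - 1L,
        row_max = max(px[, 1]) - 1L, col_max = max(px[, 2]) - 1L))
    }
  }
  boxes
}

# noiseless-phantom segmentation oracle: band threshold between the
# tissue/thrombus and thrombus/lumen midpoints
oracle_threshold_mask <- function(slice, levels) {
  lo <- (levels[["tissue"]] + levels[["thrombus"]]) / 2
  hi <- (levels[["thrombus"]] + levels[["lumen"]]) / 2
  (slice > lo & slice <= hi) * 1
}

# small noiseless 32x32 phantom pair used by training tests
tiny_phantom_pair <- function() {
  pp <- function(seed) phantom_params(
    image_size = 32, n_slices = 6, noise_sigma = 0, tissue_overlap = 0,
    stent_artifact = FALSE, center_drift = 1, seed = seed)
  list(generate_study(pp(101), "train_a"), generate_study(pp(202), "train_b"))
}
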