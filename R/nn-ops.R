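# Internal numerical kernels.
#
# Feature maps are numeric arrays in (H, W, C) or (H, W, C, N) layout, N being
# the batch (sequence) axis. Convolutions are stride-1, odd-kernel,
# zero-padded "same" convolutions implemented as patch-matrix (im2col) matrix
# products so that BLAS does the heavy lifting; their backward passes are
# exact (transposed convolution for the input gradient, patch-matrix
# cross-product for the weight gradient) and are validated against finite
# differences in the test suite.

.thrombseg_cache <- new.env(parent = emptyenv())

# Linear indices into a zero-padded (H+2p, W+2p, C) array selecting, for each
# of the H*W output pixels (row index, column-major over the image), the
# k*k*C patch entries ordered (ky, kx, channel) to match an R array kernel
# of dim (k, k, C, Cout) flattened to a (k*k*C, Cout) matrix.
patch_index <- function(H, W, k, C) {
  key <- paste0("pi_", H, "_", W, "_", k, "_", C)
  idx <- .thrombseg_cache[[key]]
  if (!is.null(idx)) return(idx)
  p <- (k - 1L) %/% 2L
  Hp <- H + 2L * p
  Wp <- W + 2L * p
  base0 <- rep(seq_len(H) - 1L, times = W) + rep(seq_len(W) - 1L, each = H) * Hp
  off <- as.vector(outer(
    as.vector(outer(seq_len(k) - 1L, (seq_len(k) - 1L) * Hp, "+")),
    (seq_len(C) - 1L) * Hp * Wp, "+"
  ))
  idx <- outer(base0, off, "+") + 1L
  .thrombseg_cache[[key]] <- idx
  idx
}

as_batch4 <- function(x) {
  d <- dim(x)
  if (is.null(d)) stop("expected an array, got a vector", call. = FALSE)
  if (length(d) == 2L) x <- array(x, c(d, 1L, 1L))
  else if (length(d) == 3L) x <- array(x, c(d, 1L))
  x
}

# Stride-1 same-padding convolution. x: (H,W,Cin[,N]); W: (k,k,Cin,Cout).
# Returns list(out = (H,W,Cout,N), cols = patch matrix kept for the backward
# pass (set keep_cols = FALSE to drop it)).
conv2d <- function(x, W, b = NULL, keep_cols = TRUE) {
  x <- as_batch4(x)
  d <- dim(x)
  H <- d[1]; Wd <- d[2]; Cin <- d[3]; N <- d[4]
  k <- dim(W)[1]
  if (dim(W)[3] != Cin)
    stop("convolution weight expects ", dim(W)[3], " input channels, got ", Cin,
         call. = FALSE)
  p <- (k - 1L) %/% 2L
  Cout <- dim(W)[4]
  idx <- patch_index(H, Wd, k, Cin)
  Wmat <- matrix(W, nrow = k * k * Cin)
  HW <- H * Wd
  cols <- matrix(0, HW * N, k * k * Cin)
  pad <- array(0, c(H + 2L * p, Wd + 2L * p, Cin))
  sel_r <- p + seq_len(H)
  sel_c <- p + seq_len(Wd)
  for (n in seq_len(N)) {
    pad[sel_r, sel_c, ] <- x[, , , n]
    # index with a plain vector: a matrix index would be read as coordinates
    cols[(n - 1L) * HW + seq_len(HW), ] <- pad[as.vector(idx)]
  }
  Y <- cols %*% Wmat
  if (!is.null(b)) Y <- Y + rep(b, each = nrow(Y))
  out <- array(0, c(H, Wd, Cout, N))
  for (n in seq_len(N))
    out[, , , n] <- array(Y[(n - 1L) * HW + seq_len(HW), ], c(H, Wd, Cout))
  list(out = out, cols = if (keep_cols) cols else NULL)
}

# Backward pass of conv2d. dy: (H,W,Cout[,N]); cols: cached patch matrix;
# W: the forward kernel. Returns dW, db and dx (same shape as the input).
conv2d_bwd <- function(dy, cols, W, need_dx = TRUE) {
  dy <- as_batch4(dy)
  d <- dim(dy)
  H <- d[1]; Wd <- d[2]; Cout <- d[3]; N <- d[4]
  k <- dim(W)[1]; Cin <- dim(W)[3]
  HW <- H * Wd
  dYmat <- matrix(0, HW * N, Cout)
  for (n in seq_len(N))
    dYmat[(n - 1L) * HW + seq_len(HW), ] <- matrix(dy[, , , n], HW, Cout)
  dW <- array(crossprod(cols, dYmat), dim(W))
  db <- colSums(dYmat)
  dx <- NULL
  if (need_dx) {
    # input gradient = same-padding convolution of dy with the spatially
    # flipped kernel, input/output channels swapped (exact for stride 1)
    Wt <- aperm(W[k:1, k:1, , , drop = FALSE], c(1L, 2L, 4L, 3L))
    dx <- conv2d(dy, Wt, keep_cols = FALSE)$out
  }
  list(dW = dW, db = db, dx = dx)
}

# take batch element t of an (H,W,C,N) array as an (H,W,C) array
slice4 <- function(x, t) {
  d <- dim(x)
  array(x[, , , t], d[1:3])
}

sigmoid <- function(x) 1 / (1 + exp(-x))

relu <- function(x) {
  x[x < 0] <- 0
  x
}

# channel-wise helpers for (H,W,C[,N]) arrays
chan_mul <- function(x, v) {
  d <- dim(x)
  x * rep(v, each = d[1] * d[2], times = prod(d) / (d[1] * d[2] * length(v)))
}

chan_sum <- function(x, C) {
  d <- dim(x)
  m <- matrix(x, nrow = d[1] * d[2])
  per_col <- colSums(m)                       # one value per (channel, batch)
  rowSums(matrix(per_col, nrow = C))
}

# Batch normalization over (H, W, N) per channel.
bn_fwd <- function(x, gamma, beta, run_mean, run_var, train,
                   eps = 1e-5, momentum = 0.1) {
  x <- as_batch4(x)
  d <- dim(x)
  C <- d[3]
  xr <- matrix(aperm(x, c(1L, 2L, 4L, 3L)), ncol = C)   # (H*W*N) x C
  if (train) {
    mu <- colMeans(xr)
    v <- colMeans(xr * xr) - mu * mu
    v[v < 0] <- 0
    new_mean <- (1 - momentum) * run_mean + momentum * mu
    new_var <- (1 - momentum) * run_var + momentum * v
  } else {
    mu <- run_mean
    v <- run_var
    new_mean <- run_mean
    new_var <- run_var
  }
  istd <- 1 / sqrt(v + eps)
  xhat <- (xr - rep(mu, each = nrow(xr))) * rep(istd, each = nrow(xr))
  yr <- xhat * rep(gamma, each = nrow(xr)) + rep(beta, each = nrow(xr))
  y <- aperm(array(yr, c(d[1], d[2], d[4], C)), c(1L, 2L, 4L, 3L))
  list(out = y, xhat = xhat, istd = istd, dims = d,
       run_mean = new_mean, run_var = new_var)
}

bn_bwd <- function(dy, cache, gamma, train) {
  d <- cache$dims
  C <- d[3]
  dyr <- matrix(aperm(as_batch4(dy), c(1L, 2L, 4L, 3L)), ncol = C)
  n <- nrow(dyr)
  dgamma <- colSums(dyr * cache$xhat)
  dbeta <- colSums(dyr)
  if (train) {
    t1 <- dyr - rep(dbeta / n, each = n) -
      cache$xhat * rep(dgamma / n, each = n)
    dxr <- t1 * rep(gamma * cache$istd, each = n)
  } else {
    dxr <- dyr * rep(gamma * cache$istd, each = n)
  }
  dx <- aperm(array(dxr, c(d[1], d[2], d[4], C)), c(1L, 2L, 4L, 3L))
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# Separable Gaussian smoothing of a 2D field (zero-padded borders).
gaussian_smooth <- function(x, sigma) {
  if (sigma <= 0) return(x)
  r <- max(1L, ceiling(3 * sigma))
  g <- stats::dnorm(seq(-r, r), sd = sigma)
  g <- g / sum(g)
  k <- outer(g, g)
  conv2d(array(x, c(dim(x), 1L)), array(k, c(dim(k), 1L, 1L)),
         keep_cols = FALSE)$out[, , 1L, 1L]
}

# Resample an image at real-valued source coordinates (1-based, matrices the
# size of the output). Pixels whose source falls outside the image are 0.
warp_bilinear <- function(img, src_r, src_c) {
  H <- nrow(img); W <- ncol(img)
  inside <- src_r >= 1 & src_r <= H & src_c >= 1 & src_c <= W
  r0 <- pmin(pmax(floor(src_r), 1), H)
  c0 <- pmin(pmax(floor(src_c), 1), W)
  r1 <- pmin(r0 + 1, H)
  c1 <- pmin(c0 + 1, W)
  fr <- src_r - r0
  fc <- src_c - c0
  fr[fr < 0] <- 0; fr[fr > 1] <- 1
  fc[fc < 0] <- 0; fc[fc > 1] <- 1
  v00 <- img[cbind(c(r0), c(c0))]
  v01 <- img[cbind(c(r0), c(c1))]
  v10 <- img[cbind(c(r1), c(c0))]
  v11 <- img[cbind(c(r1), c(c1))]
  out <- (1 - c(fr)) * ((1 - c(fc)) * v00 + c(fc) * v01) +
    c(fr) * ((1 - c(fc)) * v10 + c(fc) * v11)
  out[!c(inside)] <- 0
  matrix(out, H, W)
}

warp_nearest <- function(img, src_r, src_c) {
  H <- nrow(img); W <- ncol(img)
  rr <- round(src_r)
  cc <- round(src_c)
  inside <- rr >= 1 & rr <= H & cc >= 1 & cc <= W
  rr <- pmin(pmax(rr, 1), H)
  cc <- pmin(pmax(cc, 1), W)
  out <- img[cbind(c(rr), c(cc))]
  out[!c(inside)] <- 0
  matrix(out, H, W)
}

# 8-connected (or 4-connected) component labelling by iterative minimum-label
# propagation. Returns an integer matrix: 0 = background, 1..n components.
label_components <- function(mask, connectivity = 8L) {
  H <- nrow(mask); W <- ncol(mask)
  fg <- mask > 0
  lab <- matrix(Inf, H, W)
  lab[fg] <- which(fg)
  shifts <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  if (connectivity == 8L)
    shifts <- c(shifts, list(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1)))
  shift_mat <- function(m, dr, dc) {
    out <- matrix(Inf, H, W)
    rs <- max(1, 1 + dr):min(H, H + dr)
    cs <- max(1, 1 + dc):min(W, W + dc)
    out[rs, cs] <- m[rs - dr, cs - dc]
    out
  }
  repeat {
    new <- lab
    for (s in shifts) new <- pmin(new, shift_mat(lab, s[1], s[2]))
    new[!fg] <- Inf
    if (identical(new, lab)) break
    lab <- new
  }
  ids <- sort(unique(lab[is.finite(lab)]))
  out <- matrix(0L, H, W)
  if (length(ids)) out[fg] <- match(lab[fg], ids)
  out
}

# SGD step over a nested list of numeric arrays; grads mirrors params.
sgd_step <- function(params, grads, lr) {
  for (nm in names(params)) {
    p <- params[[nm]]
    g <- grads[[nm]]
    if (is.null(g)) next
    if (is.list(p)) params[[nm]] <- sgd_step(p, g, lr)
    else params[[nm]] <- p - lr * g
  }
  params
}

# elementwise accumulate of two mirrored nested lists
acc_grads <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  if (is.list(a)) {
    for (nm in names(a)) a[[nm]] <- acc_grads(a[[nm]], b[[nm]])
    return(a)
  }
  a + b
}
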