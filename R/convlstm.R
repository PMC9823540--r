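#' Convolutional LSTM cell parameters
#'
#' Gate transformations are stride-1 same-padding 2D convolutions. Following
#' the original ConvLSTM formulation, the cell keeps input-to-gate kernels
#' `W_xi, W_xf, W_xo, W_xg`, hidden-to-gate kernels `W_hi, W_hf, W_ho, W_hg`,
#' biases `b_i, b_f, b_o, b_g` and optional peephole (Hadamard cell-to-gate)
#' weights `w_ci, w_cf, w_co`. Peephole weights are per-channel, broadcast
#' over the spatial grid, so a trained cell transfers across image sizes.
#'
#' @param input_channels channels of the input feature maps.
#' @param n_filters number of hidden/cell channels (128 in the full model).
#' @param kernel_size odd spatial kernel extent (default 3).
#' @param peephole include cell-to-gate terms (default `TRUE`).
#' @param init `"zero"` or `"random"` (scaled Gaussian; forget-gate bias 1).
#' @param seed seed for random initialization.
#' @return An object of class `convlstm_params`.
#' @export
convlstm_params <- function(input_channels, n_filters = 128L, kernel_size = 3L,
                            peephole = TRUE, init = c("random", "zero"),
                            seed = NULL) {
  init <- match.arg(init)
  k <- as.integer(kernel_size)
  if (k %% 2L == 0L) stop("kernel_size must be odd", call. = FALSE)
  Cx <- as.integer(input_channels)
  L <- as.integer(n_filters)
  mk <- function(cin) {
    if (init == "zero") array(0, c(k, k, cin, L))
    else array(stats::rnorm(k * k * cin * L, 0, sqrt(1 / (k * k * cin))),
               c(k, k, cin, L))
  }
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
  }
  p <- list(W_xi = mk(Cx), W_xf = mk(Cx), W_xo = mk(Cx), W_xg = mk(Cx),
            W_hi = mk(L), W_hf = mk(L), W_ho = mk(L), W_hg = mk(L),
            b_i = numeric(L),
            b_f = if (init == "zero") numeric(L) else rep(1, L),
            b_o = numeric(L), b_g = numeric(L),
            w_ci = numeric(L), w_cf = numeric(L), w_co = numeric(L))
  structure(c(p, list(n_filters = L, kernel_size = k, input_channels = Cx,
                      peephole = isTRUE(peephole))),
            class = "convlstm_params")
}

# Internal packed representation: one kernel over [x; h] producing the four
# gate pre-activations stacked as (i, f, g, o) channels.
pack_clstm <- function(p) {
  k <- p$kernel_size; Cx <- p$input_channels; L <- p$n_filters
  W <- array(0, c(k, k, Cx + L, 4L * L))
  gi <- function(g) (g - 1L) * L + seq_len(L)
  W[, , seq_len(Cx), gi(1)] <- p$W_xi
  W[, , seq_len(Cx), gi(2)] <- p$W_xf
  W[, , seq_len(Cx), gi(3)] <- p$W_xg
  W[, , seq_len(Cx), gi(4)] <- p$W_xo
  W[, , Cx + seq_len(L), gi(1)] <- p$W_hi
  W[, , Cx + seq_len(L), gi(2)] <- p$W_hf
  W[, , Cx + seq_len(L), gi(3)] <- p$W_hg
  W[, , Cx + seq_len(L), gi(4)] <- p$W_ho
  list(W = W, b = c(p$b_i, p$b_f, p$b_g, p$b_o),
       pc = cbind(i = p$w_ci, f = p$w_cf, o = p$w_co),
       L = L, Cx = Cx, k = k, peephole = p$peephole)
}

unpack_clstm_grads <- function(dW, db, dpc, pk) {
  L <- pk$L; Cx <- pk$Cx
  gi <- function(g) (g - 1L) * L + seq_len(L)
  xs <- seq_len(Cx); hs <- Cx + seq_len(L)
  list(W_xi = dW[, , xs, gi(1), drop = FALSE],
       W_xf = dW[, , xs, gi(2), drop = FALSE],
       W_xo = dW[, , xs, gi(4), drop = FALSE],
       W_xg = dW[, , xs, gi(3), drop = FALSE],
       W_hi = dW[, , hs, gi(1), drop = FALSE],
       W_hf = dW[, , hs, gi(2), drop = FALSE],
       W_ho = dW[, , hs, gi(4), drop = FALSE],
       W_hg = dW[, , hs, gi(3), drop = FALSE],
       b_i = db[gi(1)], b_f = db[gi(2)], b_g = db[gi(3)], b_o = db[gi(4)],
       w_ci = dpc[, "i"], w_cf = dpc[, "f"], w_co = dpc[, "o"])
}

# One cell step on the packed representation. x: (H,W,Cx); h/c: (H,W,L).
clstm_core_step <- function(x, h, c_prev, pk, keep_cache = FALSE) {
  L <- pk$L
  xh <- array(c(x, h), c(dim(x)[1], dim(x)[2], pk$Cx + L))
  cv <- conv2d(xh, pk$W, pk$b, keep_cols = keep_cache)
  z <- array(cv$out, dim(cv$out)[1:3])
  zi <- z[, , seq_len(L), drop = FALSE]
  zf <- z[, , L + seq_len(L), drop = FALSE]
  zg <- z[, , 2L * L + seq_len(L), drop = FALSE]
  zo <- z[, , 3L * L + seq_len(L), drop = FALSE]
  if (pk$peephole) {
    zi <- zi + chan_mul(c_prev, pk$pc[, "i"])
    zf <- zf + chan_mul(c_prev, pk$pc[, "f"])
  }
  i <- sigmoid(zi)
  f <- sigmoid(zf)
  g <- tanh(zg)
  c_new <- f * c_prev + i * g
  if (pk$peephole) zo <- zo + chan_mul(c_new, pk$pc[, "o"])
  o <- sigmoid(zo)
  tc <- tanh(c_new)
  h_new <- o * tc
  out <- list(H = h_new, C = c_new)
  if (keep_cache)
    out$cache <- list(i = i, f = f, g = g, o = o, c_prev = c_prev, tc = tc,
                      cols = cv$cols)
  out
}

#' One ConvLSTM gate update
#'
#' Applies the gate equations
#' \deqn{i_t = \sigma(W_{xi}*x_t + W_{hi}*H_{t-1} + w_{ci}\circ C_{t-1} + b_i)}
#' \deqn{f_t = \sigma(W_{xf}*x_t + W_{hf}*H_{t-1} + w_{cf}\circ C_{t-1} + b_f)}
#' \deqn{C_t = f_t\circ C_{t-1} + i_t\circ\tanh(W_{xg}*x_t + W_{hg}*H_{t-1} + b_g)}
#' \deqn{o_t = \sigma(W_{xo}*x_t + W_{ho}*H_{t-1} + w_{co}\circ C_t + b_o)}
#' \deqn{H_t = o_t\circ\tanh(C_t)}
#' where `*` is 2D convolution and the Hadamard cell terms vanish when
#' peepholes are disabled. Spatial dimensions are preserved.
#'
#' @param x input feature map `(H, W, input_channels)`.
#' @param state list with `H` and `C` feature maps `(H, W, n_filters)`, or
#'   `NULL` for the all-zero initial state.
#' @param params a [convlstm_params()].
#' @return A list with the new `H` and `C`.
#' @export
convlstm_step <- function(x, state, params) {
  stopifnot(inherits(params, "convlstm_params"))
  if (length(dim(x)) == 2L) x <- array(x, c(dim(x), 1L))
  if (dim(x)[3] != params$input_channels)
    stop("input has ", dim(x)[3], " channels; cell expects ",
         params$input_channels, call. = FALSE)
  L <- params$n_filters
  if (is.null(state))
    state <- list(H = array(0, c(dim(x)[1], dim(x)[2], L)),
                  C = array(0, c(dim(x)[1], dim(x)[2], L)))
  if (!identical(dim(state$H), dim(state$C)) ||
      !identical(dim(state$H)[1:2], dim(x)[1:2]) || dim(state$H)[3] != L)
    stop("state shape mismatch", call. = FALSE)
  st <- clstm_core_step(x, state$H, state$C, pack_clstm(params))
  list(H = st$H, C = st$C)
}

# Full unrolled pass in one direction over xs: (H,W,Cx,N).
# Hidden maps are stored at their original sequence positions.
clstm_run <- function(xs, pk, reverse = FALSE, keep_cache = FALSE) {
  d <- dim(xs)
  N <- d[4]
  L <- pk$L
  ord <- if (reverse) rev(seq_len(N)) else seq_len(N)
  h <- array(0, c(d[1], d[2], L))
  c_st <- h
  Hs <- array(0, c(d[1], d[2], L, N))
  caches <- if (keep_cache) vector("list", N) else NULL
  for (t in ord) {
    st <- clstm_core_step(slice4(xs, t), h, c_st, pk,
                          keep_cache = keep_cache)
    h <- st$H
    c_st <- st$C
    Hs[, , , t] <- h
    if (keep_cache) caches[[t]] <- st$cache
  }
  list(Hs = Hs, caches = caches)
}

# Backpropagation through time for one direction. dHs holds the gradient
# arriving at each stored hidden map. Returns dX and parameter grads.
clstm_bptt <- function(dHs, caches, pk, reverse = FALSE) {
  d <- dim(dHs)
  N <- d[4]
  L <- pk$L
  Cx <- pk$Cx
  ord <- if (reverse) seq_len(N) else rev(seq_len(N))   # reverse of forward order
  dW <- array(0, dim(pk$W))
  db <- numeric(4L * L)
  dpc <- matrix(0, L, 3, dimnames = list(NULL, c("i", "f", "o")))
  dX <- array(0, c(d[1], d[2], Cx, N))
  dh_rec <- array(0, c(d[1], d[2], L))
  dc_rec <- dh_rec
  first_t <- if (reverse) N else 1L    # first step of the forward pass
  for (t in ord) {
    ca <- caches[[t]]
    dh <- slice4(dHs, t) + dh_rec
    do <- dh * ca$tc
    dzo <- do * ca$o * (1 - ca$o)
    dc <- dh * ca$o * (1 - ca$tc^2) + dc_rec
    if (pk$peephole) {
      dc <- dc + chan_mul(dzo, pk$pc[, "o"])
      c_new <- ca$f * ca$c_prev + ca$i * ca$g
      dpc[, "o"] <- dpc[, "o"] + chan_sum(dzo * c_new, L)
    }
    di <- dc * ca$g
    df <- dc * ca$c_prev
    dg <- dc * ca$i
    dzi <- di * ca$i * (1 - ca$i)
    dzf <- df * ca$f * (1 - ca$f)
    dzg <- dg * (1 - ca$g^2)
    dc_prev <- dc * ca$f
    if (pk$peephole) {
      dpc[, "i"] <- dpc[, "i"] + chan_sum(dzi * ca$c_prev, L)
      dpc[, "f"] <- dpc[, "f"] + chan_sum(dzf * ca$c_prev, L)
      dc_prev <- dc_prev + chan_mul(dzi, pk$pc[, "i"]) +
        chan_mul(dzf, pk$pc[, "f"])
    }
    dZ <- array(c(dzi, dzf, dzg, dzo), c(d[1], d[2], 4L * L))
    cb <- conv2d_bwd(dZ, ca$cols, pk$W)
    dW <- dW + cb$dW
    db <- db + cb$db
    dxh <- slice4(cb$dx, 1L)
    dX[, , , t] <- dxh[, , seq_len(Cx), drop = FALSE]
    dh_rec <- if (t == first_t) array(0, c(d[1], d[2], L))
              else dxh[, , Cx + seq_len(L), drop = FALSE]
    dc_rec <- if (t == first_t) array(0, c(d[1], d[2], L)) else dc_prev
  }
  list(dX = dX, dW = dW, db = db, dpc = dpc)
}

#' Bidirectional ConvLSTM pass with fusion
#'
#' Runs one ConvLSTM over the sequence in the forward direction and a second
#' over the reversed sequence, re-aligns the backward outputs to the original
#' positions, and fuses the two hidden maps at each position: `"concat"`
#' stacks channels as `[forward; backward]`, `"sum"` adds them elementwise.
#'
#' @param seq list of `(H, W, C)` feature maps, or an `(H, W, C, N)` array.
#' @param params_fwd,params_bwd [convlstm_params()] for the two directions.
#' @param fusion_mode `"concat"` or `"sum"`.
#' @return A list of fused feature maps, one per input position.
#' @export
run_bidirectional <- function(seq, params_fwd, params_bwd,
                              fusion_mode = c("concat", "sum")) {
  fusion_mode <- match.arg(fusion_mode)
  if (is.list(seq)) {
    if (length(seq) == 0) stop("empty sequence", call. = FALSE)
    seq <- simplify2array(lapply(seq, function(s)
      if (length(dim(s)) == 2L) array(s, c(dim(s), 1L)) else s))
  }
  if (length(dim(seq)) == 3L) seq <- array(seq, c(dim(seq), 1L))
  fw <- clstm_run(seq, pack_clstm(params_fwd), reverse = FALSE)$Hs
  bw <- clstm_run(seq, pack_clstm(params_bwd), reverse = TRUE)$Hs
  N <- dim(seq)[4]
  lapply(seq_len(N), function(t) {
    a <- slice4(fw, t)
    b <- slice4(bw, t)
    da <- dim(fw)[1:3]
    if (fusion_mode == "sum") a + b
    else array(c(a, b), c(da[1], da[2], 2L * da[3]))
  })
}
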