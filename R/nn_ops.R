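# Low-level differentiable ops on single-sample tensors stored as arrays with
# dim (C, D, H, W) (channel fastest). Every *_fwd has a matching *_bwd that
# takes the upstream gradient and returns gradients for input and parameters.
# These back the attention module, the U-Net and the training loop; they are
# internal and deliberately minimal (stride-1/2, zero padding, no groups other
# than depthwise).

# Dense 3-D convolution. w: array (Cout, Cin, k, k, k); b: length Cout.
conv3d_fwd <- function(x, w, b, stride = 1L, pad = 0L, dil = 1L) {
  dx <- dim(x); dw <- dim(w)
  stopifnot(length(dx) == 4L, dw[2] == dx[1])
  .conv3d_direct(x, w, b, dw[2], dw[1], dx[2], dx[3], dx[4],
                 dw[3], stride, pad, dil)
}

conv3d_bwd <- function(x, w, dy, stride = 1L, pad = 0L, dil = 1L) {
  dx <- dim(x); dw <- dim(w)
  k <- dw[3]
  grad_w <- .conv3d_direct_dw(x, dy, dw[2], dw[1], dx[2], dx[3], dx[4],
                              k, stride, pad, dil)
  dim(grad_w) <- dw
  grad_x <- .conv3d_direct_dx(dy, w, dw[2], dw[1], dx[2], dx[3], dx[4],
                              k, stride, pad, dil)
  list(dx = grad_x, dw = grad_w, db = rowSums(matrix(dy, nrow = dw[1])))
}

# Transposed 3-D convolution (kernel 4, stride 2, pad 1 doubles each spatial
# dim). w: array (Cin, Cout, k, k, k); implemented through the adjoint
# identities of the corresponding strided convolution.
convt3d_fwd <- function(x, w, b, stride = 2L, pad = 1L) {
  dx <- dim(x); dw <- dim(w)
  stopifnot(dw[1] == dx[1])
  k <- dw[3]
  od <- (dx[2:4] - 1L) * stride - 2L * pad + k
  y <- .conv3d_direct_dx(x, w, dw[2], dw[1], od[1], od[2], od[3],
                         k, stride, pad, 1L)
  y <- y + b  # b has length Cout, recycled along the fastest (channel) dim
  dim(y) <- c(dw[2], od)
  y
}

convt3d_bwd <- function(x, w, dy, stride = 2L, pad = 1L) {
  dx <- dim(x); dw <- dim(w); dyd <- dim(dy)
  k <- dw[3]
  grad_x <- .conv3d_direct(dy, w, numeric(dw[1]), dw[2], dw[1],
                           dyd[2], dyd[3], dyd[4], k, stride, pad, 1L)
  dim(grad_x) <- dx
  grad_w <- .conv3d_direct_dw(dy, x, dw[2], dw[1], dyd[2], dyd[3], dyd[4],
                              k, stride, pad, 1L)
  dim(grad_w) <- dw
  grad_b <- rowSums(matrix(dy, nrow = dw[2]))
  list(dx = grad_x, dw = grad_w, db = grad_b)
}

# Depthwise 3-D convolution (stride 1, "same" zero padding).
# w: matrix (C x k^3); b: length C.
dwconv3d_fwd <- function(x, w, b, k, dil = 1L, pad = dil * (k - 1L) %/% 2L) {
  d <- dim(x)
  .dwconv3d(as.numeric(x), w, b, d[1], d[2], d[3], d[4], k, dil, pad)
}

dwconv3d_bwd <- function(x, w, dy, k, dil = 1L, pad = dil * (k - 1L) %/% 2L) {
  d <- dim(x)
  list(dx = .dwconv3d_bwd_dx(as.numeric(dy), w, d[1], d[2], d[3], d[4], k, dil, pad),
       dw = .dwconv3d_bwd_dw(as.numeric(x), as.numeric(dy),
                             d[1], d[2], d[3], d[4], k, dil, pad),
       db = rowSums(matrix(dy, nrow = d[1])))
}

# Group normalization over a single sample: channels are split into `groups`
# contiguous groups and normalized over (channels in group) x (all voxels),
# then scaled/shifted per channel. Batch-size independent, which matters at
# batch size 1.
gn_fwd <- function(x, gamma, beta, groups, eps = 1e-5) {
  d <- dim(x)
  C <- d[1]
  stopifnot(C %% groups == 0L)
  gs <- C %/% groups
  xm <- matrix(x, nrow = C)
  grp <- rep(seq_len(groups), each = gs)
  n_per <- gs * ncol(xm)
  mu <- as.numeric(tapply(rowSums(xm), grp, sum)) / n_per
  ssq <- as.numeric(tapply(rowSums(xm^2), grp, sum)) / n_per
  v <- ssq - mu^2
  inv_std <- 1 / sqrt(v + eps)
  xhat <- (xm - mu[grp]) * inv_std[grp]
  y <- xhat * gamma + beta
  dim(y) <- d
  list(y = y, xhat = xhat, inv_std = inv_std, grp = grp, n_per = n_per)
}

gn_bwd <- function(cache, gamma, dy) {
  d <- dim(dy)
  C <- d[1]
  dym <- matrix(dy, nrow = C)
  xhat <- cache$xhat
  grp <- cache$grp
  n <- cache$n_per
  dgamma <- rowSums(dym * xhat)
  dbeta <- rowSums(dym)
  dxhat <- dym * gamma
  s1 <- as.numeric(tapply(rowSums(dxhat), grp, sum))
  s2 <- as.numeric(tapply(rowSums(dxhat * xhat), grp, sum))
  dxm <- (dxhat - s1[grp] / n - xhat * (s2[grp] / n)) * cache$inv_std[grp]
  dim(dxm) <- d
  list(dx = dxm, dgamma = as.numeric(dgamma), dbeta = as.numeric(dbeta))
}

lrelu_fwd <- function(x, slope = 0.01) {
  .lrelu(x, slope)
}

lrelu_bwd <- function(x, dy, slope = 0.01) {
  .lrelu_bwd(x, dy, slope)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Softmax across the channel (first) dimension of a (C, D, H, W) array.
softmax_channels <- function(x) {
  d <- dim(x)
  xm <- matrix(x, nrow = d[1])
  mx <- xm[1, ]
  if (d[1] > 1L) for (r in 2:d[1]) mx <- pmax(mx, xm[r, ])
  xm <- exp(sweep(xm, 2L, mx))
  p <- sweep(xm, 2L, colSums(xm), "/")
  dim(p) <- d
  p
}

# He fan-in normal initialization for a weight array.
he_init <- function(dims, fan_in) {
  array(rnorm(prod(dims), sd = sqrt(2 / fan_in)), dim = dims)
}
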