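#' Build a 3D large-kernel attention module
#'
#' The module computes `z = lReLU(GN(input))`, pushes `z` through the
#' decomposed LK convolution chain (depthwise, depthwise dilated, pointwise),
#' squashes the result with a sigmoid into an attention map `A` in `(0, 1)`,
#' and returns `A * z + z` — a multiplicative spatial/channel gating with a
#' residual path. The chain's trainable convolution parameters (weights and
#' all three biases) equal [count_decomposed_params()] exactly, which is
#' asserted at construction; group-norm affine parameters are carried
#' separately.
#'
#' @param channels Number of feature channels the module preserves.
#' @param K Equal LK kernel side.
#' @param d Dilation rate dividing `K`.
#' @param seed Integer seed for deterministic He fan-in initialization.
#' @param groups Group-norm group count; defaults to the largest divisor of
#'   `channels` not exceeding 8.
#' @param conv_order `"dw_first"` (depthwise, then depthwise dilated — the
#'   order the chain is usually drawn in) or `"dwd_first"`. Parameter count
#'   and receptive field are identical either way.
#' @param residual `"normalized"` adds the normalized-activated input `z`
#'   (the default); `"raw"` adds the raw input instead.
#' @return An object of class `lka_attention`.
#' @examples
#' m <- build_lk_attention(8, 6, 2, seed = 1)
#' attention_n_params(m)  # 8 * (27 + 27 + 8 + 3)
#' @export
build_lk_attention <- function(channels, K, d, seed = 0L,
                               groups = NULL,
                               conv_order = c("dw_first", "dwd_first"),
                               residual = c("normalized", "raw")) {
  channels <- as.integer(check_count(channels, "channels"))
  spec <- decompose_kernel(K, d)
  conv_order <- match.arg(conv_order)
  residual <- match.arg(residual)
  if (is.null(groups)) {
    groups <- max(Filter(function(g) channels %% g == 0L, seq_len(min(8L, channels))))
  }
  stopifnot(channels %% groups == 0L)
  params <- with_seed(seed, list(
    dw_w = matrix(rnorm(channels * spec$k_dw^3, sd = sqrt(2 / spec$k_dw^3)),
                  nrow = channels),
    dw_b = numeric(channels),
    dwd_w = matrix(rnorm(channels * spec$k_dwd^3, sd = sqrt(2 / spec$k_dwd^3)),
                   nrow = channels),
    dwd_b = numeric(channels),
    pw_w = matrix(rnorm(channels * channels, sd = sqrt(2 / channels)),
                  nrow = channels),
    pw_b = numeric(channels),
    gn_gamma = rep(1, channels),
    gn_beta = numeric(channels)
  ))
  mod <- structure(list(
    spec = spec, channels = channels, groups = as.integer(groups),
    slope = 0.01, conv_order = conv_order, residual = residual,
    params = params
  ), class = "lka_attention")
  n_conv <- attention_n_params(mod)
  stopifnot(n_conv == count_decomposed_params(channels, K, d))
  mod
}

#' Convolution parameter count of an attention module
#'
#' Counts the weights and biases of the three convolutions in the decomposed
#' chain (group-norm affine parameters excluded); equals
#' [count_decomposed_params()] by construction.
#'
#' @param module An [build_lk_attention()] module.
#' @param with_gn_affine Also count the 2C group-norm scale/shift parameters.
#' @return Integer-valued count.
#' @export
attention_n_params <- function(module, with_gn_affine = FALSE) {
  p <- module$params
  n <- length(p$dw_w) + length(p$dw_b) + length(p$dwd_w) + length(p$dwd_b) +
    length(p$pw_w) + length(p$pw_b)
  if (with_gn_affine) n <- n + length(p$gn_gamma) + length(p$gn_beta)
  n
}

#' @export
print.lka_attention <- function(x, ...) {
  cat(sprintf(
    "LK attention module: %d channels, equal LK %d^3 (DW %d^3 + DWD %d^3 @ d=%d)\n",
    x$channels, x$spec$K, x$spec$k_dw, x$spec$k_dwd, x$spec$d))
  cat(sprintf("  conv parameters: %d (+%d GN affine), GN groups: %d\n",
              attention_n_params(x), 2L * x$channels, x$groups))
  invisible(x)
}

# Core single-sample forward on a (C, D, H, W) array; optionally keeps the
# intermediates needed for the backward pass.
attention_fwd_core <- function(module, x, keep_cache = FALSE) {
  p <- module$params
  s <- module$spec
  gn <- gn_fwd(x, p$gn_gamma, p$gn_beta, module$groups)
  z <- lrelu_fwd(gn$y, module$slope)
  if (module$conv_order == "dw_first") {
    c1 <- dwconv3d_fwd(z, p$dw_w, p$dw_b, s$k_dw, 1L, s$pad_dw[1])
    c2 <- dwconv3d_fwd(c1, p$dwd_w, p$dwd_b, s$k_dwd, s$d, s$pad_dwd[1])
  } else {
    c1 <- dwconv3d_fwd(z, p$dwd_w, p$dwd_b, s$k_dwd, s$d, s$pad_dwd[1])
    c2 <- dwconv3d_fwd(c1, p$dw_w, p$dw_b, s$k_dw, 1L, s$pad_dw[1])
  }
  pre <- p$pw_w %*% matrix(c2, nrow = module$channels) + p$pw_b
  a <- sigmoid(pre)
  dim(a) <- dim(x)
  res <- if (module$residual == "normalized") z else x
  out <- a * z + res
  r <- list(output = out, attention_map = a)
  if (keep_cache) {
    r$cache <- list(x = x, gn = gn, z = z, c1 = c1, c2 = c2, a = a)
  }
  r
}

# Backward of attention_fwd_core; returns dx and per-parameter gradients.
attention_bwd_core <- function(module, cache, dout) {
  p <- module$params
  s <- module$spec
  a <- cache$a
  z <- cache$z
  da <- dout * z
  dz <- dout * a
  dx_extra <- NULL
  if (module$residual == "normalized") dz <- dz + dout else dx_extra <- dout
  dpre <- da * a * (1 - a)
  dprem <- matrix(dpre, nrow = module$channels)
  c2m <- matrix(cache$c2, nrow = module$channels)
  d_pw_w <- tcrossprod(dprem, c2m)
  d_pw_b <- rowSums(dprem)
  dc2 <- crossprod(p$pw_w, dprem)
  dim(dc2) <- dim(cache$c2)
  if (module$conv_order == "dw_first") {
    b2 <- dwconv3d_bwd(cache$c1, p$dwd_w, dc2, s$k_dwd, s$d, s$pad_dwd[1])
    d_dwd_w <- b2$dw; d_dwd_b <- b2$db
    b1 <- dwconv3d_bwd(z, p$dw_w, b2$dx, s$k_dw, 1L, s$pad_dw[1])
    d_dw_w <- b1$dw; d_dw_b <- b1$db
  } else {
    b2 <- dwconv3d_bwd(cache$c1, p$dw_w, dc2, s$k_dw, 1L, s$pad_dw[1])
    d_dw_w <- b2$dw; d_dw_b <- b2$db
    b1 <- dwconv3d_bwd(z, p$dwd_w, b2$dx, s$k_dwd, s$d, s$pad_dwd[1])
    d_dwd_w <- b1$dw; d_dwd_b <- b1$db
  }
  dz <- dz + b1$dx
  dgn_y <- lrelu_bwd(cache$gn$y, dz, module$slope)
  gb <- gn_bwd(cache$gn, p$gn_gamma, dgn_y)
  dx <- gb$dx
  if (!is.null(dx_extra)) dx <- dx + dx_extra
  list(dx = dx,
       grads = list(dw_w = d_dw_w, dw_b = d_dw_b,
                    dwd_w = d_dwd_w, dwd_b = d_dwd_b,
                    pw_w = d_pw_w, pw_b = d_pw_b,
                    gn_gamma = gb$dgamma, gn_beta = gb$dbeta))
}

#' Apply an LK attention module to a feature map
#'
#' Computes `z = lReLU(GN(x))`, the attention map
#' `A = sigmoid(pointwise(DWD(DW(z))))` and the gated output `A * z + z`
#' (elementwise). The module is channel- and shape-preserving; every
#' convolution in the chain uses zero "same" padding at stride 1.
#'
#' @param module An [build_lk_attention()] module.
#' @param x A feature map: either a `(C, D, H, W)` array or a
#'   `(batch, C, D, H, W)` array with `C == module$channels`.
#' @return A list with `output` and `attention_map`, both shaped like `x`;
#'   attention values lie strictly in `(0, 1)`.
#' @export
attention_forward <- function(module, x) {
  stopifnot(inherits(module, "lka_attention"))
  d <- dim(x)
  if (is.null(d) || !(length(d) %in% c(4L, 5L))) {
    stop("x must be a (C, D, H, W) or (batch, C, D, H, W) array", call. = FALSE)
  }
  cdim <- if (length(d) == 4L) d[1] else d[2]
  if (cdim != module$channels) {
    stop("channel mismatch: module has ", module$channels,
         " channels but input has ", cdim, call. = FALSE)
  }
  if (length(d) == 4L) {
    r <- attention_fwd_core(module, x)
    return(list(output = r$output, attention_map = r$attention_map))
  }
  out <- array(0, d)
  amap <- array(0, d)
  for (b in seq_len(d[1])) {
    xb <- array(x[b, , , , ], d[-1])
    r <- attention_fwd_core(module, xb)
    out[b, , , , ] <- r$output
    amap[b, , , , ] <- r$attention_map
  }
  list(output = out, attention_map = amap)
}
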