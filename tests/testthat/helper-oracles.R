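# Independent reference implementations used as oracles. These deliberately
# share no code with the package internals: plain nested loops and direct
# set arithmetic at tiny problem sizes.

# Naive depthwise 3-D convolution with dilation and zero "same" padding.
# x: (C, D, H, W); w: (C x k^3) with tap order tz + k*(ty + k*tx).
naive_dwconv <- function(x, w, b, k, dil, pad) {
  d <- dim(x)
  y <- array(0, d)
  for (c in seq_len(d[1])) {
    for (oz in seq_len(d[2])) for (oy in seq_len(d[3])) for (ox in seq_len(d[4])) {
      acc <- b[c]
      for (tx in 0:(k - 1)) for (ty in 0:(k - 1)) for (tz in 0:(k - 1)) {
        iz <- oz - pad + tz * dil
        iy <- oy - pad + ty * dil
        ix <- ox - pad + tx * dil
        if (iz >= 1 && iz <= d[2] && iy >= 1 && iy <= d[3] &&
            ix >= 1 && ix <= d[4]) {
          t <- tz + k * (ty + k * tx) + 1L
          acc <- acc + x[c, iz, iy, ix] * w[c, t]
        }
      }
      y[c, oz, oy, ox] <- acc
    }
  }
  y
}

# Naive group normalization over a single (C, D, H, W) sample.
naive_gn <- function(x, gamma, beta, groups, eps = 1e-5) {
  d <- dim(x)
  gs <- d[1] / groups
  y <- array(0, d)
  for (g in seq_len(groups)) {
    ch <- ((g - 1) * gs + 1):(g * gs)
    v <- x[ch, , , , drop = FALSE]
    mu <- mean(v)
    va <- mean((v - mu)^2)
    for (c in ch) {
      y[c, , , ] <- gamma[c] * (x[c, , , ] - mu) / sqrt(va + eps) + beta[c]
    }
  }
  y
}

# Full naive LK attention chain per the module definition.
naive_attention <- function(module, x) {
  p <- module$params
  s <- module$spec
  z0 <- naive_gn(x, p$gn_gamma, p$gn_beta, module$groups)
  z <- ifelse(z0 > 0, z0, module$slope * z0)
  if (module$conv_order == "dw_first") {
    c1 <- naive_dwconv(z, p$dw_w, p$dw_b, s$k_dw, 1, s$pad_dw[1])
    c2 <- naive_dwconv(c1, p$dwd_w, p$dwd_b, s$k_dwd, s$d, s$pad_dwd[1])
  } else {
    c1 <- naive_dwconv(z, p$dwd_w, p$dwd_b, s$k_dwd, s$d, s$pad_dwd[1])
    c2 <- naive_dwconv(c1, p$dw_w, p$dw_b, s$k_dw, 1, s$pad_dw[1])
  }
  d <- dim(x)
  pre <- array(0, d)
  for (oz in seq_len(d[2])) for (oy in seq_len(d[3])) for (ox in seq_len(d[4])) {
    pre[, oz, oy, ox] <- p$pw_w %*% c2[, oz, oy, ox] + p$pw_b
  }
  a <- 1 / (1 + exp(-pre))
  list(output = a * z + z, attention_map = a)
}

# Exact directed/pooled Hausdorff machinery by exhaustive pairwise distances.
oracle_boundary <- function(mask) {
  d <- dim(mask)
  out <- array(FALSE, d)
  for (z in seq_len(d[1])) for (y in seq_len(d[2])) for (x in seq_len(d[3])) {
    if (mask[z, y, x] == 0) next
    nb <- c(
      if (z > 1) mask[z - 1, y, x] else 0, if (z < d[1]) mask[z + 1, y, x] else 0,
      if (y > 1) mask[z, y - 1, x] else 0, if (y < d[2]) mask[z, y + 1, x] else 0,
      if (x > 1) mask[z, y, x - 1] else 0, if (x < d[3]) mask[z, y, x + 1] else 0)
    out[z, y, x] <- length(nb) < 6 || any(nb == 0)
  }
  out
}

oracle_surface_distances <- function(a, b, spacing) {
  pa <- which(oracle_boundary(a), arr.ind = TRUE)
  pb <- which(oracle_boundary(b), arr.ind = TRUE)
  pa <- sweep(pa, 2, spacing, "*")
  pb <- sweep(pb, 2, spacing, "*")
  d_ab <- apply(pa, 1, function(p) {
    min(sqrt(colSums((t(pb) - p)^2)))
  })
  d_ba <- apply(pb, 1, function(p) {
    min(sqrt(colSums((t(pa) - p)^2)))
  })
  list(ab = d_ab, ba = d_ba)
}

# Random binary mask with roughly the given foreground fraction.
random_mask <- function(dims, frac = 0.3) {
  array(stats::runif(prod(dims)) < frac, dims)
}

# Tiny network configuration used across tests.
tiny_config <- function(attention = list(), O = 2L, S = 3L, width = 2L,
                        I = 1L, ds = TRUE) {
  network_config(in_channels = I, out_channels = O, base_width = width,
                 n_scales = S, attention = attention, deep_supervision = ds)
}

# Finite-difference gradient of a scalar-valued function of net$params[[nm]]
# at flat index i.
fd_grad <- function(net, nm, i, lossfun, eps = 1e-5) {
  p <- net
  p$params[[nm]][i] <- p$params[[nm]][i] + eps
  up <- lossfun(p)
  p$params[[nm]][i] <- p$params[[nm]][i] - 2 * eps
  dn <- lossfun(p)
  (up - dn) / (2 * eps)
}
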