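test_that("zeroed convolutions force a uniform 0.5 attention map", {
  mod <- build_lk_attention(3, 6, 2, seed = 1)
  for (nm in c("dw_w", "dw_b", "dwd_w", "dwd_b", "pw_w", "pw_b")) {
    mod$params[[nm]][] <- 0
  }
  x <- array(rnorm(3 * 4 * 5 * 6), c(3, 4, 5, 6))
  r <- attention_forward(mod, x)
  expect_true(all(abs(r$attention_map - 0.5) < 1e-12))
  # output = (1 + A) * z = 1.5 * z with z the normalized-activated input
  gn <- lka3d:::gn_fwd(x, mod$params$gn_gamma, mod$params$gn_beta, mod$groups)
  z <- lka3d:::lrelu_fwd(gn$y, 0.01)
  expect_equal(r$output, 1.5 * z, tolerance = 1e-12)
})

test_that("the module is shape-preserving for all standard configurations", {
  # (K, d) pairs of the fully-applied network, small spatial grids
  for (cfg in list(c(6, 2), c(10, 2), c(15, 3), c(21, 3))) {
    mod <- build_lk_attention(2, cfg[1], cfg[2], seed = 0)
    x <- array(rnorm(2 * 5 * 6 * 4), c(2, 5, 6, 4))
    r <- attention_forward(mod, x)
    expect_identical(dim(r$output), dim(x))
    expect_identical(dim(r$attention_map), dim(x))
    expect_true(all(r$attention_map > 0 & r$attention_map < 1))
  }
  # batched 5-D input
  mod <- build_lk_attention(2, 6, 2, seed = 0)
  xb <- array(rnorm(2 * 2 * 4 * 4 * 4), c(2, 2, 4, 4, 4))
  rb <- attention_forward(mod, xb)
  expect_identical(dim(rb$output), dim(xb))
  r1 <- attention_forward(mod, array(xb[1, , , , ], c(2, 4, 4, 4)))
  expect_equal(array(rb$output[1, , , , ], c(2, 4, 4, 4)), r1$output)
})

test_that("forward pass equals the naive direct-convolution oracle", {
  set.seed(7)
  for (rep in 1:3) {
    mod <- build_lk_attention(2, 6, 2, seed = rep)
    x <- array(rnorm(2 * 6 * 6 * 6), c(2, 6, 6, 6))
    got <- attention_forward(mod, x)
    want <- naive_attention(mod, x)
    expect_equal(got$output, want$output, tolerance = 1e-5)
    expect_equal(got$attention_map, want$attention_map, tolerance = 1e-5)
  }
  # impulse input, larger dilation
  mod <- build_lk_attention(2, 10, 2, seed = 9)
  x <- array(0, c(2, 7, 7, 7)); x[1, 4, 4, 4] <- 1
  expect_equal(attention_forward(mod, x)$output, naive_attention(mod, x)$output,
               tolerance = 1e-5)
})

test_that("gating keeps the output within (1, 2) times the gated input", {
  mod <- build_lk_attention(4, 6, 2, seed = 3)
  x <- array(rnorm(4 * 5 * 5 * 5), c(4, 5, 5, 5))
  r <- attention_forward(mod, x)
  gn <- lka3d:::gn_fwd(x, mod$params$gn_gamma, mod$params$gn_beta, mod$groups)
  z <- lka3d:::lrelu_fwd(gn$y, 0.01)
  ratio <- (r$output / z)[abs(z) > 1e-8]
  expect_true(all(ratio > 1 & ratio < 2))
})

test_that("depthwise stages do not mix channels before the pointwise conv", {
  mod <- build_lk_attention(3, 6, 2, seed = 5)
  s <- mod$spec
  p <- mod$params
  z <- array(rnorm(3 * 5 * 5 * 5), c(3, 5, 5, 5))
  chain <- function(z) {
    c1 <- lka3d:::dwconv3d_fwd(z, p$dw_w, p$dw_b, s$k_dw, 1L, s$pad_dw[1])
    lka3d:::dwconv3d_fwd(c1, p$dwd_w, p$dwd_b, s$k_dwd, s$d, s$pad_dwd[1])
  }
  base <- chain(z)
  z2 <- z; z2[2, , , ] <- 0  # zero channel 2
  pert <- chain(z2)
  expect_equal(pert[1, , , ], base[1, , , ])  # other channels untouched
  expect_equal(pert[3, , , ], base[3, , , ])
  expect_false(isTRUE(all.equal(pert[2, , , ], base[2, , , ])))
})

test_that("receptive field matches the gradient footprint of the chain", {
  for (cfg in list(c(6, 2, 7), c(10, 2, 11), c(15, 3, 17), c(21, 3, 23),
                   c(1, 1, 1))) {
    spec <- decompose_kernel(cfg[1], cfg[2])
    expect_identical(receptive_field(spec), cfg[3])
    n <- cfg[3] + 2L  # grid just larger than the expected footprint
    ctr <- (n + 1L) %/% 2L
    w_dw <- matrix(runif(spec$k_dw^3, 0.5, 1), nrow = 1)
    w_dwd <- matrix(runif(spec$k_dwd^3, 0.5, 1), nrow = 1)
    dout <- array(0, c(1, n, n, n)); dout[1, ctr, ctr, ctr] <- 1
    # backpropagate an impulse through DWD then DW to find the input voxels
    # that influence the centre output
    g <- lka3d:::dwconv3d_bwd(array(0, c(1, n, n, n)), w_dwd, dout,
                              spec$k_dwd, spec$d, spec$pad_dwd[1])$dx
    g <- lka3d:::dwconv3d_bwd(array(0, c(1, n, n, n)), w_dw, g,
                              spec$k_dw, 1L, spec$pad_dw[1])$dx
    nz <- which(array(g, c(n, n, n)) != 0, arr.ind = TRUE)
    side <- max(apply(nz, 2, function(v) diff(range(v)) + 1L))
    expect_identical(as.integer(side), as.integer(cfg[3]))
  }
})

test_that("construction-time parameter count matches the calculus per scale", {
  # (channels, K, d) of the fully-applied network, finest to coarsest
  table2 <- list(c(32, 21, 3), c(64, 15, 3), c(128, 10, 2),
                 c(256, 6, 2), c(512, 6, 2))
  for (row in table2) {
    mod <- build_lk_attention(row[1], row[2], row[3], seed = 0)
    expect_equal(attention_n_params(mod),
                 count_decomposed_params(row[1], row[2], row[3]))
  }
  expect_equal(attention_n_params(build_lk_attention(1, 1, 1, seed = 0)), 6)
})

test_that("channel mismatch and invalid geometry are rejected", {
  mod <- build_lk_attention(2, 6, 2, seed = 0)
  expect_error(attention_forward(mod, array(0, c(3, 4, 4, 4))), "channel mismatch")
  expect_error(build_lk_attention(4, 21, 4), "divide")
})

test_that("attention backward agrees with finite differences", {
  mod <- build_lk_attention(2, 6, 2, seed = 11)
  x <- array(rnorm(2 * 4 * 4 * 4), c(2, 4, 4, 4))
  w_out <- array(rnorm(2 * 4 * 4 * 4), c(2, 4, 4, 4))  # random loss direction
  lossfun <- function(m, xx) sum(w_out * lka3d:::attention_fwd_core(m, xx)$output)
  fwd <- lka3d:::attention_fwd_core(mod, x, keep_cache = TRUE)
  bwd <- lka3d:::attention_bwd_core(mod, fwd$cache, w_out)
  eps <- 1e-6
  set.seed(1)
  # parameters
  for (nm in names(mod$params)) {
    i <- sample(length(mod$params[[nm]]), 1)
    m2 <- mod; m2$params[[nm]][i] <- m2$params[[nm]][i] + eps
    m3 <- mod; m3$params[[nm]][i] <- m3$params[[nm]][i] - eps
    fd <- (lossfun(m2, x) - lossfun(m3, x)) / (2 * eps)
    expect_equal(bwd$grads[[nm]][i], fd, tolerance = 1e-4,
                 info = paste("param", nm))
  }
  # input
  for (rep in 1:4) {
    i <- sample(length(x), 1)
    x2 <- x; x2[i] <- x2[i] + eps
    x3 <- x; x3[i] <- x3[i] - eps
    fd <- (lossfun(mod, x2) - lossfun(mod, x3)) / (2 * eps)
    expect_equal(bwd$dx[i], fd, tolerance = 1e-4, info = paste("input", i))
  }
})
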