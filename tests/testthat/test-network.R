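test_that("attention placement adds exactly the calculus parameter count", {
  base <- network_config(1, 7, attention = list())
  mid <- network_config(1, 7, attention = mid_placements())
  full <- network_config(1, 7, attention = full_placements())
  n_base <- count_network_params(base)
  # conv-only differences reproduce the published per-variant increments
  expect_equal(count_network_params(mid, conv_only_attention = TRUE) - n_base,
               76672)
  expect_equal(count_network_params(full, conv_only_attention = TRUE) - n_base,
               444064)
  # with the module GN affine pairs included the difference grows by 2C each
  expect_equal(count_network_params(mid) - n_base, 76672 + 2 * 128)
  # additivity for an arbitrary placement set
  pl <- list(list(scale = 1L, K = 6L, d = 2L), list(scale = 4L, K = 6L, d = 2L))
  var <- network_config(1, 7, attention = pl)
  ch <- base$channels
  expect_equal(count_network_params(var, conv_only_attention = TRUE) - n_base,
               count_decomposed_params(ch[2], 6, 2) +
                 count_decomposed_params(ch[5], 6, 2))
})

test_that("single-module increments reproduce every published variant", {
  base <- network_config(1, 7, attention = list())
  n_base <- count_network_params(base)
  # (decoder scale, K, d, expected added k-parameters)
  rows <- list(list(4L, 6L, 2L, 291.33), list(3L, 6L, 2L, 80.13),
               list(2L, 6L, 2L, 23.68), list(1L, 6L, 2L, 7.74),
               list(0L, 6L, 2L, 2.85), list(0L, 10L, 2L, 5.98),
               list(0L, 15L, 3L, 9.12), list(0L, 21L, 3L, 16.10),
               list(2L, 21L, 3L, 76.67))
  for (r in rows) {
    cfg <- network_config(1, 7, attention = list(list(scale = r[[1]],
                                                      K = r[[2]], d = r[[3]])))
    added <- count_network_params(cfg, conv_only_attention = TRUE) - n_base
    expect_equal(round(added / 1000, 2), r[[4]],
                 info = sprintf("scale %d K %d", r[[1]], r[[2]]))
  }
})

test_that("instantiated weight arrays sum to the analytic breakdown", {
  for (cfg in list(tiny_config(),
                   tiny_config(attention = list(list(scale = 0L, K = 6L, d = 2L))),
                   tiny_config(O = 3L, S = 4L, width = 4L, I = 2L),
                   tiny_config(ds = FALSE))) {
    net <- build_network(cfg, seed = 1)
    expect_equal(sum(vapply(net$params, length, numeric(1))),
                 count_network_params(cfg))
    expect_equal(sum(net$breakdown$params), count_network_params(net))
  }
})

test_that("a degenerate one-scale network matches a hand parameter count", {
  cfg <- network_config(1, 1, base_width = 1L, n_scales = 1L,
                        attention = list(), deep_supervision = FALSE)
  # two 3^3 convs (1->1): 2 * (27 + 1); two GN pairs: 2 * 2; head 1^3: 1 + 1
  expect_equal(count_network_params(cfg), 2 * 28 + 4 + 2)
})

test_that("forward pass has the contracted shapes and determinism", {
  cfg <- tiny_config(attention = list(list(scale = 1L, K = 6L, d = 2L)),
                     O = 3L, S = 3L, width = 2L)
  net <- build_network(cfg, seed = 2)
  x <- array(rnorm(1 * 8 * 8 * 12), c(1, 8, 8, 12))
  out <- network_forward(net, x)
  expect_identical(dim(out$main), c(3L, 8L, 8L, 12L))
  # heads at all scales except the two lowest: scales 0 only aux at... S=3 -> head scale 0 only
  expect_identical(length(out$aux), 0L)
  expect_identical(names(out$attention_maps), "1")
  expect_identical(dim(out$attention_maps[["1"]]), c(4L, 4L, 4L, 6L))
  expect_true(all(is.finite(out$main)))
  out2 <- network_forward(build_network(cfg, seed = 2), x)
  expect_identical(out$main, out2$main)
  # Base variant: no attention maps
  net0 <- build_network(tiny_config(), seed = 0)
  expect_identical(length(network_forward(net0, array(0, c(1, 4, 4, 4)))$attention_maps), 0L)
})

test_that("deep supervision heads follow the except-two-lowest rule", {
  cfg4 <- tiny_config(S = 4L, O = 2L)
  net4 <- build_network(cfg4, seed = 0)
  out <- network_forward(net4, array(rnorm(512), c(1, 8, 8, 8)))
  expect_identical(names(out$aux), "1")             # 4 scales -> heads at 0, 1
  expect_identical(dim(out$aux[["1"]]), c(2L, 4L, 4L, 4L))
  cfg6 <- network_config(1, 2, base_width = 1L, n_scales = 6L)
  expect_identical(lka3d:::head_scales(cfg6), 0:3)  # 6 scales -> heads at 0..3
})

test_that("invalid inputs are rejected with the required divisibility", {
  net <- build_network(tiny_config(S = 3L), seed = 0)
  expect_error(network_forward(net, array(0, c(1, 6, 8, 8))), "divisible by 4")
  expect_error(network_forward(net, array(0, c(2, 8, 8, 8))), "channel mismatch")
  expect_error(network_config(1, 2, n_scales = 3L, input_shape = c(6, 8, 8)),
               "divisible")
  expect_error(network_config(1, 2, n_scales = 3L,
                              attention = list(list(scale = 2L, K = 6L, d = 2L))),
               "decoder scale")
})

test_that("batch entries are processed independently", {
  cfg <- tiny_config(S = 2L, O = 2L)
  net <- build_network(cfg, seed = 4)
  x <- array(rnorm(2 * 1 * 4 * 4 * 4), c(2, 1, 4, 4, 4))
  out <- network_forward(net, x)
  xp <- x[c(2, 1), , , , , drop = FALSE]
  outp <- network_forward(net, xp)
  expect_equal(out$main[1, , , , ], outp$main[2, , , , ])
  expect_equal(out$main[2, , , , ], outp$main[1, , , , ])
})

test_that("network gradients agree with finite differences", {
  cfg <- tiny_config(attention = list(list(scale = 0L, K = 6L, d = 2L)),
                     O = 2L, S = 3L, width = 2L)
  net <- build_network(cfg, seed = 6)
  set.seed(8)
  x <- array(rnorm(64), c(1, 4, 4, 4))
  label <- array(sample(0:1, 64, replace = TRUE), c(4, 4, 4))
  lossfun <- function(n) {
    fwd <- lka3d:::network_fwd_core(n, x, keep_cache = FALSE)
    lka3d:::supervised_loss(n, fwd, label, weights = NULL,
                            loss_type = "weighted_dice")$loss
  }
  fwd <- lka3d:::network_fwd_core(net, x, keep_cache = TRUE)
  sl <- lka3d:::supervised_loss(net, fwd, label, NULL, "weighted_dice")
  grads <- lka3d:::network_bwd_core(net, fwd$cache, sl$dlogits)
  expect_setequal(names(grads), names(net$params))
  nms <- sample(names(net$params), 12)
  for (nm in nms) {
    i <- sample(length(net$params[[nm]]), 1)
    fd <- fd_grad(net, nm, i, lossfun, eps = 1e-5)
    expect_equal(grads[[nm]][i], fd, tolerance = 5e-3,
                 info = paste(nm, "index", i))
  }
})
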