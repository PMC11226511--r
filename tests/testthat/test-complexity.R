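test_that("kernel decomposition reproduces the standard module geometries", {
  # (K, d) -> (k_dw, pad_dw, k_dwd, pad_dwd) for every module configuration
  cases <- list(
    list(K = 6, d = 2, k_dw = 3, pad_dw = 1, k_dwd = 3, pad_dwd = 2),
    list(K = 10, d = 2, k_dw = 3, pad_dw = 1, k_dwd = 5, pad_dwd = 4),
    list(K = 15, d = 3, k_dw = 5, pad_dw = 2, k_dwd = 5, pad_dwd = 6),
    list(K = 21, d = 3, k_dw = 5, pad_dw = 2, k_dwd = 7, pad_dwd = 9),
    list(K = 1, d = 1, k_dw = 1, pad_dw = 0, k_dwd = 1, pad_dwd = 0)
  )
  for (cs in cases) {
    spec <- decompose_kernel(cs$K, cs$d)
    expect_equal(spec$k_dw, cs$k_dw, info = paste("K =", cs$K))
    expect_equal(spec$k_dwd, cs$k_dwd, info = paste("K =", cs$K))
    expect_equal(spec$pad_dw, rep(cs$pad_dw, 3), info = paste("K =", cs$K))
    expect_equal(spec$pad_dwd, rep(cs$pad_dwd, 3), info = paste("K =", cs$K))
    # "same"-size condition of each conv at stride 1
    expect_equal(2 * cs$pad_dw, cs$k_dw - 1)
    expect_equal(2 * cs$pad_dwd, cs$d * (cs$k_dwd - 1))
  }
  expect_error(decompose_kernel(21, 4), "divide")
})

test_that("parameter counts match the closed forms exactly", {
  expect_identical(count_original_params(32, 21), 9483296)
  expect_identical(count_original_params(512, 6), 56623616)
  expect_identical(count_original_params(1, 1), 2)
  expect_identical(count_decomposed_params(32, 21, 3), 16096)
  expect_identical(count_decomposed_params(128, 21, 3), 76672)
  expect_identical(count_decomposed_params(512, 6, 2), 291328)
  # degenerate d = 1: chain degenerates to 1^3 DW + K^3 DWD + pointwise
  expect_identical(count_decomposed_params(1, 21, 1),
                   1 * (1 + 21^3 + 1 + 3))
  expect_error(count_original_params(0, 3))
  expect_error(count_decomposed_params(8, 21, 4))
})

test_that("decomposed count equals a brute-force weight enumeration", {
  set.seed(42)
  for (rep in 1:8) {
    C <- sample(1:8, 1)
    d <- sample(1:3, 1)
    K <- d * (2 * sample(1:3, 1) - 1)  # odd multiple keeps padding integral
    mod <- build_lk_attention(C, K, d, seed = rep)
    spec <- decompose_kernel(K, d)
    # enumerate the chain's weight arrays from the definition alone
    n_oracle <- C * spec$k_dw^3 + C +   # DW weights + biases
      C * spec$k_dwd^3 + C +            # DWD weights + biases
      C * C + C                         # pointwise weights + biases
    expect_equal(attention_n_params(mod), n_oracle)
    expect_equal(n_oracle, count_decomposed_params(C, K, d))
  }
})

test_that("decomposition efficiency grows with the channel count", {
  tab <- complexity_table(c(32, 64, 128, 256, 512), 21, 3)
  expect_true(all(diff(tab$ratio) < 0))
  expect_equal(tab$ratio, tab$n_prm_decomposed / tab$n_prm_original)
})

test_that("FLOPs equal parameters times voxel count", {
  expect_identical(count_flops(16096, c(1, 1, 1)), 16096)
  expect_identical(count_flops(2, c(2, 3, 4)), 48)
  expect_identical(count_flops(count_original_params(32, 21), c(10, 12, 8)),
                   9483296 * 960)
  for (C in c(3, 32)) for (dims in list(c(2, 5, 7), c(4, 4, 4))) {
    expect_identical(count_flops(count_decomposed_params(C, 6, 2), dims),
                     count_decomposed_params(C, 6, 2) * prod(dims))
  }
})

test_that("optimal continuous dilation solves the stationarity equation", {
  r <- optimal_dilation(21)
  expect_equal(round(r$d_star, 4), 3.4159)
  expect_lt(abs(r$residual), 1e-6)
  expect_identical(r$d_int, 3L)
  # grid-search oracle over the d-dependent objective
  grid <- seq(1, 10, by = 1e-4)
  obj <- (2 * grid - 1)^3 + (21 / grid)^3
  expect_equal(grid[which.min(obj)], r$d_star, tolerance = 1e-3)
  # the root grows with the kernel size
  roots <- vapply(c(6, 10, 15, 21), function(K) optimal_dilation(K)$d_star,
                  numeric(1))
  expect_true(all(diff(roots) > 0))
})

test_that("kernel coverage is the kernel-to-feature-space volume ratio", {
  expect_equal(round(100 * kernel_coverage(c(21, 21, 21), c(40, 48, 32)), 2),
               15.07)
  expect_equal(round(100 * kernel_coverage(c(6, 6, 6), c(10, 12, 8)), 2), 22.50)
  expect_identical(kernel_coverage(c(1, 1, 1), c(1, 1, 1)), 1)
  expect_error(kernel_coverage(c(3, 3, 3), c(0, 4, 4)))
})

test_that("the complexity table renders counts in k/M units half-up", {
  tab <- complexity_table(c(32, 512), 21, 3, dims = c(2, 2, 2))
  expect_equal(format_param_count(tab$n_prm_decomposed[1]), "16.10 k")
  expect_equal(format_param_count(tab$n_prm_decomposed[2]), "503.30 k")
  expect_equal(format_param_count(tab$n_prm_original[1]), "9.48 M")
  expect_equal(format_percent(tab$ratio[1]), "0.17%")
  expect_equal(tab$flops_decomposed, tab$n_prm_decomposed * 8)
  expect_identical(nrow(complexity_table(integer(0), 21, 3)), 0L)
  out <- capture.output(print(tab))
  expect_true(any(grepl("16.10 k", out, fixed = TRUE)))
})
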