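#' Decompose a cubic large-kernel convolution
#'
#' A `K x K x K` large-kernel (LK) convolution can be replaced by the chain of
#' a `(2d-1)^3` depthwise (DW) convolution, a `(K/d)^3` depthwise dilated
#' (DWD) convolution with dilation `d`, and a `1x1x1` pointwise convolution.
#' This function derives the kernel geometry of that chain, including the
#' zero paddings that keep every convolution "same"-sized at stride 1.
#'
#' @param K Side of the cubic large kernel (positive integer).
#' @param d Dilation rate (positive integer); must divide `K`.
#' @return An object of class `lka_decomposition` with elements `K`, `d`,
#'   `k_dw`, `k_dwd`, `pad_dw`, `pad_dwd` (integer triples) and
#'   `receptive_field`, the side of the cubic input region seen by one output
#'   voxel of the DW + DWD chain.
#' @examples
#' decompose_kernel(21, 3)  # 5^3 DW, 7^3 DWD at dilation 3
#' @export
decompose_kernel <- function(K, d) {
  K <- check_count(K, "K")
  d <- check_count(d, "d")
  if (K %% d != 0L) {
    stop("dilation d = ", d, " must divide the kernel size K = ", K,
         " (the equal LK size is k_dwd * d)", call. = FALSE)
  }
  k_dw <- 2L * d - 1L
  k_dwd <- K %/% d
  if ((d * (k_dwd - 1L)) %% 2L != 0L) {
    # K/d is always odd when K and d have the same parity structure used in
    # practice; guard anyway so "same" padding stays integral.
    stop("d * (K/d - 1) must be even for a symmetric same-size padding",
         call. = FALSE)
  }
  spec <- structure(list(
    K = K, d = d, k_dw = k_dw, k_dwd = k_dwd,
    pad_dw = rep(d - 1L, 3L),
    pad_dwd = rep(as.integer(d * (k_dwd - 1L) / 2L), 3L),
    receptive_field = k_dw + d * (k_dwd - 1L)
  ), class = "lka_decomposition")
  spec
}

#' @export
print.lka_decomposition <- function(x, ...) {
  cat(sprintf("LK decomposition: %d^3 kernel, dilation %d\n", x$K, x$d))
  cat(sprintf("  DW  conv: %d^3, padding %d\n", x$k_dw, x$pad_dw[1]))
  cat(sprintf("  DWD conv: %d^3, dilation %d, padding %d\n",
              x$k_dwd, x$d, x$pad_dwd[1]))
  cat(sprintf("  receptive field of DW+DWD chain: %d^3\n", x$receptive_field))
  invisible(x)
}

#' Effective receptive field of a decomposed LK convolution
#'
#' Side of the cubic input region that influences one output voxel of the
#' DW followed by DWD convolution chain: `k_dw + d * (k_dwd - 1)`.
#'
#' @param spec An [decompose_kernel()] result.
#' @return Positive integer.
#' @export
receptive_field <- function(spec) {
  stopifnot(inherits(spec, "lka_decomposition"))
  spec$receptive_field
}

#' Parameter count of an original large-kernel convolution
#'
#' Number of trainable parameters of a dense `K^3` convolution with `C` input
#' and `C` output channels and one bias per output channel:
#' `C * (C * K^3 + 1)`.
#'
#' @param C Channel count (positive integer).
#' @param K Kernel side (positive integer).
#' @return Exact integer-valued count (as a double to avoid 32-bit overflow).
#' @examples
#' count_original_params(32, 21)  # 9,483,296
#' @export
count_original_params <- function(C, K) {
  C <- check_count(C, "C"); K <- check_count(K, "K")
  C * (C * as.numeric(K)^3 + 1)
}

#' Parameter count of the decomposed large-kernel convolution
#'
#' Trainable parameters of the DW + DWD + pointwise chain, biases included:
#' `C * ((2d-1)^3 + (K/d)^3 + C + 3)`. The `C + 3` term is the `C x C`
#' pointwise weight plus one bias for each of the three convolutions, so the
#' instantiated attention module (see [build_lk_attention()]) carries exactly
#' this many convolution parameters.
#'
#' @inheritParams count_original_params
#' @param d Dilation rate; must divide `K`.
#' @return Exact integer-valued count.
#' @examples
#' count_decomposed_params(32, 21, 3)  # 16,096
#' @export
count_decomposed_params <- function(C, K, d) {
  spec <- decompose_kernel(K, d)
  C <- check_count(C, "C")
  C * (as.numeric(spec$k_dw)^3 + as.numeric(spec$k_dwd)^3 + C + 3)
}

#' FLOP count of a same-size convolution
#'
#' For stride-1 "same" convolutions both the original and the decomposed
#' variant cost their parameter count once per output voxel, so the FLOP
#' count is `params * H * W * D`.
#'
#' @param params Parameter count of the convolution (from
#'   [count_original_params()] or [count_decomposed_params()]).
#' @param dims Positive integer triple of feature-map spatial dimensions.
#' @return Exact integer-valued count.
#' @export
count_flops <- function(params, dims) {
  if (!is.numeric(params) || length(params) != 1L || params < 0) {
    stop("params must be a single non-negative number", call. = FALSE)
  }
  dims <- check_dims_triple(dims)
  params * prod(as.numeric(dims))
}

#' Optimal continuous dilation for a kernel size
#'
#' Minimizes the d-dependent part of the decomposed parameter count,
#' `(2d-1)^3 + (K/d)^3`, over positive real `d`. Setting the derivative to
#' zero gives the stationarity condition `24 d^2 - 24 d - 3 K^3 / d^4 + 6 = 0`,
#' whose positive root is found by bisection on `[1, K]`.
#'
#' @param K Kernel side, at least 2.
#' @param tol Absolute tolerance of the root (default `1e-8`).
#' @return A list with `d_star` (the continuous root), `residual` (the
#'   stationarity equation evaluated at the root), and `d_int`, the better of
#'   `floor(d_star)` and `ceiling(d_star)` under the exact objective restricted
#'   to divisors-agnostic integer dilations.
#' @examples
#' optimal_dilation(21)$d_star  # ~3.4159
#' @export
optimal_dilation <- function(K, tol = 1e-8) {
  K <- check_count(K, "K")
  if (K < 2) stop("K must be at least 2", call. = FALSE)
  f <- function(d) 24 * d^2 - 24 * d - 3 * as.numeric(K)^3 / d^4 + 6
  lo <- 1; hi <- as.numeric(K)
  if (f(lo) >= 0 || f(hi) <= 0) {
    stop("no sign change of the stationarity equation on [1, K]", call. = FALSE)
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  d_star <- (lo + hi) / 2
  obj <- function(d) (2 * d - 1)^3 + (as.numeric(K) / d)^3
  cand <- unique(pmax(1, c(floor(d_star), ceiling(d_star))))
  d_int <- cand[which.min(obj(cand))]
  list(d_star = d_star, residual = f(d_star), d_int = as.integer(d_int))
}

#' Kernel coverage of an attention module at a feature-map scale
#'
#' Ratio of the kernel voxel volume to the feature-space voxel volume,
#' `prod(kernel) / prod(scale)`; a proxy for how globally the attention map
#' can integrate context at that scale.
#'
#' @param kernel Positive integer triple (equal LK kernel per axis).
#' @param scale Positive integer triple (feature-map spatial dimensions).
#' @return The coverage fraction (may exceed 1 for kernels larger than the
#'   feature map).
#' @examples
#' kernel_coverage(c(21, 21, 21), c(40, 48, 32))  # 0.1507
#' @export
kernel_coverage <- function(kernel, scale) {
  kernel <- check_dims_triple(kernel, "kernel")
  scale <- check_dims_triple(scale, "scale")
  prod(as.numeric(kernel)) / prod(as.numeric(scale))
}

#' Complexity comparison table for the LK decomposition
#'
#' One row per channel count, comparing the dense `K^3` convolution with its
#' decomposition at dilation `d`: exact parameter counts, their ratio, and
#' (optionally) FLOPs at the given feature-map dimensions.
#'
#' @param channel_list Positive integer vector of channel counts.
#' @param K Kernel side.
#' @param d Dilation rate dividing `K`.
#' @param dims Optional spatial dimensions triple for FLOP columns.
#' @return A `data.frame` of class `lka_complexity_table` with columns `C`,
#'   `n_prm_original`, `n_prm_decomposed`, `ratio` and, when `dims` is given,
#'   `flops_original` and `flops_decomposed`. The print method renders counts
#'   in k/M units with two decimals (half-up) and the ratio as a percentage.
#' @examples
#' complexity_table(c(32, 64, 128, 256, 512), 21, 3)
#' @export
complexity_table <- function(channel_list, K, d, dims = NULL) {
  spec <- decompose_kernel(K, d)  # validates (K, d)
  channel_list <- vapply(channel_list, check_count, numeric(1), name = "C")
  rows <- lapply(channel_list, function(C) {
    o <- count_original_params(C, K)
    dc <- count_decomposed_params(C, K, d)
    r <- data.frame(C = C, n_prm_original = o, n_prm_decomposed = dc,
                    ratio = dc / o)
    if (!is.null(dims)) {
      r$flops_original <- count_flops(o, dims)
      r$flops_decomposed <- count_flops(dc, dims)
    }
    r
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(C = numeric(0), n_prm_original = numeric(0),
                      n_prm_decomposed = numeric(0), ratio = numeric(0))
  }
  attr(out, "K") <- spec$K
  attr(out, "d") <- spec$d
  class(out) <- c("lka_complexity_table", "data.frame")
  out
}

#' Render a parameter count in k/M units
#'
#' Half-up rounding to two decimals in units of 1e3 ("k") or 1e6 ("M"),
#' matching the conventional presentation of network parameter counts.
#'
#' @param n Non-negative count.
#' @param unit `"auto"`, `"k"` or `"M"`.
#' @return Character scalar such as `"16.10 k"` or `"9.48 M"`.
#' @export
format_param_count <- function(n, unit = c("auto", "k", "M")) {
  unit <- match.arg(unit)
  if (unit == "auto") unit <- if (n >= 1e6) "M" else "k"
  div <- if (unit == "M") 1e6 else 1e3
  sprintf("%.2f %s", round_half_up(n / div, 2L), unit)
}

#' Render a fraction as a percentage
#'
#' @param x Fraction in `[0, 1]` (or above).
#' @param digits Decimal places (half-up).
#' @return Character scalar such as `"0.17%"`.
#' @export
format_percent <- function(x, digits = 2L) {
  sprintf(paste0("%.", digits, "f%%"), round_half_up(100 * x, digits))
}

#' @export
print.lka_complexity_table <- function(x, ...) {
  cat(sprintf("Complexity of a %d^3 convolution vs its decomposition (d = %d)\n",
              attr(x, "K"), attr(x, "d")))
  df <- data.frame(
    C = x$C,
    original = vapply(x$n_prm_original, format_param_count, character(1)),
    decomposed = vapply(x$n_prm_decomposed, format_param_count, character(1)),
    ratio = vapply(x$ratio, format_percent, character(1))
  )
  if (!is.null(x$flops_original)) {
    df$flops_original <- vapply(x$flops_original, format_param_count, character(1),
                                unit = "M")
    df$flops_decomposed <- vapply(x$flops_decomposed, format_param_count,
                                  character(1), unit = "M")
  }
  print(df, row.names = FALSE)
  invisible(x)
}
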