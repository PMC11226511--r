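#' Configure a 3D LK attention U-Net
#'
#' Describes the six-scale encoder-decoder: two `3^3` convolutions (each with
#' group norm and leaky ReLU) per scale, stride-2 `3^3` transition
#' convolutions for downsampling, `4^3` stride-2 transposed convolutions for
#' upsampling, channel-concatenating skip connections, segmentation heads
#' (`1^3` convolutions) at all scales except the two lowest, and LK attention
#' modules inserted directly after selected transposed convolutions (before
#' concatenation with the skip).
#'
#' @param in_channels Number of input channels `I` (imaging modalities).
#' @param out_channels Number of segmentation classes `O` (softmax heads
#'   include the background class; sigmoid heads are one channel per region).
#' @param base_width Channels at the finest scale (32 for the full-size
#'   network).
#' @param max_width Channel cap (512).
#' @param n_scales Number of scales (6 for the full-size network; the deepest
#'   feature map is `1/2^(n_scales-1)` of the input).
#' @param attention List of placements, each `list(scale, K, d)` with `scale`
#'   a decoder scale index (0 = finest). Use [mid_placements()] /
#'   [full_placements()] for the standard variants, or `list()` for the Base
#'   network.
#' @param head_activation `"softmax"` (multi-organ, exclusive classes) or
#'   `"sigmoid"` (overlapping region channels).
#' @param deep_supervision Add auxiliary heads (and losses) at intermediate
#'   decoder scales.
#' @param input_shape Optional spatial dimension triple; when given it must be
#'   divisible by `2^(n_scales-1)`.
#' @return An object of class `lka_net_config`.
#' @examples
#' cfg <- network_config(1, 7, attention = mid_placements())
#' count_network_params(cfg)
#' @export
network_config <- function(in_channels = 1L, out_channels = 2L,
                           base_width = 32L, max_width = 512L,
                           n_scales = 6L, attention = list(),
                           head_activation = c("softmax", "sigmoid"),
                           deep_supervision = TRUE, input_shape = NULL) {
  in_channels <- as.integer(check_count(in_channels, "in_channels"))
  out_channels <- as.integer(check_count(out_channels, "out_channels"))
  base_width <- as.integer(check_count(base_width, "base_width"))
  n_scales <- as.integer(check_count(n_scales, "n_scales"))
  head_activation <- match.arg(head_activation)
  ch <- pmin(base_width * 2^(seq_len(n_scales) - 1L), max_width)
  attention <- lapply(attention, function(p) {
    p <- as.list(p)
    names(p)[seq_along(p)] <- c("scale", "K", "d")[seq_along(p)]
    if (p$scale < 0 || p$scale > n_scales - 2L) {
      stop("attention scale index must be a decoder scale in 0..",
           n_scales - 2L, call. = FALSE)
    }
    decompose_kernel(p$K, p$d)  # validates (K, d)
    p
  })
  if (!is.null(input_shape)) {
    input_shape <- check_dims_triple(input_shape, "input_shape")
    div <- 2L^(n_scales - 1L)
    if (any(input_shape %% div != 0L)) {
      stop("input_shape must be divisible by ", div, " for ", n_scales,
           " scales", call. = FALSE)
    }
  }
  structure(list(
    in_channels = in_channels, out_channels = out_channels,
    base_width = base_width, max_width = as.integer(max_width),
    n_scales = n_scales, channels = as.integer(ch),
    attention = attention, head_activation = head_activation,
    deep_supervision = deep_supervision, input_shape = input_shape
  ), class = "lka_net_config")
}

#' Standard attention placements
#'
#' `mid_placements()` is the single equal-21 module at the middle decoder
#' scale (128 channels for the full-size network); `full_placements()` puts a
#' module after every transposed convolution with the per-scale kernel and
#' dilation of the fully-applied network (finest to coarsest:
#' 21/3, 15/3, 10/2, 6/2, 6/2).
#'
#' @return A list of `list(scale, K, d)` placements.
#' @export
mid_placements <- function() list(list(scale = 2L, K = 21L, d = 3L))

#' @rdname mid_placements
#' @export
full_placements <- function() list(
  list(scale = 0L, K = 21L, d = 3L),
  list(scale = 1L, K = 15L, d = 3L),
  list(scale = 2L, K = 10L, d = 2L),
  list(scale = 3L, K = 6L, d = 2L),
  list(scale = 4L, K = 6L, d = 2L)
)

#' @export
print.lka_net_config <- function(x, ...) {
  cat(sprintf("LK attention U-Net config: %d scales, channels %s\n",
              x$n_scales, paste(x$channels, collapse = "/")))
  cat(sprintf("  I = %d, O = %d (%s), deep supervision: %s\n",
              x$in_channels, x$out_channels, x$head_activation,
              x$deep_supervision))
  if (length(x$attention)) {
    for (p in x$attention) {
      cat(sprintf("  attention @ decoder scale %d: K = %d, d = %d (C = %d)\n",
                  p$scale, p$K, p$d, x$channels[p$scale + 1L]))
    }
  } else cat("  no attention modules (Base)\n")
  invisible(x)
}

# Decoder scales with a segmentation head: all scales except the two lowest.
head_scales <- function(config) {
  hs <- 0:max(0L, config$n_scales - 3L)
  if (!config$deep_supervision) hs <- 0L
  hs
}

gn_groups_for <- function(C) {
  max(Filter(function(g) C %% g == 0L, seq_len(min(8L, C))))
}

#' Per-component parameter breakdown of a network configuration
#'
#' Exact trainable-parameter count of every component (convolution weights
#' and biases, group-norm affine scale/shift, attention modules split into
#' their convolution chain and their internal group norm), computed
#' analytically from the configuration. Summing the `params` column gives
#' [count_network_params()].
#'
#' @param config An [network_config()].
#' @return A `data.frame` with columns `component` and `params`.
#' @export
network_param_breakdown <- function(config) {
  stopifnot(inherits(config, "lka_net_config"))
  ch <- as.numeric(config$channels)
  S <- config$n_scales
  conv_n <- function(cin, cout, k) cin * cout * k^3 + cout
  rows <- list()
  add <- function(name, n) rows[[length(rows) + 1L]] <<- data.frame(
    component = name, params = n)
  add("enc0.conv1", conv_n(config$in_channels, ch[1], 3))
  add("enc0.gn1", 2 * ch[1])
  add("enc0.conv2", conv_n(ch[1], ch[1], 3))
  add("enc0.gn2", 2 * ch[1])
  for (s in seq_len(S - 1L)) {
    add(sprintf("down%d.conv", s), conv_n(ch[s], ch[s + 1], 3))
    add(sprintf("down%d.gn", s), 2 * ch[s + 1])
    add(sprintf("enc%d.conv1", s), conv_n(ch[s + 1], ch[s + 1], 3))
    add(sprintf("enc%d.gn1", s), 2 * ch[s + 1])
    add(sprintf("enc%d.conv2", s), conv_n(ch[s + 1], ch[s + 1], 3))
    add(sprintf("enc%d.gn2", s), 2 * ch[s + 1])
  }
  att_by_scale <- stats::setNames(
    config$attention,
    vapply(config$attention, function(p) as.character(p$scale), character(1)))
  for (s in if (S >= 2L) (S - 2L):0L else integer(0)) {
    add(sprintf("up%d", s), conv_n(ch[s + 2], ch[s + 1], 4))
    p <- att_by_scale[[as.character(s)]]
    if (!is.null(p)) {
      add(sprintf("att%d.conv", s), count_decomposed_params(ch[s + 1], p$K, p$d))
      add(sprintf("att%d.gn", s), 2 * ch[s + 1])
    }
    add(sprintf("dec%d.conv1", s), conv_n(2 * ch[s + 1], ch[s + 1], 3))
    add(sprintf("dec%d.gn1", s), 2 * ch[s + 1])
    add(sprintf("dec%d.conv2", s), conv_n(ch[s + 1], ch[s + 1], 3))
    add(sprintf("dec%d.gn2", s), 2 * ch[s + 1])
  }
  for (s in head_scales(config)) {
    add(sprintf("head%d", s), conv_n(ch[s + 1], config$out_channels, 1))
  }
  do.call(rbind, rows)
}

#' Total trainable parameters of a network or configuration
#'
#' For a configuration the count is analytic (see
#' [network_param_breakdown()]); for an instantiated network it is the sum of
#' the lengths of all weight arrays — the two agree by construction.
#'
#' @param x An [network_config()] or a [build_network()] result.
#' @param conv_only_attention Count only the convolution parameters of
#'   attention modules, excluding their internal group-norm affine pairs.
#'   The conv-only difference between an attention variant and the Base
#'   network is exactly the sum of [count_decomposed_params()] over the
#'   placements.
#' @return Integer-valued total.
#' @export
count_network_params <- function(x, conv_only_attention = FALSE) {
  bd <- if (inherits(x, "lka_net_config")) network_param_breakdown(x)
        else if (inherits(x, "lka_net")) x$breakdown
        else stop("x must be an lka_net_config or lka_net", call. = FALSE)
  if (conv_only_attention) bd <- bd[!grepl("^att[0-9]+\\.gn$", bd$component), ]
  sum(bd$params)
}

#' Instantiate a 3D LK attention U-Net
#'
#' Builds all weight arrays for the configured network with deterministic
#' He fan-in initialization (biases zero, group-norm scale one / shift zero)
#' under the given seed, and records the per-component parameter breakdown.
#'
#' @param config An [network_config()].
#' @param seed Integer seed for the initialization.
#' @return An object of class `lka_net` holding the flat named parameter list
#'   (`$params`), the attention module skeletons and the breakdown table.
#' @export
build_network <- function(config, seed = 0L) {
  stopifnot(inherits(config, "lka_net_config"))
  ch <- config$channels
  S <- config$n_scales
  params <- list()
  with_seed(seed, {
    conv_init <- function(cin, cout, k) {
      list(w = he_init(c(cout, cin, k, k, k), cin * k^3), b = numeric(cout))
    }
    add_conv <- function(name, cin, cout, k) {
      p <- conv_init(cin, cout, k)
      params[[paste0(name, ".w")]] <<- p$w
      params[[paste0(name, ".b")]] <<- p$b
    }
    add_gn <- function(name, C) {
      params[[paste0(name, ".gamma")]] <<- rep(1, C)
      params[[paste0(name, ".beta")]] <<- numeric(C)
    }
    add_conv("enc0.conv1", config$in_channels, ch[1], 3L); add_gn("enc0.gn1", ch[1])
    add_conv("enc0.conv2", ch[1], ch[1], 3L); add_gn("enc0.gn2", ch[1])
    for (s in seq_len(S - 1L)) {
      add_conv(sprintf("down%d.conv", s), ch[s], ch[s + 1], 3L)
      add_gn(sprintf("down%d.gn", s), ch[s + 1])
      add_conv(sprintf("enc%d.conv1", s), ch[s + 1], ch[s + 1], 3L)
      add_gn(sprintf("enc%d.gn1", s), ch[s + 1])
      add_conv(sprintf("enc%d.conv2", s), ch[s + 1], ch[s + 1], 3L)
      add_gn(sprintf("enc%d.gn2", s), ch[s + 1])
    }
    for (s in if (S >= 2L) (S - 2L):0L else integer(0)) {
      # transposed conv weights: (Cin, Cout, 4, 4, 4)
      params[[sprintf("up%d.w", s)]] <- he_init(c(ch[s + 2], ch[s + 1], 4L, 4L, 4L),
                                                ch[s + 2] * 64)
      params[[sprintf("up%d.b", s)]] <- numeric(ch[s + 1])
      add_conv(sprintf("dec%d.conv1", s), 2L * ch[s + 1], ch[s + 1], 3L)
      add_gn(sprintf("dec%d.gn1", s), ch[s + 1])
      add_conv(sprintf("dec%d.conv2", s), ch[s + 1], ch[s + 1], 3L)
      add_gn(sprintf("dec%d.gn2", s), ch[s + 1])
    }
    for (s in head_scales(config)) {
      add_conv(sprintf("head%d", s), ch[s + 1], config$out_channels, 1L)
    }
  })
  attention <- list()
  for (i in seq_along(config$attention)) {
    p <- config$attention[[i]]
    mod <- build_lk_attention(ch[p$scale + 1L], p$K, p$d,
                              seed = seed + 1000L + p$scale)
    pre <- sprintf("att%d.", p$scale)
    for (nm in names(mod$params)) params[[paste0(pre, nm)]] <- mod$params[[nm]]
    mod$params <- NULL
    attention[[as.character(p$scale)]] <- mod
  }
  net <- structure(list(
    config = config, channels = ch, params = params, attention = attention,
    breakdown = network_param_breakdown(config), seed = seed
  ), class = "lka_net")
  stopifnot(sum(vapply(params, length, numeric(1))) ==
              count_network_params(config))
  net
}

#' @export
print.lka_net <- function(x, ...) {
  print(x$config)
  cat(sprintf("  total trainable parameters: %s\n",
              format_param_count(count_network_params(x))))
  invisible(x)
}

# Attention module view with parameters bound from the network's flat list.
att_module_view <- function(net, s) {
  mod <- net$attention[[as.character(s)]]
  pre <- sprintf("att%d.", s)
  mod$params <- list(
    dw_w = net$params[[paste0(pre, "dw_w")]],
    dw_b = net$params[[paste0(pre, "dw_b")]],
    dwd_w = net$params[[paste0(pre, "dwd_w")]],
    dwd_b = net$params[[paste0(pre, "dwd_b")]],
    pw_w = net$params[[paste0(pre, "pw_w")]],
    pw_b = net$params[[paste0(pre, "pw_b")]],
    gn_gamma = net$params[[paste0(pre, "gn_gamma")]],
    gn_beta = net$params[[paste0(pre, "gn_beta")]]
  )
  mod
}

# conv -> GN -> lReLU unit.
unit_fwd <- function(net, name_conv, name_gn, x, stride = 1L, pad = 1L,
                     keep_cache = FALSE) {
  p <- net$params
  C <- length(p[[paste0(name_conv, ".b")]])
  y <- conv3d_fwd(x, p[[paste0(name_conv, ".w")]], p[[paste0(name_conv, ".b")]],
                  stride, pad)
  gn <- gn_fwd(y, p[[paste0(name_gn, ".gamma")]], p[[paste0(name_gn, ".beta")]],
               gn_groups_for(C))
  out <- lrelu_fwd(gn$y, 0.01)
  if (keep_cache) list(out = out, cache = list(x = x, conv = y, gn = gn,
                                               stride = stride, pad = pad))
  else list(out = out)
}

unit_bwd <- function(net, name_conv, name_gn, cache, dout, grads) {
  p <- net$params
  dgn_y <- lrelu_bwd(cache$gn$y, dout, 0.01)
  gb <- gn_bwd(cache$gn, p[[paste0(name_gn, ".gamma")]], dgn_y)
  grads[[paste0(name_gn, ".gamma")]] <- gb$dgamma
  grads[[paste0(name_gn, ".beta")]] <- gb$dbeta
  cb <- conv3d_bwd(cache$x, p[[paste0(name_conv, ".w")]], gb$dx,
                   cache$stride, cache$pad)
  grads[[paste0(name_conv, ".w")]] <- cb$dw
  grads[[paste0(name_conv, ".b")]] <- cb$db
  list(dx = cb$dx, grads = grads)
}

concat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1] + db[1], da[2:4]))
  out[seq_len(da[1]), , , ] <- a
  out[da[1] + seq_len(db[1]), , , ] <- b
  out
}

# Single-sample forward on a (C, D, H, W) array.
network_fwd_core <- function(net, x, keep_cache = FALSE) {
  config <- net$config
  S <- config$n_scales
  if (dim(x)[1] != config$in_channels) {
    stop("channel mismatch: network expects ", config$in_channels,
         " input channels, got ", dim(x)[1], call. = FALSE)
  }
  div <- 2L^(S - 1L)
  if (any(dim(x)[2:4] %% div != 0L)) {
    stop("spatial dimensions ", paste(dim(x)[2:4], collapse = "x"),
         " must be divisible by ", div, call. = FALSE)
  }
  cache <- if (keep_cache) list(units = list(), att = list()) else NULL
  keep <- keep_cache
  skips <- vector("list", S)
  u1 <- unit_fwd(net, "enc0.conv1", "enc0.gn1", x, keep_cache = keep)
  if (keep) cache$units[["enc0.1"]] <- u1$cache
  u2 <- unit_fwd(net, "enc0.conv2", "enc0.gn2", u1$out, keep_cache = keep)
  if (keep) cache$units[["enc0.2"]] <- u2$cache
  skips[[1]] <- u2$out
  h <- u2$out
  for (s in seq_len(S - 1L)) {
    d <- unit_fwd(net, sprintf("down%d.conv", s), sprintf("down%d.gn", s), h,
                  stride = 2L, keep_cache = keep)
    if (keep) cache$units[[sprintf("down%d", s)]] <- d$cache
    u1 <- unit_fwd(net, sprintf("enc%d.conv1", s), sprintf("enc%d.gn1", s),
                   d$out, keep_cache = keep)
    if (keep) cache$units[[sprintf("enc%d.1", s)]] <- u1$cache
    u2 <- unit_fwd(net, sprintf("enc%d.conv2", s), sprintf("enc%d.gn2", s),
                   u1$out, keep_cache = keep)
    if (keep) cache$units[[sprintf("enc%d.2", s)]] <- u2$cache
    skips[[s + 1L]] <- u2$out
    h <- u2$out
  }
  attention_maps <- list()
  dec_out <- vector("list", max(1L, S - 1L))  # dec_out[[s+1]] at scale s
  if (S == 1L) dec_out[[1L]] <- h
  for (s in if (S >= 2L) (S - 2L):0L else integer(0)) {
    upname <- sprintf("up%d", s)
    u <- convt3d_fwd(h, net$params[[paste0(upname, ".w")]],
                     net$params[[paste0(upname, ".b")]])
    if (keep) cache$units[[upname]] <- list(x = h, out_dim = dim(u))
    skey <- as.character(s)
    if (!is.null(net$attention[[skey]])) {
      mod <- att_module_view(net, s)
      r <- attention_fwd_core(mod, u, keep_cache = keep)
      if (keep) cache$att[[skey]] <- r$cache
      attention_maps[[skey]] <- r$attention_map
      u <- r$output
    }
    cc <- concat_channels(u, skips[[s + 1L]])
    u1 <- unit_fwd(net, sprintf("dec%d.conv1", s), sprintf("dec%d.gn1", s), cc,
                   keep_cache = keep)
    if (keep) cache$units[[sprintf("dec%d.1", s)]] <- u1$cache
    u2 <- unit_fwd(net, sprintf("dec%d.conv2", s), sprintf("dec%d.gn2", s),
                   u1$out, keep_cache = keep)
    if (keep) cache$units[[sprintf("dec%d.2", s)]] <- u2$cache
    dec_out[[s + 1L]] <- u2$out
    h <- u2$out
  }
  logits <- list()
  for (s in head_scales(config)) {
    hn <- sprintf("head%d", s)
    logits[[as.character(s)]] <- conv3d_fwd(dec_out[[s + 1L]],
                                            net$params[[paste0(hn, ".w")]],
                                            net$params[[paste0(hn, ".b")]],
                                            1L, 0L)
  }
  out <- list(main = logits[["0"]],
              aux = logits[setdiff(names(logits), "0")],
              attention_maps = attention_maps)
  if (keep) {
    cache$dec_out <- dec_out
    out$cache <- cache
  }
  out
}

# Backward through the whole network. dlogits is a named list keyed by head
# scale ("0", "1", ...) with gradients wrt the head logits. Returns the flat
# named gradient list (same names as net$params).
network_bwd_core <- function(net, cache, dlogits) {
  config <- net$config
  S <- config$n_scales
  grads <- list()
  d_dec <- vector("list", S - 1L)
  for (s in head_scales(config)) {
    skey <- as.character(s)
    if (is.null(dlogits[[skey]])) next
    hn <- sprintf("head%d", s)
    cb <- conv3d_bwd(cache$dec_out[[s + 1L]], net$params[[paste0(hn, ".w")]],
                     dlogits[[skey]], 1L, 0L)
    grads[[paste0(hn, ".w")]] <- cb$dw
    grads[[paste0(hn, ".b")]] <- cb$db
    d_dec[[s + 1L]] <- cb$dx
  }
  d_skip <- vector("list", S)
  if (S == 1L) d_skip[[1L]] <- d_dec[[1L]]
  for (s in if (S >= 2L) 0:(S - 2L) else integer(0)) {
    dh <- d_dec[[s + 1L]]
    if (is.null(dh)) dh <- array(0, dim(cache$dec_out[[s + 1L]]))
    b2 <- unit_bwd(net, sprintf("dec%d.conv2", s), sprintf("dec%d.gn2", s),
                   cache$units[[sprintf("dec%d.2", s)]], dh, grads)
    grads <- b2$grads
    b1 <- unit_bwd(net, sprintf("dec%d.conv1", s), sprintf("dec%d.gn1", s),
                   cache$units[[sprintf("dec%d.1", s)]], b2$dx, grads)
    grads <- b1$grads
    C <- config$channels[s + 1L]
    dcc <- b1$dx
    du <- array(dcc[seq_len(C), , , ], c(C, dim(dcc)[2:4]))
    d_skip[[s + 1L]] <- array(dcc[C + seq_len(C), , , ], c(C, dim(dcc)[2:4]))
    skey <- as.character(s)
    if (!is.null(net$attention[[skey]])) {
      mod <- att_module_view(net, s)
      ab <- attention_bwd_core(mod, cache$att[[skey]], du)
      pre <- sprintf("att%d.", s)
      for (nm in names(ab$grads)) grads[[paste0(pre, nm)]] <- ab$grads[[nm]]
      du <- ab$dx
    }
    upname <- sprintf("up%d", s)
    ub <- convt3d_bwd(cache$units[[upname]]$x, net$params[[paste0(upname, ".w")]],
                      du)
    grads[[paste0(upname, ".w")]] <- ub$dw
    grads[[paste0(upname, ".b")]] <- ub$db
    if (s == S - 2L) {
      d_skip[[S]] <- ub$dx
    } else {
      d_dec[[s + 2L]] <- if (is.null(d_dec[[s + 2L]])) ub$dx
                         else d_dec[[s + 2L]] + ub$dx
    }
  }
  dh <- d_skip[[S]]
  for (s in if (S >= 2L) (S - 1L):1L else integer(0)) {
    b2 <- unit_bwd(net, sprintf("enc%d.conv2", s), sprintf("enc%d.gn2", s),
                   cache$units[[sprintf("enc%d.2", s)]], dh, grads)
    grads <- b2$grads
    b1 <- unit_bwd(net, sprintf("enc%d.conv1", s), sprintf("enc%d.gn1", s),
                   cache$units[[sprintf("enc%d.1", s)]], b2$dx, grads)
    grads <- b1$grads
    db <- unit_bwd(net, sprintf("down%d.conv", s), sprintf("down%d.gn", s),
                   cache$units[[sprintf("down%d", s)]], b1$dx, grads)
    grads <- db$grads
    dh <- db$dx + d_skip[[s]]
  }
  b2 <- unit_bwd(net, "enc0.conv2", "enc0.gn2", cache$units[["enc0.2"]], dh, grads)
  grads <- b2$grads
  b1 <- unit_bwd(net, "enc0.conv1", "enc0.gn1", cache$units[["enc0.1"]],
                 b2$dx, grads)
  b1$grads
}

#' Forward pass of the LK attention U-Net
#'
#' @param net A [build_network()] result.
#' @param x Input volume: a `(C, D, H, W)` array or a `(batch, C, D, H, W)`
#'   array with `C` equal to the configured input channels and spatial
#'   dimensions divisible by `2^(n_scales - 1)`.
#' @return A list with `main` (logits at full resolution, class channel
#'   first), `aux` (named list of auxiliary deep-supervision logits at coarser
#'   scales) and `attention_maps` (named by decoder scale; present only for
#'   scales carrying an attention module). No activation is applied; see
#'   [predict_volumes()] for probabilities and label maps.
#' @export
network_forward <- function(net, x) {
  stopifnot(inherits(net, "lka_net"))
  d <- dim(x)
  if (is.null(d) || !(length(d) %in% c(4L, 5L))) {
    stop("x must be a (C, D, H, W) or (batch, C, D, H, W) array", call. = FALSE)
  }
  if (length(d) == 4L) return(network_fwd_core(net, x))
  per <- lapply(seq_len(d[1]), function(b) {
    network_fwd_core(net, array(x[b, , , , ], d[-1]))
  })
  stack <- function(get) {
    pieces <- lapply(per, get)
    out <- array(0, c(d[1], dim(pieces[[1]])))
    for (b in seq_len(d[1])) out[b, , , , ] <- pieces[[b]]
    out
  }
  aux_names <- names(per[[1]]$aux)
  att_names <- names(per[[1]]$attention_maps)
  list(
    main = stack(function(r) r$main),
    aux = stats::setNames(lapply(aux_names, function(nm) {
      stack(function(r) r$aux[[nm]])
    }), aux_names),
    attention_maps = stats::setNames(lapply(att_names, function(nm) {
      stack(function(r) r$attention_maps[[nm]])
    }), att_names)
  )
}
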