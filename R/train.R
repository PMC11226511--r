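#' Training configuration
#'
#' Defaults follow the reference optimization recipe: Adam with initial
#' learning rate 3e-4, 200 epochs at batch size 1, and a polynomial
#' learning-rate decay of power 0.9 (a constant-rate switch is provided).
#'
#' @param epochs Number of passes over the training samples.
#' @param lr Initial learning rate.
#' @param loss `"weighted_dice"` (softmax heads, background excluded from the
#'   loss classes, dataset-level class weights) or `"bce_dice"` (sigmoid
#'   region heads).
#' @param lr_schedule `"poly"` (`lr * (1 - t/T)^0.9`) or `"constant"`.
#' @param betas,adam_eps Adam moment decays and epsilon.
#' @param max_steps Optional hard cap on optimizer steps (overrides epochs
#'   when reached first).
#' @param stop_dice Optional early-stopping target: training halts once the
#'   monitored mean foreground Dice on the training samples reaches this
#'   value (checked every `monitor_every` steps).
#' @param monitor_every Interval (steps) for Dice monitoring; 0 disables it.
#' @param augmentation_policy Policy applied to each sample draw
#'   ([no_augmentation()] to disable).
#' @param grad_clip Optional global gradient-norm clip.
#' @param seed Seed controlling initialization, data order and augmentation.
#' @param log_path Optional CSV path for the step log.
#' @return An object of class `lka_train_config`.
#' @export
train_config <- function(epochs = 200L, lr = 3e-4,
                         loss = c("weighted_dice", "bce_dice"),
                         lr_schedule = c("poly", "constant"),
                         betas = c(0.9, 0.999), adam_eps = 1e-8,
                         max_steps = NULL, stop_dice = NULL,
                         monitor_every = 10L,
                         augmentation_policy = no_augmentation(),
                         grad_clip = NULL, seed = 0L, log_path = NULL) {
  structure(list(epochs = as.integer(epochs), batch_size = 1L, lr = lr,
                 loss = match.arg(loss), lr_schedule = match.arg(lr_schedule),
                 poly_power = 0.9, betas = betas, adam_eps = adam_eps,
                 max_steps = max_steps, stop_dice = stop_dice,
                 monitor_every = as.integer(monitor_every),
                 augmentation_policy = augmentation_policy,
                 grad_clip = grad_clip, seed = as.integer(seed),
                 log_path = log_path),
            class = "lka_train_config")
}

adam_init <- function(params) {
  # p * 0 keeps each parameter's exact structure (vector vs array)
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_step <- function(params, grads, state, lr, betas, eps) {
  state$t <- state$t + 1L
  b1 <- betas[1]; b2 <- betas[2]
  corr1 <- 1 - b1^state$t
  corr2 <- 1 - b2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    dim(g) <- dim(state$m[[nm]])
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / corr1) / (sqrt(state$v[[nm]] / corr2) + eps)
  }
  list(params = params, state = state)
}

grad_global_norm <- function(grads) {
  sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
}

# Build per-head targets and return loss + gradients wrt all head logits.
supervised_loss <- function(net, fwd, label, weights, loss_type) {
  config <- net$config
  hs <- head_scales(config)
  wts <- deep_supervision_weights(hs)
  total <- 0
  dlogits <- list()
  for (s in hs) {
    skey <- as.character(s)
    logits <- if (s == 0L) fwd$main else fwd$aux[[skey]]
    lab <- downsample_label(label, s)
    w <- wts[[skey]]
    if (loss_type == "weighted_dice") {
      target <- one_hot(lab, config$out_channels)
      probs <- softmax_channels(logits)
      fg <- seq(2L, config$out_channels)
      l <- soft_dice_loss(probs, target, weights = weights, classes = fg)
      dp <- soft_dice_loss_grad(probs, target, weights = weights, classes = fg)
      # softmax jacobian: dl_i = p_i * (dp_i - sum_j dp_j p_j)
      pm <- matrix(probs, nrow = config$out_channels)
      dpm <- matrix(dp, nrow = config$out_channels)
      dlm <- pm * (dpm - rep(colSums(dpm * pm), each = config$out_channels))
      dim(dlm) <- dim(logits)
    } else {
      target <- array(0, c(config$out_channels, dim(lab)))
      for (c in seq_len(config$out_channels)) target[c, , , ] <- lab == c
      probs <- sigmoid(logits)
      l <- bce_dice_loss(probs, target)
      dp <- bce_dice_loss_grad(probs, target)
      dlm <- dp * probs * (1 - probs)
    }
    total <- total + w * l
    dlogits[[skey]] <- w * dlm
  }
  list(loss = total, dlogits = dlogits)
}

monitor_dice <- function(net, samples, loss_type) {
  scores <- vapply(samples, function(s) {
    pred <- predict_sample(net, s)$label
    if (loss_type == "weighted_dice") {
      cls <- seq_len(net$config$out_channels - 1L)
      mean(vapply(cls, function(c) dice_score(pred == c, s$label == c),
                  numeric(1)))
    } else {
      mean(vapply(seq_len(net$config$out_channels), function(c) {
        dice_score(pred[[c]], s$label == c)
      }, numeric(1)))
    }
  }, numeric(1))
  mean(scores)
}

#' Train an LK attention U-Net
#'
#' Runs Adam over the given samples (batch size 1) with deep-supervision
#' losses at every head scale, geometric head weights normalized to sum 1,
#' and optional on-the-fly augmentation. Fully seeded: initialization, data
#' order and augmentation draws all derive from `config$seed`, so two runs
#' with the same seed produce identical logs.
#'
#' @param net_config An [network_config()] (or an already built
#'   [build_network()] to fine-tune).
#' @param samples List of [volume_sample()] objects with labels.
#' @param config An [train_config()].
#' @return An object of class `lka_fit` with the trained `net`, the step
#'   `log` data frame (epoch, step, loss, lr, monitored Dice) and the class
#'   weights used.
#' @export
train <- function(net_config, samples, config = train_config()) {
  stopifnot(inherits(config, "lka_train_config"), length(samples) >= 1L)
  net <- if (inherits(net_config, "lka_net")) net_config
         else build_network(net_config, seed = config$seed)
  O <- net$config$out_channels
  weights <- NULL
  if (config$loss == "weighted_dice") {
    weights <- class_weights_from_labels(lapply(samples, `[[`, "label"), O)
  }
  opt <- adam_init(net$params)
  total_steps <- config$epochs * length(samples)
  if (!is.null(config$max_steps)) total_steps <- min(total_steps, config$max_steps)
  log <- list()
  step <- 0L
  stopped <- FALSE
  with_seed(config$seed + 1L, {
    for (epoch in seq_len(config$epochs)) {
      if (stopped || step >= total_steps) break
      order_idx <- sample(length(samples))
      for (i in order_idx) {
        if (step >= total_steps) break
        step <- step + 1L
        s <- samples[[i]]
        s <- augment(s, config$augmentation_policy)
        lr <- if (config$lr_schedule == "poly") {
          config$lr * (1 - (step - 1) / total_steps)^config$poly_power
        } else config$lr
        x <- s$image
        fwd <- network_fwd_core(net, x, keep_cache = TRUE)
        sl <- supervised_loss(net, fwd, s$label, weights, config$loss)
        if (!is.finite(sl$loss)) {
          stop("non-finite loss at epoch ", epoch, ", step ", step,
               " (sample '", s$id, "'): ", sl$loss, call. = FALSE)
        }
        grads <- network_bwd_core(net, fwd$cache, sl$dlogits)
        if (!is.null(config$grad_clip)) {
          gn <- grad_global_norm(grads)
          if (gn > config$grad_clip) {
            grads <- lapply(grads, function(g) g * (config$grad_clip / gn))
          }
        }
        upd <- adam_step(net$params, grads, opt, lr, config$betas,
                         config$adam_eps)
        net$params <- upd$params
        opt <- upd$state
        mon <- NA_real_
        if (config$monitor_every > 0L && step %% config$monitor_every == 0L) {
          mon <- monitor_dice(net, samples, config$loss)
          if (!is.null(config$stop_dice) && mon >= config$stop_dice) {
            stopped <- TRUE
          }
        }
        log[[step]] <- data.frame(epoch = epoch, step = step, sample = s$id,
                                  loss = sl$loss, lr = lr, dice = mon,
                                  seed = config$seed)
        if (stopped) break
      }
    }
  })
  log <- do.call(rbind, log)
  if (!is.null(config$log_path)) utils::write.csv(log, config$log_path,
                                                  row.names = FALSE)
  structure(list(net = net, config = config, log = log,
                 class_weights = weights),
            class = "lka_fit")
}

#' @export
print.lka_fit <- function(x, ...) {
  cat(sprintf("Trained LK attention U-Net: %d steps, final loss %.4f\n",
              nrow(x$log), x$log$loss[nrow(x$log)]))
  mon <- x$log$dice[!is.na(x$log$dice)]
  if (length(mon)) cat(sprintf("  last monitored mean foreground Dice: %.3f\n",
                               mon[length(mon)]))
  print(x$net)
  invisible(x)
}

# Predict a single preprocessed sample: pad to a divisible grid, forward,
# activate, restore the original grid.
predict_sample <- function(net, sample, return_attention = FALSE) {
  config <- net$config
  div <- 2L^(config$n_scales - 1L)
  d <- dim(sample$image)[2:4]
  target <- as.integer(ceiling(d / div) * div)
  padded <- if (all(target == d)) sample else crop_or_pad(sample, target)
  fwd <- network_fwd_core(net, padded$image)
  out <- list()
  if (config$head_activation == "softmax") {
    probs <- softmax_channels(fwd$main)
    lab <- array(max.col(t(matrix(probs, nrow = config$out_channels)),
                         ties.method = "first") - 1L,
                 dim(fwd$main)[2:4])
    if (!all(target == d)) lab <- restore_to_original(lab, padded$meta$crop)
    out$label <- lab
  } else {
    probs <- sigmoid(fwd$main)
    masks <- lapply(seq_len(config$out_channels), function(c) {
      m <- array(probs[c, , , ] >= 0.5, dim(fwd$main)[2:4])
      if (!all(target == d)) {
        m <- restore_to_original(m * 1L, padded$meta$crop) > 0
      }
      m
    })
    out$label <- masks
  }
  if (return_attention) out$attention_maps <- fwd$attention_maps
  out
}

#' Predict label volumes (and optional attention maps)
#'
#' Applies the network to each sample (spatial dims are zero-padded up to the
#' required divisibility and the prediction mapped back), then argmax over
#' softmax classes or a 0.5 threshold on per-channel sigmoids. Input samples
#' are never mutated.
#'
#' @param fit An [train()] result, [build_network()] network or checkpoint
#'   path.
#' @param samples List of [volume_sample()] objects.
#' @param save_attention Optional directory: per-scale attention maps are
#'   written as NIfTI volumes aligned to the input grid (mean over channels,
#'   nearest-neighbour upsampling of coarse maps).
#' @return List with one element per sample: `label` (integer array for
#'   softmax, list of binary masks for sigmoid) and `attention_maps`.
#' @export
predict_volumes <- function(fit, samples, save_attention = NULL) {
  net <- if (inherits(fit, "lka_fit")) fit$net
         else if (inherits(fit, "lka_net")) fit
         else load_checkpoint(fit)
  if (inherits(samples, "lka_volume")) samples <- list(samples)
  if (!is.null(save_attention)) {
    dir.create(save_attention, showWarnings = FALSE, recursive = TRUE)
  }
  lapply(samples, function(s) {
    r <- predict_sample(net, s, return_attention = !is.null(save_attention))
    if (!is.null(save_attention) && length(r$attention_maps)) {
      for (skey in names(r$attention_maps)) {
        a <- r$attention_maps[[skey]]
        mean_map <- apply(a, c(2, 3, 4), mean)
        up <- upsample_nearest(mean_map, dim(s$image)[2:4])
        out <- volume_sample(up, spacing = s$spacing, id = s$id, meta = s$meta)
        write_volume(out, file.path(save_attention,
                                    sprintf("%s_attention_scale%s.nii.gz",
                                            s$id, skey)))
      }
    }
    r[c("label", "attention_maps")]
  })
}

#' @export
predict.lka_fit <- function(object, samples, ...) {
  predict_volumes(object, samples, ...)
}

# Nearest-neighbour upsampling of a 3-D array to target dims.
upsample_nearest <- function(vol, target) {
  d <- dim(vol)
  ax <- lapply(1:3, function(a) (seq_len(target[a]) - 0.5) * d[a] / target[a] - 0.5)
  grid <- expand.grid(z = ax[[1]], y = ax[[2]], x = ax[[3]])
  array(sample_channel(vol, grid$z, grid$y, grid$x, "nearest"), target)
}

#' Save / load a network checkpoint
#'
#' The checkpoint is a versioned list holding the network configuration, the
#' flat parameter list and the initialization seed.
#'
#' @param x An [lka_fit][train()] or [build_network()] network.
#' @param path Checkpoint file path (RDS).
#' @export
save_checkpoint <- function(x, path) {
  net <- if (inherits(x, "lka_fit")) x$net else x
  stopifnot(inherits(net, "lka_net"))
  saveRDS(list(format = "lka3d-checkpoint", version = 1L,
               config = net$config, params = net$params, seed = net$seed),
          path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @return `load_checkpoint` returns the reconstructed `lka_net`.
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (!identical(ck$format, "lka3d-checkpoint")) {
    stop("not an lka3d checkpoint: ", path, call. = FALSE)
  }
  net <- build_network(ck$config, seed = ck$seed)
  stopifnot(identical(sort(names(net$params)), sort(names(ck$params))))
  net$params <- ck$params
  net
}
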