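# Training losses. Probabilities and targets are arrays with the class
# channel first: (O, D, H, W) for one sample or (batch, O, D, H, W). All
# losses are differentiable in the probabilities; *_grad returns the exact
# analytic gradient used by the training loop.

flatten_class_first <- function(x) {
  d <- dim(x)
  if (length(d) == 4L) {
    matrix(x, nrow = d[1])
  } else if (length(d) == 5L) {
    matrix(aperm(x, c(2L, 1L, 3L, 4L, 5L)), nrow = d[2])
  } else stop("expected a 4-D or 5-D class-first array", call. = FALSE)
}

#' One-hot encoding of an integer label volume
#'
#' @param label 3-D integer array with values in `0:(n_classes-1)`.
#' @param n_classes Number of classes including background.
#' @return A `(n_classes, D, H, W)` array of 0/1 values.
#' @export
one_hot <- function(label, n_classes) {
  d <- dim(label)
  out <- array(0, c(n_classes, d))
  lm <- as.integer(label)
  idx <- (lm + 1L) + n_classes * (seq_along(lm) - 1L)
  out[idx] <- 1
  out
}

soft_dice_per_class <- function(pm, tm, eps = 1e-5) {
  num <- 2 * rowSums(pm * tm) + eps
  den <- rowSums(pm) + rowSums(tm) + eps
  num / den
}

#' Weighted soft Dice loss
#'
#' `1 - sum_c w_c * softDice_c / sum_c w_c` where
#' `softDice_c = (2 * sum(p*t) + eps) / (sum(p) + sum(t) + eps)`. With
#' `weights = NULL` all classes are weighted equally. For multi-organ
#' training the background channel is excluded via `classes`.
#'
#' @param probs Class-first probability array in `[0, 1]`.
#' @param target One-hot array of the same shape.
#' @param weights Per-class weights aligned with `classes` (see
#'   [class_weights_from_labels()]); `NULL` for uniform.
#' @param classes Integer vector of class-channel indices entering the loss
#'   (default: all channels).
#' @param eps Smoothing constant (default `1e-5`).
#' @return Non-negative scalar loss.
#' @export
soft_dice_loss <- function(probs, target, weights = NULL, classes = NULL,
                           eps = 1e-5) {
  pm <- flatten_class_first(probs)
  tm <- flatten_class_first(target)
  if (!all(dim(pm) == dim(tm))) stop("probs/target shape mismatch", call. = FALSE)
  if (is.null(classes)) classes <- seq_len(nrow(pm))
  if (is.null(weights)) weights <- rep(1, length(classes))
  if (length(weights) != length(classes)) {
    stop("need one weight per loss class (", length(classes), "), got ",
         length(weights), call. = FALSE)
  }
  sdc <- soft_dice_per_class(pm[classes, , drop = FALSE],
                             tm[classes, , drop = FALSE], eps)
  1 - sum(weights * sdc) / sum(weights)
}

# Gradient of soft_dice_loss wrt probs (same shape as probs).
soft_dice_loss_grad <- function(probs, target, weights = NULL, classes = NULL,
                                eps = 1e-5) {
  d <- dim(probs)
  pm <- flatten_class_first(probs)
  tm <- flatten_class_first(target)
  if (is.null(classes)) classes <- seq_len(nrow(pm))
  if (is.null(weights)) weights <- rep(1, length(classes))
  g <- matrix(0, nrow(pm), ncol(pm))
  wsum <- sum(weights)
  for (i in seq_along(classes)) {
    c <- classes[i]
    num <- 2 * sum(pm[c, ] * tm[c, ]) + eps
    den <- sum(pm[c, ]) + sum(tm[c, ]) + eps
    # d softDice_c / d p = (2 t * den - num) / den^2
    g[c, ] <- -(weights[i] / wsum) * (2 * tm[c, ] * den - num) / den^2
  }
  if (length(d) == 5L) {
    ga <- array(g, c(d[2], d[1], d[3], d[4], d[5]))
    aperm(ga, c(2L, 1L, 3L, 4L, 5L))
  } else {
    dim(g) <- d
    g
  }
}

#' BCE + soft Dice loss for overlapping region channels
#'
#' Sum (1:1 weighting) of the mean binary cross-entropy over all voxels and
#' channels and the unweighted soft Dice loss over the channels. Used with
#' per-channel sigmoid heads (e.g. the three nested tumor regions).
#'
#' @param probs Class-first probability array in `[0, 1]`.
#' @param target Binary array of the same shape (channels may overlap).
#' @param eps Dice smoothing constant.
#' @param clip Probability clipping bound for the BCE logarithms.
#' @return Non-negative scalar loss.
#' @export
bce_dice_loss <- function(probs, target, eps = 1e-5, clip = 1e-7) {
  pm <- flatten_class_first(probs)
  tm <- flatten_class_first(target)
  if (!all(dim(pm) == dim(tm))) stop("probs/target shape mismatch", call. = FALSE)
  pc <- pmin(pmax(pm, clip), 1 - clip)
  bce <- -mean(tm * log(pc) + (1 - tm) * log(1 - pc))
  dice <- 1 - mean(soft_dice_per_class(pm, tm, eps))
  bce + dice
}

bce_dice_loss_grad <- function(probs, target, eps = 1e-5, clip = 1e-7) {
  d <- dim(probs)
  pm <- flatten_class_first(probs)
  tm <- flatten_class_first(target)
  pc <- pmin(pmax(pm, clip), 1 - clip)
  g_bce <- (-tm / pc + (1 - tm) / (1 - pc)) / length(pm)
  inside <- (pm > clip & pm < 1 - clip)
  g_bce[!inside] <- 0
  g_dice <- matrix(0, nrow(pm), ncol(pm))
  for (c in seq_len(nrow(pm))) {
    num <- 2 * sum(pm[c, ] * tm[c, ]) + eps
    den <- sum(pm[c, ]) + sum(tm[c, ]) + eps
    g_dice[c, ] <- -(2 * tm[c, ] * den - num) / den^2 / nrow(pm)
  }
  g <- g_bce + g_dice
  if (length(d) == 5L) {
    ga <- array(g, c(d[2], d[1], d[3], d[4], d[5]))
    aperm(ga, c(2L, 1L, 3L, 4L, 5L))
  } else {
    dim(g) <- d
    g
  }
}

#' Dataset-level class weights for the weighted soft Dice loss
#'
#' The weight of each foreground class is one minus the ratio of its
#' foreground voxel count to the background voxel count, pooled over the
#' whole collection of label volumes and clamped to `[0, 1]`. Rare classes
#' therefore get weights near 1 and classes as abundant as the background get
#' 0.
#'
#' @param labels A single integer label array or a list of them (values
#'   `0:(n_classes-1)`, 0 = background).
#' @param n_classes Number of classes including background.
#' @return Named numeric vector of length `n_classes - 1` (classes
#'   `1:(n_classes-1)`). A class absent from every volume gets weight 1 with
#'   a warning.
#' @export
class_weights_from_labels <- function(labels, n_classes) {
  if (!is.list(labels)) labels <- list(labels)
  n_classes <- check_count(n_classes, "n_classes")
  counts <- numeric(n_classes)
  for (lab in labels) {
    if (any(lab != floor(lab))) stop("labels must be integer-valued", call. = FALSE)
    tab <- tabulate(as.integer(lab) + 1L, nbins = n_classes)
    counts <- counts + tab
  }
  bg <- counts[1]
  w <- numeric(n_classes - 1L)
  for (c in seq_len(n_classes - 1L)) {
    fg <- counts[c + 1L]
    if (fg == 0) {
      warning("class ", c, " is absent from all label volumes; weight set to 1")
      w[c] <- 1
    } else {
      w[c] <- min(max(1 - fg / bg, 0), 1)
    }
  }
  stats::setNames(w, paste0("class", seq_len(n_classes - 1L)))
}

# Downsample an integer label volume by 2^level with nearest-neighbour
# striding (used for deep-supervision targets).
downsample_label <- function(label, level) {
  if (level == 0L) return(label)
  f <- 2L^level
  d <- dim(label)
  label[seq(1L, d[1], by = f), seq(1L, d[2], by = f), seq(1L, d[3], by = f),
        drop = FALSE]
}

# Geometric deep-supervision weights 1, 1/2, 1/4, ... normalized to sum 1,
# keyed by head scale.
deep_supervision_weights <- function(scales) {
  w <- 0.5^scales
  stats::setNames(w / sum(w), as.character(scales))
}
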