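#' On-the-fly augmentation policy
#'
#' Per-transform firing probabilities and parameter ranges. The defaults are
#' the standard policy for this pipeline: multiplicative brightness
#' (p=0.30, U(0.7, 1.3)), contrast about the channel mean (p=0.15,
#' U(0.6, 1.4)), additive Gaussian noise (p=0.15, sigma ~ U(0, 1)), Gaussian
#' blur (p=0.20, kernel sigma ~ U(0.5, 1.5)), gamma on the min-max-normalized
#' intensities (p=0.15, gamma ~ U(0.7, 1.5)), isotropic scaling (p=0.30,
#' U(0.65, 1.6)), rotation (p=0.30, per-axis angles U(-30, 30) degrees),
#' elastic deformation (p=0.30, amplitude alpha ~ U(5, 10) voxels, field
#' smoothing sigma = 3*alpha), and flipping (p=0.50, each axis independently
#' with probability 1/2).
#'
#' Intensity transforms never touch the label volume; spatial transforms are
#' applied identically to image (trilinear) and label (nearest-neighbour).
#'
#' @param brightness,contrast,noise,blur,gamma,scaling,rotation,elastic,flip
#'   Each a list `list(p = probability, range = c(lo, hi))` (flip takes only
#'   `p`). Ranges must be ordered.
#' @return An object of class `lka_aug_policy`.
#' @export
augmentation_policy <- function(
    brightness = list(p = 0.30, range = c(0.7, 1.3)),
    contrast = list(p = 0.15, range = c(0.6, 1.4)),
    noise = list(p = 0.15, range = c(0, 1)),
    blur = list(p = 0.20, range = c(0.5, 1.5)),
    gamma = list(p = 0.15, range = c(0.7, 1.5)),
    scaling = list(p = 0.30, range = c(0.65, 1.6)),
    rotation = list(p = 0.30, range = c(-30, 30)),
    elastic = list(p = 0.30, range = c(5, 10)),
    flip = list(p = 0.50)) {
  pol <- list(brightness = brightness, contrast = contrast, noise = noise,
              blur = blur, gamma = gamma, scaling = scaling,
              rotation = rotation, elastic = elastic, flip = flip)
  for (nm in names(pol)) {
    tr <- pol[[nm]]
    if (is.null(tr$p) || tr$p < 0 || tr$p > 1) {
      stop("probability of '", nm, "' must be in [0, 1]", call. = FALSE)
    }
    if (!is.null(tr$range)) {
      if (length(tr$range) != 2L || tr$range[1] > tr$range[2]) {
        stop("range of '", nm, "' must be an ordered pair", call. = FALSE)
      }
    }
  }
  structure(pol, class = "lka_aug_policy")
}

#' A policy that applies no transform (identity)
#' @return An `lka_aug_policy` with every probability 0.
#' @export
no_augmentation <- function() {
  pol <- augmentation_policy()
  for (nm in names(pol)) pol[[nm]]$p <- 0
  pol
}

# Apply a spatial coordinate mapping to a sample. map(z, y, x) receives the
# 0-based target voxel grid and returns source coordinates.
apply_spatial <- function(sample, map) {
  d <- dim(sample$image)[2:4]
  ax <- lapply(d, function(n) seq_len(n) - 1)
  grid <- expand.grid(z = ax[[1]], y = ax[[2]], x = ax[[3]])
  src <- map(grid$z, grid$y, grid$x)
  C <- dim(sample$image)[1]
  out <- sample
  for (c in seq_len(C)) {
    vol <- array(sample$image[c, , , ], d)
    fill <- min(vol)
    out$image[c, , , ] <- sample_channel(vol, src$z, src$y, src$x, "trilinear",
                                         clamp = FALSE, fill = fill)
  }
  if (!is.null(sample$label)) {
    out$label <- array(sample_channel(sample$label, src$z, src$y, src$x,
                                      "nearest", clamp = FALSE, fill = 0), d)
  }
  out
}

rotation_matrix3 <- function(angles_deg) {
  a <- angles_deg * pi / 180
  cz <- cos(a[1]); sz <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cx <- cos(a[3]); sx <- sin(a[3])
  rz <- matrix(c(1, 0, 0, 0, cz, -sz, 0, sz, cz), 3, byrow = TRUE)
  ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
  rx <- matrix(c(cx, -sx, 0, sx, cx, 0, 0, 0, 1), 3, byrow = TRUE)
  rz %*% ry %*% rx
}

#' Apply the augmentation policy to a sample
#'
#' Transforms are visited in the policy's order; each fires independently
#' with its probability and draws its parameters uniformly from its range.
#' With a seed the draw (and therefore the output) is deterministic.
#'
#' @param sample An [volume_sample()].
#' @param policy An [augmentation_policy()].
#' @param seed Optional integer seed for the random draws.
#' @return The augmented sample.
#' @export
augment <- function(sample, policy = augmentation_policy(), seed = NULL) {
  stopifnot(inherits(sample, "lka_volume"), inherits(policy, "lka_aug_policy"))
  if (!is.null(seed)) return(with_seed(seed, augment(sample, policy)))
  d <- dim(sample$image)[2:4]
  C <- dim(sample$image)[1]
  fires <- function(tr) stats::runif(1) < tr$p
  draw <- function(tr) stats::runif(1, tr$range[1], tr$range[2])

  if (fires(policy$brightness)) {
    sample$image <- sample$image * draw(policy$brightness)
  }
  if (fires(policy$contrast)) {
    f <- draw(policy$contrast)
    for (c in seq_len(C)) {
      m <- mean(sample$image[c, , , ])
      sample$image[c, , , ] <- m + (sample$image[c, , , ] - m) * f
    }
  }
  if (fires(policy$noise)) {
    s <- draw(policy$noise)
    sample$image <- sample$image + stats::rnorm(length(sample$image), sd = s)
  }
  if (fires(policy$blur)) {
    s <- draw(policy$blur)
    for (c in seq_len(C)) {
      sample$image[c, , , ] <- gaussian_blur3(array(sample$image[c, , , ], d), s)
    }
  }
  if (fires(policy$gamma)) {
    g <- draw(policy$gamma)
    for (c in seq_len(C)) {
      v <- sample$image[c, , , ]
      lo <- min(v); hi <- max(v)
      if (hi > lo) {
        sample$image[c, , , ] <- ((v - lo) / (hi - lo))^g * (hi - lo) + lo
      }
    }
  }
  if (fires(policy$scaling)) {
    f <- draw(policy$scaling)
    ctr <- (d - 1) / 2
    sample <- apply_spatial(sample, function(z, y, x) {
      list(z = ctr[1] + (z - ctr[1]) / f,
           y = ctr[2] + (y - ctr[2]) / f,
           x = ctr[3] + (x - ctr[3]) / f)
    })
  }
  if (fires(policy$rotation)) {
    ang <- stats::runif(3, policy$rotation$range[1], policy$rotation$range[2])
    rot <- rotation_matrix3(ang)
    inv <- t(rot)  # rotations are orthogonal
    ctr <- (d - 1) / 2
    sample <- apply_spatial(sample, function(z, y, x) {
      p <- cbind(z - ctr[1], y - ctr[2], x - ctr[3]) %*% t(inv)
      list(z = p[, 1] + ctr[1], y = p[, 2] + ctr[2], x = p[, 3] + ctr[3])
    })
  }
  if (fires(policy$elastic)) {
    alpha <- draw(policy$elastic)
    sig <- 3 * alpha
    field <- lapply(1:3, function(a) {
      u <- gaussian_blur3(array(stats::runif(prod(d), -1, 1), d), sig)
      m <- max(abs(u))
      if (m > 0) u * (alpha / m) else u
    })
    sample <- apply_spatial(sample, function(z, y, x) {
      idx <- 1L + z + d[1] * (y + d[2] * x)
      list(z = z + field[[1]][idx], y = y + field[[2]][idx],
           x = x + field[[3]][idx])
    })
  }
  if (fires(policy$flip)) {
    for (a in 1:3) {
      if (stats::runif(1) < 0.5) {
        idx <- rev(seq_len(d[a]))
        if (a == 1) {
          sample$image <- sample$image[, idx, , , drop = FALSE]
          if (!is.null(sample$label)) sample$label <- sample$label[idx, , , drop = FALSE]
        } else if (a == 2) {
          sample$image <- sample$image[, , idx, , drop = FALSE]
          if (!is.null(sample$label)) sample$label <- sample$label[, idx, , drop = FALSE]
        } else {
          sample$image <- sample$image[, , , idx, drop = FALSE]
          if (!is.null(sample$label)) sample$label <- sample$label[, , idx, drop = FALSE]
        }
      }
    }
  }
  sample
}
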