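test_that("weighted soft Dice loss hits its closed-form values", {
  lab <- array(sample(0:1, 4^3, replace = TRUE), c(4, 4, 4))
  target <- one_hot(lab, 2)
  expect_lt(soft_dice_loss(target, target), 1e-4)        # perfect prediction
  expect_gt(soft_dice_loss(1 - target, target), 0.999)   # inverted prediction
  # uniform 0.5 probabilities on a half-foreground volume:
  # softDice = (2*0.5*F + eps) / (0.5*N + F + eps) with F = N/2
  n <- 4^3
  lab2 <- array(rep(0:1, each = n / 2), c(4, 4, 4))
  probs <- array(0.5, c(2, 4, 4, 4))
  eps <- 1e-5
  want <- 1 - (2 * 0.5 * (n / 2) + eps) / (0.5 * n + n / 2 + eps)
  expect_equal(soft_dice_loss(probs, one_hot(lab2, 2), classes = 2), want)
})

test_that("soft Dice loss decreases along the path toward the target", {
  set.seed(3)
  lab <- array(sample(0:2, 5^3, replace = TRUE), c(5, 5, 5))
  target <- one_hot(lab, 3)
  uniform <- array(1 / 3, dim(target))
  losses <- vapply(seq(0, 1, by = 0.1), function(t) {
    soft_dice_loss((1 - t) * uniform + t * target, target)
  }, numeric(1))
  expect_true(all(diff(losses) < 0))
})

test_that("soft Dice gradient matches finite differences", {
  set.seed(5)
  lab <- array(sample(0:1, 27, replace = TRUE), c(3, 3, 3))
  target <- one_hot(lab, 2)
  probs <- array(runif(length(target), 0.1, 0.9), dim(target))
  w <- c(0.3, 0.9)
  g <- lka3d:::soft_dice_loss_grad(probs, target, weights = w)
  eps <- 1e-6
  for (i in sample(length(probs), 6)) {
    p2 <- probs; p2[i] <- p2[i] + eps
    p3 <- probs; p3[i] <- p3[i] - eps
    fd <- (soft_dice_loss(p2, target, weights = w) -
             soft_dice_loss(p3, target, weights = w)) / (2 * eps)
    expect_equal(g[i], fd, tolerance = 1e-5)
  }
})

test_that("BCE + Dice loss matches an independent recomputation", {
  # probabilities 0.5 everywhere: the BCE term is exactly log 2
  set.seed(4)
  target <- array(sample(0:1, 2 * 27, replace = TRUE), c(2, 3, 3, 3))
  half <- array(0.5, c(2, 3, 3, 3))
  eps <- 1e-5
  sd_c <- vapply(1:2, function(c) {
    p <- half[c, , , ]; t <- target[c, , , ]
    (2 * sum(p * t) + eps) / (sum(p) + sum(t) + eps)
  }, numeric(1))
  expect_equal(bce_dice_loss(half, target), log(2) + 1 - mean(sd_c))
  # perfect clipped probabilities drive the loss to ~0
  expect_lt(bce_dice_loss(target, target), 1e-4)
  # random tensors against a from-scratch oracle
  set.seed(9)
  probs <- array(runif(2 * 27, 0.05, 0.95), c(2, 3, 3, 3))
  bce <- 0
  for (c in 1:2) for (i in 1:3) for (j in 1:3) for (k in 1:3) {
    p <- probs[c, i, j, k]; t <- target[c, i, j, k]
    bce <- bce - (t * log(p) + (1 - t) * log(1 - p))
  }
  bce <- bce / (2 * 27)
  sd_c <- vapply(1:2, function(c) {
    p <- probs[c, , , ]; t <- target[c, , , ]
    (2 * sum(p * t) + eps) / (sum(p) + sum(t) + eps)
  }, numeric(1))
  expect_equal(bce_dice_loss(probs, target), bce + 1 - mean(sd_c),
               tolerance = 1e-10)
  # gradient
  g <- lka3d:::bce_dice_loss_grad(probs, target)
  for (i in sample(length(probs), 5)) {
    p2 <- probs; p2[i] <- p2[i] + 1e-6
    p3 <- probs; p3[i] <- p3[i] - 1e-6
    fd <- (bce_dice_loss(p2, target) - bce_dice_loss(p3, target)) / 2e-6
    expect_equal(g[i], fd, tolerance = 1e-4)
  }
})

test_that("class weights are one minus the foreground/background ratio", {
  lab <- array(0L, c(10, 10, 10))
  lab[1:10, 1:10, 1] <- 1L  # 100 voxels of class 1, 900 background
  w <- class_weights_from_labels(lab, n_classes = 2)
  expect_equal(unname(w), 1 - 100 / 900)
  # class with as many voxels as the background clamps to 0
  lab2 <- array(0L, c(4, 4, 4))
  lab2[1:32] <- 1L
  expect_equal(unname(class_weights_from_labels(lab2, 2)), 0)
  # absent class gets weight 1 with a warning
  expect_warning(w3 <- class_weights_from_labels(lab, n_classes = 3),
                 "absent")
  expect_equal(unname(w3[2]), 1)
  # pooled over a collection of volumes
  wp <- class_weights_from_labels(list(lab, array(0L, c(10, 10, 10))), 2)
  expect_equal(unname(wp), 1 - 100 / 1900)
})

test_that("deep-supervision weights are geometric and normalized", {
  w <- lka3d:::deep_supervision_weights(0:3)
  expect_equal(sum(w), 1)
  expect_equal(unname(w / w[1]), c(1, 1/2, 1/4, 1/8))
  lab <- array(sample(0:1, 8^3, replace = TRUE), c(8, 8, 8))
  expect_identical(dim(lka3d:::downsample_label(lab, 2)), c(2L, 2L, 2L))
  expect_identical(lka3d:::downsample_label(lab, 0), lab)
})
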