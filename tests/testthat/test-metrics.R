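test_that("Dice matches hand-counted and brute-force set arithmetic", {
  cube <- array(0, c(4, 4, 4)); cube[1:2, 1:2, 1:2] <- 1
  shifted <- array(0, c(4, 4, 4)); shifted[2:3, 1:2, 1:2] <- 1
  expect_equal(dice_score(cube, cube), 1)
  expect_equal(dice_score(cube, shifted), 2 * 4 / (8 + 8))  # overlap 4
  disjoint <- array(0, c(4, 4, 4)); disjoint[4, 4, 4] <- 1
  expect_equal(dice_score(cube, disjoint), 0)
  # random masks against direct set arithmetic
  set.seed(11)
  for (rep in 1:10) {
    a <- random_mask(c(6, 6, 6), 0.4)
    b <- random_mask(c(6, 6, 6), 0.4)
    want <- 2 * sum(a & b) / (sum(a) + sum(b))
    expect_equal(dice_score(a, b), want)
    expect_equal(dice_score(a, b), dice_score(b, a))  # symmetry
    expect_gte(dice_score(a, b), 0); expect_lte(dice_score(a, b), 1)
  }
  expect_error(dice_score(array(0, c(2, 2, 2)), array(0, c(3, 3, 3))), "grid")
})

test_that("empty-mask conventions follow the challenge rules", {
  empty <- array(0, c(4, 4, 4))
  full <- array(0, c(4, 4, 4)); full[2, 2, 2] <- 1
  expect_equal(dice_score(empty, empty), 1)
  expect_equal(hd95(empty, empty), 0)
  expect_equal(dice_score(full, empty, fp_penalty = 0), 0)
  expect_equal(hd95(full, empty, fp_penalty = 373.13), 373.13)
  # without the convention the distance is undefined (infinite)
  expect_identical(hd95(full, empty), Inf)
})

test_that("HD95 matches the exhaustive surface-distance oracle", {
  # two parallel single-voxel planes 3 voxels apart at 1 mm spacing
  a <- array(0, c(8, 5, 5)); a[2, , ] <- 1
  b <- array(0, c(8, 5, 5)); b[5, , ] <- 1
  expect_equal(hd95(a, b, spacing = c(1, 1, 1)), 3)
  expect_equal(hd95(a, b, spacing = c(2, 1, 1)), 6)  # linear in spacing
  expect_equal(hd95(a, a), 0)
  set.seed(13)
  for (rep in 1:5) {
    x <- random_mask(c(6, 6, 6), 0.3)
    y <- random_mask(c(6, 6, 6), 0.3)
    if (sum(x) == 0 || sum(y) == 0) next
    sp <- c(1, 1.5, 2)
    d <- oracle_surface_distances(x, y, sp)
    want <- unname(quantile(c(d$ab, d$ba), 0.95, type = 7))
    expect_equal(hd95(x, y, sp), want)
    expect_equal(hd95(x, y, sp), hd95(y, x, sp))  # pooled symmetry
    expect_lte(hd95(x, y, sp), max(d$ab, d$ba))   # below the exact Hausdorff
    # directed-max variant never exceeds... and isotropic scaling is linear
    expect_equal(hd95(x, y, c(2, 3, 4)), 2 * hd95(x, y, c(1, 1.5, 2)))
  }
  expect_error(hd95(a, b, spacing = c(0, 1, 1)), "positive")
})

test_that("boundary extraction uses 6-connectivity erosion", {
  m <- array(0, c(5, 5, 5)); m[2:4, 2:4, 2:4] <- 1
  bd <- lka3d:::boundary_voxels(m)
  expect_equal(sum(bd), 27 - 1)    # only the centre voxel is interior
  expect_true(all(bd[m == 0] == FALSE))
  # masks touching the volume edge keep their outer face as boundary
  m2 <- array(1, c(3, 3, 3))
  expect_equal(sum(lka3d:::boundary_voxels(m2)), 26)
})

test_that("tumor region maps nest as ET within TC within WT", {
  set.seed(17)
  lab <- array(sample(c(0L, 1L, 2L, 4L), 6^3, replace = TRUE), c(6, 6, 6))
  r <- brats_region_maps(lab)
  expect_true(all(r$et[r$et] <= r$tc[r$et]))
  expect_true(all(!r$et | r$tc))
  expect_true(all(!r$tc | r$wt))
  expect_equal(sum(r$et), sum(lab == 4))
  expect_equal(sum(r$tc), sum(lab %in% c(1, 4)))
  expect_equal(sum(r$wt), sum(lab %in% c(1, 2, 4)))
  only_ed <- array(c(0L, 2L), c(2, 2, 2))
  r2 <- brats_region_maps(only_ed)
  expect_equal(sum(r2$et), 0); expect_equal(sum(r2$tc), 0)
  expect_equal(sum(r2$wt), 4)
  only_et <- array(c(0L, 4L), c(2, 2, 2))
  r3 <- brats_region_maps(only_et)
  expect_equal(r3$et, r3$tc); expect_equal(r3$tc, r3$wt)
  expect_error(brats_region_maps(array(3L, c(2, 2, 2))), "unknown label")
})

test_that("paired t-test matches the textbook closed form", {
  a <- c(91.2, 90.5, 92.3, 89.9, 91.8, 90.1)
  b <- c(90.8, 90.9, 91.7, 90.2, 91.1, 89.8)
  d <- a - b
  t <- mean(d) / (sd(d) / sqrt(length(d)))
  p <- 2 * pt(-abs(t), df = length(d) - 1)
  expect_equal(paired_ttest(a, b), p, tolerance = 1e-8)
  # no effect: p near 1; strong constant shift at n = 21: p < 0.001
  set.seed(19)
  x <- rnorm(21)
  expect_gt(paired_ttest(x, x + rnorm(21, 0, 1e-3)), 0.05)
  expect_lt(paired_ttest(x, x + 5 + rnorm(21, 0, 0.1)), 0.001)
  expect_error(paired_ttest(1:3, 1:2), "equal length")
  expect_error(paired_ttest(1, 2), "at least 2")
  expect_error(paired_ttest(c(1, 2), c(2, 3)), "zero variance")
})

test_that("evaluation reports aggregate mean (sd) per class plus a mean row", {
  set.seed(23)
  gt <- lapply(1:4, function(i) array(sample(0:2, 6^3, TRUE), c(6, 6, 6)))
  pred <- lapply(gt, function(g) {
    p <- g; flip <- sample(length(p), 20); p[flip] <- sample(0:2, 20, TRUE); p
  })
  rep1 <- evaluate_cases(pred, gt, c(organ1 = 1, organ2 = 2))
  expect_equal(nrow(rep1$per_case), 8)
  s <- rep1$summary
  expect_equal(s$dice_mean[s$class == "mean"],
               mean(s$dice_mean[s$class != "mean"]))
  expect_equal(s$dice_mean[s$class == "organ1"],
               mean(rep1$per_case$dice[rep1$per_case$class == "organ1"]))
  # comparing a prediction set against itself is degenerate, so jitter one
  pred2 <- lapply(gt, function(g) {
    p <- g; flip <- sample(length(p), 40); p[flip] <- sample(0:2, 40, TRUE); p
  })
  rep2 <- evaluate_cases(pred2, gt, c(organ1 = 1, organ2 = 2))
  pv <- compare_reports(rep1, rep2, "dice")
  expect_true(all(pv >= 0 & pv <= 1))
  expect_named(pv, c("organ1", "organ2", "mean"))
})
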