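#' Dice overlap between two binary masks
#'
#' `2 |X ∩ Y| / (|X| + |Y|)`. Two empty masks agree perfectly (Dice 1). When
#' the ground truth is empty but the prediction is not, the challenge
#' false-positive convention applies if `fp_penalty` is given: that penalty
#' Dice (0 for the enhancing-tumor channel) is returned instead of the
#' undefined ratio; with `fp_penalty = NULL` the plain formula is used (which
#' yields 0 for an empty ground truth as well).
#'
#' @param pred,gt Binary (logical or 0/1) arrays on the same grid; `gt` is
#'   the reference mask.
#' @param fp_penalty Optional penalty Dice for the empty-gt/non-empty-pred
#'   case (BraTS ET uses 0).
#' @return Dice score in `[0, 1]`.
#' @export
dice_score <- function(pred, gt, fp_penalty = NULL) {
  if (!identical(dim(pred), dim(gt))) {
    stop("pred and gt must share the same grid", call. = FALSE)
  }
  p <- pred != 0
  g <- gt != 0
  np <- sum(p); ng <- sum(g)
  if (ng == 0 && np == 0) return(1)
  if (ng == 0 && np > 0 && !is.null(fp_penalty)) return(fp_penalty)
  2 * sum(p & g) / (np + ng)
}

# Boundary voxels of a binary mask under 6-connectivity: foreground voxels
# with at least one background (or out-of-volume) face neighbour.
boundary_voxels <- function(mask) {
  m <- mask != 0
  d <- dim(m)
  pad <- array(FALSE, d + 2L)
  pad[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- m
  inner <- pad[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] &
    pad[1:d[1], 2:(d[2] + 1L), 2:(d[3] + 1L)] &
    pad[3:(d[1] + 2L), 2:(d[2] + 1L), 2:(d[3] + 1L)] &
    pad[2:(d[1] + 1L), 1:d[2], 2:(d[3] + 1L)] &
    pad[2:(d[1] + 1L), 3:(d[2] + 2L), 2:(d[3] + 1L)] &
    pad[2:(d[1] + 1L), 2:(d[2] + 1L), 1:d[3]] &
    pad[2:(d[1] + 1L), 2:(d[2] + 1L), 3:(d[3] + 2L)]
  m & !inner
}

boundary_coords_mm <- function(mask, spacing) {
  w <- which(boundary_voxels(mask), arr.ind = TRUE)
  if (nrow(w) == 0L) return(matrix(numeric(0), 0L, 3L))
  sweep(w - 1, 2L, spacing, "*")
}

#' 95th-percentile Hausdorff distance between two binary masks
#'
#' The 95th percentile of the boundary-to-boundary Euclidean distances
#' between prediction and reference, in millimetres via the voxel spacing.
#' Boundaries are foreground voxels with a background face-neighbour
#' (6-connectivity). By default the two directed surface-distance sets
#' (prediction to reference and reference to prediction) are pooled before
#' taking the percentile (`method = "pooled"`); `method = "directed_max"`
#' instead takes the maximum of the two directed 95th percentiles.
#'
#' @inheritParams dice_score
#' @param spacing Positive voxel spacing triple in mm.
#' @param fp_penalty Optional penalty value (mm) returned when the ground
#'   truth is empty and the prediction is not — the BraTS enhancing-tumor
#'   convention uses 373.13.
#' @param method Percentile pooling convention, see above.
#' @return Non-negative distance in mm; 0 for identical masks and for two
#'   empty masks.
#' @examples
#' m <- array(0, c(4, 4, 4)); m[2, 2, 2] <- 1
#' hd95(m, m)  # 0
#' @export
hd95 <- function(pred, gt, spacing = c(1, 1, 1), fp_penalty = NULL,
                 method = c("pooled", "directed_max")) {
  method <- match.arg(method)
  if (!identical(dim(pred), dim(gt))) {
    stop("pred and gt must share the same grid", call. = FALSE)
  }
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (any(spacing <= 0)) stop("spacing must be strictly positive", call. = FALSE)
  np <- sum(pred != 0); ng <- sum(gt != 0)
  if (ng == 0 && np == 0) return(0)
  if (ng == 0 && np > 0 && !is.null(fp_penalty)) return(fp_penalty)
  if (np == 0 || ng == 0) return(Inf)
  a <- boundary_coords_mm(pred, spacing)
  b <- boundary_coords_mm(gt, spacing)
  d_ab <- .min_dist_to_set(a, b)
  d_ba <- .min_dist_to_set(b, a)
  if (method == "pooled") {
    unname(stats::quantile(c(d_ab, d_ba), 0.95, type = 7))
  } else {
    max(stats::quantile(d_ab, 0.95, type = 7),
        stats::quantile(d_ba, 0.95, type = 7))
  }
}

#' BraTS evaluation region masks from a tumor label volume
#'
#' Maps the annotated classes — necrotic/non-enhancing core (label 1),
#' peritumoral edema (label 2) and enhancing tumor (label 4) — to the three
#' nested evaluation regions: ET (enhancing tumor), TC (tumor core = ET +
#' NCR/NET) and WT (whole tumor = TC + ED), so `ET ⊆ TC ⊆ WT`.
#'
#' @param label Integer array with values in `{0, 1, 2, 4}`.
#' @return Named list of binary arrays `et`, `tc`, `wt`.
#' @export
brats_region_maps <- function(label) {
  vals <- unique(as.integer(label))
  bad <- setdiff(vals, c(0L, 1L, 2L, 4L))
  if (length(bad)) {
    stop("unknown label values: ", paste(bad, collapse = ", "),
         " (expected 0, 1, 2, 4)", call. = FALSE)
  }
  list(et = label == 4L,
       tc = label == 4L | label == 1L,
       wt = label == 4L | label == 1L | label == 2L)
}

#' Two-sided paired t-test between per-case score vectors
#'
#' @param scores_a,scores_b Numeric vectors of equal length (>= 2), one score
#'   per test case.
#' @return The two-sided p-value.
#' @export
paired_ttest <- function(scores_a, scores_b) {
  if (length(scores_a) != length(scores_b)) {
    stop("score vectors must have equal length", call. = FALSE)
  }
  if (length(scores_a) < 2L) {
    stop("need at least 2 paired cases", call. = FALSE)
  }
  d <- scores_a - scores_b
  if (stats::sd(d) == 0) {
    stop("paired differences have zero variance; the t statistic is undefined",
         call. = FALSE)
  }
  stats::t.test(scores_a, scores_b, paired = TRUE)$p.value
}

#' Evaluate predicted label volumes against references
#'
#' Computes per-case, per-class Dice and HD95 and aggregates them as
#' mean (standard deviation) per class plus a cross-class mean, the layout
#' used for segmentation benchmark tables.
#'
#' @param pred List of predicted integer label arrays.
#' @param gt List of reference label arrays (same length and grids).
#' @param classes Named integer vector mapping class names to label values,
#'   e.g. `c(liver = 1, lungs = 2)`.
#' @param spacing Voxel spacing triple in mm, or a list of one triple per case.
#' @param fp_penalty_hd95 Optional named numeric: HD95 penalty per class name
#'   for the empty-gt/non-empty-pred convention (Dice penalty 0 is applied to
#'   the same classes).
#' @return An object of class `lka_eval_report` with `$per_case` (data frame)
#'   and `$summary`.
#' @export
evaluate_cases <- function(pred, gt, classes, spacing = c(1, 1, 1),
                           fp_penalty_hd95 = NULL) {
  stopifnot(length(pred) == length(gt), length(pred) >= 1L)
  if (!is.list(spacing)) spacing <- rep(list(spacing), length(pred))
  rows <- list()
  for (i in seq_along(pred)) {
    for (j in seq_along(classes)) {
      cname <- names(classes)[j]
      pen <- if (!is.null(fp_penalty_hd95) && cname %in% names(fp_penalty_hd95))
        fp_penalty_hd95[[cname]] else NULL
      pm <- pred[[i]] == classes[j]
      gm <- gt[[i]] == classes[j]
      rows[[length(rows) + 1L]] <- data.frame(
        case = i, class = cname,
        dice = dice_score(pm, gm, fp_penalty = if (is.null(pen)) NULL else 0),
        hd95 = hd95(pm, gm, spacing[[i]], fp_penalty = pen))
    }
  }
  per_case <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(per_case, per_case$class), function(df) {
    data.frame(class = df$class[1],
               dice_mean = mean(df$dice), dice_sd = stats::sd(df$dice),
               hd95_mean = mean(df$hd95), hd95_sd = stats::sd(df$hd95))
  }))
  summ <- summ[match(names(classes), summ$class), ]
  overall <- data.frame(class = "mean",
                        dice_mean = mean(summ$dice_mean), dice_sd = NA,
                        hd95_mean = mean(summ$hd95_mean), hd95_sd = NA)
  structure(list(per_case = per_case, summary = rbind(summ, overall)),
            class = "lka_eval_report")
}

#' @export
print.lka_eval_report <- function(x, ...) {
  cat("Segmentation evaluation:", length(unique(x$per_case$case)), "cases\n")
  s <- x$summary
  fmt <- function(m, s) ifelse(is.na(s), sprintf("%.2f", m),
                               sprintf("%.2f (%.2f)", m, s))
  print(data.frame(class = s$class,
                   dice = fmt(100 * s$dice_mean, 100 * s$dice_sd),
                   hd95 = fmt(s$hd95_mean, s$hd95_sd)),
        row.names = FALSE)
  invisible(x)
}

#' Compare two prediction sets with paired t-tests
#'
#' @param report_a,report_b [evaluate_cases()] reports over the same cases
#'   and classes.
#' @param metric `"dice"` or `"hd95"`.
#' @return Named vector of two-sided p-values, one per class plus the
#'   cross-class per-case mean.
#' @export
compare_reports <- function(report_a, report_b, metric = c("dice", "hd95")) {
  metric <- match.arg(metric)
  a <- report_a$per_case; b <- report_b$per_case
  stopifnot(nrow(a) == nrow(b))
  classes <- unique(a$class)
  p <- vapply(classes, function(cl) {
    paired_ttest(a[[metric]][a$class == cl], b[[metric]][b$class == cl])
  }, numeric(1))
  ma <- tapply(a[[metric]], a$case, mean)
  mb <- tapply(b[[metric]], b$case, mean)
  c(stats::setNames(p, classes), mean = paired_ttest(as.numeric(ma), as.numeric(mb)))
}
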