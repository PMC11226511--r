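#' Configure the synthetic phantom generator
#'
#' The phantom emulates a multi-class 3-D scan: each foreground class is a
#' set of ellipsoidal "organs" of a distinct mean intensity placed on a noisy
#' background. Blobs are kept disjoint by rejection sampling, so the label
#' volume is unambiguous and the image is trivially segmentable at high
#' contrast — the regime unit tests need.
#'
#' @param dims Grid dimension triple (default 64^3).
#' @param n_classes Number of foreground classes.
#' @param blobs_per_class Ellipsoids per class.
#' @param radius_range Semi-axis range in voxels, `U(lo, hi)` per axis.
#' @param intensity_means Per-class mean intensities (default `1, 2, ...` on
#'   a background of mean 0).
#' @param intensity_sd Within-blob intensity noise sd.
#' @param background_sd Background noise sd.
#' @param spacing Voxel spacing triple (mm).
#' @param seed Integer seed; the same seed reproduces the phantom bit for bit.
#' @param max_tries Rejection-sampling retry budget per blob.
#' @return An object of class `lka_phantom_config`.
#' @export
phantom_config <- function(dims = c(64, 64, 64), n_classes = 3L,
                           blobs_per_class = 2L, radius_range = c(5, 10),
                           intensity_means = seq_len(n_classes),
                           intensity_sd = 0.1, background_sd = 0.1,
                           spacing = c(1, 1, 1), seed = 0L,
                           max_tries = 1000L) {
  dims <- check_dims_triple(dims, "dims")
  n_classes <- as.integer(check_count(n_classes, "n_classes"))
  stopifnot(length(intensity_means) == n_classes,
            radius_range[1] > 0, radius_range[1] <= radius_range[2])
  structure(list(dims = dims, n_classes = n_classes,
                 blobs_per_class = as.integer(blobs_per_class),
                 radius_range = radius_range,
                 intensity_means = intensity_means,
                 intensity_sd = intensity_sd, background_sd = background_sd,
                 spacing = spacing, seed = as.integer(seed),
                 max_tries = as.integer(max_tries)),
            class = "lka_phantom_config")
}

#' Generate a synthetic phantom volume
#'
#' @param config An [phantom_config()].
#' @return An [volume_sample()] with a single-channel image and an integer
#'   label volume (0 = background, `1..n_classes` = blob classes).
#' @examples
#' p <- generate_phantom(phantom_config(dims = c(32, 32, 32), seed = 1))
#' table(p$label)
#' @export
generate_phantom <- function(config) {
  stopifnot(inherits(config, "lka_phantom_config"))
  with_seed(config$seed, {
    d <- config$dims
    label <- array(0L, d)
    image <- array(stats::rnorm(prod(d), 0, config$background_sd), d)
    placed <- list()  # (center, bounding radius) of accepted blobs
    ax <- lapply(d, function(n) seq_len(n) - 1)
    for (cls in seq_len(config$n_classes)) {
      for (b in seq_len(config$blobs_per_class)) {
        ok <- FALSE
        for (try in seq_len(config$max_tries)) {
          r <- stats::runif(3, config$radius_range[1], config$radius_range[2])
          ctr <- vapply(1:3, function(a) {
            stats::runif(1, r[a], d[a] - 1 - r[a])
          }, numeric(1))
          clash <- any(vapply(placed, function(p) {
            sqrt(sum((p$ctr - ctr)^2)) < p$r + max(r) + 1
          }, logical(1)))
          if (!clash) { ok <- TRUE; break }
        }
        if (!ok) {
          stop("could not place ", config$blobs_per_class, " disjoint blobs of ",
               config$n_classes, " classes with radii in [",
               config$radius_range[1], ", ", config$radius_range[2],
               "] on a ", paste(d, collapse = "x"),
               " grid within the retry budget", call. = FALSE)
        }
        placed[[length(placed) + 1L]] <- list(ctr = ctr, r = max(r))
        # ellipsoid membership on the subgrid around the blob
        zi <- which(abs(ax[[1]] - ctr[1]) <= r[1])
        yi <- which(abs(ax[[2]] - ctr[2]) <= r[2])
        xi <- which(abs(ax[[3]] - ctr[3]) <= r[3])
        sub <- expand.grid(z = zi, y = yi, x = xi)
        inside <- ((sub$z - 1 - ctr[1]) / r[1])^2 +
          ((sub$y - 1 - ctr[2]) / r[2])^2 +
          ((sub$x - 1 - ctr[3]) / r[3])^2 <= 1
        sub <- sub[inside, , drop = FALSE]
        idx <- sub$z + d[1] * (sub$y - 1L) + d[1] * d[2] * (sub$x - 1L)
        label[idx] <- cls
        image[idx] <- config$intensity_means[cls] +
          stats::rnorm(length(idx), 0, config$intensity_sd)
      }
    }
    volume_sample(image, label = label, spacing = config$spacing,
                  id = sprintf("phantom-seed%d", config$seed))
  })
}

#' Write a phantom dataset with a manifest
#'
#' @param dir Output directory (created if needed).
#' @param n Number of phantoms; phantom `i` uses seed `seed + i - 1`.
#' @param config Template [phantom_config()].
#' @return Path of the manifest CSV, invisibly.
#' @export
write_phantom_dataset <- function(dir, n, config = phantom_config()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_len(n), function(i) {
    cfg <- config
    cfg$seed <- config$seed + i - 1L
    p <- generate_phantom(cfg)
    img <- file.path(dir, sprintf("%s_image.nii.gz", p$id))
    lab <- file.path(dir, sprintf("%s_label.nii.gz", p$id))
    write_volume(p, img, "image")
    write_volume(p, lab, "label")
    data.frame(id = p$id, image = basename(img), label = basename(lab))
  })
  write_manifest(do.call(rbind, rows), file.path(dir, "manifest.csv"))
  invisible(file.path(dir, "manifest.csv"))
}
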