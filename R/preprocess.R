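# Resampling, cropping/padding and intensity normalization of volume samples.

# Sample one 3-D channel at fractional voxel coordinates.
sample_channel <- function(vol, zc, yc, xc, interp = c("trilinear", "nearest"),
                           clamp = TRUE, fill = 0) {
  interp <- match.arg(interp)
  d <- dim(vol)
  f <- if (interp == "trilinear") .trilinear_sample else .nearest_sample
  f(as.numeric(vol), d[1], d[2], d[3], zc, yc, xc, clamp, fill)
}

#' Resample a volume to a target spacing
#'
#' Downsampling first applies Gaussian pre-smoothing (per-axis sigma of
#' `factor / 3` voxels where `factor` is the spacing ratio, only on axes that
#' are actually downsampled) to avoid aliasing, then trilinear interpolation
#' on the new grid. Labels are resampled nearest-neighbour without smoothing.
#' Output dimensions are `round(dims * spacing / target)` (at least 1).
#'
#' @param sample An [volume_sample()].
#' @param target_spacing Positive spacing triple in mm (scalar recycled).
#' @param antialias Apply the Gaussian pre-smoothing (default `TRUE`).
#' @return The resampled sample.
#' @export
resample_volume <- function(sample, target_spacing, antialias = TRUE) {
  stopifnot(inherits(sample, "lka_volume"))
  if (length(target_spacing) == 1L) target_spacing <- rep(target_spacing, 3L)
  if (any(target_spacing <= 0)) stop("target spacing must be positive", call. = FALSE)
  d <- dim(sample$image)[2:4]
  factor <- target_spacing / sample$spacing
  nd <- pmax(1L, as.integer(round(d * sample$spacing / target_spacing)))
  if (any(nd < 1L)) stop("resampling would produce an empty volume", call. = FALSE)
  # voxel-centre alignment: target voxel i sits at source coordinate
  # (i + 0.5) * factor - 0.5
  ax <- lapply(1:3, function(a) (seq_len(nd[a]) - 0.5) * factor[a] - 0.5)
  grid <- expand.grid(z = ax[[1]], y = ax[[2]], x = ax[[3]])
  sigma <- ifelse(antialias & factor > 1, factor / 3, 0)
  C <- dim(sample$image)[1]
  img <- array(0, c(C, nd))
  for (c in seq_len(C)) {
    vol <- array(sample$image[c, , , ], d)
    if (any(sigma > 0)) vol <- gaussian_blur3(vol, sigma)
    img[c, , , ] <- sample_channel(vol, grid$z, grid$y, grid$x, "trilinear")
  }
  label <- NULL
  if (!is.null(sample$label)) {
    label <- array(sample_channel(sample$label, grid$z, grid$y, grid$x,
                                  "nearest"), nd)
  }
  out <- sample
  out$image <- img
  out$label <- label
  out$spacing <- as.numeric(target_spacing)
  out
}

#' Center crop or zero-pad a volume to an exact shape
#'
#' The inverse mapping (original shape and offsets) is recorded in
#' `meta$crop` so that predictions can be written back onto the original grid
#' with [restore_to_original()].
#'
#' @param sample An [volume_sample()].
#' @param target_shape Positive integer triple.
#' @return The cropped/padded sample.
#' @export
crop_or_pad <- function(sample, target_shape) {
  stopifnot(inherits(sample, "lka_volume"))
  tgt <- check_dims_triple(target_shape, "target_shape")
  cur <- dim(sample$image)[2:4]
  # per axis: source range copied and where it lands in the target
  src_start <- pmax(0L, (cur - tgt) %/% 2L)
  dst_start <- pmax(0L, (tgt - cur) %/% 2L)
  extent <- pmin(cur, tgt)
  C <- dim(sample$image)[1]
  img <- array(0, c(C, tgt))
  sz <- src_start[1] + seq_len(extent[1]); dz <- dst_start[1] + seq_len(extent[1])
  sy <- src_start[2] + seq_len(extent[2]); dy <- dst_start[2] + seq_len(extent[2])
  sx <- src_start[3] + seq_len(extent[3]); dx <- dst_start[3] + seq_len(extent[3])
  img[, dz, dy, dx] <- sample$image[, sz, sy, sx, drop = FALSE]
  label <- NULL
  if (!is.null(sample$label)) {
    label <- array(0L, tgt)
    label[dz, dy, dx] <- sample$label[sz, sy, sx]
  }
  out <- sample
  out$image <- img
  out$label <- label
  out$meta$crop <- list(orig_shape = cur, src_start = src_start,
                        dst_start = dst_start, extent = extent)
  out
}

#' Map a prediction on a cropped/padded grid back to the original grid
#'
#' @param pred 3-D array on the cropped/padded grid.
#' @param crop The `meta$crop` record written by [crop_or_pad()].
#' @param fill Value for voxels outside the cropped region (default 0,
#'   background).
#' @return 3-D array on the original grid.
#' @export
restore_to_original <- function(pred, crop, fill = 0L) {
  out <- array(fill, crop$orig_shape)
  sz <- crop$src_start[1] + seq_len(crop$extent[1])
  sy <- crop$src_start[2] + seq_len(crop$extent[2])
  sx <- crop$src_start[3] + seq_len(crop$extent[3])
  dz <- crop$dst_start[1] + seq_len(crop$extent[1])
  dy <- crop$dst_start[2] + seq_len(crop$extent[2])
  dx <- crop$dst_start[3] + seq_len(crop$extent[3])
  out[sz, sy, sx] <- pred[dz, dy, dx]
  out
}

#' Intensity normalization
#'
#' For MRI, per-channel z-scoring over the nonzero (brain-masked) voxels;
#' for CT, clipping to the 0.5/99.5 intensity percentiles of the volume
#' followed by z-scoring over all voxels. A zero-variance channel is centred
#' but not scaled, with a warning.
#'
#' @param sample An [volume_sample()].
#' @param modality `"mri"` or `"ct"`.
#' @param clip_quantiles CT clipping quantiles (default `c(0.005, 0.995)`).
#' @return The normalized sample.
#' @export
normalize_intensity <- function(sample, modality = c("mri", "ct"),
                                clip_quantiles = c(0.005, 0.995)) {
  stopifnot(inherits(sample, "lka_volume"))
  modality <- match.arg(modality)
  if (any(!is.finite(sample$image))) {
    stop("image contains non-finite values", call. = FALSE)
  }
  C <- dim(sample$image)[1]
  out <- sample
  for (c in seq_len(C)) {
    v <- sample$image[c, , , ]
    if (modality == "ct") {
      q <- stats::quantile(v, clip_quantiles, names = FALSE)
      v <- pmin(pmax(v, q[1]), q[2])
      region <- rep(TRUE, length(v))
    } else {
      region <- v != 0
      if (!any(region)) region <- rep(TRUE, length(v))
    }
    mu <- mean(v[region])
    s <- stats::sd(v[region])
    if (!is.finite(s) || s == 0) {
      warning("channel ", c, " has zero variance; centred but not scaled")
      v <- v - mu
    } else {
      v <- (v - mu) / s
    }
    out$image[c, , , ] <- v
  }
  out
}
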