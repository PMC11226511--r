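#' Construct a volume sample
#'
#' The unit flowing through I/O, preprocessing, augmentation and training:
#' a channel-first image array, an optional integer label volume on the same
#' grid, the voxel spacing in mm and opaque orientation metadata.
#'
#' @param image Numeric array: `(D, H, W)` (promoted to one channel) or
#'   `(C, D, H, W)`.
#' @param label Optional integer `(D, H, W)` array.
#' @param spacing Positive spacing triple in mm.
#' @param id Identifier string.
#' @param meta List of opaque metadata (orientation/affine, crop records).
#' @return An object of class `lka_volume`.
#' @export
volume_sample <- function(image, label = NULL, spacing = c(1, 1, 1),
                          id = "sample", meta = list()) {
  d <- dim(image)
  if (is.null(d) || !(length(d) %in% c(3L, 4L))) {
    stop("image must be a 3-D or 4-D array", call. = FALSE)
  }
  if (length(d) == 3L) dim(image) <- c(1L, d)
  if (!is.null(label)) {
    if (!identical(dim(label), dim(image)[2:4])) {
      stop("label grid ", paste(dim(label), collapse = "x"),
           " does not match image grid ",
           paste(dim(image)[2:4], collapse = "x"), call. = FALSE)
    }
  }
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("spacing must be a positive triple (mm)", call. = FALSE)
  }
  structure(list(image = image, label = label, spacing = as.numeric(spacing),
                 id = as.character(id), meta = meta),
            class = "lka_volume")
}

#' @export
print.lka_volume <- function(x, ...) {
  d <- dim(x$image)
  cat(sprintf("Volume '%s': %d channel(s), %dx%dx%d voxels @ %s mm%s\n",
              x$id, d[1], d[2], d[3], d[4],
              paste(signif(x$spacing, 3), collapse = "x"),
              if (is.null(x$label)) "" else sprintf(
                ", labels {%s}", paste(sort(unique(as.integer(x$label))),
                                       collapse = ","))))
  invisible(x)
}

#' Read a NIfTI volume (and optionally its label volume)
#'
#' 3-D files become single-channel samples; the 4th dimension of a 4-D file
#' is interpreted as channels (imaging modalities). Voxel spacing is taken
#' from the header and the full header is kept in `meta` so that
#' [write_volume()] round-trips orientation.
#'
#' @param path Path to a `.nii` / `.nii.gz` image.
#' @param label_path Optional path to an integer label volume on the same grid.
#' @param id Identifier (defaults to the file name).
#' @return An [volume_sample()] object.
#' @export
read_volume <- function(path, label_path = NULL, id = NULL) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  d <- dim(arr)
  if (length(d) == 2L) stop("2-D images are not supported: ", path, call. = FALSE)
  if (!(length(d) %in% c(3L, 4L))) {
    stop("expected a 3-D or 4-D NIfTI volume, got ", length(d), "-D: ", path,
         call. = FALSE)
  }
  if (length(d) == 4L) arr <- aperm(arr, c(4L, 1L, 2L, 3L))
  arr <- array(as.numeric(arr), dim(arr))  # strip NIfTI attributes
  spacing <- RNifti::pixdim(img)[1:3]
  label <- NULL
  if (!is.null(label_path)) {
    lab <- as.array(RNifti::readNifti(label_path))
    if (length(dim(lab)) != 3L) {
      stop("label volume must be 3-D: ", label_path, call. = FALSE)
    }
    label <- array(round(as.numeric(lab)), dim(lab))
  }
  volume_sample(arr, label = label, spacing = spacing,
                id = if (is.null(id)) sub("\\.nii(\\.gz)?$", "", basename(path))
                     else id,
                meta = list(header = RNifti::niftiHeader(img)))
}

#' Write a volume sample as NIfTI
#'
#' @param sample An [volume_sample()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param what `"image"` (channels become the 4th NIfTI dimension; a single
#'   channel is written 3-D) or `"label"`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(sample, path, what = c("image", "label")) {
  what <- match.arg(what)
  arr <- if (what == "image") {
    a <- sample$image
    if (dim(a)[1] == 1L) array(a, dim(a)[2:4]) else aperm(a, c(2L, 3L, 4L, 1L))
  } else {
    if (is.null(sample$label)) stop("sample has no label volume", call. = FALSE)
    sample$label
  }
  hdr <- sample$meta$header
  img <- if (!is.null(hdr) && identical(as.integer(hdr$dim[2:4]),
                                        as.integer(dim(arr)[1:3]))) {
    RNifti::asNifti(arr, reference = hdr)
  } else {
    out <- RNifti::asNifti(arr)
    RNifti::pixdim(out) <- sample$spacing
    out
  }
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a dataset manifest
#'
#' @param df Data frame with columns `id`, `image`, `label`.
#' @param path CSV output path.
#' @export
write_manifest <- function(df, path) {
  stopifnot(all(c("id", "image") %in% names(df)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a dataset manifest into volume samples
#'
#' @param path Manifest CSV with columns `id`, `image` and optionally `label`
#'   (paths relative to the manifest's directory or absolute).
#' @return List of [volume_sample()] objects.
#' @export
read_manifest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  base <- dirname(path)
  resolve <- function(p) ifelse(file.exists(p), p, file.path(base, p))
  lapply(seq_len(nrow(df)), function(i) {
    read_volume(resolve(df$image[i]),
                label_path = if ("label" %in% names(df) && nzchar(df$label[i]))
                  resolve(df$label[i]) else NULL,
                id = df$id[i])
  })
}
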