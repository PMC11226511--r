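#' @useDynLib lka3d, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif quantile sd t.test setNames
#' @importFrom utils write.csv read.csv
NULL

# Validate a single positive integer-valued scalar.
check_count <- function(x, name = deparse(substitute(x))) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 || x != floor(x)) {
    stop(name, " must be a single positive integer", call. = FALSE)
  }
  as.numeric(x)
}

# Validate a positive integer triple (scalars are recycled).
check_dims_triple <- function(x, name = deparse(substitute(x))) {
  if (length(x) == 1L) x <- rep(x, 3L)
  if (!is.numeric(x) || length(x) != 3L || any(is.na(x)) ||
      any(x < 1) || any(x != floor(x))) {
    stop(name, " must be a positive integer triple", call. = FALSE)
  }
  as.integer(x)
}

# Half-up decimal rounding (R's round() is half-even).
round_half_up <- function(x, digits = 0L) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

# Run code under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Normalized 1-D Gaussian kernel with radius 3*sigma (minimum length 1).
gaussian_kernel1d <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

# Separable Gaussian blur of a 3-D (D, H, W) array with per-axis sigmas
# (in voxels), replicate padding at the edges.
gaussian_blur3 <- function(vol, sigma) {
  if (length(sigma) == 1L) sigma <- rep(sigma, 3L)
  d <- dim(vol)
  out <- vol
  for (ax in 1:3) {
    if (sigma[ax] > 0) {
      out <- .conv1d_axis(as.numeric(out), d[1], d[2], d[3],
                          gaussian_kernel1d(sigma[ax]), ax)
    }
  }
  dim(out) <- d
  out
}
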