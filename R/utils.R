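# internal helpers shared across modules

# voxel_size is user-facing (dx, dy, dz) µm; arrays are stored [y, x, z],
# so C++ entry points take spacing reordered to (sy, sx, sz)
spacing_yxz <- function(voxel_size) {
  as.numeric(voxel_size[c(2, 1, 3)])
}

voxel_volume <- function(voxel_size) prod(as.numeric(voxel_size))

check_voxel_size <- function(voxel_size) {
  if (length(voxel_size) != 3 || !is.numeric(voxel_size) || any(voxel_size <= 0)) {
    abort("`voxel_size` must be three positive values (dx, dy, dz) in µm.")
  }
  invisible(as.numeric(voxel_size))
}

# deterministic per-sample seed derivation, kept inside 32-bit integer range
derive_seed <- function(master_seed, index) {
  as.integer((as.numeric(master_seed) * 48271 + index * 1000003) %% 2147483647)
}

with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

#' Otsu threshold of an intensity array
#'
#' Exhaustively searches the binned intensity histogram for the threshold
#' maximizing between-class variance.
#'
#' @param x numeric vector or array of intensities.
#' @param nbins number of histogram bins.
#' @return The threshold intensity (a scalar); voxels strictly above it are
#'   foreground.
#' @export
otsu_threshold <- function(x, nbins = 256) {
  x <- as.numeric(x)
  rng <- range(x, finite = TRUE)
  if (!is.finite(rng[1]) || rng[1] == rng[2]) {
    abort("Otsu thresholding needs a non-degenerate intensity histogram.")
  }
  edges <- seq(rng[1], rng[2], length.out = nbins + 1)
  h <- tabulate(pmin(pmax(findInterval(x, edges, rightmost.closed = TRUE), 1L), nbins),
                nbins = nbins)
  p <- h / sum(h)
  mids <- (edges[-1] + edges[-(nbins + 1)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[nbins]
  w1 <- 1 - w0
  between <- (mu_t * w0 - mu)^2 / (w0 * w1)
  between[!is.finite(between)] <- -Inf
  k <- which.max(between)
  edges[k + 1]
}

# format a physical box for error messages
fmt_box <- function(origin, extent) {
  paste0("[", paste(sprintf("%g", origin), collapse = ", "), "] + [",
         paste(sprintf("%g", extent), collapse = ", "), "] µm")
}
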