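#' Segmentation configuration
#'
#' Parameters of the classical adipocyte segmentation pipeline: intensity
#' thresholding of the lipid channel, "circular open" (morphological opening
#' with a ball of physical radius `open_radius`, removing regions that cannot
#' accommodate a sphere of that size), "separate objects" (distance-transform
#' watershed with h-maxima seed suppression), and object filtering.
#'
#' @param backend `"classical"` (default, deterministic) or `"learned"` (a
#'   trained pixel classifier from [train_learned_backend()], passed via
#'   `learned_model`).
#' @param threshold_method `"otsu"` or `"fixed"`.
#' @param fixed_threshold intensity threshold when `threshold_method="fixed"`.
#' @param h_maxima seed-suppression depth in µm applied to the distance map;
#'   maxima shallower than this merge into their taller neighbour. Default 4.
#' @param open_radius physical radius (µm) of the circular-open structuring
#'   ball; 0 disables. Default 10.
#' @param min_volume objects below this volume (µm³) are discarded.
#' @param border_policy `"exclude_touching"` drops objects clipped by the grid
#'   boundary (their volumes are biased low); `"keep"` retains them.
#' @param crop_extent optional `(x, y, z)` µm crop applied before analysis.
#' @param crop_origin crop origin `(x, y, z)` µm, default `(0, 0, 0)`.
#' @param open_first if `TRUE` (default) the circular open is applied to the
#'   binary mask before object separation; if `FALSE` it is applied per object
#'   after separation.
#' @param depth_normalize if `TRUE` (default), correct exponential depth decay
#'   of intensity before thresholding (robust log-linear fit of per-slice
#'   upper-quantile intensity).
#' @param learned_model optional fitted backend from [train_learned_backend()].
#' @return A `segmentation_config` object.
#' @export
segmentation_config <- function(backend = c("classical", "learned"),
                                threshold_method = c("otsu", "fixed"),
                                fixed_threshold = NULL,
                                h_maxima = 4,
                                open_radius = 10,
                                min_volume = 20000,
                                border_policy = c("exclude_touching", "keep"),
                                crop_extent = NULL,
                                crop_origin = c(0, 0, 0),
                                open_first = TRUE,
                                depth_normalize = TRUE,
                                learned_model = NULL) {
  backend <- match.arg(backend)
  threshold_method <- match.arg(threshold_method)
  border_policy <- match.arg(border_policy)
  if (h_maxima < 0 || open_radius < 0 || min_volume < 0) {
    abort("`h_maxima`, `open_radius` and `min_volume` must be >= 0.")
  }
  if (threshold_method == "fixed" && is.null(fixed_threshold)) {
    abort("`fixed_threshold` is required when `threshold_method = \"fixed\"`.")
  }
  if (backend == "learned" && is.null(learned_model)) {
    abort(paste0(
      "The learned backend needs a trained model: pass `learned_model = ",
      "train_learned_backend(...)`. The classical backend remains the default."
    ))
  }
  structure(
    list(backend = backend, threshold_method = threshold_method,
         fixed_threshold = fixed_threshold, h_maxima = h_maxima,
         open_radius = open_radius, min_volume = min_volume,
         border_policy = border_policy, crop_extent = crop_extent,
         crop_origin = crop_origin, open_first = open_first,
         depth_normalize = depth_normalize, learned_model = learned_model),
    class = "segmentation_config"
  )
}

# robust depth-decay correction: fit log of per-slice 99th-percentile
# intensity against depth, divide the decay out (only if intensity decays)
depth_normalize_volume <- function(arr, voxel_size) {
  nz <- dim(arr)[3]
  if (nz < 4) return(arr)
  ref <- vapply(seq_len(nz), function(iz) quantile(arr[, , iz], 0.99, names = FALSE),
                numeric(1))
  keep <- ref > 0.05 * max(ref) & ref > 0
  if (sum(keep) < 3) return(arr)
  z <- (seq_len(nz) - 1) * voxel_size[3]
  b <- coef(lm(log(ref[keep]) ~ z[keep]))[[2]]
  if (!is.finite(b) || b >= 0) return(arr)
  corr <- exp(-b * z) # > 1 at depth
  arr * rep(corr, each = dim(arr)[1] * dim(arr)[2])
}

#' Foreground extraction on the lipid channel
#'
#' Thresholds the lipid channel (Otsu by default, after optional depth
#' normalization) and fills enclosed holes in 3D.
#'
#' @param volume an [image_volume()] or bare 3D array (lipid intensities).
#' @param config a [segmentation_config()].
#' @param voxel_size required when `volume` is a bare array.
#' @return Logical 3D array (the binary mask), with the chosen threshold in
#'   attribute `"threshold"`.
#' @export
binarize <- function(volume, config = segmentation_config(), voxel_size = NULL) {
  vs <- get_voxel_size(volume, voxel_size)
  arr <- get_channel(volume, "lipid")
  if (config$backend == "learned") {
    mask <- predict_learned(config$learned_model, arr)
  } else {
    if (config$depth_normalize) arr <- depth_normalize_volume(arr, vs)
    thr <- if (config$threshold_method == "otsu") {
      otsu_threshold(arr)
    } else {
      config$fixed_threshold
    }
    mask <- arr > thr
  }
  mask <- fill_holes(mask)
  if (config$backend != "learned" ) attr(mask, "threshold") <- thr
  mask
}

# fill 3D holes: background components not connected to the grid boundary
fill_holes <- function(mask) {
  dims <- dim(mask)
  bg <- .label_components(!mask, as.integer(dims), 6L)
  dim(bg) <- dims
  if (max(bg) == 0L) return(mask)
  border <- unique(c(bg[1, , ], bg[dims[1], , ], bg[, 1, ], bg[, dims[2], ],
                     bg[, , 1], bg[, , dims[3]]))
  hole <- bg > 0L & !(bg %in% border)
  out <- mask | hole
  dim(out) <- dims
  out
}

#' Circular open: ball opening in physical units
#'
#' Removes foreground regions that cannot accommodate a ball of the given
#' physical radius: the result is the union of all inscribed Euclidean balls
#' of radius greater than `radius` (the ball granulometry). A voxel survives
#' exactly when it is covered by a maximal inscribed ball wider than the
#' structuring radius, which makes the operation anti-extensive, idempotent
#' and monotone in `radius` — on discrete grids the classic
#' erode-then-dilate composition loses radius-monotonicity, so the
#' granulometric form is used. Computed with two distance transforms (the
#' second an additively weighted, power-diagram transform), anisotropy-aware.
#'
#' @param mask logical 3D array.
#' @param radius ball radius in µm; 0 is the identity.
#' @param voxel_size voxel spacing `(dx, dy, dz)` µm.
#' @return Logical 3D array, a subset of `mask`.
#' @export
circular_open <- function(mask, radius, voxel_size) {
  check_voxel_size(voxel_size)
  if (radius < 0) abort("`radius` must be >= 0.")
  dims <- dim(mask)
  if (radius == 0 || !any(mask)) {
    out <- mask & TRUE
    dim(out) <- dims
    return(out)
  }
  sp <- spacing_yxz(voxel_size)
  # squared distance to background (kept squared: no sqrt round-trip)
  f0 <- ifelse(as.logical(mask), 1e20, 0)
  d2 <- .sq_dt3d(f0, as.integer(dims), sp)
  centers <- d2 > radius^2
  if (!any(centers)) return(array(FALSE, dims))
  # power distance min_c (|x - c|^2 - D(c)^2) over ball centers c;
  # negative values lie strictly inside some maximal inscribed ball. A voxel
  # sitting exactly on an inscribed-ball boundary is background by
  # construction, so ties (pow == 0 up to rounding) are excluded.
  f <- rep(1e20, prod(dims))
  f[centers] <- -d2[centers]
  pow <- .sq_dt3d(f, as.integer(dims), sp)
  out <- array(pow < -1e-7 * max(1, radius^2), dims)
  out
}

#' Separate touching objects by distance-transform watershed
#'
#' Computes the Euclidean distance transform of the mask in physical units
#' (anisotropy-aware), suppresses shallow maxima with an h-maxima transform
#' (depth `config$h_maxima` µm), and floods the mask from the resulting seeds
#' in order of decreasing distance. Every voxel of the mask is assigned to a
#' basin (fronts with larger distance win; ties resolve deterministically).
#'
#' @param mask logical 3D array.
#' @param voxel_size voxel spacing `(dx, dy, dz)` µm.
#' @param config a [segmentation_config()] (uses `h_maxima`).
#' @return A [label_volume()].
#' @export
separate_objects <- function(mask, voxel_size, config = segmentation_config()) {
  check_voxel_size(voxel_size)
  dims <- dim(mask)
  if (!any(mask)) {
    return(label_volume(array(0L, dims), voxel_size))
  }
  sp <- spacing_yxz(voxel_size)
  d <- .edt3d(as.logical(mask), as.integer(dims), sp)
  h <- config$h_maxima
  relief <- if (h > 0) {
    .reconstruct_dilation(pmax(d - h, 0), d, as.integer(dims))
  } else {
    d
  }
  mx <- .regional_maxima(relief, as.logical(mask), as.integer(dims))
  seeds <- .label_components(mx, as.integer(dims), 26L)
  lab <- .watershed_seeded(d, seeds, as.logical(mask), as.integer(dims))
  dim(lab) <- dims
  label_volume(lab, voxel_size)
}

#' Filter labelled objects by size and border contact
#'
#' Removes objects smaller than `config$min_volume` µm³ and (by default)
#' objects touching the grid boundary, then relabels survivors contiguously
#' from 1 preserving label order.
#'
#' @param labels a [label_volume()].
#' @param config a [segmentation_config()].
#' @return A filtered [label_volume()].
#' @export
filter_objects <- function(labels, config = segmentation_config()) {
  stopifnot(inherits(labels, "label_volume"))
  lab <- labels$labels
  nl <- max(lab)
  if (nl == 0L) return(labels)
  st <- .label_stats(as.integer(lab), as.integer(dim(lab)),
                     spacing_yxz(labels$voxel_size), nl)
  vol <- st[, 1] * voxel_volume(labels$voxel_size)
  keep <- st[, 1] > 0 & vol >= config$min_volume
  if (config$border_policy == "exclude_touching") keep <- keep & st[, 11] == 0
  lut <- integer(nl + 1L)
  lut[which(keep) + 1L] <- seq_len(sum(keep))
  out <- array(lut[lab + 1L], dim(lab))
  label_volume(out, labels$voxel_size, meta = labels$meta)
}

#' Segment an adipocyte volume end-to-end
#'
#' Composes crop, foreground extraction, circular open, object separation and
#' object filtering, recording voxel/object counts entering and leaving each
#' stage in a run log (attribute `"run_log"` of the result).
#'
#' @param image an [image_volume()] with a lipid channel.
#' @param config a [segmentation_config()].
#' @return A [label_volume()] with a `run_log` tibble attached as an
#'   attribute.
#' @export
segment_volume <- function(image, config = segmentation_config()) {
  stopifnot(inherits(image, "image_volume"))
  log_rows <- list()
  push <- function(stage, value) {
    log_rows[[length(log_rows) + 1L]] <<- tibble(stage = stage, value = value)
  }
  if (!is.null(config$crop_extent)) {
    image <- crop_volume(image, config$crop_extent, config$crop_origin)
    push("crop_voxels", prod(dim(image)))
  }
  vs <- image$voxel_size
  mask <- binarize(image, config)
  push("binarize_voxels", sum(mask))
  if (config$open_first && config$open_radius > 0) {
    mask <- circular_open(mask, config$open_radius, vs)
    push("circular_open_voxels", sum(mask))
  }
  labels <- separate_objects(mask, vs, config)
  push("separate_objects_count", n_objects(labels))
  if (!config$open_first && config$open_radius > 0) {
    lab <- labels$labels
    for (id in seq_len(max(lab))) {
      m <- lab == id
      if (!any(m)) next
      opened <- circular_open(array(m, dim(lab)), config$open_radius, vs)
      lab[m & !opened] <- 0L
    }
    labels <- label_volume(lab, vs, meta = labels$meta)
    push("circular_open_count", n_objects(labels))
  }
  labels <- filter_objects(labels, config)
  push("filter_objects_count", n_objects(labels))
  attr(labels, "run_log") <- dplyr::bind_rows(log_rows)
  labels
}

#' Sliding-window average of a z-stack
#'
#' Mean over a sliding window of `window` consecutive slices along z; output
#' depth is `depth - window + 1`. Window 1 is the identity.
#'
#' @param frames 3D array `[y, x, z]` or list of 2D matrices.
#' @param window window length in slices.
#' @return 3D array of averaged slices.
#' @export
zstack_average <- function(frames, window) {
  if (is.list(frames)) frames <- simplify2array(frames)
  dims <- dim(frames)
  if (window < 1) abort("`window` must be >= 1.")
  if (window > dims[3]) {
    abort(sprintf("`window` (%d) exceeds stack depth (%d).", window, dims[3]))
  }
  if (window == 1) return(frames)
  nout <- dims[3] - window + 1L
  out <- array(0, c(dims[1], dims[2], nout))
  for (i in seq_len(nout)) {
    out[, , i] <- rowMeans(array(frames[, , i:(i + window - 1)],
                                 c(dims[1] * dims[2], window)), dims = 1)
  }
  dim(out) <- c(dims[1], dims[2], nout)
  out
}
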