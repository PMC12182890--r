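#' Two-channel 3D image volume
#'
#' Container for a light-sheet acquisition (or synthetic phantom): one or two
#' intensity channels on a shared grid with physical voxel spacing. Channels
#' follow the staining convention of cleared adipose tissue: `lipid` (Nile
#' Red-like, bright adipocyte interiors) and `ecm` (5-DTAF-like, extracellular
#' matrix shell between cells).
#'
#' Arrays are stored `[y, x, z]` (each z-slice is a y-by-x matrix, the order in
#' which TIFF pages are read); all physical coordinates are reported `(x, y,
#' z)` in µm, with the origin at the center of the first voxel.
#'
#' @param lipid 3D numeric array, lipid channel.
#' @param ecm optional 3D numeric array, ECM channel (same shape).
#' @param voxel_size physical voxel spacing `(dx, dy, dz)` in µm.
#' @param meta optional named list of provenance metadata.
#' @return An `image_volume` object.
#' @export
image_volume <- function(lipid, ecm = NULL, voxel_size = c(1.62, 1.62, 4),
                         meta = list()) {
  check_voxel_size(voxel_size)
  if (length(dim(lipid)) != 3) abort("`lipid` must be a 3D array.")
  if (!is.null(ecm) && !identical(dim(ecm), dim(lipid))) {
    abort("All channels must share the same grid shape.")
  }
  channels <- list(lipid = lipid)
  if (!is.null(ecm)) channels$ecm <- ecm
  structure(
    list(channels = channels, voxel_size = as.numeric(voxel_size), meta = meta),
    class = "image_volume"
  )
}

#' Integer-labelled 3D volume
#'
#' Labels are positive integers identifying objects; 0 is background.
#'
#' @param labels 3D integer array.
#' @param voxel_size physical voxel spacing `(dx, dy, dz)` in µm.
#' @param meta optional named list of provenance metadata.
#' @return A `label_volume` object.
#' @export
label_volume <- function(labels, voxel_size = c(1.62, 1.62, 4), meta = list()) {
  check_voxel_size(voxel_size)
  if (length(dim(labels)) != 3) abort("`labels` must be a 3D array.")
  if (min(labels) < 0) abort("Labels must be non-negative integers.")
  storage.mode(labels) <- "integer"
  structure(
    list(labels = labels, voxel_size = as.numeric(voxel_size), meta = meta),
    class = "label_volume"
  )
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf(
    "<image_volume> %d x %d x %d voxels (x, y, z), %s, voxel %s µm\n",
    d[2], d[1], d[3], paste(names(x$channels), collapse = " + "),
    paste(sprintf("%g", x$voxel_size), collapse = " x ")
  ))
  invisible(x)
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf(
    "<label_volume> %d x %d x %d voxels (x, y, z), %d objects, voxel %s µm\n",
    d[2], d[1], d[3], n_objects(x),
    paste(sprintf("%g", x$voxel_size), collapse = " x ")
  ))
  invisible(x)
}

#' @export
dim.image_volume <- function(x) dim(x$channels[[1]])

#' @export
dim.label_volume <- function(x) dim(x$labels)

#' Number of distinct objects in a label volume
#' @param x a `label_volume`.
#' @return Integer count of nonzero labels.
#' @export
n_objects <- function(x) {
  labs <- if (inherits(x, "label_volume")) x$labels else x
  m <- max(labs)
  if (m == 0L) return(0L)
  sum(tabulate(labs, nbins = m) > 0L)
}

# accept an image_volume or a bare array for channel extraction
get_channel <- function(volume, channel = "lipid") {
  if (inherits(volume, "image_volume")) {
    ch <- volume$channels[[channel]]
    if (is.null(ch)) abort(sprintf("Volume has no `%s` channel.", channel))
    ch
  } else if (is.array(volume) && length(dim(volume)) == 3) {
    volume
  } else {
    abort("Expected an `image_volume` or a 3D array.")
  }
}

get_voxel_size <- function(x, voxel_size = NULL) {
  if (!is.null(voxel_size)) return(check_voxel_size(voxel_size))
  if (inherits(x, c("image_volume", "label_volume"))) return(x$voxel_size)
  abort("`voxel_size` must be supplied for bare arrays.")
}
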