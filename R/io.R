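#' Write an image volume to TIFF
#'
#' Each channel is written as a multi-page 32-bit float TIFF
#' (`<path>_<channel>.tif`); voxel spacing and provenance go to a JSON
#' sidecar (`<path>.json`) since baseline TIFF writers carry no physical
#' calibration.
#'
#' @param volume an [image_volume()].
#' @param path base path ending in `.tif`.
#' @return Invisibly, the paths written.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "image_volume"))
  base <- sub("\\.tiff?$", "", path)
  paths <- character(0)
  for (ch in names(volume$channels)) {
    arr <- volume$channels[[ch]]
    rng <- range(arr)
    scale <- if (rng[2] > rng[1]) rng[2] - rng[1] else 1
    pages <- lapply(seq_len(dim(arr)[3]), function(z) (arr[, , z] - rng[1]) / scale)
    p <- paste0(base, "_", ch, ".tif")
    tiff::writeTIFF(pages, p, bits.per.sample = 32, compression = "deflate")
    paths <- c(paths, p)
  }
  sidecar <- paste0(base, ".json")
  jsonlite::write_json(
    list(voxel_size = volume$voxel_size,
         channels = as.list(setNames(basename(paths), names(volume$channels))),
         ranges = lapply(volume$channels, function(a) range(a)),
         meta = volume$meta),
    sidecar, auto_unbox = TRUE, digits = NA
  )
  invisible(c(paths, sidecar))
}

# parse PhysicalSize attributes out of an OME-XML description, if any
parse_ome_spacing <- function(desc) {
  if (is.null(desc) || !grepl("<OME", desc, fixed = TRUE)) return(NULL)
  doc <- tryCatch(xml2::read_xml(desc), error = function(e) NULL)
  if (is.null(doc)) return(NULL)
  px <- xml2::xml_find_first(doc, "//*[local-name()='Pixels']")
  if (inherits(px, "xml_missing")) return(NULL)
  vals <- vapply(c("PhysicalSizeX", "PhysicalSizeY", "PhysicalSizeZ"),
                 function(a) suppressWarnings(as.numeric(xml2::xml_attr(px, a))),
                 numeric(1))
  if (any(is.na(vals)) || any(vals <= 0)) return(NULL)
  unname(vals)
}

#' Read an image volume from TIFF
#'
#' Voxel spacing is taken, in order of precedence, from `spacing_override`,
#' an OME-XML `PhysicalSize` description embedded in the TIFF, or the JSON
#' sidecar written by [write_volume()]. If none yields a spacing, an error is
#' raised.
#'
#' @param path path to a channel TIFF (e.g. `<base>_lipid.tif`) or the base
#'   path used with [write_volume()].
#' @param spacing_override voxel spacing `(dx, dy, dz)` µm.
#' @return An [image_volume()].
#' @export
read_volume <- function(path, spacing_override = NULL) {
  base <- sub("(_lipid|_ecm)?\\.tiff?$", "", path)
  sidecar <- paste0(base, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else NULL

  read_channel <- function(p, rng = NULL) {
    if (!file.exists(p)) return(NULL)
    pages <- tryCatch(tiff::readTIFF(p, all = TRUE, info = TRUE),
                      error = function(e) abort(sprintf("Cannot read TIFF `%s`: %s", p, e$message)))
    arr <- simplify2array(lapply(pages, unclass))
    if (!is.null(rng)) arr <- arr * (rng[2] - rng[1]) + rng[1]
    list(arr = arr, info = attributes(pages[[1]]))
  }

  if (!is.null(meta)) {
    chans <- lapply(names(meta$channels), function(ch) {
      rng <- as.numeric(unlist(meta$ranges[[ch]]))
      read_channel(file.path(dirname(path), meta$channels[[ch]]), rng)$arr
    })
    names(chans) <- names(meta$channels)
    spacing <- spacing_override %||% as.numeric(unlist(meta$voxel_size))
    return(image_volume(chans$lipid, chans$ecm, voxel_size = spacing,
                        meta = list(source = path)))
  }

  got <- read_channel(path)
  if (is.null(got)) abort(sprintf("File not found: %s", path))
  spacing <- spacing_override %||% parse_ome_spacing(got$info$description)
  if (is.null(spacing)) {
    abort(paste0("No voxel spacing available for `", path,
                 "`: no OME metadata, no sidecar, and no `spacing_override`."))
  }
  image_volume(got$arr, voxel_size = spacing, meta = list(source = path))
}

#' Write / read a label volume as 16-bit TIFF
#'
#' Labels are stored losslessly in 16 bits (object counts here are far below
#' 65535); voxel spacing goes to a JSON sidecar.
#'
#' @param labels a [label_volume()].
#' @param path path ending in `.tif`.
#' @return Invisibly, the paths written.
#' @export
write_labels <- function(labels, path) {
  stopifnot(inherits(labels, "label_volume"))
  lab <- labels$labels
  if (max(lab) > 65535) abort("More than 65535 labels; 16-bit storage would clip.")
  pages <- lapply(seq_len(dim(lab)[3]), function(z) lab[, , z] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16, compression = "deflate")
  sidecar <- sub("\\.tiff?$", ".json", path)
  jsonlite::write_json(list(voxel_size = labels$voxel_size, kind = "labels"),
                       sidecar, auto_unbox = TRUE, digits = NA)
  invisible(c(path, sidecar))
}

#' @rdname write_labels
#' @param spacing_override voxel spacing `(dx, dy, dz)` µm when no sidecar is
#'   present.
#' @export
read_labels <- function(path, spacing_override = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  lab <- round(simplify2array(lapply(pages, unclass)) * 65535)
  storage.mode(lab) <- "integer"
  sidecar <- sub("\\.tiff?$", ".json", path)
  spacing <- spacing_override %||% (
    if (file.exists(sidecar)) as.numeric(unlist(jsonlite::read_json(sidecar)$voxel_size)) else NULL
  )
  if (is.null(spacing)) abort("No voxel spacing available (no sidecar, no override).")
  label_volume(lab, voxel_size = spacing, meta = list(source = path))
}

#' Crop a volume to a physical box
#'
#' Voxel alignment: the starting index is `floor(origin / spacing)` and the
#' number of voxels per axis `floor(extent / spacing)`.
#'
#' @param volume an [image_volume()] or [label_volume()].
#' @param extent crop extent `(x, y, z)` in µm.
#' @param origin crop origin `(x, y, z)` in µm, default 0.
#' @return A cropped volume of the same class, with crop provenance in
#'   `meta`.
#' @export
crop_volume <- function(volume, extent, origin = c(0, 0, 0)) {
  vs <- volume$voxel_size
  dims <- dim(volume) # (y, x, z)
  avail <- dims[c(2, 1, 3)] # (x, y, z) voxels
  start <- floor(origin / vs)
  count <- floor(extent / vs)
  if (any(start < 0) || any(count < 1) || any(start + count > avail)) {
    abort(sprintf("Crop box %s exceeds volume box %s.",
                  fmt_box(origin, extent), fmt_box(c(0, 0, 0), avail * vs)))
  }
  ix <- (start[1] + 1):(start[1] + count[1])
  iy <- (start[2] + 1):(start[2] + count[2])
  iz <- (start[3] + 1):(start[3] + count[3])
  meta <- c(volume$meta, list(crop_origin = origin, crop_extent = extent))
  if (inherits(volume, "image_volume")) {
    chans <- lapply(volume$channels, function(a) a[iy, ix, iz, drop = FALSE])
    out <- image_volume(chans$lipid, chans$ecm, voxel_size = vs, meta = meta)
  } else {
    out <- label_volume(volume$labels[iy, ix, iz, drop = FALSE], voxel_size = vs,
                        meta = meta)
  }
  out
}

#' Write / read feature tables
#'
#' @param features an `adipo_features` tibble.
#' @param path CSV path.
#' @return `read_features` returns an `adipo_features` tibble.
#' @export
write_features <- function(features, path) {
  readr::write_csv(features, path)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  class(out) <- c("adipo_features", class(out))
  out
}
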