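#' Per-object volume
#'
#' Volume of every labelled object: voxel count times the physical voxel
#' volume `dx * dy * dz`.
#'
#' @param labels a [label_volume()] or integer 3D array.
#' @param voxel_size required for bare arrays.
#' @return Tibble with `label_id`, `n_voxels`, `volume` (µm³).
#' @export
measure_volume <- function(labels, voxel_size = NULL) {
  vs <- get_voxel_size(labels, voxel_size)
  lab <- if (inherits(labels, "label_volume")) labels$labels else labels
  nl <- max(lab)
  counts <- if (nl > 0) tabulate(lab[lab > 0L], nbins = nl) else integer(0)
  ids <- which(counts > 0)
  tibble(label_id = ids, n_voxels = counts[ids],
         volume = counts[ids] * voxel_volume(vs))
}

#' Equivalent diameter of a volume
#'
#' Diameter of the sphere with the same volume: `(6 V / pi)^(1/3)`.
#'
#' @param V volume(s) in µm³, strictly positive.
#' @return Equivalent diameter(s) in µm.
#' @export
equivalent_diameter <- function(V) {
  if (any(V <= 0)) abort("Volumes must be strictly positive.")
  (6 * V / pi)^(1 / 3)
}

#' Sphericity
#'
#' Ratio of the surface area of the volume-matched sphere to the object's
#' surface area, `pi^(1/3) * (6 V)^(2/3) / A`. A perfect sphere attains the
#' maximum value 1; values slightly above 1 can occur within meshing
#' tolerance. (Note the sphere surface is the numerator — the only orientation
#' for which the sphere is the maximum.)
#'
#' @param V volume(s), µm³.
#' @param A surface area(s), µm².
#' @return Dimensionless sphericity values.
#' @export
sphericity <- function(V, A) {
  if (any(V <= 0) || any(A <= 0, na.rm = TRUE)) {
    abort("`V` and `A` must be strictly positive.")
  }
  pi^(1 / 3) * (6 * V)^(2 / 3) / A
}

#' Per-object surface area by isosurface meshing
#'
#' For each object: extract its padded bounding box, Gaussian-smooth the
#' binary mask (sigma 1 voxel per axis), mesh the 0.5 isosurface with the
#' physical anisotropic spacing, and sum the triangle areas. Direct
#' voxel-face counting is avoided because it overestimates curved surfaces by
#' up to ~50%, which would corrupt sphericity.
#'
#' @param labels a [label_volume()] or integer 3D array.
#' @param voxel_size required for bare arrays.
#' @param smooth_sigma pre-smoothing sigma in voxels (per axis).
#' @return Tibble with `label_id`, `surface_area` (µm²; `NA` for objects too
#'   thin to mesh, which are reported in a message).
#' @export
measure_surface_area <- function(labels, voxel_size = NULL, smooth_sigma = 1) {
  vs <- get_voxel_size(labels, voxel_size)
  lab <- if (inherits(labels, "label_volume")) labels$labels else labels
  dims <- dim(lab)
  nl <- max(lab)
  if (nl == 0L) return(tibble(label_id = integer(0), surface_area = numeric(0)))
  st <- .label_stats(as.integer(lab), as.integer(dims), spacing_yxz(vs), nl)
  ids <- which(st[, 1] > 0)
  pad <- max(3L, ceiling(3 * smooth_sigma))
  areas <- rep(NA_real_, length(ids))
  too_thin <- integer(0)
  for (k in seq_along(ids)) {
    id <- ids[k]
    y0 <- st[id, 5] + 1; y1 <- st[id, 6] + 1
    x0 <- st[id, 7] + 1; x1 <- st[id, 8] + 1
    z0 <- st[id, 9] + 1; z1 <- st[id, 10] + 1
    if ((y1 - y0) < 1 || (x1 - x0) < 1 || (z1 - z0) < 1) {
      too_thin <- c(too_thin, id)
      next
    }
    sub <- lab[max(1, y0 - pad):min(dims[1], y1 + pad),
               max(1, x0 - pad):min(dims[2], x1 + pad),
               max(1, z0 - pad):min(dims[3], z1 + pad), drop = FALSE] == id
    sd3 <- dim(sub)
    num <- array(as.numeric(sub), sd3)
    if (smooth_sigma > 0) {
      num <- .gauss_blur3d(num, as.integer(sd3), rep(smooth_sigma, 3))
    }
    areas[k] <- .isosurface_area(num, as.integer(sd3), 0.5, spacing_yxz(vs))
  }
  if (length(too_thin) > 0) {
    inform(sprintf("Surface area undefined for %d object(s) thinner than 2 voxels on an axis: %s",
                   length(too_thin), paste(too_thin, collapse = ", ")))
  }
  tibble(label_id = ids, surface_area = areas)
}

#' Nearest object distance (NOD)
#'
#' Euclidean distance from each object's centroid ("center of gravity") to
#' the nearest other object's centroid.
#'
#' @param centroids matrix or data frame with columns `x`, `y`, `z` (µm).
#' @return Numeric vector of NOD values (µm), one per object.
#' @export
nearest_object_distance <- function(centroids) {
  if (is.data.frame(centroids)) {
    centroids <- as.matrix(centroids[, c("x", "y", "z")])
  }
  n <- nrow(centroids)
  if (n < 2) abort("NOD is undefined for fewer than 2 objects.")
  dm <- as.matrix(dist(centroids))
  diag(dm) <- Inf
  unname(apply(dm, 1, min))
}

#' Total object volume of a mask or label image
#'
#' Sum of all nonzero-voxel volumes; for a label image this equals the sum of
#' per-object volumes exactly.
#'
#' @param x logical mask, integer array, [label_volume()] or [image_volume()]
#'   channel.
#' @param voxel_size required for bare arrays.
#' @param channel channel to use when `x` is an [image_volume()] (the channel
#'   is binarized as `> 0`).
#' @return Total volume in µm³.
#' @export
total_object_volume <- function(x, voxel_size = NULL, channel = "lipid") {
  if (inherits(x, "image_volume")) {
    vs <- x$voxel_size
    arr <- x$channels[[channel]]
  } else {
    vs <- get_voxel_size(x, voxel_size)
    arr <- if (inherits(x, "label_volume")) x$labels else x
  }
  sum(arr > 0) * voxel_volume(vs)
}

#' Measure all per-adipocyte features
#'
#' One row per labelled object with the six standard measurements: volume V,
#' equivalent diameter, surface area A, sphericity, centroid (unweighted mean
#' of voxel centers, physical µm) and nearest-object distance. The object
#' count is the row count and the total object volume the sum of `volume`.
#'
#' @param labels a [label_volume()] or integer 3D array.
#' @param voxel_size required for bare arrays.
#' @param sample_id,group identifiers attached to every row.
#' @param surface if `FALSE`, skip surface meshing (surface area and
#'   sphericity become `NA`); useful when only volumes are needed.
#' @return An `adipo_features` tibble.
#' @export
measure_features <- function(labels, voxel_size = NULL, sample_id = NA_character_,
                             group = NA_character_, surface = TRUE) {
  vs <- get_voxel_size(labels, voxel_size)
  lab <- if (inherits(labels, "label_volume")) labels$labels else labels
  nl <- max(lab)
  if (nl == 0L) {
    out <- tibble(label_id = integer(0), n_voxels = integer(0), volume = numeric(0),
                  equiv_diameter = numeric(0), surface_area = numeric(0),
                  sphericity = numeric(0), x = numeric(0), y = numeric(0),
                  z = numeric(0), nod = numeric(0),
                  sample_id = character(0), group = character(0))
    class(out) <- c("adipo_features", class(out))
    return(out)
  }
  st <- .label_stats(as.integer(lab), as.integer(dim(lab)), spacing_yxz(vs), nl)
  ids <- which(st[, 1] > 0)
  counts <- st[ids, 1]
  out <- tibble(
    label_id = ids,
    n_voxels = as.integer(counts),
    volume = counts * voxel_volume(vs),
    x = st[ids, 2] / counts,
    y = st[ids, 3] / counts,
    z = st[ids, 4] / counts
  )
  out$equiv_diameter <- equivalent_diameter(out$volume)
  if (surface) {
    sa <- measure_surface_area(labels, vs)
    out <- dplyr::left_join(out, sa, by = "label_id")
    out$sphericity <- ifelse(is.na(out$surface_area), NA_real_,
                             sphericity(out$volume, pmax(out$surface_area, 1e-12)))
  } else {
    out$surface_area <- NA_real_
    out$sphericity <- NA_real_
  }
  out$nod <- if (nrow(out) >= 2) {
    nearest_object_distance(out[, c("x", "y", "z")])
  } else {
    NA_real_
  }
  out$sample_id <- sample_id
  out$group <- group
  out <- out[, c("label_id", "n_voxels", "volume", "equiv_diameter",
                 "surface_area", "sphericity", "x", "y", "z", "nod",
                 "sample_id", "group")]
  class(out) <- c("adipo_features", class(out))
  out
}

#' Measure every sample of a segmented study
#'
#' @param labelled named list of [label_volume()]s (names are sample ids).
#' @param groups named character vector mapping sample ids to groups.
#' @param ... passed to [measure_features()].
#' @return Combined `adipo_features` tibble.
#' @export
measure_study <- function(labelled, groups, ...) {
  out <- purrr::imap_dfr(labelled, function(lv, id) {
    measure_features(lv, sample_id = id, group = unname(groups[[id]]), ...)
  })
  class(out) <- c("adipo_features", class(out))
  out
}
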