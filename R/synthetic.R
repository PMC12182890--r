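#' Parameters of the synthetic tissue-phantom generator
#'
#' The generator emulates cleared mesenteric adipose tissue imaged by light
#' sheet microscopy: densely packed convex adipocytes (lipid channel bright
#' inside each cell), a thin extracellular-matrix shell between cells (ECM
#' channel), anisotropic optical blur, exponential depth attenuation of the
#' fluorescence signal, and Poisson-Gaussian (photon + read) camera noise.
#'
#' @param n_cells number of adipocytes to generate (>= 1).
#' @param domain_size physical extent `(x, y, z)` of the tissue block in µm.
#' @param volume_mean mean true cell volume, µm³.
#' @param volume_cv coefficient of variation of the volume distribution.
#'   Dimensionless; default 0.4, a dispersion giving the ~40-130 µm equivalent
#'   diameter range typical of rat visceral adipocytes.
#' @param volume_family `"lognormal"` (random draws) or
#'   `"quantile_matched_lognormal"` (values placed at evenly spaced quantiles
#'   and rescaled so the sample mean equals `volume_mean` exactly — used to
#'   calibrate cohorts to a prescribed mean).
#' @param ecm_gap minimum surface-to-surface clearance between cells, µm; the
#'   ECM shell fills this gap.
#' @param psf_sigma Gaussian blur sigmas `(x, y, z)` in µm emulating the
#'   system PSF (lateral ~2 µm for a 4x/0.35 objective; axial ~3 µm for a
#'   4 µm light sheet).
#' @param attenuation_length depth constant L in µm: signal is scaled by
#'   `exp(-z / L)`. `Inf` disables attenuation. Default 400 µm, matching a
#'   usable imaging depth of roughly 400 µm.
#' @param noise list with `photon_scale` (expected photons at unit intensity;
#'   larger is cleaner) and `read_sigma` (Gaussian read noise, photons).
#' @param voxel_size voxel spacing `(dx, dy, dz)` µm; default 1.62 x 1.62 x 4.
#' @param seed integer seed making the phantom fully reproducible.
#' @return A validated `generator_params` list.
#' @export
generator_params <- function(n_cells,
                             domain_size,
                             volume_mean = 250000,
                             volume_cv = 0.4,
                             volume_family = c("lognormal", "quantile_matched_lognormal"),
                             ecm_gap = 4,
                             psf_sigma = c(2, 2, 3),
                             attenuation_length = 400,
                             noise = list(photon_scale = 100, read_sigma = 2),
                             voxel_size = c(1.62, 1.62, 4),
                             seed = 1L) {
  volume_family <- match.arg(volume_family)
  if (n_cells < 1) abort("`n_cells` must be >= 1.")
  if (length(domain_size) != 3 || any(domain_size <= 0)) {
    abort("`domain_size` must be three positive extents (x, y, z) in µm.")
  }
  if (volume_mean <= 0) abort("`volume_mean` must be positive.")
  if (volume_cv < 0) abort("`volume_cv` must be >= 0.")
  if (ecm_gap < 0) abort("`ecm_gap` must be >= 0.")
  if (length(psf_sigma) != 3 || any(psf_sigma < 0)) {
    abort("`psf_sigma` must be three non-negative sigmas (x, y, z) in µm.")
  }
  if (attenuation_length <= 0) abort("`attenuation_length` must be positive (Inf allowed).")
  check_voxel_size(voxel_size)
  structure(
    list(
      n_cells = as.integer(n_cells),
      domain_size = as.numeric(domain_size),
      volume_mean = volume_mean,
      volume_cv = volume_cv,
      volume_family = volume_family,
      ecm_gap = ecm_gap,
      psf_sigma = as.numeric(psf_sigma),
      attenuation_length = attenuation_length,
      noise = noise,
      voxel_size = as.numeric(voxel_size),
      seed = as.integer(seed)
    ),
    class = "generator_params"
  )
}

#' Draw true adipocyte volumes
#'
#' Volumes follow a right-skewed lognormal law parameterized by mean and
#' coefficient of variation. The `quantile_matched_lognormal` family places
#' the `n_cells` values at evenly spaced quantiles `(i - 0.5) / n` of that
#' lognormal and rescales them so the sample mean equals `volume_mean` to
#' floating precision — the documented contract used to calibrate cohorts.
#'
#' @param params a [generator_params()] object.
#' @return Numeric vector of `n_cells` volumes in µm³.
#' @export
sample_true_volumes <- function(params) {
  stopifnot(inherits(params, "generator_params"))
  n <- params$n_cells
  m <- params$volume_mean
  cv <- params$volume_cv
  if (cv == 0) return(rep(m, n))
  sdlog <- sqrt(log(1 + cv^2))
  meanlog <- log(m) - sdlog^2 / 2
  if (params$volume_family == "quantile_matched_lognormal") {
    v <- qlnorm((seq_len(n) - 0.5) / n, meanlog, sdlog)
    v * (m / mean(v))
  } else {
    with_seed(params$seed, rlnorm(n, meanlog, sdlog))
  }
}

#' Pack adipocytes into the tissue domain
#'
#' Random sequential addition with rejection, inserting the largest spheres
#' first: each cell is a sphere whose radius derives from its true volume,
#' placed uniformly at random, accepted only if fully inside the domain (with
#' an `ecm_gap` margin from the walls, so every cell keeps its matrix shell)
#' and at surface-to-surface clearance `>= ecm_gap` from every accepted cell.
#' Deterministic given `params$seed`.
#'
#' @param volumes true volumes in µm³ (e.g. from [sample_true_volumes()]).
#' @param params a [generator_params()] object.
#' @param max_attempts placement attempts per cell before giving up.
#' @return Tibble of ground-truth cells: `label_id`, `true_volume`,
#'   `true_radius`, `x`, `y`, `z` (centroid, µm). Rows are ordered by
#'   `label_id`, assigned in insertion (largest-first) order.
#' @export
pack_adipocytes <- function(volumes, params, max_attempts = 20000) {
  stopifnot(inherits(params, "generator_params"))
  L <- params$domain_size
  frac <- sum(volumes) / prod(L)
  if (frac > 0.55) {
    abort(sprintf(
      "Packing density %.1f%% exceeds the 55%% random-sequential-addition feasibility bound.",
      100 * frac
    ))
  }
  radii <- (3 * volumes / (4 * pi))^(1 / 3)
  ord <- order(radii, decreasing = TRUE)
  radii <- radii[ord]
  vols <- volumes[ord]
  n <- length(radii)
  if (2 * max(radii) > min(L)) {
    abort("Largest cell diameter exceeds the domain extent; packing impossible.")
  }
  centers <- matrix(NA_real_, n, 3)
  gap <- params$ecm_gap
  with_seed(params$seed, {
    for (i in seq_len(n)) {
      r <- radii[i]
      # cells keep their ECM shell clear of the domain wall too
      lo <- r + gap
      hi <- L - r - gap
      if (any(hi < lo)) {
        abort(sprintf("Cell of radius %.1f µm cannot fit inside the domain.", r))
      }
      placed <- FALSE
      for (a in seq_len(max_attempts)) {
        p <- lo + stats::runif(3) * (hi - lo)
        if (i == 1) { ok <- TRUE } else {
          prev <- centers[seq_len(i - 1), , drop = FALSE]
          dd <- sqrt((prev[, 1] - p[1])^2 + (prev[, 2] - p[2])^2 + (prev[, 3] - p[3])^2)
          ok <- all(dd >= radii[seq_len(i - 1)] + r + gap)
        }
        if (ok) { centers[i, ] <- p; placed <- TRUE; break }
      }
      if (!placed) {
        achieved <- sum(vols[seq_len(i - 1)]) / prod(L)
        abort(sprintf(
          "Packing failed at cell %d/%d after %d attempts (achieved packing fraction %.1f%%).",
          i, n, max_attempts, 100 * achieved
        ))
      }
    }
  })
  tibble(
    label_id = seq_len(n),
    true_volume = vols,
    true_radius = radii,
    x = centers[, 1], y = centers[, 2], z = centers[, 3]
  )
}

#' Render a packed cell configuration into a two-channel phantom
#'
#' Rasterizes each sphere into the ground-truth label grid, builds the clean
#' optical scene (lipid: bright cell interiors; ECM: shell of thickness
#' `ecm_gap` around cells), then applies anisotropic Gaussian blur
#' (`psf_sigma`), exponential depth attenuation `exp(-z / attenuation_length)`
#' and Poisson-Gaussian noise. Noise is seeded from `params$seed`.
#'
#' @param cells tibble from [pack_adipocytes()].
#' @param params a [generator_params()] object.
#' @return A `tissue_phantom`: list with `image` ([image_volume()]), `labels`
#'   ([label_volume()]), `cells` (ground truth tibble) and `params`.
#' @export
render_tissue <- function(cells, params) {
  stopifnot(inherits(params, "generator_params"))
  vs <- params$voxel_size
  L <- params$domain_size
  dims <- c(floor(L[2] / vs[2]), floor(L[1] / vs[1]), floor(L[3] / vs[3])) + 1L # (y, x, z)
  if (nrow(cells) > 0 && min(cells$true_radius) < max(vs)) {
    warn(sprintf(
      "Voxel spacing (max %g µm) is coarser than the smallest cell radius (%.1f µm); features will be poorly resolved.",
      max(vs), min(cells$true_radius)
    ))
  }
  sp <- spacing_yxz(vs)
  lab <- .raster_spheres(as.integer(dims), sp,
                         as.matrix(cells[, c("x", "y", "z")]), cells$true_radius)
  dim(lab) <- dims
  fg <- lab > 0L
  lipid <- array(as.numeric(fg), dims)

  # ECM shell: background voxels within ecm_gap of any cell surface
  ecm <- array(0, dims)
  if (params$ecm_gap > 0) {
    d_out <- .edt3d(!fg, as.integer(dims), sp)
    ecm[!fg & d_out <= params$ecm_gap] <- 1
  }

  sigma_vox <- params$psf_sigma / vs           # (x, y, z) voxels
  sig <- sigma_vox[c(2, 1, 3)]                 # (y, x, z)
  blur <- function(a) {
    if (all(sig <= 0)) return(a)
    array(.gauss_blur3d(as.numeric(a), as.integer(dims), sig), dims)
  }
  lipid <- blur(lipid)
  ecm <- blur(ecm)

  if (is.finite(params$attenuation_length)) {
    att <- exp(-(seq_len(dims[3]) - 1) * vs[3] / params$attenuation_length)
    att <- rep(att, each = dims[1] * dims[2])
    lipid <- lipid * att
    ecm <- ecm * att
    dim(lipid) <- dims
    dim(ecm) <- dims
  }

  ps <- params$noise$photon_scale %||% 0
  rs <- params$noise$read_sigma %||% 0
  if (ps > 0 || rs > 0) {
    with_seed(params$seed + 1L, {
      shoot <- function(a) {
        if (ps > 0) a <- rpois(length(a), ps * pmax(a, 0)) / ps
        if (rs > 0 && ps > 0) a <- a + rnorm(length(a), sd = rs / ps)
        if (rs > 0 && ps == 0) a <- a + rnorm(length(a), sd = rs)
        array(a, dims)
      }
      lipid <- shoot(lipid)
      ecm <- shoot(ecm)
    })
  }

  structure(
    list(
      image = image_volume(lipid, ecm, voxel_size = vs,
                           meta = list(seed = params$seed)),
      labels = label_volume(lab, voxel_size = vs, meta = list(ground_truth = TRUE)),
      cells = cells,
      params = params
    ),
    class = "tissue_phantom"
  )
}

#' @export
print.tissue_phantom <- function(x, ...) {
  cat(sprintf("<tissue_phantom> %d cells, domain %s µm, seed %d\n",
              nrow(x$cells),
              paste(sprintf("%g", x$params$domain_size), collapse = " x "),
              x$params$seed))
  invisible(x)
}

#' Generate a single phantom from generator parameters
#'
#' Convenience wrapper chaining [sample_true_volumes()], [pack_adipocytes()]
#' and [render_tissue()].
#'
#' @param params a [generator_params()] object.
#' @return A `tissue_phantom`.
#' @export
simulate_tissue <- function(params) {
  render_tissue(pack_adipocytes(sample_true_volumes(params), params), params)
}

#' Study layout: groups x samples x cells per sample
#'
#' The default layout mirrors a two-condition rodent obesity study: 2 groups
#' (healthy, obese) of 3 animals each, 450 analyzed adipocytes per animal,
#' i.e. 1350 cells per group.
#'
#' @param groups character vector of unique group labels.
#' @param samples_per_group samples (animals) per group.
#' @param cells_per_sample adipocytes per sample.
#' @return A `study_design` list.
#' @export
study_design <- function(groups = c("healthy", "obese"),
                         samples_per_group = 3,
                         cells_per_sample = 450) {
  if (anyDuplicated(groups)) abort("Group labels must be unique.")
  if (samples_per_group < 1 || cells_per_sample < 1) {
    abort("`samples_per_group` and `cells_per_sample` must be >= 1.")
  }
  structure(
    list(groups = as.character(groups),
         samples_per_group = as.integer(samples_per_group),
         cells_per_sample = as.integer(cells_per_sample)),
    class = "study_design"
  )
}

#' Generate a full multi-sample synthetic study
#'
#' One phantom per sample, with sample-specific seeds derived deterministically
#' from `master_seed`. When `out_dir` is given, volumes, labels and ground
#' truth are written there along with a machine-readable manifest.
#'
#' @param design a [study_design()].
#' @param params_per_group named list mapping each group label to its
#'   [generator_params()] (the per-group `n_cells` and `seed` fields are
#'   overridden by the design and master seed).
#' @param master_seed integer master seed.
#' @param out_dir optional output directory.
#' @return List with `phantoms` (named list of `tissue_phantom`s) and
#'   `manifest` (tibble: group, sample_id, seed, n_cells and file paths when
#'   written).
#' @export
generate_study <- function(design, params_per_group, master_seed = 1L,
                           out_dir = NULL) {
  stopifnot(inherits(design, "study_design"))
  missing_groups <- setdiff(design$groups, names(params_per_group))
  if (length(missing_groups) > 0) {
    abort(sprintf("No generator params supplied for group(s): %s.",
                  paste(missing_groups, collapse = ", ")))
  }
  grid <- tidyr::expand_grid(group = design$groups,
                             sample = seq_len(design$samples_per_group))
  grid$sample_id <- paste0(grid$group, "_s", grid$sample)
  if (anyDuplicated(grid$sample_id)) abort("Duplicate sample ids in design.")
  phantoms <- vector("list", nrow(grid))
  names(phantoms) <- grid$sample_id
  manifest <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    p <- params_per_group[[grid$group[i]]]
    p$n_cells <- design$cells_per_sample
    p$seed <- derive_seed(master_seed, i)
    ph <- simulate_tissue(p)
    phantoms[[i]] <- ph
    row <- tibble(group = grid$group[i], sample_id = grid$sample_id[i],
                  seed = p$seed, n_cells = nrow(ph$cells))
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      base <- file.path(out_dir, grid$sample_id[i])
      write_volume(ph$image, paste0(base, ".tif"))
      write_labels(ph$labels, paste0(base, "_labels.tif"))
      readr::write_csv(ph$cells, paste0(base, "_truth.csv"))
      row$image_path <- paste0(base, "_lipid.tif")
      row$labels_path <- paste0(base, "_labels.tif")
      row$truth_path <- paste0(base, "_truth.csv")
    }
    manifest[[i]] <- row
  }
  manifest <- dplyr::bind_rows(manifest)
  if (!is.null(out_dir)) {
    readr::write_csv(manifest, file.path(out_dir, "manifest.csv"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  list(phantoms = phantoms, manifest = manifest)
}

#' Ground truth of a study as one tidy table
#'
#' @param study result of [generate_study()].
#' @return Tibble with one row per ground-truth cell, carrying `group` and
#'   `sample_id`.
#' @export
study_ground_truth <- function(study) {
  purrr::map2_dfr(study$phantoms, names(study$phantoms), function(ph, id) {
    g <- study$manifest$group[study$manifest$sample_id == id]
    dplyr::mutate(ph$cells, sample_id = id, group = g)
  })
}
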