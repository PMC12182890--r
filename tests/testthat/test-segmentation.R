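test_that("otsu threshold separates a two-mode histogram", {
  set.seed(1)
  x <- c(rep(10, 500), rep(200, 500))
  thr <- otsu_threshold(x)
  expect_gt(thr, 10)
  expect_lt(thr, 200)
  # exhaustive search over candidate thresholds maximizing between-class variance
  cands <- seq(min(x), max(x), length.out = 512)
  bcv <- sapply(cands, function(t) {
    w0 <- mean(x <= t)
    if (w0 %in% c(0, 1)) return(-Inf)
    w0 * (1 - w0) * (mean(x[x <= t]) - mean(x[x > t]))^2
  })
  best <- cands[which.max(bcv)]
  expect_identical(x > thr, x > best)
  expect_error(otsu_threshold(rep(3, 100)), "histogram")
})

test_that("binarize recovers a noise-free sphere and rejects empty scenes", {
  sph <- raster_sphere_array(c(60, 60, 60), c(30, 30, 30), 20)
  img <- image_volume(array(as.numeric(sph), dim(sph)) + 0.01,
                      voxel_size = c(1, 1, 1))
  cfg <- segmentation_config(depth_normalize = FALSE)
  mask <- binarize(img, cfg)
  expect_equal(sum(mask), sum(sph), tolerance = 0.03)
  # all-background region with a fixed threshold gives an empty mask
  flat <- image_volume(array(runif(8000, 0, 0.1), c(20, 20, 20)),
                       voxel_size = c(1, 1, 1))
  cfg2 <- segmentation_config(threshold_method = "fixed", fixed_threshold = 0.5,
                              depth_normalize = FALSE)
  expect_false(any(binarize(flat, cfg2)))
})

test_that("binarize fills interior holes", {
  a <- array(FALSE, c(20, 20, 20))
  a[5:15, 5:15, 5:15] <- TRUE
  a[9:11, 9:11, 9:11] <- FALSE # enclosed cavity
  img <- image_volume(array(as.numeric(a), dim(a)), voxel_size = c(1, 1, 1))
  cfg <- segmentation_config(threshold_method = "fixed", fixed_threshold = 0.5,
                             depth_normalize = FALSE)
  mask <- binarize(img, cfg)
  expect_true(all(mask[5:15, 5:15, 5:15]))
  expect_identical(sum(mask), 1331L)
})

test_that("circular open matches brute force and its lattice properties", {
  # sphere r=6 voxels with an attached 3-voxel-wide tube; radius-4 opening
  # removes the tube and keeps the sphere body (exhaustive all-pairs oracle)
  vs <- c(1, 1, 1)
  small <- raster_sphere_array(c(20, 34, 20), c(10, 10, 10), 6)
  small[10:12, 16:32, 10:12] <- TRUE
  expect_identical(circular_open(small, 4, vs), brute_ball_open(small, 4, vs))
  expect_identical(circular_open(small, 2, vs), brute_ball_open(small, 2, vs))

  # larger fixture: tube removed, sphere body retained
  mask <- raster_sphere_array(c(30, 46, 30), c(15, 15, 15), 10)
  mask[14:16, 25:44, 14:16] <- TRUE
  opened <- circular_open(mask, 4, vs)
  expect_true(all(opened[mask & raster_sphere_array(c(30, 46, 30), c(15, 15, 15), 5)]))
  expect_false(any(opened[, 30:46, ]))

  # identity at radius 0; anti-extensive; idempotent; monotone in radius
  expect_identical(circular_open(mask, 0, vs), mask & TRUE)
  expect_true(all(mask[opened]))
  expect_identical(circular_open(opened, 4, vs), opened)
  o6 <- circular_open(mask, 6, vs)
  expect_true(all(opened[o6]))

  # anisotropy awareness: a 4-voxel-thick slab at dz = 4 µm survives a 6 µm
  # opening only because the z extent is 16 µm, not 4 voxels x 1 µm
  slab <- array(FALSE, c(20, 20, 12))
  slab[3:18, 3:18, 5:8] <- TRUE
  expect_gt(sum(circular_open(slab, 6, c(1.62, 1.62, 4))), 0)
  expect_identical(sum(circular_open(slab, 6, c(1, 1, 1))), 0L)
})

test_that("separate objects splits touching spheres at their true centers", {
  # two r=20 µm spheres, centers 36 µm apart: overlapping union, 2 labels
  dims <- c(50, 90, 50)
  a <- raster_sphere_array(dims, c(25, 25, 25), 20) |
    raster_sphere_array(dims, c(61, 25, 25), 20)
  lv <- separate_objects(a, c(1, 1, 1), segmentation_config(h_maxima = 4))
  expect_identical(n_objects(lv), 2L)
  # full coverage of the mask
  expect_gte(sum(lv$labels > 0) / sum(a), 0.99)
  f <- measure_features(lv, surface = FALSE)
  cents <- as.matrix(f[order(f$x), c("x", "y", "z")])
  expect_lt(sqrt(sum((cents[1, ] - c(25, 25, 25))^2)), 2)
  expect_lt(sqrt(sum((cents[2, ] - c(61, 25, 25))^2)), 2)

  # a single convex sphere stays one label; empty masks give zero labels
  single <- raster_sphere_array(c(40, 40, 40), c(20, 20, 20), 15)
  expect_identical(n_objects(separate_objects(single, c(1, 1, 1))), 1L)
  empty <- array(FALSE, c(10, 10, 10))
  expect_identical(n_objects(separate_objects(empty, c(1, 1, 1))), 0L)
})

test_that("object filtering enforces size and border policies", {
  lab <- array(0L, c(30, 30, 30))
  lab[10:20, 10:20, 10:20] <- 1L          # interior, 1331 voxels
  lab[1:5, 1:5, 1:5] <- 2L                # touches the boundary
  lv <- label_volume(lab, c(5, 5, 5))     # voxel volume 125 µm³
  keep_all <- filter_objects(lv, segmentation_config(min_volume = 0,
                                                     border_policy = "keep"))
  expect_identical(keep_all$labels, lv$labels)
  no_border <- filter_objects(lv, segmentation_config(min_volume = 0))
  expect_identical(n_objects(no_border), 1L)
  expect_identical(sort(unique(as.integer(no_border$labels))), c(0L, 1L))

  # three objects of 5k / 50k / 500k µm³ with min_volume = 10k -> 2 remain
  lab2 <- array(0L, c(40, 40, 40))
  lab2[2:6, 2:9, 2:2] <- 1L
  lab2[20:24, 20:29, 20:27] <- 2L
  lab2[30:39, 2:21, 25:39] <- 3L
  lv2 <- label_volume(lab2, c(5, 5, 5))
  vols <- measure_volume(lv2)$volume
  expect_identical(sum(vols < 10000), 1L)
  kept <- filter_objects(lv2, segmentation_config(min_volume = 10000,
                                                  border_policy = "keep"))
  expect_identical(n_objects(kept), 2L)
})

test_that("the composed classical segmentation recovers phantom cells", {
  p <- tiny_params(5, seed = 31)
  ph <- simulate_tissue(p)
  lab <- segment_volume(ph$image, segmentation_config())
  expect_identical(n_objects(lab), 5L)
  f <- measure_features(lab, surface = FALSE)
  gt <- ph$cells
  for (i in seq_len(nrow(f))) {
    dmin <- min(sqrt((gt$x - f$x[i])^2 + (gt$y - f$y[i])^2 + (gt$z - f$z[i])^2))
    expect_lt(dmin, 3)
  }
  log <- attr(lab, "run_log")
  expect_true(all(c("binarize_voxels", "filter_objects_count") %in% log$stage))

  # min_volume above every cell volume empties the result
  lab0 <- segment_volume(ph$image, segmentation_config(min_volume = 1e9))
  expect_identical(n_objects(lab0), 0L)

  # determinism of the classical backend
  lab2 <- segment_volume(ph$image, segmentation_config())
  expect_identical(lab$labels, lab2$labels)
})

test_that("end-to-end recovery matches >= 95% of interior cells on a default phantom", {
  p <- generator_params(n_cells = 50, domain_size = c(600, 600, 220),
                        volume_mean = 2e5, volume_cv = 0.4,
                        volume_family = "quantile_matched_lognormal",
                        voxel_size = c(3.24, 3.24, 4), seed = 17)
  ph <- simulate_tissue(p)
  lab <- segment_volume(ph$image, segmentation_config())
  f <- measure_features(lab, surface = FALSE)
  expect_gt(nrow(f), 0.9 * 50)
  expect_lt(abs(nrow(f) - 50), 0.05 * 50 + 1e-9) # count within ±5%
  gt <- ph$cells
  matched <- 0
  for (i in seq_len(nrow(gt))) {
    dmin <- min(sqrt((f$x - gt$x[i])^2 + (f$y - gt$y[i])^2 + (f$z - gt$z[i])^2))
    if (dmin <= 5) matched <- matched + 1
  }
  expect_gte(matched, 0.95 * nrow(gt))
})

test_that("z-stack averaging has the documented window arithmetic", {
  stack <- array(rnorm(6 * 5 * 9), c(6, 5, 9))
  expect_identical(zstack_average(stack, 1), stack)
  const <- array(3, c(4, 4, 6))
  expect_equal(zstack_average(const, 5), array(3, c(4, 4, 2)))
  out <- zstack_average(stack, 5)
  expect_identical(dim(out), c(6L, 5L, 5L))
  expect_equal(out[2, 3, 1], mean(stack[2, 3, 1:5]))
  expect_error(zstack_average(stack, 10), "depth")
})

test_that("the learned backend trains with decreasing loss and segments well", {
  expect_error(train_learned_backend(list(), rounds = c(0, 0)), "round")
  p <- generator_params(n_cells = 4, domain_size = c(200, 200, 120),
                        volume_mean = 1.5e5, volume_cv = 0.2,
                        volume_family = "quantile_matched_lognormal",
                        noise = list(photon_scale = 0, read_sigma = 0),
                        voxel_size = c(3.24, 3.24, 4), seed = 8)
  ph <- simulate_tissue(p)
  model <- train_learned_backend(ph, rounds = c(50), seed = 2)
  expect_lt(tail(model$loss$loss, 1), model$loss$loss[1])
  cfg <- segmentation_config(backend = "learned", learned_model = model)
  mask <- binarize(ph$image, cfg)
  expect_gt(dice_coef(mask, ph$labels$labels > 0), 0.8)
  expect_error(segmentation_config(backend = "learned"), "train_learned_backend")
})
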