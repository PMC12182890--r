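test_that("volume measurement is voxel count times voxel volume", {
  lab <- array(0L, c(3, 3, 3))
  lab[2, 2, 2] <- 1L
  v <- measure_volume(label_volume(lab, c(1.62, 1.62, 4)))
  expect_equal(v$volume, 10.4976)

  cube <- array(1L, c(10, 10, 10))
  expect_equal(measure_volume(label_volume(cube, c(1, 1, 1)))$volume, 1000)

  sph <- raster_sphere_array(c(110, 110, 110), c(54, 54, 54), 40)
  v40 <- measure_volume(label_volume(array(as.integer(sph), dim(sph)), c(1, 1, 1)))
  expect_equal(v40$volume, 268082.57, tolerance = 0.03)
})

test_that("equivalent diameter follows the matching-sphere closed form", {
  expect_equal(equivalent_diameter(523598.776), 100, tolerance = 1e-6)
  expect_equal(equivalent_diameter(1), (6 / pi)^(1 / 3))
  expect_equal(equivalent_diameter(1), 1.2407, tolerance = 1e-4)
  expect_equal(equivalent_diameter(299242), 82.99, tolerance = 1e-3)
  expect_error(equivalent_diameter(c(10, 0)), "positive")
})

test_that("surface area meshing tracks analytic areas for canonical solids", {
  sph <- raster_sphere_array(c(50, 50, 50), c(24, 24, 24), 20)
  a <- measure_surface_area(label_volume(array(as.integer(sph), dim(sph)), c(1, 1, 1)))
  expect_equal(a$surface_area, 4 * pi * 20^2, tolerance = 0.03)

  cube <- raster_cube_array(40)
  ac <- measure_surface_area(label_volume(array(as.integer(cube), dim(cube)), c(1, 1, 1)))
  expect_equal(ac$surface_area, 9600, tolerance = 0.05)

  # anisotropic stress: same 20 µm sphere on a 1.62 x 1.62 x 4 µm grid
  sph_a <- raster_sphere_array(c(40, 40, 16), c(30, 30, 28), 20, c(1.62, 1.62, 4))
  aa <- measure_surface_area(label_volume(array(as.integer(sph_a), dim(sph_a)),
                                          c(1.62, 1.62, 4)))
  expect_equal(aa$surface_area, 4 * pi * 20^2, tolerance = 0.08)
})

test_that("sphericity attains 1 for spheres and the closed forms for cubes/spheroids", {
  r <- 20
  expect_equal(sphericity(4 / 3 * pi * r^3, 4 * pi * r^2), 1)
  a <- 7
  expect_equal(sphericity(a^3, 6 * a^2), (pi / 6)^(1 / 3))
  # prolate spheroid semi-axes (20, 20, 40) µm: analytic area oracle
  ax <- 20; cz <- 40
  e <- sqrt(1 - ax^2 / cz^2)
  area <- 2 * pi * ax^2 * (1 + (cz / (ax * e)) * asin(e))
  vol <- 4 / 3 * pi * ax^2 * cz
  expect_equal(sphericity(vol, area), 0.929, tolerance = 1e-3)
  expect_error(sphericity(-1, 10), "positive")

  # sphere maximality among equal-volume meshed fixtures
  sph <- raster_sphere_array(c(50, 50, 50), c(24, 24, 24), 20)
  lv_s <- label_volume(array(as.integer(sph), dim(sph)), c(1, 1, 1))
  psi_s <- with(measure_features(lv_s), sphericity)
  side <- round((4 / 3 * pi * 20^3)^(1 / 3))
  cube <- raster_cube_array(side)
  lv_c <- label_volume(array(as.integer(cube), dim(cube)), c(1, 1, 1))
  psi_c <- with(measure_features(lv_c), sphericity)
  el <- array(FALSE, c(30, 30, 50))                            # prolate spheroid
  for (iz in 1:50) {
    el[, , iz] <- outer((1:30) - 15, (1:30) - 15,
                        function(y, x) (x / 10)^2 + (y / 10)^2) +
      ((iz - 25) / 20)^2 <= 1
  }
  lv_e <- label_volume(array(as.integer(el), dim(el)), c(1, 1, 1))
  psi_e <- with(measure_features(lv_e), sphericity)
  expect_gt(psi_s, psi_c)
  expect_gt(psi_s, psi_e)
})

test_that("nearest object distance matches brute-force all-pairs", {
  expect_equal(nearest_object_distance(cbind(x = c(0, 10), y = 0, z = 0)), c(10, 10))
  pts <- rbind(c(0, 0, 0), c(3, 4, 0), c(10, 0, 0))
  colnames(pts) <- c("x", "y", "z")
  expect_equal(nearest_object_distance(pts), c(5, 5, sqrt(49 + 16)), tolerance = 1e-9)
  expect_equal(nearest_object_distance(pts)[3], 8.062, tolerance = 1e-3)
  expect_error(nearest_object_distance(pts[1, , drop = FALSE]), "fewer than 2")
})

test_that("total object volume is conserved and matches the analytic ECM shell", {
  expect_equal(total_object_volume(array(FALSE, c(5, 5, 5)), c(1, 1, 1)), 0)
  lab <- array(0L, c(10, 10, 10)); lab[2:4, 2:4, 2:4] <- 1L; lab[7:9, 7:9, 7:9] <- 2L
  lv <- label_volume(lab, c(2, 2, 2))
  expect_identical(total_object_volume(lv), sum(measure_volume(lv)$volume))

  # noise-free phantom: ECM shell volume vs analytic shell of thickness g
  g <- 6
  p <- generator_params(5, c(260, 260, 140), volume_mean = 1.3e5, volume_cv = 0,
                        ecm_gap = g, psf_sigma = c(0, 0, 0),
                        attenuation_length = Inf,
                        noise = list(photon_scale = 0, read_sigma = 0),
                        voxel_size = c(2, 2, 2), seed = 12)
  ph <- simulate_tissue(p)
  ecm_vol <- total_object_volume(ph$image, channel = "ecm")
  r <- ph$cells$true_radius
  analytic <- sum(4 / 3 * pi * ((r + g)^3 - r^3))
  expect_equal(ecm_vol, analytic, tolerance = 0.10)
})

test_that("measure_features is internally consistent and matches ground truth", {
  p <- tiny_params(5, seed = 13)
  ph <- simulate_tissue(p)
  f <- measure_features(ph$labels, sample_id = "s", group = "g")
  expect_identical(nrow(f), 5L)
  expect_equal(f$equiv_diameter, (6 * f$volume / pi)^(1 / 3), tolerance = 1e-9)
  expect_equal(f$volume, ph$cells$true_volume[match(f$label_id, ph$cells$label_id)],
               tolerance = 0.03)
  expect_equal(sum(f$volume), total_object_volume(ph$labels), tolerance = 1e-12)
  # centroids within a voxel of the true centers
  expect_true(all(abs(f$x - ph$cells$x) < 3.24))

  # two objects: both NOD values equal their centroid distance
  lab <- array(0L, c(20, 40, 20))
  lab[8:12, 5:9, 8:12] <- 1L
  lab[8:12, 30:34, 8:12] <- 2L
  f2 <- measure_features(label_volume(lab, c(1, 1, 1)), surface = FALSE)
  d12 <- sqrt(sum((as.matrix(f2[1, c("x", "y", "z")]) -
                   as.matrix(f2[2, c("x", "y", "z")]))^2))
  expect_equal(f2$nod, rep(d12, 2))
})

test_that("whole-voxel translation shifts centroids and preserves shape features", {
  sph <- raster_sphere_array(c(60, 60, 40), c(20, 20, 16), 12, c(1, 1, 2))
  base <- array(0L, dim(sph)); base[sph] <- 1L
  shifted <- array(0L, dim(sph))
  shifted[(1:60) > 5, (1:60) > 7, (1:40) > 3] <- base[1:55, 1:53, 1:37]
  f1 <- measure_features(label_volume(base, c(1, 1, 2)))
  f2 <- measure_features(label_volume(shifted, c(1, 1, 2)))
  expect_equal(f2$volume, f1$volume)
  expect_equal(f2$surface_area, f1$surface_area, tolerance = 1e-9)
  expect_equal(f2$sphericity, f1$sphericity, tolerance = 1e-9)
  expect_equal(c(f2$x - f1$x, f2$y - f1$y, f2$z - f1$z), c(7 * 1, 5 * 1, 3 * 2))
})

test_that("scaling a shape scales V by s^3 and A by s^2, leaving sphericity fixed", {
  small <- raster_sphere_array(c(30, 30, 30), c(14, 14, 14), 10)
  big <- raster_sphere_array(c(60, 60, 60), c(28, 28, 28), 20)
  fs <- measure_features(label_volume(array(as.integer(small), dim(small)), c(1, 1, 1)))
  fb <- measure_features(label_volume(array(as.integer(big), dim(big)), c(1, 1, 1)))
  expect_equal(fb$volume / fs$volume, 8, tolerance = 0.02)
  expect_equal(fb$surface_area / fs$surface_area, 4, tolerance = 0.03)
  expect_equal(fb$sphericity, fs$sphericity, tolerance = 0.02)
})
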