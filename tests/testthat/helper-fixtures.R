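# fixture builders shared across tests; everything generated in code

# binary array [y, x, z] of a sphere given center (x, y, z) and radius, all
# in voxel units on an isotropic-or-not grid with spacing (dx, dy, dz) µm
raster_sphere_array <- function(dims_yxz, center_xyz, radius, voxel_size = c(1, 1, 1)) {
  ny <- dims_yxz[1]; nx <- dims_yxz[2]; nz <- dims_yxz[3]
  xs <- (seq_len(nx) - 1) * voxel_size[1]
  ys <- (seq_len(ny) - 1) * voxel_size[2]
  zs <- (seq_len(nz) - 1) * voxel_size[3]
  dx2 <- outer(ys - center_xyz[2], xs - center_xyz[1],
               function(y, x) x^2 + y^2)
  out <- array(FALSE, dims_yxz)
  for (iz in seq_len(nz)) {
    out[, , iz] <- dx2 + (zs[iz] - center_xyz[3])^2 <= radius^2
  }
  out
}

raster_cube_array <- function(side_vox, pad = 10) {
  n <- side_vox + 2 * pad
  a <- array(FALSE, c(n, n, n))
  a[(pad + 1):(pad + side_vox), (pad + 1):(pad + side_vox),
    (pad + 1):(pad + side_vox)] <- TRUE
  a
}

# small quickly-rendered phantom parameters
tiny_params <- function(n_cells = 10, seed = 1, volume_mean = 150000, ...) {
  generator_params(
    n_cells = n_cells, domain_size = c(300, 300, 160),
    volume_mean = volume_mean, volume_cv = 0.3,
    volume_family = "quantile_matched_lognormal",
    voxel_size = c(3.24, 3.24, 4), seed = seed, ...
  )
}

# brute-force ball opening: union of all inscribed euclidean balls of radius
# greater than `radius`, with every distance computed by exhaustive all-pairs
# search in physical coordinates
brute_ball_open <- function(mask, radius, voxel_size) {
  dims <- dim(mask)
  phys <- function(ind) cbind((ind[, 2] - 1) * voxel_size[1],  # x
                              (ind[, 1] - 1) * voxel_size[2],  # y
                              (ind[, 3] - 1) * voxel_size[3])  # z
  p_fg <- phys(which(mask, arr.ind = TRUE))
  p_bg <- phys(which(!mask, arr.ind = TRUE))
  cross_d2 <- function(a, b) {
    outer(rowSums(a^2), rep(1, nrow(b))) +
      outer(rep(1, nrow(a)), rowSums(b^2)) - 2 * a %*% t(b)
  }
  d2_fg <- pmax(apply(cross_d2(p_fg, p_bg), 1, min), 0)
  centers <- which(d2_fg > radius^2)
  out <- array(FALSE, dims)
  if (length(centers) == 0) return(out)
  d2_to_centers <- cross_d2(p_fg, p_fg[centers, , drop = FALSE])
  covered <- rowSums(sweep(d2_to_centers, 2, d2_fg[centers], "<")) > 0
  out[which(mask)] <- covered
  out
}

# exhaustive-permutation Mann-Whitney oracle (tie-free inputs)
mw_enumeration_oracle <- function(x, y) {
  n1 <- length(x)
  n <- n1 + length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(n, n1)
  us <- apply(combs, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  mu <- n1 * (n - n1) / 2
  list(U = u_obs, p = mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9))
}

# literal step-up definition: largest k with p_(k) <= k * Q / m
bh_oracle <- function(p, Q) {
  m <- length(p)
  ps <- sort(p)
  k <- 0
  for (i in seq_len(m)) if (ps[i] <= i * Q / m) k <- i
  if (k == 0) rep(FALSE, m) else p <= ps[k]
}

dice_coef <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))
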