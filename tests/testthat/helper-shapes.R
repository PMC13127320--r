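# shared fixture builders: all fixtures are generated in code at test time

# spherical cap patch: surface points of a sphere of radius r within a polar
# cap of the given half-angle (degrees) about +z, centred in the grid
cap_patch <- function(r, half_angle = 30, grid_dim = c(80, 80, 80),
                      spacing = c(1, 1, 1)) {
  m <- sphere_mask(r, spacing = spacing, grid_dim = grid_dim)
  s <- extract_surface(m)
  ctr <- grid_dim * spacing / 2
  d <- sweep(s$points, 2, ctr)
  keep <- d[, 3] > cos(half_angle * pi / 180) * sqrt(rowSums(d^2))
  surface_patch(s$points[keep, , drop = FALSE])
}

# solid cube of `side` voxels centred in a grid with 3-voxel padding
cube_mask <- function(side = 10, pad = 3, spacing = c(1, 1, 1)) {
  n <- side + 2 * pad
  v <- array(FALSE, c(n, n, n))
  rng <- (pad + 1):(pad + side)
  v[rng, rng, rng] <- TRUE
  structure_mask(v, spacing = spacing)
}

# sphere with a radial Gaussian bulge of given amplitude (mm) and angular
# width (rad) in direction `dir`
bulged_sphere <- function(radius, amp, sigma, dir = c(0, 0, 1),
                          grid_dim = c(80, 80, 80), spacing = c(1, 1, 1)) {
  ctr <- grid_dim * spacing / 2
  dir <- dir / sqrt(sum(dir^2))
  ax <- (seq_len(grid_dim[1]) - 0.5) * spacing[1] - ctr[1]
  ay <- (seq_len(grid_dim[2]) - 0.5) * spacing[2] - ctr[2]
  az <- (seq_len(grid_dim[3]) - 0.5) * spacing[3] - ctr[3]
  g <- as.matrix(expand.grid(x = ax, y = ay, z = az))
  r <- sqrt(rowSums(g^2))
  u <- g / pmax(r, 1e-12)
  ca <- pmin(pmax(u %*% dir, -1), 1)
  rad <- radius + amp * exp(-acos(ca)^2 / (2 * sigma^2))
  structure_mask(array(r <= rad, grid_dim), spacing = spacing)
}

# brute-force directed mean distance between point sets
brute_mda <- function(src, tgt) {
  mean(apply(src, 1, function(p) sqrt(min(colSums((t(tgt) - p)^2)))))
}

# reduced-scale study configuration used across tests (same physical extent
# as the default lattice at a quarter the voxel count per axis)
test_config <- function(...) {
  cfg <- default_study_config(grid_dim = c(64, 64, 64), spacing = c(2, 2, 2))
  dots <- list(...)
  for (nm in names(dots)) cfg[[nm]] <- dots[[nm]] # no recursive list merging
  cfg
}
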