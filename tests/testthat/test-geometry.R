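test_that("morph_offset matches analytic sphere volumes and identity/empty cases", {
  m <- sphere_mask(20, grid_dim = c(64, 64, 64))
  expect_identical(morph_offset(m, 0)$voxels, m$voxels)

  grown <- morph_offset(m, 5)
  expect_lt(abs(mask_volume(grown) / (4 / 3 * pi * 25^3) - 1), 0.02)
  shrunk <- morph_offset(m, -5)
  expect_lt(abs(mask_volume(shrunk) / (4 / 3 * pi * 15^3) - 1), 0.03)

  expect_warning(empty <- morph_offset(m, -25), class = "adaptbias_emptied_mask")
  expect_equal(sum(empty$voxels), 0)
  expect_true(isTRUE(attr(empty, "emptied")))

  expect_error(structure_mask(array(TRUE, c(2, 2, 2)), spacing = c(1, 0, 1)),
               class = "adaptbias_geometry_error")
})

test_that("morph_offset is monotone in the offset and round-trips convex masks", {
  m <- sphere_mask(12, grid_dim = c(48, 48, 48))
  offs <- c(-6, -3, 0, 2, 5)
  fg <- lapply(offs, function(r) suppressWarnings(morph_offset(m, r))$voxels)
  for (i in seq_len(length(offs) - 1)) {
    expect_true(all(fg[[i + 1]][fg[[i]]]), info = sprintf("offset %g vs %g", offs[i], offs[i + 1]))
  }
  # contract(expand(M, r), r) contains M for convex M at fine resolution
  rt <- morph_offset(morph_offset(m, 4), -4)
  expect_true(all(rt$voxels[m$voxels]))
})

test_that("extract_surface counts and bounds match direct enumeration", {
  single <- structure_mask(array(c(rep(FALSE, 13), TRUE, rep(FALSE, 13)), c(3, 3, 3)),
                           spacing = c(1, 2, 3))
  s1 <- extract_surface(single)
  expect_equal(nrow(s1$points), 1)
  expect_equal(as.numeric(s1$points), c(1.5, 3, 4.5)) # centre of voxel (2,2,2)

  cm <- cube_mask(10)
  expect_equal(nrow(extract_surface(cm)$points), 10^3 - 8^3)

  ms <- sphere_mask(15, grid_dim = c(40, 40, 40))
  ss <- extract_surface(ms)
  d <- sqrt(rowSums(sweep(ss$points, 2, c(20, 20, 20))^2))
  expect_true(all(d >= 13.5 & d <= 16.5))

  expect_error(extract_surface(structure_mask(array(FALSE, c(4, 4, 4)))),
               class = "adaptbias_empty_structure_error")
})

test_that("compute_mda equals the brute-force all-pairs oracle and planar geometry", {
  set.seed(71)
  A <- surface_patch(matrix(runif(600, 0, 50), ncol = 3))
  B <- surface_patch(matrix(runif(600, 0, 50), ncol = 3))
  expect_equal(compute_mda(A, B), brute_mda(A$points, B$points), tolerance = 1e-9)
  expect_equal(compute_mda(A, B, "symmetric"),
               (brute_mda(A$points, B$points) + brute_mda(B$points, A$points)) / 2,
               tolerance = 1e-9)
  # exchange invariance of the symmetric mode
  expect_equal(compute_mda(A, B, "symmetric"), compute_mda(B, A, "symmetric"))

  expect_equal(compute_mda(A, A), 0)

  g <- as.matrix(expand.grid(seq(0, 10), seq(0, 10)))
  P1 <- surface_patch(cbind(g, 0))
  P2 <- surface_patch(cbind(g, 5))
  expect_equal(compute_mda(P1, P2), 5)
  expect_equal(compute_mda(P1, P2, "symmetric"), 5)

  expect_error(compute_mda(surface_patch(matrix(numeric(0), ncol = 3)), A),
               class = "adaptbias_empty_structure_error")
})

test_that("sign_dmda signs concentric spherical caps and flips under reflection", {
  ctr <- c(36, 36, 36)
  cap27 <- cap_patch(27, grid_dim = c(72, 72, 72))
  cap25 <- cap_patch(25, grid_dim = c(72, 72, 72))
  out <- sign_dmda(cap27, cap25, ctr)
  inw <- sign_dmda(cap25, cap27, ctr)
  expect_equal(out, 2, tolerance = 0.5 / 2) # +/- 0.5 mm voxelization at 1 mm grid
  expect_equal(inw, -2, tolerance = 0.5 / 2)
  expect_equal(sign(out), -sign(inw))
  expect_equal(sign_dmda(cap25, cap25, ctr), 0)
})

test_that("classify_octant follows the dominant-axis rule with AP tie-break", {
  expect_equal(classify_octant(c(0, -30, -10), c(0, 0, 0)), "inferior-anterior")
  expect_equal(classify_octant(c(20, 5, 8), c(0, 0, 0)), "superior-left-lateral")
  expect_equal(classify_octant(c(5, 5, 1), c(0, 0, 0)), "superior-posterior") # 45-degree tie
  expect_error(classify_octant(c(1, 1, 1), c(1, 1, 1)),
               class = "adaptbias_domain_error")

  set.seed(5)
  u <- matrix(rnorm(3000), ncol = 3)
  labs <- apply(u, 1, classify_octant, center = c(0, 0, 0))
  expect_true(all(labs %in% adaptbias:::octant_labels()))
  # isotropic directions hit every octant at roughly uniform azimuth
  expect_equal(length(unique(labs)), 8)
  expect_gt(min(table(labs)), 1000 / 8 * 0.5)
})

test_that("patch_area matches analytic areas for a cube face and a sphere", {
  cm <- cube_mask(10, pad = 3)
  s <- extract_surface(cm)
  face <- surface_patch(s$points[s$points[, 1] == max(s$points[, 1]), , drop = FALSE])
  expect_equal(patch_area(face, cm), 1.0, tolerance = 0.1)

  ms <- sphere_mask(25, grid_dim = c(72, 72, 72))
  full <- extract_surface(ms)
  expect_equal(patch_area(full, ms), 4 * pi * 2.5^2, tolerance = 0.05)

  expect_error(patch_area(surface_patch(matrix(numeric(0), ncol = 3)), cm),
               class = "adaptbias_empty_structure_error")
  off <- surface_patch(matrix(c(100, 100, 100), ncol = 3))
  expect_error(patch_area(off, cm), class = "adaptbias_inconsistent_patch_error")
})

test_that("all geometry agrees with brute-force enumeration on small grids", {
  set.seed(9)
  for (rep in 1:3) {
    v <- array(runif(20 * 18 * 16) > 0.8, c(20, 18, 16))
    sp <- c(1, 1.5, 2)
    m <- structure_mask(v, spacing = sp)
    if (!any(v)) next
    # EDT against all-pairs distances
    d <- adaptbias:::edt_mm(v, sp)
    idx <- which(v, arr.ind = TRUE)
    pts <- adaptbias:::voxel_centres(m, idx)
    all_idx <- as.matrix(expand.grid(1:20, 1:18, 1:16))
    allpts <- adaptbias:::voxel_centres(m, all_idx)
    bf <- apply(allpts, 1, function(p) sqrt(min(colSums((t(pts) - p)^2))))
    bfa <- array(0, dim(v)); bfa[all_idx] <- bf
    expect_lt(max(abs(d - bfa)), 1e-9)
    # surface voxels against direct 6-neighbour enumeration
    surf <- adaptbias:::surface_voxels(v)
    for (k in seq_len(min(50, nrow(idx)))) {
      i <- idx[k, ]
      nb <- rbind(i + c(1, 0, 0), i - c(1, 0, 0), i + c(0, 1, 0),
                  i - c(0, 1, 0), i + c(0, 0, 1), i - c(0, 0, 1))
      onbg <- apply(nb, 1, function(j) {
        any(j < 1) || any(j > dim(v)) || !v[j[1], j[2], j[3]]
      })
      expect_identical(surf[i[1], i[2], i[3]], any(onbg))
    }
  }
})
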