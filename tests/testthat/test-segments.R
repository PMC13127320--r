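test_that("identify_test_segments finds a constructed bulge and nothing on identical CTVs", {
  base <- sphere_mask(25, grid_dim = c(80, 80, 80))
  expect_length(identify_test_segments(base, base), 0)

  bulged <- bulged_sphere(25, amp = 8, sigma = 10 / 25) # ~10 mm angular width
  segs <- identify_test_segments(base, bulged)
  expect_length(segs, 1)
  seg <- segs[[1]]
  expect_identical(seg$host, "b")
  expect_gt(seg$area_cm2, 1)
  expect_lt(seg$area_cm2, 25)
  # centred on the bulge apex (+z here)
  u <- colMeans(seg$segment$points) - c(40, 40, 40)
  expect_gt(u[3] / sqrt(sum(u^2)), 0.95)
  # matched patch lies on the other surface, near the apex
  expect_gt(nrow(seg$matched$points), 0)

  # symmetric in its inputs up to which surface hosts the patch
  segs_sw <- identify_test_segments(bulged, base)
  expect_length(segs_sw, 1)
  expect_identical(segs_sw[[1]]$host, "a")
  expect_equal(segs_sw[[1]]$segment$points, seg$segment$points)

  # a 0.3 cm^2 spike fails the area filter
  spiked <- bulged_sphere(25, amp = 8, sigma = 2 / 25)
  expect_length(identify_test_segments(base, spiked), 0)

  other_grid <- sphere_mask(25, grid_dim = c(80, 80, 80), spacing = c(1, 1, 2))
  expect_error(identify_test_segments(base, other_grid),
               class = "adaptbias_geometry_error")
})

test_that("screening keeps exactly the cases with above-threshold deviations", {
  base <- sphere_mask(22, grid_dim = c(64, 64, 64))
  small <- bulged_sphere(22, amp = 3, sigma = 0.4, grid_dim = c(64, 64, 64))
  big <- bulged_sphere(22, amp = 8, sigma = 0.4, grid_dim = c(64, 64, 64))
  cohort <- list(
    low1 = list(a = base, b = small), hit1 = list(a = base, b = big),
    low2 = list(a = small, b = small), hit2 = list(a = big, b = base)
  )
  sc <- screen_fractions(cohort)
  expect_equal(sc$eligible, c(FALSE, TRUE, FALSE, TRUE))
  expect_equal(sc$n_segments[sc$eligible], c(1L, 1L))

  empty <- screen_fractions(list())
  expect_equal(nrow(empty), 0)

  # monotone in bulge amplitude: once eligible, larger bumps stay eligible
  amps <- c(6, 8, 10, 12)
  elig <- vapply(amps, function(a) {
    length(identify_test_segments(base, bulged_sphere(22, a, 0.4, grid_dim = c(64, 64, 64)))) >= 1
  }, logical(1))
  expect_true(all(diff(as.integer(elig)) >= 0))
  expect_true(elig[1])
})

test_that("complementary segments partition the CTV surface", {
  base <- sphere_mask(20, grid_dim = c(64, 64, 64))
  bulged <- bulged_sphere(20, amp = 8, sigma = 0.45, grid_dim = c(64, 64, 64))
  seg <- identify_test_segments(base, bulged)[[1]]$segment
  surf <- extract_surface(bulged)
  comp <- complementary_segment(bulged, seg)
  expect_equal(nrow(comp$points) + nrow(seg$points), nrow(surf$points))
  expect_equal(nrow(dplyr::intersect(as.data.frame(comp$points),
                                     as.data.frame(seg$points))), 0)

  whole <- complementary_segment(base, extract_surface(base))
  expect_equal(nrow(whole$points), 0)

  off <- surface_patch(matrix(c(0, 0, 0), ncol = 3))
  expect_error(complementary_segment(base, off),
               class = "adaptbias_inconsistent_patch_error")
})

test_that("pairwise comparisons implement the worse/better and tie rules", {
  # ties are non-positive
  rec <- tidyr::expand_grid(segment_id = c("S1", "S2"),
                            physician_id = c("P1", "P2"),
                            algorithm = c("contour_dir", "hybrid_dir"))
  rec$mda_gt_unadjusted <- ifelse(rec$algorithm == "contour_dir", 8, 2)
  rec$dmda_gt_unadjusted <- rec$mda_gt_unadjusted
  rec$mda_gt_adjusted <- 3
  rec$dmda_gt_adjusted <- 3
  cmp <- build_pairwise_comparisons(rec)
  expect_equal(nrow(cmp), 4)
  expect_true(all(cmp$worse_algorithm == "contour_dir"))
  expect_false(any(cmp$positive))

  # missing arm errors with the offending keys
  expect_error(build_pairwise_comparisons(rec[-1, ]), "S1/P1",
               class = "adaptbias_domain_error")

  # near-deterministic ordering: slope 0.7, tiny residual
  prof <- physician_profiles(slopes = rep(0.7, 13), residual_sd = 0.1)
  high <- simulate_records(prof, seed = 3)
  p_high <- mean(build_pairwise_comparisons(high)$positive)
  expect_gte(p_high, 0.95)

  # perfect correctors: proportion near 1/2 across 50 seeds
  prof0 <- physician_profiles(slopes = rep(0, 13), residual_sd = 2)
  p_null <- vapply(1:50, function(s) {
    mean(build_pairwise_comparisons(simulate_records(prof0, seed = s))$positive)
  }, numeric(1))
  expect_equal(mean(p_null), 0.5, tolerance = 0.1 / 0.5)
})

test_that("comparison count is physicians x segments on complete data", {
  prof <- physician_profiles()
  rec <- simulate_records(prof, n_segments = 13, seed = 8, include_rigid = TRUE)
  cmp <- build_pairwise_comparisons(rec)
  expect_equal(nrow(cmp), 13 * 13)
  smry <- summarize_comparisons(cmp)
  expect_equal(smry$n[1], 169)
  expect_equal(sum(smry$n[-1]), 169)
  expect_true(all(smry$ci_lower <= smry$proportion & smry$proportion <= smry$ci_upper))
})
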