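test_that("the physician panel has the designed mean, range and groups", {
  prof <- physician_profiles()
  expect_equal(nrow(prof), 13)
  expect_equal(mean(prof$correction_slope), 0.7009, tolerance = 1e-10)
  expect_equal(range(prof$correction_slope), c(0.4317, 1.0332))
  expect_true(all(prof$residual_sd == 2.02))
  expect_setequal(unique(prof$experience_group), c("A", "B", "C"))
  # group A holds the best correctors (lowest slopes)
  agg <- tapply(prof$correction_slope, prof$experience_group, mean)
  expect_true(agg[["A"]] < agg[["B"]] && agg[["B"]] < agg[["C"]])

  drawn <- physician_profiles(slope_sd = 0.15, seed = 3)
  expect_equal(nrow(drawn), 13)
  expect_identical(drawn, physician_profiles(slope_sd = 0.15, seed = 3))
})

test_that("simulate_adjustment follows the linear under-correction law", {
  p_perfect <- list(correction_slope = 0, residual_sd = 0)
  expect_equal(simulate_adjustment(c(-8, 3, 5), p_perfect, seed = 1), c(0, 0, 0))
  p_bias <- list(correction_slope = 1, residual_sd = 0)
  expect_equal(simulate_adjustment(c(-8, 3, 5), p_bias, seed = 1), c(-8, 3, 5))

  p <- list(correction_slope = 0.7, residual_sd = 2.02)
  draws <- simulate_adjustment(rep(8, 1e4), p, seed = 9)
  expect_equal(mean(draws), 5.6, tolerance = 0.07 / 5.6)
  expect_equal(sd(draws), 2.02, tolerance = 0.05 / 2.02)
  expect_identical(draws, simulate_adjustment(rep(8, 1e4), p, seed = 9))
})

test_that("an error-free case collapses to one structure", {
  cfg <- test_config(filling_scale = c(1, 1, 1), grid_dim = c(48, 48, 48),
                     spacing = c(2, 2, 2))
  case <- generate_case(3, cfg, sites = NULL)
  expect_identical(case$ctv1$voxels, case$ground_truth$voxels)
  for (alg in names(case$ctv2)) {
    expect_identical(case$ctv2[[alg]]$voxels, case$ctv1$voxels)
  }
})

test_that("cases are deterministic and algorithm errors order as constructed", {
  cfg <- test_config()
  sites <- adaptbias:::build_site_table(cfg, 11)
  s1 <- dplyr::filter(sites, case_id == "C04")
  a <- generate_case(21, cfg, sites = s1, case_id = "C04")
  b <- generate_case(21, cfg, sites = s1, case_id = "C04")
  expect_identical(a$ctv2$contour_dir$voxels, b$ctv2$contour_dir$voxels)
  expect_identical(a$ground_truth$voxels, b$ground_truth$voxels)

  m <- adaptbias:::measure_case(a, cfg)
  expect_gte(nrow(m), 3)
  wide <- tidyr::pivot_wider(dplyr::distinct(m, segment_id, algorithm, mda_gt_unadjusted),
                             names_from = algorithm, values_from = mda_gt_unadjusted)
  worse <- s1$worse_algorithm_true[match(wide$segment_id, s1$segment_id)]
  expect_true(all(ifelse(worse == "contour_dir",
                         wide$contour_dir > wide$hybrid_dir,
                         wide$hybrid_dir > wide$contour_dir)))
  # signs follow the constructed bump direction
  signs <- dplyr::filter(m, algorithm == s1$worse_algorithm_true[1],
                         segment_id == s1$segment_id[1])
  expect_equal(sign(signs$dmda_gt_unadjusted[1]), s1$sign[1])
})

test_that("the full study has the designed scale, coverage and determinism", {
  cfg <- test_config()
  st <- generate_study(cfg, seed = 6)
  expect_equal(dplyr::n_distinct(st$records$segment_id), 13)
  expect_equal(nrow(st$records), 13 * 3 * 13)
  expect_setequal(unique(st$records$octant), cfg$octants)
  expect_true(all(st$screening$eligible))
  expect_equal(abs(st$records$dmda_gt_adjusted), st$records$mda_gt_adjusted)
  expect_equal(abs(st$records$dmda_gt_unadjusted), st$records$mda_gt_unadjusted)
  # every record sits in the schedule cell of its case/algorithm/physician
  chk <- dplyr::anti_join(
    dplyr::select(st$records, physician_id, case_id, algorithm, session),
    st$schedule, by = c("physician_id", "case_id", "algorithm", "session"))
  expect_equal(nrow(chk), 0)

  st2 <- generate_study(cfg, seed = 6)
  expect_identical(st$records, st2$records)
})

test_that("eligibility is monotone in the propagation-error amplitude", {
  base_cfg <- test_config(n_cases = 1, n_segments = 1,
                          hybrid_worse_segments = integer(0))
  n_found <- vapply(c(3, 6, 9), function(amp) {
    cfg <- utils::modifyList(base_cfg, list(worse_amp_range = c(amp, amp)))
    sites <- adaptbias:::build_site_table(cfg, 2)
    case <- generate_case(2, cfg, sites = sites, case_id = "C01")
    length(identify_test_segments(case$ctv2$contour_dir, case$ctv2$hybrid_dir))
  }, integer(1))
  expect_true(all(diff(n_found) >= 0))
  expect_equal(n_found[1], 0L) # 3 mm error is below the 5 mm threshold
  expect_gte(n_found[3], 1L)
})

test_that("a study with all errors below threshold raises the no-eligible-cases error", {
  cfg <- test_config(worse_amp_range = c(2, 3), better_amp_range = c(0.3, 0.6),
                     n_cases = 2, n_segments = 2, hybrid_worse_segments = integer(0))
  expect_error(generate_study(cfg, seed = 1), class = "adaptbias_domain_error")
})
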