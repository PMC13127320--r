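#' Physician correction profiles
#'
#' The simulated physicians correct a propagated contour according to a
#' linear under-correction law: the signed deviation that remains after
#' adjustment is `slope * unadjusted + noise`. A slope of 0 is a perfect
#' corrector, 1 leaves the algorithm's error untouched. The default panel of
#' 13 physicians spans slopes 0.4317 to 1.0332 with mean 0.7009 and residual
#' SD 2.02 mm, the operating range the analysis is designed around;
#' alternatively slopes can be drawn from a normal distribution
#' (`slope_sd`) or supplied directly. Experience groups are assigned by
#' slope rank: the best correctors (lowest slopes) form group A (> 4 years),
#' then B (2-4 years), the remainder C (0.5-2 years).
#'
#' @param n_physicians Number of physicians (default 13).
#' @param mean_slope Target mean of the slope panel.
#' @param slope_range Anchor range for the deterministic panel.
#' @param residual_sd Residual SD of the correction law in mm.
#' @param slopes Optional explicit slope vector (overrides everything else).
#' @param slope_sd If non-NULL, draw slopes from `N(mean_slope, slope_sd^2)`
#'   using `seed`.
#' @param seed Seed for drawn slopes.
#' @return A tibble with `physician_id`, `experience_group`,
#'   `correction_slope`, `residual_sd`.
#' @export
physician_profiles <- function(n_physicians = 13, mean_slope = 0.7009,
                               slope_range = c(0.4317, 1.0332),
                               residual_sd = 2.02, slopes = NULL,
                               slope_sd = NULL, seed = 1) {
  if (is.null(slopes)) {
    if (!is.null(slope_sd)) {
      slopes <- with_seed(seed, stats::rnorm(n_physicians, mean_slope, slope_sd))
    } else if (n_physicians == 1L) {
      slopes <- mean_slope
    } else if (n_physicians == 2L) {
      slopes <- mean_slope + c(-1, 1) * diff(slope_range) / 2
    } else {
      # anchors at the range ends, inner values evenly spaced then shifted
      # so the panel mean equals mean_slope exactly
      inner <- seq(slope_range[1], slope_range[2],
                   length.out = n_physicians)[2:(n_physicians - 1)]
      shift <- (n_physicians * mean_slope - sum(slope_range) - sum(inner)) /
        (n_physicians - 2)
      slopes <- c(slope_range[1], inner + shift, slope_range[2])
    }
  }
  if (any(residual_sd < 0)) abort_domain("`residual_sd` must be non-negative")
  n <- length(slopes)
  rk <- rank(slopes, ties.method = "first")
  ng <- c(floor(n / 3), floor(n / 3))
  grp <- ifelse(rk <= ng[1], "A", ifelse(rk <= ng[1] + ng[2], "B", "C"))
  tibble::tibble(
    physician_id = sprintf("P%02d", seq_len(n)),
    experience_group = grp,
    correction_slope = slopes,
    residual_sd = rep_len(residual_sd, n)
  )
}

#' Simulate a physician's adjustment of a signed deviation
#'
#' Applies the linear under-correction law of a physician profile:
#' `adjusted = slope * unadjusted + e`, `e ~ N(0, residual_sd^2)`,
#' deterministically under the seed.
#'
#' @param unadjusted_dmda Signed deviation(s) in mm before adjustment.
#' @param profile One row of [physician_profiles()] (or any list with
#'   `correction_slope` and `residual_sd`).
#' @param seed Integer seed.
#' @return Adjusted signed deviation(s) in mm.
#' @export
simulate_adjustment <- function(unadjusted_dmda, profile, seed = 1) {
  noise <- with_seed(seed, stats::rnorm(length(unadjusted_dmda), 0,
                                        profile$residual_sd[1]))
  profile$correction_slope[1] * unadjusted_dmda + noise
}

# unit direction of an octant label under the fixed axis convention
# (+x left, +y posterior, +z superior)
octant_direction <- function(label) {
  z <- if (grepl("^superior", label)) 1 else -1
  xy <- if (grepl("anterior", label)) c(0, -1)
  else if (grepl("posterior", label)) c(0, 1)
  else if (grepl("right-lateral", label)) c(-1, 0)
  else c(1, 0)
  v <- c(xy, z)
  v / sqrt(sum(v^2))
}

# rasterize a star-shaped region: v inside iff |T (v - c)| <= R(direction),
# where R is a radial function of the unit direction (n x 3 -> n, mm)
mask_from_radial <- function(radial_fun, center, grid_dim, spacing,
                             origin = c(0, 0, 0), transform = diag(3), id = NULL) {
  ax <- origin[1] + (seq_len(grid_dim[1]) - 0.5) * spacing[1] - center[1]
  ay <- origin[2] + (seq_len(grid_dim[2]) - 0.5) * spacing[2] - center[2]
  az <- origin[3] + (seq_len(grid_dim[3]) - 0.5) * spacing[3] - center[3]
  g <- expand.grid(x = ax, y = ay, z = az)
  w <- as.matrix(g) %*% t(transform)
  r <- sqrt(rowSums(w^2))
  u <- w / pmax(r, 1e-12)
  inside <- r <= radial_fun(u)
  structure_mask(array(inside, dim = grid_dim), spacing = spacing,
                 origin = origin, id = id)
}

# radial function of a bladder-like shape: ellipsoid radii plus smooth lobes
# (wobble) plus site-specific Gaussian angular bumps
radial_function <- function(radii, wobble = NULL, bumps = NULL) {
  function(u) {
    base <- 1 / sqrt((u[, 1] / radii[1])^2 + (u[, 2] / radii[2])^2 +
                       (u[, 3] / radii[3])^2)
    r <- base
    if (!is.null(wobble)) {
      for (k in seq_len(nrow(wobble$dirs))) {
        ca <- pmin(pmax(u %*% wobble$dirs[k, ], -1), 1)
        r <- r + base * wobble$amps[k] * exp(-acos(ca)^2 / (2 * wobble$sigma^2))
      }
    }
    if (!is.null(bumps) && nrow(bumps) > 0L) {
      for (k in seq_len(nrow(bumps))) {
        d <- c(bumps$dx[k], bumps$dy[k], bumps$dz[k])
        ca <- pmin(pmax(u %*% d, -1), 1)
        r <- r + bumps$amp[k] * exp(-acos(ca)^2 / (2 * bumps$sigma[k]^2))
      }
    }
    as.numeric(r)
  }
}

#' Default configuration of the synthetic study
#'
#' The study conditions the generator emulates: 13 physicians, 10 cases with
#' 13 test segments (three cases carry two), per-algorithm propagation
#' errors producing local deviations beyond the 5 mm relevance threshold in
#' 6 of the 8 octants, a bladder-filling global deformation between the
#' reference and the anatomy of the day, and the linear physician-correction
#' law.
#'
#' @param grid_dim,spacing Lattice of the synthetic volumes (default 128^3
#'   at 1 mm isotropic; a coarser 64^3 at 2 mm keeps the same physical
#'   extent).
#' @return A named list of generator settings.
#' @export
default_study_config <- function(grid_dim = c(128, 128, 128),
                                 spacing = c(1, 1, 1)) {
  list(
    grid_dim = grid_dim,
    spacing = spacing,
    n_physicians = 13,
    n_cases = 10,
    n_segments = 13,
    base_radii = c(36, 33, 31),        # mm; bladder-like CTV half-axes
    radii_jitter = 0.06,               # relative case-to-case size variation
    wobble_amp = 0.03,                 # relative smooth shape irregularity
    wobble_sigma = 0.9,                # rad
    n_wobble_lobes = 4,
    filling_scale = c(1.03, 1.05, 1.09), # bladder filling CBCT1 -> CBCT2
    octants = c("inferior-anterior", "inferior-posterior",
                "inferior-right-lateral", "inferior-left-lateral",
                "superior-anterior", "superior-posterior"),
    worse_amp_range = c(8, 9.5),       # mm, worse algorithm's local error
    better_amp_range = c(0.5, 1.5),    # mm, better algorithm's local error
    bump_sigma_rad = 0.5,
    hybrid_worse_segments = c(5, 9),   # segments where the hybrid arm is worse
    deviation_mm = 5,
    rim_mm = 1,
    area_min_cm2 = 1,
    area_max_cm2 = 25,
    gt_noise_mm = 0,                   # landmark-registration noise on ground truth
    profiles = physician_profiles()
  )
}

# site table: one row per test segment with its case, octant, error sign and
# per-algorithm bump amplitudes
build_site_table <- function(config, seed) {
  n_seg <- config$n_segments
  n_cases <- config$n_cases
  if (n_seg < n_cases) abort_domain("need at least one segment per case")
  case_of <- c(seq_len(n_cases), seq_len(n_seg - n_cases))
  octs <- config$octants[(seq_len(n_seg) - 1L) %% length(config$octants) + 1L]
  # a case's second error site goes to the covered octant farthest from its
  # first site, so the two deviation regions cannot fuse
  if (n_seg > n_cases) {
    dirs <- t(vapply(config$octants, octant_direction, numeric(3)))
    for (i in seq(n_cases + 1L, n_seg)) {
      first_oct <- octs[case_of[i]]
      ang <- drop(dirs %*% octant_direction(first_oct))
      octs[i] <- config$octants[which.min(ang)]
    }
  }
  with_seed(seed, {
    amp_w <- stats::runif(n_seg, config$worse_amp_range[1], config$worse_amp_range[2])
    amp_b <- stats::runif(n_seg, config$better_amp_range[1], config$better_amp_range[2])
    sgn <- ifelse(seq_len(n_seg) %% 2L == 1L, 1, -1)
    hyb_worse <- seq_len(n_seg) %in% config$hybrid_worse_segments
    tibble::tibble(
      segment_id = sprintf("S%02d", seq_len(n_seg)),
      case_id = sprintf("C%02d", case_of),
      octant = octs,
      sign = sgn,
      worse_algorithm_true = ifelse(hyb_worse, "hybrid_dir", "contour_dir"),
      amp_contour = sgn * ifelse(hyb_worse, amp_b, amp_w),
      amp_hybrid = sgn * ifelse(hyb_worse, amp_w, amp_b),
      sigma = config$bump_sigma_rad
    )
  })
}

#' Generate one synthetic adaptive-radiotherapy case
#'
#' Builds the reference CTV (the structure of the pre-treatment image), the
#' true anatomy-of-the-day CTV (the reference under a known bladder-filling
#' anisotropic scaling, the local ground truth), and each propagation
#' algorithm's CTV: the ground truth corrupted by that algorithm's local
#' error bumps for the deformable arms, and the rigidly placed reference for
#' the copy arm. All deformations are analytic, so forward and inverse
#' mappings are exact by construction.
#'
#' @param seed Integer seed (shape wobble and radius jitter).
#' @param config Study configuration ([default_study_config()]).
#' @param sites Site table rows for this case (segment error sites); NULL
#'   for an error-free case.
#' @param case_id Identifier stored on the masks.
#' @return A list with `ctv1`, `ground_truth`, `ctv2` (named list per
#'   algorithm), `center` (mm), `sites`.
#' @export
generate_case <- function(seed, config = default_study_config(), sites = NULL,
                          case_id = "C01") {
  gd <- config$grid_dim; sp <- config$spacing
  center <- gd * sp / 2
  pars <- with_seed(seed, {
    radii <- config$base_radii * (1 + stats::runif(3, -config$radii_jitter,
                                                   config$radii_jitter))
    dirs <- matrix(stats::rnorm(3 * config$n_wobble_lobes), ncol = 3)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    amps <- stats::runif(config$n_wobble_lobes, -config$wobble_amp, config$wobble_amp)
    list(radii = radii, wobble = list(dirs = dirs, amps = amps,
                                      sigma = config$wobble_sigma))
  })
  bumps_of <- function(amp_col) {
    if (is.null(sites) || nrow(sites) == 0L) return(NULL)
    d <- t(vapply(sites$octant, octant_direction, numeric(3)))
    tibble::tibble(dx = d[, 1], dy = d[, 2], dz = d[, 3],
                   amp = sites[[amp_col]], sigma = sites$sigma)
  }
  S <- diag(config$filling_scale)
  Sinv <- diag(1 / config$filling_scale)
  r_gt <- radial_function(pars$radii, pars$wobble)
  # ctv1 is the ground truth pulled back through the filling deformation
  ctv1 <- mask_from_radial(r_gt, center, gd, sp, transform = S, id = "ctv1")
  gt <- mask_from_radial(r_gt, center, gd, sp, id = "ground_truth")
  algo_mask <- function(amp_col, id) {
    mask_from_radial(radial_function(pars$radii, pars$wobble, bumps_of(amp_col)),
                     center, gd, sp, id = id)
  }
  ctv2 <- list(
    contour_dir = algo_mask("amp_contour", "ctv2_contour_dir"),
    hybrid_dir = algo_mask("amp_hybrid", "ctv2_hybrid_dir"),
    rigid_copy = structure_mask(ctv1$voxels, spacing = sp, origin = c(0, 0, 0),
                                id = "ctv2_rigid_copy")
  )
  list(ctv1 = ctv1, ground_truth = gt, ctv2 = ctv2, center = center,
       sites = sites, case_id = case_id, scale = diag(S), inverse_scale = diag(Sinv))
}

# geometric measurement of one case: per (segment, algorithm) unadjusted
# signed deviations against the local ground truth
measure_case <- function(case, config) {
  segs <- identify_test_segments(case$ctv2$contour_dir, case$ctv2$hybrid_dir,
                                 deviation_mm = config$deviation_mm,
                                 rim_mm = config$rim_mm,
                                 area_min_cm2 = config$area_min_cm2,
                                 area_max_cm2 = config$area_max_cm2)
  if (length(segs) == 0L) return(NULL)
  site_dirs <- t(vapply(case$sites$octant, octant_direction, numeric(3)))
  centers <- purrr::map(case$ctv2, mask_centroid)
  # one segment per generating error site: if residual fragments map to the
  # same site, keep the largest
  site_of <- vapply(segs, function(sg) {
    u <- colMeans(sg$segment$points) - case$center
    which.max(site_dirs %*% (u / sqrt(sum(u^2))))
  }, numeric(1))
  areas <- vapply(segs, function(sg) sg$area_cm2, numeric(1))
  keep <- vapply(split(seq_along(segs), site_of),
                 function(ix) ix[which.max(areas[ix])], numeric(1))
  segs <- segs[sort(keep)]
  purrr::map_dfr(segs, function(sg) {
    patches <- list()
    if (sg$host == "b") { # identify() was called with a = contour, b = hybrid
      patches$hybrid_dir <- sg$segment
      patches$contour_dir <- sg$matched
      host_alg <- "hybrid_dir"
    } else {
      patches$contour_dir <- sg$segment
      patches$hybrid_dir <- sg$matched
      host_alg <- "contour_dir"
    }
    patches$rigid_copy <- project_patch(sg$segment, case$ctv2$rigid_copy)
    gt_patch <- project_patch(sg$segment, case$ground_truth)
    # match the segment to its generating error site by direction
    u <- colMeans(sg$segment$points) - case$center
    u <- u / sqrt(sum(u^2))
    site <- case$sites[which.max(site_dirs %*% u), ]
    inter <- compute_mda(sg$segment, patches[[setdiff(c("contour_dir", "hybrid_dir"),
                                                      host_alg)]])
    purrr::map_dfr(names(patches), function(alg) {
      dm <- sign_dmda(patches[[alg]], gt_patch, centers[[alg]])
      tibble::tibble(
        case_id = case$case_id, segment_id = site$segment_id,
        octant = sg$octant, host_algorithm = host_alg, algorithm = alg,
        dmda_gt_unadjusted = as.numeric(dm),
        mda_gt_unadjusted = abs(as.numeric(dm)),
        inter_algo_mda = inter, area_cm2 = sg$area_cm2
      )
    })
  })
}

#' Record-level simulation of the cross-over study
#'
#' Simulates the measurement table directly (no volumetric geometry): per
#' segment, the worse and better deformable arms receive unadjusted signed
#' deviations drawn from the configured magnitude ranges; each physician's
#' adjusted deviation follows the linear under-correction law with optional
#' segment and physician random intercepts. This is the generator used for
#' statistical calibration studies; [generate_study()] produces the same
#' table from actual volumes.
#'
#' @param profiles Physician panel ([physician_profiles()]).
#' @param n_segments Number of test segments (default 13).
#' @param worse_range,better_range Magnitude ranges (mm) of the unadjusted
#'   deviation for the worse and better arm.
#' @param rigid_range Magnitude range for the rigid-copy arm (used when
#'   `include_rigid`).
#' @param hybrid_worse_segments Indices of segments where the hybrid arm is
#'   the worse one.
#' @param include_rigid Include the rigid-copy arm (default FALSE: the two
#'   deformable arms of the primary endpoint).
#' @param segment_re_sd,physician_re_sd SDs (mm) of segment and physician
#'   random intercepts added to the adjusted values.
#' @param seed Integer seed.
#' @return A segment-record tibble (one row per segment x algorithm x
#'   physician) with unadjusted/adjusted `dmda` and `mda` columns.
#' @export
simulate_records <- function(profiles = physician_profiles(),
                             n_segments = 13,
                             worse_range = c(5.5, 9.5),
                             better_range = c(0.5, 2.5),
                             rigid_range = c(2, 8),
                             hybrid_worse_segments = c(5, 9),
                             include_rigid = FALSE,
                             segment_re_sd = 0, physician_re_sd = 0,
                             seed = 1) {
  n_phys <- nrow(profiles)
  with_seed(seed, {
    sgn <- ifelse(seq_len(n_segments) %% 2L == 1L, 1, -1)
    hyb_worse <- seq_len(n_segments) %in% hybrid_worse_segments
    amp_w <- sgn * stats::runif(n_segments, worse_range[1], worse_range[2])
    amp_b <- sgn * stats::runif(n_segments, better_range[1], better_range[2])
    seg <- tibble::tibble(
      segment_id = sprintf("S%02d", seq_len(n_segments)),
      contour_dir = ifelse(hyb_worse, amp_b, amp_w),
      hybrid_dir = ifelse(hyb_worse, amp_w, amp_b)
    )
    if (include_rigid) {
      seg$rigid_copy <- sgn * stats::runif(n_segments, rigid_range[1], rigid_range[2])
    }
    long <- tidyr::pivot_longer(seg, -"segment_id", names_to = "algorithm",
                                values_to = "dmda_gt_unadjusted")
    rec <- tidyr::expand_grid(long, physician_id = profiles$physician_id) |>
      dplyr::left_join(profiles, by = "physician_id")
    seg_re <- stats::rnorm(n_segments, 0, segment_re_sd)
    names(seg_re) <- seg$segment_id
    phys_re <- stats::rnorm(n_phys, 0, physician_re_sd)
    names(phys_re) <- profiles$physician_id
    rec |>
      dplyr::mutate(
        dmda_gt_adjusted = unname(
          .data$correction_slope * .data$dmda_gt_unadjusted +
            seg_re[.data$segment_id] + phys_re[.data$physician_id] +
            stats::rnorm(dplyr::n(), 0, .data$residual_sd)),
        mda_gt_unadjusted = abs(.data$dmda_gt_unadjusted),
        mda_gt_adjusted = abs(.data$dmda_gt_adjusted)
      ) |>
      dplyr::select(dplyr::all_of(c(
        "segment_id", "algorithm", "physician_id", "experience_group",
        "dmda_gt_unadjusted", "mda_gt_unadjusted",
        "dmda_gt_adjusted", "mda_gt_adjusted")))
  })
}

#' Generate the full synthetic study from volumes
#'
#' Runs the whole pipeline: generates the synthetic cases, screens the
#' fractions, identifies test segments on the deformable propagations,
#' measures unadjusted signed deviations against the local ground truth for
#' all three arms, draws the cross-over schedule, and simulates every
#' physician's adjustment per presentation. Identical seeds reproduce every
#' output exactly.
#'
#' @param config Study configuration ([default_study_config()]).
#' @param seed Integer master seed; per-stage substreams are derived from it.
#' @param out_dir If non-NULL, masks (NIfTI), tables (CSV) and a run
#'   manifest (JSON) are written beneath this directory.
#' @return A list with `records` (segment-record tibble including schedule
#'   context), `schedule`, `screening`, `sites`, `measurements`, `config`,
#'   `seed`, and (when written) `manifest`.
#' @export
generate_study <- function(config = default_study_config(), seed = 1,
                           out_dir = NULL) {
  sites <- build_site_table(config, child_seed(seed, "sites"))
  case_ids <- sprintf("C%02d", seq_len(config$n_cases))
  cases <- purrr::map(seq_along(case_ids), function(i) {
    generate_case(child_seed(seed, paste0("case", i)), config,
                  sites = dplyr::filter(sites, .data$case_id == case_ids[i]),
                  case_id = case_ids[i])
  })
  names(cases) <- case_ids
  measurements <- purrr::map_dfr(cases, measure_case, config = config)
  if (nrow(measurements) == 0L) {
    abort_domain("no eligible cases: all propagation errors below the threshold")
  }
  screening <- measurements |>
    dplyr::distinct(.data$case_id, .data$segment_id) |>
    dplyr::count(.data$case_id, name = "n_segments") |>
    dplyr::right_join(tibble::tibble(case_id = case_ids), by = "case_id") |>
    dplyr::mutate(n_segments = dplyr::coalesce(.data$n_segments, 0L),
                  eligible = .data$n_segments >= 1L) |>
    dplyr::arrange(.data$case_id)
  if (!any(screening$eligible)) {
    abort_domain("no eligible cases: all propagation errors below the threshold")
  }
  schedule <- generate_crossover(
    n_physicians = config$n_physicians, n_cases = config$n_cases,
    seed = child_seed(seed, "schedule"))
  profiles <- config$profiles
  records <- measurements |>
    dplyr::left_join(dplyr::select(schedule, dplyr::all_of(c(
      "physician_id", "case_id", "algorithm", "session", "order_in_session",
      "preceding_algorithm"))),
      by = c("case_id", "algorithm"), relationship = "many-to-many") |>
    dplyr::left_join(profiles, by = "physician_id") |>
    dplyr::arrange(.data$segment_id, .data$algorithm, .data$physician_id)
  noise <- with_seed(child_seed(seed, "adjust"),
                     stats::rnorm(nrow(records), 0, records$residual_sd))
  records <- records |>
    dplyr::mutate(
      dmda_gt_adjusted = .data$correction_slope * .data$dmda_gt_unadjusted + noise,
      mda_gt_adjusted = abs(.data$dmda_gt_adjusted)
    ) |>
    dplyr::select(dplyr::all_of(c(
      "case_id", "segment_id", "octant", "algorithm", "physician_id",
      "experience_group", "session", "order_in_session", "preceding_algorithm",
      "mda_gt_unadjusted", "dmda_gt_unadjusted",
      "mda_gt_adjusted", "dmda_gt_adjusted", "inter_algo_mda", "area_cm2")))
  out <- list(records = records, schedule = schedule, screening = screening,
              sites = sites, measurements = measurements, config = config,
              seed = seed)
  if (!is.null(out_dir)) {
    out$manifest <- write_study(out, cases, out_dir)
  }
  out
}
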