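#' Project a surface patch onto another structure's surface
#'
#' Maps each patch point to its nearest surface voxel centre on `target` and
#' returns the unique set of hit points, preserving surface-voxel semantics.
#' Used to carry a test segment across algorithm variants and onto the local
#' ground-truth shell.
#'
#' @param patch A [surface_patch()].
#' @param target A [structure_mask()] to project onto.
#' @return A [surface_patch()] on `target`'s surface.
#' @export
project_patch <- function(patch, target) {
  assert_patch(patch); assert_mask(target)
  surf <- extract_surface(target)
  idx <- unique(cpp_nearest(patch$points, surf$points)$index)
  surface_patch(surf$points[sort(idx), , drop = FALSE],
                parent_id = target$id %||% NA_character_,
                octant = patch$octant, component_id = patch$component_id)
}

# crop a mask to the bounding box of a set of mm points, padded by `pad_vox`
# voxels, shifting the origin accordingly
crop_mask_to <- function(mask, points, pad_vox = 6L) {
  d <- dim(mask$voxels)
  lo <- hi <- integer(3)
  for (a in 1:3) {
    vi <- (points[, a] - mask$origin[a]) / mask$spacing[a] + 0.5
    lo[a] <- max(1L, floor(min(vi)) - pad_vox)
    hi[a] <- min(d[a], ceiling(max(vi)) + pad_vox)
  }
  v <- mask$voxels[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  structure_mask(v, spacing = mask$spacing,
                 origin = mask$origin + (lo - 1L) * mask$spacing, id = mask$id)
}

# patch area with the computation restricted to the patch neighbourhood
patch_area_local <- function(patch, mask) {
  patch_area(patch, crop_mask_to(mask, patch$points))
}

#' Identify test segments between two propagated CTVs
#'
#' Implements the rim-and-contraction recipe for locating clinically
#' relevant local deviations between two propagations of the same CTV:
#' a 1 mm outer surface rim of one structure is intersected with the other
#' structure contracted inward by the deviation threshold; each connected
#' component of that intersection marks one deviation site. The test
#' segment on the outer structure's surface collects its surface points
#' farther than the threshold from the other surface, grouped by nearest
#' marker component; the matched patch is the nearest-point projection onto
#' the other structure's surface. Both offset directions are evaluated, and
#' patches outside the area bounds are discarded.
#'
#' @param ctv_a,ctv_b [structure_mask()] objects on a common grid.
#' @param deviation_mm Clinical-relevance threshold in mm (default 5).
#' @param rim_mm Rim thickness in mm (default 1).
#' @param area_min_cm2,area_max_cm2 Surface-area bounds for a local segment.
#' @return A list of segment pairs; each element has `segment` (patch on the
#'   deviating surface), `matched` (projection onto the other surface),
#'   `host` (`"a"` or `"b"`), `octant`, and `area_cm2`.
#' @export
identify_test_segments <- function(ctv_a, ctv_b, deviation_mm = 5, rim_mm = 1,
                                   area_min_cm2 = 1, area_max_cm2 = 25) {
  assert_mask(ctv_a, "ctv_a"); assert_mask(ctv_b, "ctv_b")
  assert_same_grid(ctv_a, ctv_b)
  if (!any(ctv_a$voxels) || !any(ctv_b$voxels)) abort_empty("both CTVs must be non-empty")
  out <- c(
    segments_one_direction(ctv_a, ctv_b, "b", deviation_mm, rim_mm),
    segments_one_direction(ctv_b, ctv_a, "a", deviation_mm, rim_mm)
  )
  keep <- list()
  for (seg in out) {
    host_mask <- if (seg$host == "b") ctv_b else ctv_a
    other_mask <- if (seg$host == "b") ctv_a else ctv_b
    area <- patch_area_local(seg$segment, host_mask)
    if (area < area_min_cm2 || area > area_max_cm2) next
    seg$segment$area_cm2 <- area
    seg$area_cm2 <- area
    centroid <- colMeans(seg$segment$points)
    seg$octant <- classify_octant(centroid, mask_centroid(host_mask))
    seg$segment$octant <- seg$octant
    seg$matched <- project_patch(seg$segment, other_mask)
    keep[[length(keep) + 1L]] <- seg
  }
  keep
}

# relabel connected components, unioning any pair whose point sets lie
# within `gap_mm` of each other
merge_close_components <- function(lab, ref, gap_mm) {
  k <- max(lab)
  if (k <= 1L) return(lab)
  pts <- lapply(seq_len(k), function(cc) {
    voxel_centres(ref, which(lab == cc, arr.ind = TRUE))
  })
  parent <- seq_len(k)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(k - 1L)) {
    for (j in seq((i + 1L), k)) {
      if (min(cpp_nearest(pts[[i]], pts[[j]])$dist) <= gap_mm) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  roots <- vapply(seq_len(k), find, integer(1))
  new_id <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0] <- new_id[lab[lab > 0]]
  out
}

# one direction of the recipe: deviations where `outer` ('s surface) lies
# beyond `base`; host tags which input hosts the returned segment
segments_one_direction <- function(base, outer, host, deviation_mm, rim_mm) {
  # the rim must be at least one voxel thick to exist on the lattice
  rim_eff <- max(rim_mm, max(base$spacing))
  rim <- morph_offset(base, rim_eff)$voxels & !base$voxels
  contracted <- suppressWarnings(morph_offset(outer, -deviation_mm))$voxels
  marker <- rim & contracted
  if (!any(marker)) return(list())
  lab <- array(cpp_label(marker, dim(marker), 26L), dim = dim(marker))
  # the marker shell is one voxel thick and can fragment at coarse
  # resolution; components within the deviation threshold of each other
  # mark the same site and are merged (single linkage)
  lab <- merge_close_components(lab, base, deviation_mm)
  # surface points of `outer` beyond `base`'s surface by > deviation_mm
  outer_surf <- surface_voxels(outer$voxels)
  base_surf_d <- edt_mm(surface_voxels(base$voxels), base$spacing)
  cand <- outer_surf & !base$voxels & base_surf_d > deviation_mm
  if (!any(cand)) return(list())
  cand_idx <- which(cand, arr.ind = TRUE)
  cand_pts <- voxel_centres(outer, cand_idx)
  mark_idx <- which(marker, arr.ind = TRUE)
  mark_pts <- voxel_centres(base, mark_idx)
  comp <- lab[mark_idx][cpp_nearest(cand_pts, mark_pts)$index]
  lapply(sort(unique(comp)), function(cc) {
    pts <- cand_pts[comp == cc, , drop = FALSE]
    list(
      segment = surface_patch(pts, parent_id = outer$id %||% NA_character_,
                              component_id = as.integer(cc)),
      matched = NULL, host = host, component_id = as.integer(cc)
    )
  })
}

#' Screen a cohort of fractions for eligible cases
#'
#' A case (dose fraction) is eligible when the two propagated CTVs exhibit at
#' least one test segment, i.e. a local surface deviation beyond the
#' clinical-relevance threshold within the area bounds.
#'
#' @param cohort A named list of cases; each case is a list with masks `a`
#'   and `b` (the two propagations).
#' @param ... Passed on to [identify_test_segments()].
#' @return A tibble with `case_id`, `n_segments`, `eligible`.
#' @export
screen_fractions <- function(cohort, ...) {
  if (length(cohort) == 0L) {
    return(tibble::tibble(case_id = character(), n_segments = integer(),
                          eligible = logical()))
  }
  ids <- names(cohort) %||% as.character(seq_along(cohort))
  n_seg <- purrr::map_int(cohort, function(case) {
    length(identify_test_segments(case$a, case$b, ...))
  })
  tibble::tibble(case_id = ids, n_segments = unname(n_seg),
                 eligible = unname(n_seg) >= 1L)
}

#' Complementary segment of a test segment
#'
#' The remainder of the CTV surface once the test segment is removed; the
#' two patches partition the surface point set.
#'
#' @param ctv A [structure_mask()].
#' @param test_segment A [surface_patch()] on `ctv`'s surface.
#' @return A [surface_patch()] (possibly empty if the segment covers the
#'   whole surface).
#' @export
complementary_segment <- function(ctv, test_segment) {
  assert_mask(ctv); assert_patch(test_segment, "test_segment")
  surf <- extract_surface(ctv)
  nn <- cpp_nearest(test_segment$points, surf$points)
  if (any(nn$dist > 1e-6)) abort_patch("test segment is not on the CTV surface")
  keep <- !seq_len(nrow(surf$points)) %in% nn$index
  surface_patch(surf$points[keep, , drop = FALSE],
                parent_id = ctv$id %||% NA_character_)
}

#' Build the primary-endpoint pairwise comparisons
#'
#' For every (segment, physician) cell with records from both deformable
#' algorithms, the algorithm with the larger unadjusted MDA to ground truth
#' is labelled worse; the comparison is positive when, after physician
#' adjustment, the worse algorithm's segment still has the strictly larger
#' absolute MDA to ground truth (ties count as non-positive). The rigid-copy
#' arm is excluded from the pairing. Each comparison also carries the
#' adjustment magnitudes per arm and the subgroup split at the median
#' inter-algorithm MDA.
#'
#' @param records A tibble of segment records with columns `segment_id`,
#'   `physician_id`, `algorithm`, `mda_gt_unadjusted`, `mda_gt_adjusted`,
#'   `dmda_gt_unadjusted`, `dmda_gt_adjusted` and optionally
#'   `inter_algo_mda` (surface distance between the two algorithms'
#'   unadjusted segments; recycled within segment).
#' @param algorithms The two algorithm labels to pair (default the two
#'   deformable arms).
#' @return A tibble with one row per comparison: `segment_id`,
#'   `physician_id`, `worse_algorithm`, `better_algorithm`, `positive`,
#'   `adjustment_magnitude_worse`, `adjustment_magnitude_better`,
#'   `larger_adjustment_on_worse`, `inter_algo_mda`, `above_median`.
#' @export
build_pairwise_comparisons <- function(records,
                                       algorithms = c("contour_dir", "hybrid_dir")) {
  stopifnot(length(algorithms) == 2L)
  rec <- dplyr::filter(records, .data$algorithm %in% algorithms)
  counts <- dplyr::count(rec, .data$segment_id, .data$physician_id)
  bad <- dplyr::filter(counts, .data$n != 2L)
  if (nrow(bad) > 0L) {
    abort_domain(paste0(
      "incomplete pairs (need both algorithm arms) for: ",
      paste(utils::head(paste0(bad$segment_id, "/", bad$physician_id), 5L),
            collapse = ", ")))
  }
  wide <- rec |>
    dplyr::mutate(arm = ifelse(.data$algorithm == algorithms[1], "a1", "a2")) |>
    dplyr::select(dplyr::any_of(c("segment_id", "physician_id", "arm",
                                  "mda_gt_unadjusted", "mda_gt_adjusted",
                                  "dmda_gt_unadjusted", "dmda_gt_adjusted",
                                  "inter_algo_mda"))) |>
    tidyr::pivot_wider(names_from = "arm",
                       values_from = dplyr::any_of(c(
                         "mda_gt_unadjusted", "mda_gt_adjusted",
                         "dmda_gt_unadjusted", "dmda_gt_adjusted",
                         "inter_algo_mda")))
  cmp <- wide |>
    dplyr::mutate(
      a1_worse = .data$mda_gt_unadjusted_a1 >= .data$mda_gt_unadjusted_a2,
      worse_algorithm = ifelse(.data$a1_worse, algorithms[1], algorithms[2]),
      better_algorithm = ifelse(.data$a1_worse, algorithms[2], algorithms[1]),
      adj_worse = ifelse(.data$a1_worse, .data$mda_gt_adjusted_a1, .data$mda_gt_adjusted_a2),
      adj_better = ifelse(.data$a1_worse, .data$mda_gt_adjusted_a2, .data$mda_gt_adjusted_a1),
      positive = .data$adj_worse > .data$adj_better,
      adjustment_magnitude_worse = ifelse(
        .data$a1_worse,
        abs(.data$dmda_gt_adjusted_a1 - .data$dmda_gt_unadjusted_a1),
        abs(.data$dmda_gt_adjusted_a2 - .data$dmda_gt_unadjusted_a2)),
      adjustment_magnitude_better = ifelse(
        .data$a1_worse,
        abs(.data$dmda_gt_adjusted_a2 - .data$dmda_gt_unadjusted_a2),
        abs(.data$dmda_gt_adjusted_a1 - .data$dmda_gt_unadjusted_a1)),
      larger_adjustment_on_worse =
        .data$adjustment_magnitude_worse > .data$adjustment_magnitude_better
    )
  if ("inter_algo_mda_a1" %in% names(cmp)) {
    cmp$inter_algo_mda <- cmp$inter_algo_mda_a1
  } else {
    # fall back to the gap between the two arms' unadjusted signed deviations
    cmp$inter_algo_mda <- abs(cmp$dmda_gt_unadjusted_a1 - cmp$dmda_gt_unadjusted_a2)
  }
  med <- stats::median(cmp$inter_algo_mda)
  cmp |>
    dplyr::mutate(above_median = .data$inter_algo_mda > med) |>
    dplyr::select(dplyr::all_of(c(
      "segment_id", "physician_id", "worse_algorithm", "better_algorithm",
      "positive", "adjustment_magnitude_worse", "adjustment_magnitude_better",
      "larger_adjustment_on_worse", "inter_algo_mda", "above_median")))
}

#' Summarize pairwise comparisons as a primary-endpoint table
#'
#' Counts positive comparisons overall and in the above-/below-median
#' inter-algorithm MDA subgroups, with exact (Clopper-Pearson) confidence
#' intervals and the exact binomial superiority p-value against 0.5.
#'
#' @param comparisons Output of [build_pairwise_comparisons()].
#' @param conf_level Confidence level for the exact intervals.
#' @return A tibble with rows `all`, `above_median`, `at_or_below_median`.
#' @export
summarize_comparisons <- function(comparisons, conf_level = 0.95) {
  one <- function(df, label) {
    k <- sum(df$positive); n <- nrow(df)
    ci <- clopper_pearson_ci(k, n, level = conf_level)
    tibble::tibble(
      subgroup = label, positives = k, n = n, proportion = k / n,
      ci_lower = ci[1], ci_upper = ci[2],
      p_exact = exact_binomial_test(k, n, p0 = 0.5, direction = "greater")
    )
  }
  dplyr::bind_rows(
    one(comparisons, "all"),
    one(dplyr::filter(comparisons, .data$above_median), "above_median"),
    one(dplyr::filter(comparisons, !.data$above_median), "at_or_below_median")
  )
}
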