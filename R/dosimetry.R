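#' Dose grids
#'
#' A `dose_grid` stores dose as a percentage of the prescription on the same
#' lattice as the structure masks it is evaluated against.
#'
#' @param values 3D numeric array of dose in % of prescription (>= 0).
#' @param spacing,origin Grid geometry in mm, as for [structure_mask()].
#' @return A `dose_grid` object.
#' @export
dose_grid <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(dim(values)) != 3L) abort_geometry("`values` must be a 3D array")
  if (any(values < 0)) abort_domain("dose values must be non-negative")
  if (length(spacing) != 3L || any(spacing <= 0)) {
    abort_geometry("`spacing` must be three strictly positive mm values")
  }
  structure(list(values = values, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "dose_grid")
}

assert_dose_congruent <- function(dose, mask) {
  if (!inherits(dose, "dose_grid")) abort_geometry("`dose` must be a dose_grid")
  if (!identical(dim(dose$values), dim(mask$voxels)) ||
      !isTRUE(all.equal(dose$spacing, mask$spacing))) {
    abort_geometry("dose grid and mask are not congruent")
  }
  invisible(TRUE)
}

# rasterize a patch's mm points onto a reference grid
rasterize_patch <- function(patch, ref) {
  idx <- round(sweep(sweep(patch$points, 2, ref$origin), 2, ref$spacing, `/`) + 0.5)
  d <- dim(ref$voxels)
  ok <- idx[, 1] >= 1 & idx[, 1] <= d[1] & idx[, 2] >= 1 & idx[, 2] <= d[2] &
    idx[, 3] >= 1 & idx[, 3] <= d[3]
  v <- array(FALSE, dim = d)
  v[idx[ok, , drop = FALSE]] <- TRUE
  v
}

# morphological closing with an ellipsoidal structuring element of mm radii:
# dilation/erosion are distance-transform thresholds in the radius-scaled metric
close_ellipsoid <- function(v, spacing, radii_mm) {
  if (!any(v)) return(v)
  sc <- spacing / radii_mm
  dil <- array(cpp_edt_sq(v, dim(v), sc), dim = dim(v)) <= 1
  if (!any(!dil)) return(dil)
  ero_d <- array(cpp_edt_sq(!dil, dim(v), sc), dim = dim(v))
  dil & ero_d > 1
}

#' Extract the inter-shell volume between two surface shells
#'
#' Rasterizes both shells, closes their union with an ellipsoidal
#' structuring element, labels the connected components of the closed volume
#' outside the shells, retains only components whose one-voxel dilation
#' touches both shells, and subtracts the generating CTV. An empty result is
#' legal (zero volume).
#'
#' @param shell_a,shell_b [surface_patch()] objects (e.g. ground-truth shell
#'   and test segment).
#' @param exclude A [structure_mask()] to subtract (the generating CTV); also
#'   defines the lattice.
#' @param closing_radii_mm Ellipsoid radii in mm (default 10,10,10).
#' @return A `test_segment_volume`: `mask` ([structure_mask()]),
#'   `volume_cm3`, `parent_ctv_id`, `margin_mm` (`NA` until a margin
#'   analysis sets it).
#' @export
intershell_volume <- function(shell_a, shell_b, exclude,
                              closing_radii_mm = c(10, 10, 10)) {
  assert_patch(shell_a, "shell_a"); assert_patch(shell_b, "shell_b")
  assert_mask(exclude, "exclude")
  if (length(closing_radii_mm) == 1L) closing_radii_mm <- rep(closing_radii_mm, 3)
  ra <- rasterize_patch(shell_a, exclude)
  rb <- rasterize_patch(shell_b, exclude)
  shells <- ra | rb
  # adjacency is tested against each shell's exclusive voxels so that
  # coincident shells cannot validate a component
  ra_only <- ra & !rb
  rb_only <- rb & !ra
  closed <- close_ellipsoid(shells, exclude$spacing, closing_radii_mm)
  core <- closed & !shells
  res <- array(FALSE, dim = dim(core))
  if (any(core)) {
    lab <- array(cpp_label(core, dim(core), 26L), dim = dim(core))
    for (cc in seq_len(max(lab))) {
      comp <- lab == cc
      dil <- comp
      for (axis in 1:3) {
        dil <- dil | shift_edge(dil, -1L, axis) | shift_edge(dil, 1L, axis)
      }
      if (any(dil & ra_only) && any(dil & rb_only)) res <- res | comp
    }
  }
  # the rasterized shells are zero-volume surfaces in the continuum: the
  # voxels they occupy belong to the inter-shell volume when it is non-empty
  if (any(res)) res <- res | shells
  res <- res & !exclude$voxels
  mask <- structure_mask(res, spacing = exclude$spacing, origin = exclude$origin,
                         id = "intershell")
  structure(
    list(mask = mask, volume_cm3 = mask_volume(mask) / 1000,
         parent_ctv_id = exclude$id %||% NA_character_, margin_mm = NA_real_),
    class = "test_segment_volume"
  )
}

#' @exportS3Method base::print
print.test_segment_volume <- function(x, ...) {
  cat(sprintf("<test_segment_volume> %.3f cm^3 (parent %s, margin %s mm)\n",
              x$volume_cm3, x$parent_ctv_id, format(x$margin_mm)))
  invisible(x)
}

#' Expand a PTV-style margin around a CTV
#'
#' Isotropic outward expansion by the margin, delegating to [morph_offset()].
#'
#' @param ctv A [structure_mask()].
#' @param margin_mm Margin in mm (>= 0); the analysis uses 3, 5 and 7 mm.
#' @return The margin-expanded [structure_mask()].
#' @export
expand_margin <- function(ctv, margin_mm) {
  if (margin_mm < 0) abort_domain("`margin_mm` must be non-negative")
  morph_offset(ctv, margin_mm)
}

#' Generalized equivalent uniform dose
#'
#' The power mean of the voxel doses inside the region with exponent `a`:
#' `EUD = (mean(d^a))^(1/a)`. The tumour-typical `a = -20` emphasizes cold
#' spots. Doses below `eps` are floored before exponentiation so empty beam
#' corners cannot dominate the negative-exponent mean.
#'
#' @param dose A [dose_grid()] in % of prescription.
#' @param region A non-empty [structure_mask()] congruent with `dose`.
#' @param a Power-mean exponent (default -20; must be non-zero).
#' @param eps Dose floor in % (default 0.1).
#' @return EUD in % of prescription, between min and max region dose.
#' @export
geud <- function(dose, region, a = -20, eps = 0.1) {
  assert_mask(region, "region")
  assert_dose_congruent(dose, region)
  if (a == 0) abort_domain("`a` must be non-zero")
  if (!any(region$voxels)) abort_empty("region has no voxels: EUD undefined")
  d <- pmax(dose$values[region$voxels], eps)
  # power mean via logs for numerical stability at large |a|
  exp(log_mean_exp(a * log(d)) / a)
}

# log-mean-exp: log(mean(exp(x))) without overflow
log_mean_exp <- function(x) {
  m <- max(x)
  m + log(mean(exp(x - m)))
}

#' Synthetic planned dose for a target volume
#'
#' Emulates an adapted plan: 100% of prescription inside the (margin
#' expanded) target with a sigmoid lateral falloff outside it. The penumbra
#' width is the 80%-to-20% falloff distance; the surface dose is
#' `edge_dose` % at the target boundary.
#'
#' @param target A [structure_mask()] (typically the margin-expanded CTV).
#' @param penumbra_mm 80-20% falloff distance in mm (default 6).
#' @param edge_dose Dose in % at the target surface (default 95).
#' @return A [dose_grid()].
#' @export
dose_model <- function(target, penumbra_mm = 6, edge_dose = 95) {
  assert_mask(target, "target")
  if (!any(target$voxels)) abort_empty("target is empty")
  # signed distance: positive outside the target
  d_out <- edt_mm(target$voxels, target$spacing)
  d_in <- edt_mm(!target$voxels, target$spacing)
  s <- d_out
  s[target$voxels] <- -d_in[target$voxels]
  w <- penumbra_mm / (2 * log(4))               # logistic scale from the 80-20 span
  s0 <- w * log(edge_dose / (100 - edge_dose))  # shift so dose(0) = edge_dose
  vals <- 100 / (1 + exp((s - s0) / w))
  dose_grid(vals, spacing = target$spacing, origin = target$origin)
}

#' Margin-wise EUD coverage of test-segment volumes
#'
#' For each margin, re-plans the synthetic dose to the margin-expanded CTV
#' and computes the gEUD of every inter-shell test volume; reports the
#' fraction of volumes whose EUD falls below the threshold. Under the
#' synthetic dose model the fraction is non-increasing in the margin.
#'
#' @param volumes List of `test_segment_volume` objects (or masks).
#' @param ctv The generating CTV [structure_mask()].
#' @param margins Margins in mm (default 3, 5, 7).
#' @param threshold EUD threshold in % (default 95).
#' @param a gEUD exponent (default -20).
#' @param penumbra_mm,edge_dose Passed to [dose_model()].
#' @return A tibble with `margin_mm`, `n`, `n_below`, `frac_below`, and the
#'   per-volume EUDs nested in `euds`.
#' @export
coverage_summary <- function(volumes, ctv, margins = c(3, 5, 7), threshold = 95,
                             a = -20, penumbra_mm = 6, edge_dose = 95) {
  assert_mask(ctv, "ctv")
  if (length(volumes) == 0L) {
    return(tibble::tibble(margin_mm = numeric(), n = integer(),
                          n_below = integer(), frac_below = numeric(),
                          euds = list()))
  }
  masks <- purrr::map(volumes, function(v) {
    if (inherits(v, "test_segment_volume")) v$mask else v
  })
  purrr::map_dfr(margins, function(m) {
    ptv <- expand_margin(ctv, m)
    dose <- dose_model(ptv, penumbra_mm = penumbra_mm, edge_dose = edge_dose)
    euds <- purrr::map_dbl(masks, function(mk) {
      if (!any(mk$voxels)) return(NA_real_)
      geud(dose, mk, a = a)
    })
    ok <- !is.na(euds)
    tibble::tibble(margin_mm = m, n = sum(ok), n_below = sum(euds[ok] < threshold),
                   frac_below = sum(euds[ok] < threshold) / max(1L, sum(ok)),
                   euds = list(euds))
  })
}

#' Slice-wise closed planar contours of a mask
#'
#' Converts a binary mask to closed polygons per axial slice (the export
#' format used for re-importing structures), via the 0.5 iso-contour of each
#' slice.
#'
#' @param mask A [structure_mask()].
#' @return A tibble with `slice`, `z_mm`, `contour` (polygon index within
#'   slice), `x`, `y` (mm vertex coordinates).
#' @export
mask_slice_contours <- function(mask) {
  assert_mask(mask)
  d <- dim(mask$voxels)
  xs <- mask$origin[1] + (seq_len(d[1]) - 0.5) * mask$spacing[1]
  ys <- mask$origin[2] + (seq_len(d[2]) - 0.5) * mask$spacing[2]
  out <- purrr::map_dfr(seq_len(d[3]), function(k) {
    sl <- mask$voxels[, , k]
    if (!any(sl)) return(NULL)
    cl <- grDevices::contourLines(xs, ys, array(as.numeric(sl), dim(sl)), levels = 0.5)
    if (length(cl) == 0L) return(NULL)
    purrr::imap_dfr(cl, function(cc, i) {
      tibble::tibble(slice = k,
                     z_mm = mask$origin[3] + (k - 0.5) * mask$spacing[3],
                     contour = i, x = cc$x, y = cc$y)
    })
  })
  out
}
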