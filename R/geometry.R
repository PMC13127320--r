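#' Surface patches
#'
#' A `surface_patch` is a labelled set of surface points (voxel centres, in
#' mm) on a parent structure's surface: either a whole-surface patch, a test
#' segment, or a complementary segment.
#'
#' @param points Numeric matrix (n x 3) of mm coordinates.
#' @param parent_id Identifier of the structure the patch lies on.
#' @param octant One of the eight octant labels, or `NA`.
#' @param area_cm2 Patch surface area in cm^2, or `NA` if not yet measured.
#' @param component_id Connected-component index, or `NA`.
#' @return A `surface_patch` object.
#' @export
surface_patch <- function(points, parent_id = NA_character_, octant = NA_character_,
                          area_cm2 = NA_real_, component_id = NA_integer_) {
  points <- as.matrix(points)
  if (ncol(points) != 3L) abort_geometry("`points` must be an n x 3 mm-coordinate matrix")
  storage.mode(points) <- "double"
  colnames(points) <- c("x", "y", "z")
  structure(
    list(points = points, parent_id = parent_id, octant = octant,
         area_cm2 = area_cm2, component_id = component_id),
    class = "surface_patch"
  )
}

#' @exportS3Method base::print
print.surface_patch <- function(x, ...) {
  cat(sprintf("<surface_patch> %d points on %s; octant %s; area %s cm^2\n",
              nrow(x$points), x$parent_id %||% "?",
              x$octant, format(x$area_cm2, digits = 3)))
  invisible(x)
}

#' @export
as_tibble.surface_patch <- function(x, ...) {
  tibble::tibble(
    x = x$points[, 1], y = x$points[, 2], z = x$points[, 3],
    parent_id = x$parent_id, octant = x$octant,
    area_cm2 = x$area_cm2, component_id = x$component_id
  )
}

is_surface_patch <- function(x) inherits(x, "surface_patch")

assert_patch <- function(x, arg = "patch") {
  if (!is_surface_patch(x)) abort_geometry(sprintf("`%s` must be a surface_patch", arg))
  if (nrow(x$points) == 0L) abort_empty(sprintf("`%s` has no points", arg))
  invisible(x)
}

# ---- distance transforms ------------------------------------------------

# mm distance of every voxel to the nearest foreground voxel centre
edt_mm <- function(voxels, spacing) {
  d <- cpp_edt_sq(as.logical(voxels), dim(voxels), as.numeric(spacing))
  array(sqrt(d), dim = dim(voxels))
}

#' Expand or contract a mask by a signed physical offset
#'
#' Morphological expansion (`r > 0`) or contraction (`r < 0`) by `r` mm,
#' computed by thresholding the anisotropic Euclidean distance transform:
#' expansion keeps every voxel within `r` mm of the foreground; contraction
#' keeps foreground voxels farther than `|r|` mm from the background.
#' `r = 0` returns the mask unchanged.
#'
#' @param mask A [structure_mask()].
#' @param r Signed offset in mm (outward positive).
#' @return A [structure_mask()]; if a contraction empties the mask, the
#'   result carries `attr(, "emptied") = TRUE` and a warning is signalled.
#' @export
morph_offset <- function(mask, r) {
  assert_mask(mask)
  ext <- dim(mask$voxels) * mask$spacing
  if (abs(r) >= max(ext) / 2) {
    abort_geometry(sprintf("|r| = %.3g mm exceeds half the grid extent", abs(r)))
  }
  if (r == 0) return(mask)
  v <- mask$voxels
  if (r > 0) {
    if (!any(v)) return(mask)
    d <- edt_mm(v, mask$spacing)
    out <- d <= r
  } else {
    if (!any(!v)) {
      # no background on the grid: nothing to erode from
      return(mask)
    }
    d <- edt_mm(!v, mask$spacing)
    out <- v & d > abs(r)
  }
  res <- structure_mask(out, spacing = mask$spacing, origin = mask$origin, id = mask$id)
  if (r < 0 && !any(out)) {
    rlang::warn("contraction emptied the mask", class = "adaptbias_emptied_mask")
    attr(res, "emptied") <- TRUE
  }
  res
}

# ---- surface extraction -------------------------------------------------

# logical array marking foreground voxels with a 6-connected background
# neighbour (the grid boundary counts as background)
surface_voxels <- function(v) {
  d <- dim(v)
  bg_neighbour <- array(FALSE, dim = d)
  for (axis in 1:3) {
    for (s in c(-1L, 1L)) {
      n <- d[axis]
      idx <- seq_len(n) + s
      pad <- idx < 1L | idx > n
      idx[pad] <- 1L
      if (axis == 1) { nb <- v[idx, , , drop = FALSE]; nb[pad, , ] <- FALSE }
      else if (axis == 2) { nb <- v[, idx, , drop = FALSE]; nb[, pad, ] <- FALSE }
      else { nb <- v[, , idx, drop = FALSE]; nb[, , pad] <- FALSE }
      bg_neighbour <- bg_neighbour | !nb
    }
  }
  v & bg_neighbour
}

#' Extract the surface of a mask as a single patch
#'
#' Surface points are the centres of foreground voxels with at least one
#' 6-connected background neighbour (the grid boundary counts as
#' background), in deterministic array order.
#'
#' @param mask A [structure_mask()].
#' @param parent_id Identifier recorded on the patch; defaults to the mask id.
#' @return A [surface_patch()] covering the whole surface.
#' @export
extract_surface <- function(mask, parent_id = NULL) {
  assert_mask(mask)
  if (!any(mask$voxels)) abort_empty("cannot extract the surface of an empty mask")
  idx <- which(surface_voxels(mask$voxels), arr.ind = TRUE)
  surface_patch(voxel_centres(mask, idx), parent_id = parent_id %||% mask$id %||% NA_character_)
}

# ---- distances ----------------------------------------------------------

#' Mean distance to agreement between two surface patches
#'
#' Directed mode (the default) averages, over the source points, the
#' Euclidean distance to the nearest target point; symmetric mode averages
#' the two directed values.
#'
#' @param source,target [surface_patch()] objects (non-empty).
#' @param mode `"directed"` (source to target) or `"symmetric"`.
#' @return Mean distance in mm (non-negative scalar).
#' @export
compute_mda <- function(source, target, mode = c("directed", "symmetric")) {
  mode <- match.arg(mode)
  assert_patch(source, "source"); assert_patch(target, "target")
  d_st <- mean(cpp_nearest(source$points, target$points)$dist)
  if (mode == "directed") return(d_st)
  d_ts <- mean(cpp_nearest(target$points, source$points)$dist)
  (d_st + d_ts) / 2
}

#' Signed directional deviation of a segment from its ground truth
#'
#' The magnitude is the directed mean distance to agreement of the segment
#' against the ground-truth patch; the sign encodes whether the segment lies
#' outside (+) or inside (-) the ground truth relative to the CTV centre of
#' mass: it is the sign of the mean, over segment points, of the difference
#' between the point's radial distance from `ctv_center` and its nearest
#' ground-truth point's radial distance.
#'
#' @param segment,ground_truth [surface_patch()] objects.
#' @param ctv_center mm coordinates of the parent CTV's centre of mass.
#' @return Signed mm value; if the mean radial difference is exactly zero
#'   while the distance is not, the sign is set positive and the result
#'   carries `attr(, "ambiguous_sign") = TRUE`.
#' @export
sign_dmda <- function(segment, ground_truth, ctv_center) {
  assert_patch(segment, "segment"); assert_patch(ground_truth, "ground_truth")
  nn <- cpp_nearest(segment$points, ground_truth$points)
  mda <- mean(nn$dist)
  r_seg <- sqrt(rowSums(sweep(segment$points, 2, ctv_center)^2))
  r_gt <- sqrt(rowSums(sweep(ground_truth$points[nn$index, , drop = FALSE], 2, ctv_center)^2))
  rad <- mean(r_seg - r_gt)
  if (rad == 0 && mda > 0) {
    out <- mda
    attr(out, "ambiguous_sign") <- TRUE
    return(out)
  }
  sign(rad) * mda
}

# ---- octants ------------------------------------------------------------

octant_labels <- function() {
  c("inferior-anterior", "inferior-posterior",
    "inferior-right-lateral", "inferior-left-lateral",
    "superior-anterior", "superior-posterior",
    "superior-right-lateral", "superior-left-lateral")
}

#' Classify the octant of a point relative to a centre
#'
#' Superior/inferior follows the sign of the z displacement (ties inferior);
#' the azimuthal class is the dominant axial component: anterior/posterior
#' when `|dy| >= |dx|` (45-degree ties go to the anterior-posterior class),
#' right/left-lateral otherwise. Axis convention: +x left, +y posterior,
#' +z superior.
#'
#' @param centroid,center mm coordinates (length-3).
#' @return One of the eight octant labels.
#' @export
classify_octant <- function(centroid, center) {
  d <- as.numeric(centroid) - as.numeric(center)
  if (all(d == 0)) abort_domain("centroid coincides with the centre: octant undefined")
  si <- if (d[3] > 0) "superior" else "inferior"
  az <- if (abs(d[2]) >= abs(d[1])) {
    if (d[2] > 0) "posterior" else "anterior"
  } else {
    if (d[1] > 0) "left-lateral" else "right-lateral"
  }
  paste(si, az, sep = "-")
}

# ---- surface area -------------------------------------------------------

# replicate-edge shift of a 3D array along one axis
shift_edge <- function(a, s, axis) {
  n <- dim(a)[axis]
  idx <- pmin(pmax(seq_len(n) + s, 1L), n)
  switch(axis, a[idx, , , drop = FALSE], a[, idx, , drop = FALSE], a[, , idx, drop = FALSE])
}

# light separable smoothing of the binary occupancy (one 3-wide box pass per
# axis) so the 0.5 iso-level sits at sub-voxel accuracy without rounding
# sharp edges away
smooth_occupancy <- function(v, passes = 1L) {
  u <- array(as.numeric(v), dim = dim(v))
  for (p in seq_len(passes)) {
    for (axis in 1:3) {
      u <- (shift_edge(u, -1L, axis) + u + shift_edge(u, 1L, axis)) / 3
    }
  }
  u
}

# triangulate the 0.5 iso-surface of the smoothed occupancy; one row per
# triangle (centroid mm + area mm^2)
iso_triangles <- function(mask) {
  u <- smooth_occupancy(mask$voxels)
  cpp_iso_triangles(as.numeric(u), dim(mask$voxels), mask$spacing, mask$origin, 0.5)
}

#' Surface area of a patch in cm^2
#'
#' The mask's 0.5 iso-level surface (of the lightly smoothed occupancy) is
#' triangulated; each triangle is assigned to its nearest surface voxel, and
#' the patch area is the summed area of the triangles owned by the patch's
#' points. This partitions the total surface area exactly across patches.
#'
#' @param patch A [surface_patch()] whose points lie on `mask`'s surface.
#' @param mask The parent [structure_mask()].
#' @return Area in cm^2 (strictly positive).
#' @export
patch_area <- function(patch, mask) {
  assert_patch(patch); assert_mask(mask)
  surf_idx <- which(surface_voxels(mask$voxels), arr.ind = TRUE)
  surf_pts <- voxel_centres(mask, surf_idx)
  # patch points must be a subset of the mask's surface voxel centres
  chk <- cpp_nearest(patch$points, surf_pts)
  if (any(chk$dist > 1e-6)) {
    abort_patch("patch points do not lie on the mask's surface voxel set")
  }
  on_patch <- logical(nrow(surf_pts))
  on_patch[chk$index] <- TRUE
  tri <- iso_triangles(mask)
  if (nrow(tri) == 0L) abort_empty("mask has no iso-surface")
  own <- cpp_nearest(tri[, 1:3, drop = FALSE], surf_pts)$index
  area_mm2 <- sum(tri[on_patch[own], 4])
  if (area_mm2 <= 0) abort_patch("patch owns no surface triangles")
  area_mm2 / 100
}
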