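#' Binary structure masks with physical spacing
#'
#' A `structure_mask` represents one anatomical structure (CTV, bladder,
#' rectum, ground-truth shell, ...) as a 3D binary occupancy grid together
#' with its anisotropic voxel spacing and grid origin, all in millimetres.
#' The axis convention is fixed throughout the package: x runs right to left,
#' y anterior to posterior, z inferior to superior; voxel centres sit at
#' `origin + (index - 0.5) * spacing`.
#'
#' @param voxels A 3D `logical` (or coercible) array; `TRUE` is foreground.
#' @param spacing Numeric length-3, voxel spacing `(dx, dy, dz)` in mm; all
#'   strictly positive.
#' @param origin Numeric length-3, mm position of the grid corner.
#' @param id Optional structure identifier (character scalar).
#' @return A `structure_mask` object.
#' @examples
#' m <- sphere_mask(radius = 10, spacing = c(1, 1, 1), grid_dim = c(32, 32, 32))
#' mask_volume(m) # ~ (4/3) * pi * 10^3 mm^3
#' @export
structure_mask <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                           id = NULL) {
  if (length(dim(voxels)) != 3L || any(dim(voxels) < 1L)) {
    abort_geometry("`voxels` must be a non-empty 3D array")
  }
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    abort_geometry("`spacing` must be three strictly positive mm values")
  }
  if (length(origin) != 3L || any(!is.finite(origin))) {
    abort_geometry("`origin` must be three finite mm values")
  }
  v <- array(as.logical(voxels), dim = dim(voxels))
  v[is.na(v)] <- FALSE
  structure(
    list(voxels = v, spacing = as.numeric(spacing),
         origin = as.numeric(origin), id = id),
    class = "structure_mask"
  )
}

#' @exportS3Method base::print
print.structure_mask <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf(
    "<structure_mask%s> %dx%dx%d @ (%.3g, %.3g, %.3g) mm; %d foreground voxels (%.2f cm^3)\n",
    if (is.null(x$id)) "" else paste0(": ", x$id),
    d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
    sum(x$voxels), mask_volume(x) / 1000
  ))
  invisible(x)
}

#' @export
dim.structure_mask <- function(x) dim(x$voxels)

is_structure_mask <- function(x) inherits(x, "structure_mask")

assert_mask <- function(x, arg = "mask") {
  if (!is_structure_mask(x)) abort_geometry(sprintf("`%s` must be a structure_mask", arg))
  invisible(x)
}

assert_same_grid <- function(a, b) {
  if (!identical(dim(a$voxels), dim(b$voxels)) ||
      !isTRUE(all.equal(a$spacing, b$spacing)) ||
      !isTRUE(all.equal(a$origin, b$origin))) {
    abort_geometry("masks must share grid dimensions, spacing and origin")
  }
  invisible(TRUE)
}

#' Foreground volume of a mask in mm^3
#' @param mask A [structure_mask()].
#' @return Scalar volume in mm^3.
#' @export
mask_volume <- function(mask) {
  assert_mask(mask)
  sum(mask$voxels) * prod(mask$spacing)
}

#' Centre of mass of a mask's foreground, in mm
#' @param mask A [structure_mask()].
#' @return Numeric length-3 mm coordinate.
#' @export
mask_centroid <- function(mask) {
  assert_mask(mask)
  if (!any(mask$voxels)) abort_empty("mask has no foreground voxels")
  idx <- which(mask$voxels, arr.ind = TRUE)
  mask$origin + (colMeans(idx) - 0.5) * mask$spacing
}

# mm coordinates of voxel centres for integer array indices (n x 3)
voxel_centres <- function(mask, idx) {
  sweep(sweep(idx - 0.5, 2, mask$spacing, `*`), 2, mask$origin, `+`)
}

#' Read and write masks as NIfTI-1 volumes
#'
#' Masks are stored as binary (0/1) NIfTI-1 volumes; spacing is carried in
#' `pixdim` and the origin in the sform translation. Values above 0.5 are
#' read as foreground.
#'
#' @param path File path (`.nii` or `.nii.gz`).
#' @param mask A [structure_mask()].
#' @return `read_mask()` returns a [structure_mask()]; `write_mask()` returns
#'   `path` invisibly.
#' @export
read_mask <- function(path) {
  img <- RNifti::readNifti(path)
  hdr <- RNifti::niftiHeader(img)
  spacing <- hdr$pixdim[2:4]
  if (any(!is.finite(spacing)) || any(spacing <= 0)) {
    abort_geometry(sprintf("non-positive voxel spacing in %s", path))
  }
  origin <- c(hdr$srow_x[4], hdr$srow_y[4], hdr$srow_z[4])
  arr <- array(as.numeric(img), dim = dim(img)[1:3])
  structure_mask(arr > 0.5, spacing = spacing, origin = origin)
}

#' @rdname read_mask
#' @export
write_mask <- function(mask, path) {
  assert_mask(mask)
  arr <- array(as.integer(mask$voxels), dim = dim(mask$voxels))
  img <- RNifti::asNifti(arr)
  aff <- diag(c(mask$spacing, 1))
  aff[1:3, 4] <- mask$origin
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  RNifti::pixdim(img) <- mask$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Rasterize a sphere as a structure mask
#'
#' Convenience constructor used throughout tests and examples: a ball of the
#' given radius centred in the grid (or at `center`).
#'
#' @param radius Sphere radius in mm.
#' @param spacing Voxel spacing in mm.
#' @param grid_dim Grid dimensions (voxels).
#' @param center mm coordinates of the sphere centre; default grid centre.
#' @param origin Grid origin in mm.
#' @return A [structure_mask()].
#' @export
sphere_mask <- function(radius, spacing = c(1, 1, 1), grid_dim = c(64, 64, 64),
                        center = NULL, origin = c(0, 0, 0)) {
  center <- center %||% (origin + grid_dim * spacing / 2)
  ax <- origin[1] + (seq_len(grid_dim[1]) - 0.5) * spacing[1]
  ay <- origin[2] + (seq_len(grid_dim[2]) - 0.5) * spacing[2]
  az <- origin[3] + (seq_len(grid_dim[3]) - 0.5) * spacing[3]
  dx2 <- (ax - center[1])^2
  dy2 <- (ay - center[2])^2
  dz2 <- (az - center[3])^2
  r2 <- outer(outer(dx2, dy2, `+`), dz2, `+`)
  structure_mask(r2 <= radius^2, spacing = spacing, origin = origin)
}
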