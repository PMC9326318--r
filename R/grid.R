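#' Regular 3-D image grid
#'
#' A grid is the geometry of a sampled volume: voxel counts per axis,
#' spacing in mm, and the world position (RAS+ mm) of the centre of voxel
#' (0,0,0). Voxel indices are 0-based and a voxel is identified with its
#' centre, so the world position of voxel (i,j,k) is
#' `origin + c(i,j,k) * spacing`.
#'
#' @param shape integer vector of length 3, voxels per axis (all >= 1).
#' @param spacing numeric vector of length 3, mm per voxel (all > 0).
#' @param origin numeric vector of length 3, world mm of voxel (0,0,0).
#' @return an object of class `image_grid`.
#' @export
image_grid <- function(shape, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  shape <- as.integer(round(shape))
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(shape) != 3L || any(is.na(shape)) || any(shape < 1L))
    stop("grid shape must be 3 positive integers")
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("grid spacing must be 3 positive finite values (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("grid origin must be 3 finite world coordinates (mm)")
  structure(list(shape = shape, spacing = spacing, origin = origin,
                 orientation = "RAS+"),
            class = "image_grid")
}

#' @export
print.image_grid <- function(x, ...) {
  cat(sprintf("<image_grid> %d x %d x %d voxels, spacing (%g, %g, %g) mm, origin (%g, %g, %g) mm [%s]\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$spacing[1], x$spacing[2], x$spacing[3],
              x$origin[1], x$origin[2], x$origin[3], x$orientation))
  invisible(x)
}

#' 4x4 voxel-to-world affine of a grid (0-based voxel indices)
#' @param grid an `image_grid`.
#' @return 4x4 numeric matrix.
#' @export
grid_affine <- function(grid) {
  m <- diag(c(grid$spacing, 1))
  m[1:3, 4] <- grid$origin
  m
}

#' Convert world coordinates (mm) to continuous 0-based voxel indices
#' @param grid an `image_grid`.
#' @param xyz numeric length-3 vector or n x 3 matrix of world mm.
#' @return matrix of the same shape with continuous voxel indices.
#' @export
world_to_voxel <- function(grid, xyz) {
  xyz <- rbind_coords(xyz)
  sweep(sweep(xyz, 2, grid$origin, "-"), 2, grid$spacing, "/")
}

#' Convert 0-based voxel indices to world coordinates (mm)
#' @param grid an `image_grid`.
#' @param ijk numeric length-3 vector or n x 3 matrix of 0-based indices.
#' @return matrix of world mm coordinates.
#' @export
voxel_to_world <- function(grid, ijk) {
  ijk <- rbind_coords(ijk)
  sweep(sweep(ijk, 2, grid$spacing, "*"), 2, grid$origin, "+")
}

rbind_coords <- function(x) {
  if (is.null(dim(x))) x <- matrix(as.numeric(x), ncol = 3)
  if (ncol(x) != 3L) stop("coordinates must have 3 columns")
  x
}

#' Volume of one voxel in mm^3
#' @param grid an `image_grid`.
#' @export
voxel_volume_mm3 <- function(grid) prod(grid$spacing)

#' Test whether two grids describe the same sampling
#' @param a,b `image_grid` objects.
#' @param tol absolute tolerance (mm) on spacing and origin.
#' @export
grids_equal <- function(a, b, tol = 1e-6) {
  identical(a$shape, b$shape) &&
    all(abs(a$spacing - b$spacing) <= tol) &&
    all(abs(a$origin - b$origin) <= tol)
}

# world-extent of a grid: the box spanned by the outermost voxel *centres*
grid_extent <- function(grid) {
  lo <- grid$origin
  hi <- grid$origin + (grid$shape - 1L) * grid$spacing
  rbind(lo = lo, hi = hi)
}

#' Default 1 mm isotropic analysis grid bounding a set of masks
#'
#' Builds the common analysis grid the pipeline resamples onto: isotropic
#' voxels bounding the union of the mask voxels, expanded by a margin.
#'
#' @param masks a `tumor_mask` or list of `tumor_mask` objects.
#' @param spacing isotropic voxel size in mm (default 1).
#' @param margin margin in voxels added on every side (default 5).
#' @return an `image_grid`.
#' @export
default_analysis_grid <- function(masks, spacing = 1, margin = 5) {
  if (inherits(masks, "tumor_mask")) masks <- list(masks)
  if (length(masks) == 0L) stop("no masks supplied")
  lo <- rep(Inf, 3); hi <- rep(-Inf, 3)
  for (m in masks) {
    idx <- which(m$member, arr.ind = TRUE) - 1L
    if (nrow(idx) == 0L) next
    w_lo <- voxel_to_world(m$grid, apply(idx, 2, min))
    w_hi <- voxel_to_world(m$grid, apply(idx, 2, max))
    lo <- pmin(lo, as.numeric(w_lo)); hi <- pmax(hi, as.numeric(w_hi))
  }
  if (any(!is.finite(lo))) stop("all masks are empty")
  lo <- lo - margin * spacing
  hi <- hi + margin * spacing
  shape <- pmax(1L, as.integer(floor((hi - lo) / spacing)) + 1L)
  image_grid(shape, spacing = rep(spacing, 3), origin = lo)
}
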