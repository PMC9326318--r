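#' @importFrom RNifti readNifti writeNifti asNifti pixdim xform
NULL

MODALITIES <- c("Vp", "FAZA", "MD")
MODALITY_UNITS <- c(Vp = "mL/100 mL", FAZA = "arbitrary", MD = "mm^2/s")
MASK_FLAVORS <- c("CE", "FLAIR")

#' Parametric map on an image grid
#'
#' One scalar 3-D map: DCE-derived plasma volume (`Vp`, mL/100 mL),
#' 18F-FAZA PET uptake (`FAZA`, arbitrary/SUV-like units), or DTI mean
#' diffusivity (`MD`, mm^2/s). `NA`/`NaN` values are permitted (they mark
#' voxels outside the usable field of view, e.g. resampling borders) and
#' are excluded from all downstream statistics; infinities are not.
#'
#' @param values 3-D numeric array matching `grid$shape`.
#' @param grid an [image_grid()].
#' @param modality one of `"Vp"`, `"FAZA"`, `"MD"`.
#' @param subject_id subject identifier carried through the pipeline.
#' @param units unit string; defaults to the conventional unit per modality.
#' @return an object of class `parametric_volume`.
#' @export
parametric_volume <- function(values, grid, modality, subject_id = "",
                              units = NULL) {
  modality <- match.arg(modality, MODALITIES)
  if (is.null(units)) units <- unname(MODALITY_UNITS[modality])
  values <- as.array(values)
  if (length(dim(values)) != 3L || !all(dim(values) == grid$shape))
    stop(sprintf("values array (%s) does not match grid shape (%s)",
                 paste(dim(values), collapse = "x"),
                 paste(grid$shape, collapse = "x")))
  if (any(is.infinite(values)))
    stop(sprintf("subject '%s': %s map contains infinite values", subject_id, modality))
  if (modality == "MD" && any(values < 0, na.rm = TRUE))
    stop(sprintf("subject '%s': MD map contains negative diffusivities", subject_id))
  structure(list(grid = grid, values = values, modality = modality,
                 units = units, subject_id = subject_id),
            class = "parametric_volume")
}

#' @export
print.parametric_volume <- function(x, ...) {
  cat(sprintf("<parametric_volume> %s [%s], subject '%s', %s voxels, %d non-finite\n",
              x$modality, x$units, x$subject_id,
              paste(x$grid$shape, collapse = "x"),
              sum(!is.finite(x$values))))
  invisible(x)
}

#' Binary tumor mask on an image grid
#'
#' Either the contrast-enhancing core (`CE`) or the larger FLAIR
#' hyperintense region (`FLAIR`) used as the clustering ROI.
#'
#' @param member 3-D logical array matching `grid$shape`.
#' @param grid an [image_grid()].
#' @param flavor `"CE"` or `"FLAIR"`.
#' @param subject_id subject identifier.
#' @return an object of class `tumor_mask`.
#' @export
tumor_mask <- function(member, grid, flavor, subject_id = "") {
  flavor <- match.arg(flavor, MASK_FLAVORS)
  member <- as.array(member)
  storage.mode(member) <- "logical"
  member[is.na(member)] <- FALSE
  if (length(dim(member)) != 3L || !all(dim(member) == grid$shape))
    stop("mask array does not match grid shape")
  if (!any(member))
    stop(sprintf("subject '%s': %s tumor mask is empty", subject_id, flavor))
  structure(list(grid = grid, member = member, flavor = flavor,
                 subject_id = subject_id),
            class = "tumor_mask")
}

#' @export
print.tumor_mask <- function(x, ...) {
  cat(sprintf("<tumor_mask> %s, subject '%s', %d voxels (%.1f cm^3)\n",
              x$flavor, x$subject_id, sum(x$member), mask_volume_cm3(x)))
  invisible(x)
}

#' Mask volume in cm^3 (member voxel count times voxel volume)
#' @param mask a `tumor_mask`.
#' @export
mask_volume_cm3 <- function(mask) {
  sum(mask$member) * voxel_volume_mm3(mask$grid) / 1000
}

# --- NIfTI I/O -------------------------------------------------------------

# Extract an image_grid from a NIfTI image; only axis-aligned RAS+ grids
# (diagonal positive rotation part) are supported.
grid_from_nifti <- function(img, path = "<nifti>") {
  d <- dim(img)
  if (length(d) != 3L)
    stop(sprintf("'%s': expected 3-D volume, got %d-D", path, length(d)))
  m <- RNifti::xform(img)
  rot <- m[1:3, 1:3]
  spacing <- diag(rot)
  if (any(!is.finite(spacing)) || any(spacing <= 0) ||
      max(abs(rot - diag(spacing))) > 1e-4 * max(abs(spacing)))
    stop(sprintf("'%s': non-finite, non-positive or oblique voxel grid; only axis-aligned RAS+ NIfTI is supported", path))
  image_grid(d, spacing = spacing, origin = m[1:3, 4])
}

#' Read a parametric map from a 3-D NIfTI file
#'
#' @param path NIfTI file (.nii or .nii.gz).
#' @param modality one of `"Vp"`, `"FAZA"`, `"MD"`.
#' @param subject_id subject identifier (defaults to the file stem).
#' @return a [parametric_volume()] with the grid taken from the header;
#'   values are kept in native units and never silently resampled.
#' @export
read_volume <- function(path, modality, subject_id = NULL) {
  if (!file.exists(path)) stop(sprintf("volume file not found: '%s'", path))
  img <- RNifti::readNifti(path)
  grid <- grid_from_nifti(img, path)
  if (is.null(subject_id))
    subject_id <- sub("\\.nii(\\.gz)?$", "", basename(path))
  parametric_volume(array(as.numeric(img), dim = dim(img)), grid,
                    modality = modality, subject_id = subject_id)
}

#' Read a binary tumor mask from a 3-D NIfTI file
#'
#' Any nonzero voxel is a member. The member count and volume in cm^3 are
#' attached as attributes `n_voxels` and `volume_cm3`.
#'
#' @inheritParams read_volume
#' @param flavor `"CE"` or `"FLAIR"`.
#' @export
read_mask <- function(path, flavor, subject_id = NULL) {
  if (!file.exists(path)) stop(sprintf("mask file not found: '%s'", path))
  img <- RNifti::readNifti(path)
  grid <- grid_from_nifti(img, path)
  if (is.null(subject_id))
    subject_id <- sub("\\.nii(\\.gz)?$", "", basename(path))
  member <- array(as.numeric(img) != 0, dim = dim(img))
  member[is.na(member)] <- FALSE
  if (!any(member))
    stop(sprintf("subject '%s': mask '%s' has no nonzero voxels", subject_id, path))
  m <- tumor_mask(member, grid, flavor = flavor, subject_id = subject_id)
  attr(m, "n_voxels") <- sum(member)
  attr(m, "volume_cm3") <- mask_volume_cm3(m)
  m
}

nifti_with_grid <- function(values, grid) {
  img <- RNifti::asNifti(values)
  RNifti::pixdim(img) <- grid$spacing
  aff <- grid_affine(grid)
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::qform(img) <- structure(aff, code = 2L)
  img
}

#' Write a parametric volume, mask, or habitat label map to NIfTI
#'
#' @param x a `parametric_volume`, `tumor_mask` or `habitat_map`.
#' @param path output path (.nii or .nii.gz).
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path) {
  values <- if (inherits(x, "parametric_volume")) x$values
            else if (inherits(x, "tumor_mask")) array(as.integer(x$member), dim = x$grid$shape)
            else if (inherits(x, "habitat_map")) x$label
            else stop("cannot write object of class ", paste(class(x), collapse = "/"))
  RNifti::writeNifti(nifti_with_grid(values, x$grid), path)
  invisible(path)
}

# --- Resampling ------------------------------------------------------------

#' Resample a volume onto a target grid
#'
#' Maps every target voxel centre to world coordinates and interpolates the
#' source volume there. `"trilinear"` is for parametric maps, `"nearest"`
#' for masks and label maps. Target voxels falling outside the source grid
#' become `NA` and are treated as outside-mask downstream. Trilinear output
#' is a convex combination of source values, so it never overshoots the
#' source range.
#'
#' @param volume a [parametric_volume()].
#' @param target an [image_grid()].
#' @param method `"trilinear"` or `"nearest"`.
#' @return a [parametric_volume()] on `target`.
#' @export
resample_to_grid <- function(volume, target, method = c("trilinear", "nearest")) {
  method <- match.arg(method)
  if (grids_equal(volume$grid, target)) {
    out <- volume
    out$grid <- target
    return(out)
  }
  se <- grid_extent(volume$grid); te <- grid_extent(target)
  if (any(te["lo", ] > se["hi", ]) || any(te["hi", ] < se["lo", ]))
    stop(sprintf("subject '%s': source and target grids are disjoint in world space", volume$subject_id))
  vals <- interp_array(volume$values, volume$grid, target, method)
  parametric_volume(vals, target, volume$modality, volume$subject_id, volume$units)
}

#' Resample a tumor mask onto a target grid (nearest neighbour)
#' @param mask a [tumor_mask()].
#' @param target an [image_grid()].
#' @export
resample_mask_to_grid <- function(mask, target) {
  if (grids_equal(mask$grid, target)) {
    out <- mask; out$grid <- target
    return(out)
  }
  vals <- interp_array(array(as.numeric(mask$member), dim = mask$grid$shape),
                       mask$grid, target, "nearest")
  vals[is.na(vals)] <- 0
  tumor_mask(vals != 0, target, mask$flavor, mask$subject_id)
}

# vectorized world-space interpolation of a 3-D array
interp_array <- function(arr, src, target, method) {
  sh <- target$shape
  i <- rep(0:(sh[1] - 1L), times = sh[2] * sh[3])
  j <- rep(rep(0:(sh[2] - 1L), each = sh[1]), times = sh[3])
  k <- rep(0:(sh[3] - 1L), each = sh[1] * sh[2])
  # world position of each target voxel centre, then continuous source index
  u1 <- (target$origin[1] + i * target$spacing[1] - src$origin[1]) / src$spacing[1]
  u2 <- (target$origin[2] + j * target$spacing[2] - src$origin[2]) / src$spacing[2]
  u3 <- (target$origin[3] + k * target$spacing[3] - src$origin[3]) / src$spacing[3]
  ss <- src$shape
  out <- rep(NA_real_, length(u1))
  if (method == "nearest") {
    r1 <- round(u1); r2 <- round(u2); r3 <- round(u3)
    ok <- r1 >= 0 & r1 <= ss[1] - 1 & r2 >= 0 & r2 <= ss[2] - 1 &
          r3 >= 0 & r3 <= ss[3] - 1
    out[ok] <- arr[cbind(r1[ok] + 1, r2[ok] + 1, r3[ok] + 1)]
  } else {
    ok <- u1 >= 0 & u1 <= ss[1] - 1 & u2 >= 0 & u2 <= ss[2] - 1 &
          u3 >= 0 & u3 <= ss[3] - 1
    u1 <- u1[ok]; u2 <- u2[ok]; u3 <- u3[ok]
    f1 <- pmin(floor(u1), ss[1] - 2); f1 <- pmax(f1, 0)
    f2 <- pmin(floor(u2), ss[2] - 2); f2 <- pmax(f2, 0)
    f3 <- pmin(floor(u3), ss[3] - 2); f3 <- pmax(f3, 0)
    if (ss[1] == 1L) f1 <- rep(0, length(u1))
    if (ss[2] == 1L) f2 <- rep(0, length(u2))
    if (ss[3] == 1L) f3 <- rep(0, length(u3))
    w1 <- u1 - f1; w2 <- u2 - f2; w3 <- u3 - f3
    g1 <- pmin(f1 + 1, ss[1] - 1); g2 <- pmin(f2 + 1, ss[2] - 1)
    g3 <- pmin(f3 + 1, ss[3] - 1)
    acc <-      arr[cbind(f1 + 1, f2 + 1, f3 + 1)] * (1 - w1) * (1 - w2) * (1 - w3)
    acc <- acc + arr[cbind(g1 + 1, f2 + 1, f3 + 1)] * w1 * (1 - w2) * (1 - w3)
    acc <- acc + arr[cbind(f1 + 1, g2 + 1, f3 + 1)] * (1 - w1) * w2 * (1 - w3)
    acc <- acc + arr[cbind(g1 + 1, g2 + 1, f3 + 1)] * w1 * w2 * (1 - w3)
    acc <- acc + arr[cbind(f1 + 1, f2 + 1, g3 + 1)] * (1 - w1) * (1 - w2) * w3
    acc <- acc + arr[cbind(g1 + 1, f2 + 1, g3 + 1)] * w1 * (1 - w2) * w3
    acc <- acc + arr[cbind(f1 + 1, g2 + 1, g3 + 1)] * (1 - w1) * w2 * w3
    acc <- acc + arr[cbind(g1 + 1, g2 + 1, g3 + 1)] * w1 * w2 * w3
    out[ok] <- acc
  }
  array(out, dim = sh)
}

# --- Alignment report ------------------------------------------------------

#' Check that all volumes and masks of a cohort share their subject grid
#'
#' Report-only: for each subject the first input defines the reference
#' grid and every other input is compared against it.
#'
#' @param volumes list of [parametric_volume()] objects.
#' @param masks optional list of [tumor_mask()] objects.
#' @return a data.frame with one row per input (`subject_id`, `input`,
#'   `aligned`, `detail`); attribute `aligned` is `TRUE` when every row is.
#'   When a CE and a FLAIR mask share a grid and CE is not a subset of
#'   FLAIR, a non-subset note is added (validated, not enforced).
#' @export
check_cohort_alignment <- function(volumes, masks = list()) {
  if (length(volumes) == 0L) stop("no volumes supplied")
  inputs <- c(volumes, masks)
  ids <- vapply(inputs, function(x) x$subject_id, character(1))
  rows <- list()
  for (sid in unique(ids)) {
    grp <- inputs[ids == sid]
    ref <- grp[[1]]$grid
    for (x in grp) {
      name <- if (inherits(x, "tumor_mask")) paste0("mask:", x$flavor)
              else paste0("map:", x$modality)
      ok <- grids_equal(x$grid, ref)
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = sid, input = name, aligned = ok,
        detail = if (ok) "aligned" else
          sprintf("grid mismatch: %s vs reference %s",
                  paste(x$grid$shape, collapse = "x"),
                  paste(ref$shape, collapse = "x")),
        stringsAsFactors = FALSE)
    }
    flav <- vapply(grp, function(x) if (inherits(x, "tumor_mask")) x$flavor else "", character(1))
    ce <- grp[flav == "CE"]; fl <- grp[flav == "FLAIR"]
    if (length(ce) && length(fl) && grids_equal(ce[[1]]$grid, fl[[1]]$grid)) {
      outside <- sum(ce[[1]]$member & !fl[[1]]$member)
      if (outside > 0)
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = sid, input = "mask:CE", aligned = TRUE,
          detail = sprintf("%d CE voxels outside FLAIR mask (not enforced)", outside),
          stringsAsFactors = FALSE)
    }
  }
  report <- do.call(rbind, rows)
  attr(report, "aligned") <- all(report$aligned)
  report
}
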