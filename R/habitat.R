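# per-voxel cluster codes used by binary cluster volumes
CL_OUTSIDE <- 0L
CL_LOW <- 1L
CL_HIGH <- 2L
CL_EXCLUDED <- 3L

#' The fixed eight-habitat labelling convention
#'
#' Habitats are every combination of high (H) / low (L) states of the
#' three maps in the fixed column order perfusion (Vp), hypoxia (FAZA),
#' diffusivity (MD): 1 = HHH, 2 = HHL, 3 = HLH, 4 = HLL, 5 = LHH,
#' 6 = LHL, 7 = LLH, 8 = LLL.
#'
#' @return an object of class `habitat_definition` with the map order and
#'   the 8-row label table.
#' @export
habitat_definition <- function() {
  tbl <- expand.grid(MD = c("H", "L"), FAZA = c("H", "L"), Vp = c("H", "L"),
                     stringsAsFactors = FALSE)[, c("Vp", "FAZA", "MD")]
  tbl <- cbind(label = 1:8, tbl)
  structure(list(map_order = MODALITIES, label_table = tbl),
            class = "habitat_definition")
}

#' Label (1-8) of a high/low state triple
#' @param vp,faza,md `"H"` or `"L"` (vectorized).
#' @export
habitat_label_of <- function(vp, faza, md) {
  1L + 4L * (vp == "L") + 2L * (faza == "L") + 1L * (md == "L")
}

#' High/low state triple of a habitat label
#' @param label integer vector in 1..8.
#' @return data.frame with columns `Vp`, `FAZA`, `MD`.
#' @export
habitat_triple_of <- function(label) {
  stopifnot(all(label %in% 1:8))
  habitat_definition()$label_table[label, c("Vp", "FAZA", "MD")]
}

#' Voxel inclusion mask: mean +/- k SD inside the ROI
#'
#' A voxel enters the clustering iff it is inside the ROI, its value is
#' finite, and it lies within `k` standard deviations of the ROI mean
#' (mean and SD over finite in-ROI values). With a constant map (SD = 0)
#' every finite in-ROI voxel is included.
#'
#' @param volume a [parametric_volume()].
#' @param roi a [tumor_mask()] on the same grid.
#' @param k outlier cut in SD units (default 3).
#' @return logical array; attributes `roi_mean` and `roi_sd` carry the
#'   statistics used.
#' @export
inclusion_mask <- function(volume, roi, k = 3) {
  if (!grids_equal(volume$grid, roi$grid))
    stop(sprintf("subject '%s': %s map and %s mask are on different grids",
                 volume$subject_id, volume$modality, roi$flavor))
  v <- volume$values
  in_roi <- roi$member & is.finite(v)
  if (!any(in_roi))
    stop(sprintf("subject '%s': no finite %s values inside the ROI",
                 volume$subject_id, volume$modality))
  m <- mean(v[in_roi]); s <- stats::sd(v[in_roi])
  if (!is.finite(s)) s <- 0
  inc <- in_roi & abs(v - m) <= k * s
  attr(inc, "roi_mean") <- m
  attr(inc, "roi_sd") <- s
  inc
}

#' Binarize a map into high/low clusters at an Otsu threshold
#'
#' Included voxels with value `> T` become high (H), `<= T` low (L)
#' (values exactly at the threshold are low). In-ROI voxels failing the
#' inclusion rule are `excluded`; everything else is `outside`. The L and
#' H clusters are disjoint by construction.
#'
#' @param volume a [parametric_volume()].
#' @param roi the [tumor_mask()] defining in-ROI voxels.
#' @param included logical array from [inclusion_mask()].
#' @param otsu an [otsu_threshold()] result computed from this volume's
#'   included values.
#' @return an object of class `binary_cluster_volume`.
#' @export
binarize <- function(volume, roi, included, otsu) {
  if (!grids_equal(volume$grid, roi$grid))
    stop("volume and roi grid mismatch")
  if (!all(dim(included) == volume$grid$shape))
    stop("inclusion mask does not match grid shape")
  lab <- array(CL_OUTSIDE, dim = volume$grid$shape)
  lab[roi$member] <- CL_EXCLUDED
  lab[included & volume$values > otsu$threshold] <- CL_HIGH
  lab[included & volume$values <= otsu$threshold] <- CL_LOW
  structure(list(grid = volume$grid, label = lab, modality = volume$modality,
                 otsu = otsu, subject_id = volume$subject_id),
            class = "binary_cluster_volume")
}

#' Intersect three binary cluster volumes into the 8-habitat map
#'
#' Each voxel's (Vp, FAZA, MD) high/low triple is mapped to its habitat
#' label (1 = HHH ... 8 = LLL). A voxel excluded on at least one map gets
#' label 0 (in-mask, unassigned); voxels outside the ROI stay 0 and are
#' flagged by the ROI carried on the result.
#'
#' @param b_vp,b_faza,b_md `binary_cluster_volume`s for the three maps, in
#'   any argument order (matched by modality tag).
#' @param definition a [habitat_definition()].
#' @param subject_id subject identifier (defaults to the Vp volume's).
#' @return an object of class `habitat_map` with fields `grid`, `label`
#'   (integer array 0-8), `roi` (logical array), `definition`,
#'   `provenance` (the three `otsu_result`s).
#' @export
combine_clusters <- function(b_vp, b_faza, b_md,
                             definition = habitat_definition(),
                             subject_id = NULL) {
  vols <- list(b_vp, b_faza, b_md)
  tags <- vapply(vols, function(x) x$modality, character(1))
  if (anyDuplicated(tags) || !setequal(tags, MODALITIES))
    stop("combine_clusters needs exactly one volume per modality (Vp, FAZA, MD); got: ",
         paste(tags, collapse = ", "))
  names(vols) <- tags
  vp <- vols[["Vp"]]; faza <- vols[["FAZA"]]; md <- vols[["MD"]]
  if (!grids_equal(vp$grid, faza$grid) || !grids_equal(vp$grid, md$grid))
    stop("cluster volumes are on different grids")
  roi <- vp$label != CL_OUTSIDE
  if (!identical(roi, faza$label != CL_OUTSIDE) ||
      !identical(roi, md$label != CL_OUTSIDE))
    stop("cluster volumes disagree on the ROI")
  if (is.null(subject_id)) subject_id <- vp$subject_id
  assigned <- vp$label %in% c(CL_LOW, CL_HIGH) &
              faza$label %in% c(CL_LOW, CL_HIGH) &
              md$label %in% c(CL_LOW, CL_HIGH)
  lab <- array(0L, dim = vp$grid$shape)
  lab[assigned] <- 1L + 4L * (vp$label[assigned] == CL_LOW) +
                        2L * (faza$label[assigned] == CL_LOW) +
                        1L * (md$label[assigned] == CL_LOW)
  structure(list(grid = vp$grid, label = lab, roi = roi,
                 subject_id = subject_id, definition = definition,
                 provenance = list(Vp = vp$otsu, FAZA = faza$otsu, MD = md$otsu)),
            class = "habitat_map")
}

#' @export
print.habitat_map <- function(x, ...) {
  n_roi <- sum(x$roi)
  n_assigned <- sum(x$label > 0L)
  cat(sprintf("<habitat_map> subject '%s', %d ROI voxels, %d assigned (labels 1-8), %d unassigned\n",
              x$subject_id, n_roi, n_assigned, n_roi - n_assigned))
  tab <- tabulate(x$label[x$label > 0L], nbins = 8L)
  cat("  habitat counts:", paste(sprintf("%d:%d", 1:8, tab), collapse = " "), "\n")
  invisible(x)
}

#' Pipeline configuration
#'
#' @param mask_flavor ROI flavor used for clustering, `"FLAIR"` (default,
#'   the whole-tumor mask) or `"CE"`.
#' @param n_bins Otsu histogram bins (default 256).
#' @param outlier_k inclusion cut in SD units (default 3).
#' @param excluded_policy fate of in-ROI voxels failing the inclusion rule
#'   on a map: `"drop"` (default; habitat label 0, removed from fraction
#'   denominators) or `"nearest-cluster"` (assigned to the L or H cluster
#'   whose included-voxel mean is closer).
#' @param allow_degenerate if `TRUE`, a constant map is assigned all-low
#'   instead of failing (a constant clinical map normally indicates an
#'   upstream fault).
#' @param spacing,margin analysis-grid voxel size (mm) and margin (voxels)
#'   used when inputs need resampling onto a common grid.
#' @return an object of class `habitat_config`.
#' @export
habitat_config <- function(mask_flavor = c("FLAIR", "CE"), n_bins = 256,
                           outlier_k = 3,
                           excluded_policy = c("drop", "nearest-cluster"),
                           allow_degenerate = FALSE, spacing = 1, margin = 5) {
  mask_flavor <- match.arg(mask_flavor)
  excluded_policy <- match.arg(excluded_policy)
  if (n_bins < 2) stop("n_bins must be >= 2")
  if (outlier_k <= 0) stop("outlier_k must be > 0")
  structure(list(mask_flavor = mask_flavor, n_bins = as.integer(n_bins),
                 outlier_k = outlier_k, excluded_policy = excluded_policy,
                 allow_degenerate = isTRUE(allow_degenerate),
                 spacing = spacing, margin = margin),
            class = "habitat_config")
}

# cluster one map inside the roi according to config
cluster_map <- function(volume, roi, config) {
  inc <- inclusion_mask(volume, roi, k = config$outlier_k)
  vals <- volume$values[inc]
  if (length(vals) < 2L)
    stop(sprintf("subject '%s': ROI too small to threshold the %s map (%d usable voxels)",
                 volume$subject_id, volume$modality, length(vals)))
  if (max(vals) - min(vals) <= 0) {
    if (!config$allow_degenerate)
      stop(sprintf("subject '%s': degenerate (constant) %s map; rerun with allow_degenerate to force all-low",
                   volume$subject_id, volume$modality))
    otsu <- structure(list(threshold = vals[1], between_class_variance = 0,
                           n_bins = config$n_bins,
                           bin_edges_range = range(vals),
                           n_values = length(vals)),
                      class = "otsu_result")
    b <- binarize(volume, roi, inc, otsu)
    # all-low convention for a flat map: v <= T everywhere
    return(b)
  }
  otsu <- otsu_threshold(vals, n_bins = config$n_bins)
  b <- binarize(volume, roi, inc, otsu)
  if (config$excluded_policy == "nearest-cluster") {
    v <- volume$values
    mu_l <- mean(v[b$label == CL_LOW])
    mu_h <- mean(v[b$label == CL_HIGH])
    excl <- b$label == CL_EXCLUDED & is.finite(v)
    if (is.finite(mu_l) && is.finite(mu_h)) {
      b$label[excl] <- ifelse(abs(v[excl] - mu_h) < abs(v[excl] - mu_l),
                              CL_HIGH, CL_LOW)
    } else if (is.finite(mu_l) || is.finite(mu_h)) {
      b$label[excl] <- if (is.finite(mu_h)) CL_HIGH else CL_LOW
    }
  }
  b
}

#' Run the full habitat pipeline for one subject
#'
#' Orchestrates: common-grid resampling (trilinear for maps, nearest for
#' the mask) when the inputs are not already aligned, the mean +/- k SD
#' inclusion rule per map, a per-map Otsu threshold over the included
#' in-ROI values, binarization into high/low clusters, and intersection
#' into the 8-habitat label map. The pipeline is fully deterministic, and
#' per-subject Otsu thresholding makes it invariant to positive rescaling
#' of any input map.
#'
#' @param vp,faza,md the three [parametric_volume()]s.
#' @param roi the clustering [tumor_mask()].
#' @param config a [habitat_config()].
#' @return a `habitat_map`; its `provenance` field carries thresholds,
#'   counts and the configuration (serializable with
#'   [habitat_provenance_json()]).
#' @export
compute_habitats <- function(vp, faza, md, roi, config = habitat_config()) {
  subject_id <- roi$subject_id
  maps <- list(Vp = vp, FAZA = faza, MD = md)
  for (m in names(maps))
    if (maps[[m]]$modality != m)
      stop(sprintf("subject '%s': argument '%s' holds a %s map", subject_id,
                   tolower(m), maps[[m]]$modality))
  aligned <- all(vapply(maps, function(x) grids_equal(x$grid, roi$grid), logical(1)))
  if (!aligned) {
    target <- default_analysis_grid(roi, spacing = config$spacing,
                                    margin = config$margin)
    roi <- resample_mask_to_grid(roi, target)
    maps <- lapply(maps, resample_to_grid, target = target, method = "trilinear")
  }
  if (sum(roi$member) < 2L)
    stop(sprintf("subject '%s': ROI of %d voxel(s) cannot be thresholded",
                 subject_id, sum(roi$member)))
  clusters <- lapply(maps, cluster_map, roi = roi, config = config)
  map <- combine_clusters(clusters$Vp, clusters$FAZA, clusters$MD,
                          subject_id = subject_id)
  map$provenance <- list(
    subject_id = subject_id,
    mask_flavor = roi$flavor,
    config = unclass(config),
    n_roi_voxels = sum(roi$member),
    n_assigned = sum(map$label > 0L),
    habitat_counts = as.list(stats::setNames(tabulate(map$label[map$label > 0L], 8L),
                                             paste0("habitat_", 1:8))),
    maps = lapply(clusters, function(b) list(
      modality = b$modality,
      threshold = b$otsu$threshold,
      between_class_variance = b$otsu$between_class_variance,
      n_bins = b$otsu$n_bins,
      value_range = b$otsu$bin_edges_range,
      n_included = sum(b$label %in% c(CL_LOW, CL_HIGH)),
      n_excluded = sum(b$label == CL_EXCLUDED),
      n_low = sum(b$label == CL_LOW),
      n_high = sum(b$label == CL_HIGH))))
  map
}

#' Serialize a habitat map's provenance record to JSON
#' @param map a `habitat_map` from [compute_habitats()].
#' @param path optional output file; when omitted the JSON string is returned.
#' @export
habitat_provenance_json <- function(map, path = NULL) {
  js <- jsonlite::toJSON(map$provenance, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(path))
  }
  js
}

#' Read a habitat label map written by [write_volume()]
#'
#' The on-disk label map keeps labels 0-8 only, so in-ROI-but-unassigned
#' voxels (label 0) cannot be distinguished from voxels outside the ROI;
#' the reconstructed ROI covers labels 1-8.
#'
#' @param path NIfTI label map.
#' @param subject_id subject identifier (defaults to the file stem).
#' @export
read_habitat_map <- function(path, subject_id = NULL) {
  if (!file.exists(path)) stop(sprintf("label map not found: '%s'", path))
  img <- RNifti::readNifti(path)
  grid <- grid_from_nifti(img, path)
  lab <- array(as.integer(img), dim = dim(img))
  if (any(is.na(lab)) || any(lab < 0L | lab > 8L))
    stop(sprintf("'%s': not a habitat label map (values outside 0..8)", path))
  if (is.null(subject_id))
    subject_id <- sub("\\.nii(\\.gz)?$", "", basename(path))
  structure(list(grid = grid, label = lab, roi = lab > 0L,
                 subject_id = subject_id, definition = habitat_definition(),
                 provenance = NULL),
            class = "habitat_map")
}
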