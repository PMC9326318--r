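#' Spherical volume of interest at a stereotactic target
#'
#' Voxel membership is by voxel-centre Euclidean distance: a voxel belongs
#' to the VOI iff its centre lies within `diameter/2` mm of the target
#' point (no partial-volume weighting). The 5 mm default mirrors the
#' accuracy margin conventionally adopted for stereotactic biopsy targets.
#'
#' @param grid an [image_grid()].
#' @param center world coordinates (mm), length 3; must lie inside the
#'   grid extent.
#' @param diameter sphere diameter in mm (default 5).
#' @return an object of class `spherical_voi` with `center`, `diameter`,
#'   and `member_voxels` (n x 3 matrix of 1-based voxel indices).
#' @export
sphere_voxels <- function(grid, center, diameter = 5) {
  center <- as.numeric(center)
  if (length(center) != 3L || any(!is.finite(center)))
    stop("sphere center must be 3 finite world coordinates (mm)")
  ext <- grid_extent(grid)
  if (any(center < ext["lo", ] - grid$spacing / 2) ||
      any(center > ext["hi", ] + grid$spacing / 2))
    stop(sprintf("sphere center (%g, %g, %g) lies outside the grid extent",
                 center[1], center[2], center[3]))
  r <- diameter / 2
  cv <- as.numeric(world_to_voxel(grid, center))        # continuous 0-based
  lo <- pmax(0L, as.integer(ceiling(cv - r / grid$spacing)))
  hi <- pmin(grid$shape - 1L, as.integer(floor(cv + r / grid$spacing)))
  if (any(lo > hi))
    stop("sphere contains no voxel centres (diameter too small for this grid?)")
  cand <- as.matrix(expand.grid(i = lo[1]:hi[1], j = lo[2]:hi[2], k = lo[3]:hi[3]))
  w <- voxel_to_world(grid, cand)
  d2 <- rowSums(sweep(w, 2, center, "-")^2)
  member <- cand[d2 <= r^2, , drop = FALSE]
  if (nrow(member) == 0L)
    stop("sphere contains no voxel centres (diameter too small for this grid?)")
  structure(list(center = center, diameter = diameter,
                 member_voxels = member + 1L, grid = grid),
            class = "spherical_voi")
}

#' @export
print.spherical_voi <- function(x, ...) {
  cat(sprintf("<spherical_voi> %g mm diameter at (%g, %g, %g) mm, %d voxels\n",
              x$diameter, x$center[1], x$center[2], x$center[3],
              nrow(x$member_voxels)))
  invisible(x)
}

#' Habitat profile of a spherical VOI
#'
#' Tallies habitat labels over the VOI member voxels. Labels are ordered
#' by descending count with ties broken by ascending label, the
#' prevalence order used to report habitats involved in a biopsy sample.
#' Voxels with label 0 (unassigned or outside the ROI) are counted
#' separately as `unassigned`.
#'
#' @param map a `habitat_map`.
#' @param voi a [sphere_voxels()] result on the same grid.
#' @return an object of class `voi_habitat_profile` with `habitat_counts`
#'   (named counts for labels with count > 0), `ordered_habitats`,
#'   `dominant_fraction` (top count over assigned count; `NA` when no
#'   voxel is assigned), and `unassigned` count.
#' @export
voi_habitat_profile <- function(map, voi) {
  if (!grids_equal(map$grid, voi$grid))
    stop("VOI and habitat map are on different grids")
  labs <- map$label[voi$member_voxels]
  counts <- tabulate(labs[labs > 0L], nbins = 8L)
  present <- which(counts > 0L)
  ord <- present[order(-counts[present], present)]
  assigned <- sum(counts)
  structure(list(
    habitat_counts = stats::setNames(counts[ord], ord),
    ordered_habitats = ord,
    dominant_fraction = if (assigned > 0L) counts[ord[1]] / assigned else NA_real_,
    unassigned = sum(labs == 0L),
    n_voxels = length(labs)),
    class = "voi_habitat_profile")
}

#' @export
print.voi_habitat_profile <- function(x, ...) {
  cat(sprintf("<voi_habitat_profile> habitats [%s], dominant fraction %.2f, %d/%d voxels unassigned\n",
              paste(x$ordered_habitats, collapse = ", "),
              x$dominant_fraction, x$unassigned, x$n_voxels))
  invisible(x)
}

#' Read stereotactic biopsy targets from CSV
#'
#' Expected columns: `subject_id`, `sample_label`, `x_mm`, `y_mm`, `z_mm`
#' (world RAS+ mm).
#' @param path CSV file.
#' @export
read_targets <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "sample_label", "x_mm", "y_mm", "z_mm")
  if (!all(need %in% names(df)))
    stop("targets CSV must have columns: ", paste(need, collapse = ", "))
  df
}

#' Read semi-quantitative histology grades from CSV
#'
#' Expected columns: `subject_id`, `sample_label`, `cellularity` (1-5),
#' `necrosis_class` (0-5; 0 = 0%, 1 = <=10%, 2 = 11-25%, 3 = 26-50%,
#' 4 = 51-75%, 5 = 76-100%), `vessels` (hyperplastic vessel count, may be
#' missing). Grades refer to the central 5 mm segment of each specimen.
#' @param path CSV file.
#' @export
read_histology <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "sample_label", "cellularity", "necrosis_class")
  if (!all(need %in% names(df)))
    stop("histology CSV must have columns: ", paste(need, collapse = ", "))
  bad <- !is.na(df$cellularity) & (df$cellularity < 1 | df$cellularity > 5)
  if (any(bad)) stop("cellularity grades must be in 1..5")
  bad <- !is.na(df$necrosis_class) & (df$necrosis_class < 0 | df$necrosis_class > 5)
  if (any(bad)) stop("necrosis classes must be in 0..5")
  df
}

#' Join VOI habitat profiles with histology grades
#'
#' One row per biopsy sample combining the prevalence-ordered habitat
#' list with the semi-quantitative grades, plus a descriptive per-dominant-
#' habitat summary (median cellularity and necrosis class). No inferential
#' statistic is attached.
#'
#' @param profiles data.frame with `subject_id`, `sample_label`, and
#'   `habitats` (comma-separated prevalence-ordered label string, e.g.
#'   `"7, 8"`), as produced by the `voi` pipeline command or the packaged
#'   `"table4"` fixture.
#' @param samples histology data.frame (see [read_histology()]).
#' @return list with `table` (the joined rows; unmatched labels reported
#'   via attribute `unmatched`) and `by_dominant_habitat` (descriptive
#'   medians per dominant habitat).
#' @export
histology_correlation_table <- function(profiles, samples) {
  if (nrow(profiles) == 0L || nrow(samples) == 0L) {
    empty <- data.frame(subject_id = character(0), sample_label = character(0),
                        dominant_habitat = integer(0), habitats = character(0),
                        cellularity = numeric(0), necrosis_class = numeric(0),
                        vessels = numeric(0))
    return(list(table = empty,
                by_dominant_habitat = data.frame(dominant_habitat = integer(0),
                                                 n = integer(0),
                                                 median_cellularity = numeric(0),
                                                 median_necrosis = numeric(0))))
  }
  profiles$dominant_habitat <- vapply(strsplit(as.character(profiles$habitats), ","),
                                      function(x) as.integer(trimws(x[1])), integer(1))
  joined <- merge(profiles, samples, by = c("subject_id", "sample_label"),
                  all = FALSE)
  unmatched <- c(
    setdiff(paste(profiles$subject_id, profiles$sample_label),
            paste(joined$subject_id, joined$sample_label)),
    setdiff(paste(samples$subject_id, samples$sample_label),
            paste(joined$subject_id, joined$sample_label)))
  if (length(unmatched))
    warning("unmatched sample labels: ", paste(unmatched, collapse = "; "))
  if (!"vessels" %in% names(joined)) joined$vessels <- NA_real_
  keep <- c("subject_id", "sample_label", "dominant_habitat", "habitats",
            "cellularity", "necrosis_class", "vessels")
  tab <- joined[order(joined$subject_id, joined$sample_label), keep]
  rownames(tab) <- NULL
  summ <- do.call(rbind, lapply(sort(unique(tab$dominant_habitat)), function(h) {
    sub <- tab[tab$dominant_habitat == h, ]
    data.frame(dominant_habitat = h, n = nrow(sub),
               median_cellularity = stats::median(sub$cellularity, na.rm = TRUE),
               median_necrosis = stats::median(sub$necrosis_class, na.rm = TRUE))
  }))
  out <- list(table = tab, by_dominant_habitat = summ)
  attr(out, "unmatched") <- unmatched
  out
}
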