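#' Specification of a synthetic multiparametric tumor phantom
#'
#' The phantom emulates the data model of the imaging pipeline: a tumor
#' built from concentric ellipsoidal microenvironment zones on a 1 mm
#' isotropic grid, each zone carrying one habitat label whose high/low
#' state triple drives a bimodal per-map intensity model
#' (value ~ Normal(mu_level, sigma)). An outer halo emulates the
#' FLAIR-hyperintense infiltration/edema rim (habitat 7 by default), and
#' small peripheral "speckle" blobs inject the fragmented, poorly
#' represented habitats 3 and 4. The contrast-enhancing (CE) mask covers
#' the shells carrying habitats 1, 2, 5, 6 plus the core; the FLAIR mask
#' covers all shells and the halo, so CE is a subset of FLAIR.
#'
#' Zone radii are the semi-axes along x before applying `axes_ratio`; the
#' defaults give the six zone habitats comparable volumes (12-26% of the
#' tumor each) so that recovery metrics are informative for all of them.
#'
#' @param grid an [image_grid()]; default 96^3 voxels at 1 mm centred on 0.
#' @param tumor_center world mm of the tumor centre.
#' @param zone_radii strictly increasing radii (mm) of the 5 concentric
#'   shells.
#' @param zone_habitats habitat label (1-8) per shell, inner to outer.
#' @param halo_habitat habitat of the outer FLAIR halo.
#' @param halo_width halo thickness (mm).
#' @param axes_ratio per-axis scale of the ellipsoids (dimensionless).
#' @param level_means named list with one `c(L, H)` pair of map-unit means
#'   per modality; defaults seeded from typical high-grade glioma values
#'   (Vp in mL/100 mL, FAZA arbitrary, MD in mm^2/s).
#' @param separation class separation (mu_H - mu_L)/sigma shared by the
#'   three maps; used to derive `noise_sd` when that is not given.
#' @param noise_sd optional named per-map noise SD overriding `separation`.
#' @param speckle_fraction fraction of tumor voxels converted to habitat
#'   3/4 speckle blobs (total over both; default 0.05).
#' @param lesion_count number of lesions (>= 1); secondary lesions are
#'   scaled-down copies placed around the first.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid = image_grid(c(96, 96, 96), origin = c(-48, -48, -48)),
                         tumor_center = c(0, 0, 0),
                         zone_radii = c(16, 21, 24, 27, 29),
                         zone_habitats = c(5, 2, 1, 6, 8),
                         halo_habitat = 7,
                         halo_width = 3,
                         axes_ratio = c(1, 0.85, 0.7),
                         level_means = list(Vp = c(L = 1.0, H = 4.9),
                                            FAZA = c(L = 0.3, H = 1.4),
                                            MD = c(L = 0.98e-3, H = 1.32e-3)),
                         separation = 4,
                         noise_sd = NULL,
                         speckle_fraction = 0.05,
                         lesion_count = 1) {
  if (length(zone_radii) != 5L || any(diff(zone_radii) <= 0))
    stop("zone_radii must be 5 strictly increasing radii (mm)")
  if (length(zone_habitats) != 5L || !all(zone_habitats %in% 1:8))
    stop("zone_habitats must be 5 labels in 1..8")
  if (!halo_habitat %in% 1:8) stop("halo_habitat must be in 1..8")
  if (halo_width <= 0) stop("halo_width must be > 0")
  if (any(axes_ratio <= 0)) stop("axes_ratio must be positive")
  for (m in MODALITIES) {
    lv <- level_means[[m]]
    if (is.null(lv) || length(lv) != 2L || lv[2] <= lv[1])
      stop(sprintf("level_means$%s must be c(L, H) with H > L", m))
  }
  if (is.null(noise_sd)) {
    if (separation < 0) stop("separation must be >= 0")
    noise_sd <- vapply(MODALITIES, function(m) {
      gap <- level_means[[m]][2] - level_means[[m]][1]
      if (separation == 0) 0 else unname(gap / separation)
    }, numeric(1))
  } else {
    noise_sd <- noise_sd[MODALITIES]
    if (any(is.na(noise_sd)) || any(noise_sd < 0))
      stop("noise_sd must be a named non-negative vector covering Vp, FAZA, MD")
  }
  if (speckle_fraction < 0 || speckle_fraction > 0.5)
    stop("speckle_fraction must be in [0, 0.5]")
  if (lesion_count < 1) stop("lesion_count must be >= 1")
  spec <- structure(list(grid = grid, tumor_center = as.numeric(tumor_center),
                         zone_radii = as.numeric(zone_radii),
                         zone_habitats = as.integer(zone_habitats),
                         halo_habitat = as.integer(halo_habitat),
                         halo_width = halo_width,
                         axes_ratio = as.numeric(axes_ratio),
                         level_means = level_means,
                         separation = separation,
                         noise_sd = noise_sd,
                         speckle_fraction = speckle_fraction,
                         lesion_count = as.integer(lesion_count)),
                    class = "phantom_spec")
  check_phantom_extent(spec)
  spec
}

# lesion centres and radius scales; secondary lesions are 0.45-scaled
phantom_lesions <- function(spec) {
  r_out <- max(spec$zone_radii) + spec$halo_width
  dirs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1))
  centers <- matrix(spec$tumor_center, nrow = 1)
  scales <- 1
  if (spec$lesion_count > 1L) {
    if (spec$lesion_count > 7L) stop("at most 7 lesions are supported")
    for (i in seq_len(spec$lesion_count - 1L)) {
      d <- dirs[i, ] * spec$axes_ratio * (r_out * 1.45 + 2)
      centers <- rbind(centers, spec$tumor_center + d)
      scales <- c(scales, 0.45)
    }
  }
  list(centers = centers, scales = scales)
}

check_phantom_extent <- function(spec) {
  les <- phantom_lesions(spec)
  ext <- grid_extent(spec$grid)
  r_out <- max(spec$zone_radii) + spec$halo_width
  for (i in seq_len(nrow(les$centers))) {
    reach <- r_out * les$scales[i] * spec$axes_ratio
    if (any(les$centers[i, ] - reach < ext["lo", ]) ||
        any(les$centers[i, ] + reach > ext["hi", ]))
      stop("phantom radii exceed the grid extent")
  }
  invisible(spec)
}

#' Generate a multiparametric phantom with ground-truth habitat labels
#'
#' Each voxel's truth habitat fixes a (Vp, FAZA, MD) high/low triple via
#' the habitat definition; map values are drawn
#' `Normal(mu_level, sigma_map)` independently per voxel. The result is
#' deterministic given `seed` (the caller's RNG state is preserved).
#' Background voxels (outside the FLAIR mask) take the low level of each
#' map; MD is clipped at 0 to stay physically valid.
#'
#' @param spec a [phantom_spec()].
#' @param seed integer RNG seed.
#' @param subject_id subject identifier for the generated volumes.
#' @return list with `vp`, `faza`, `md` ([parametric_volume()]s) and
#'   `truth`, an object of class `phantom_truth` holding `label` (0-8
#'   array; 0 outside FLAIR), `ce_mask`, `flair_mask`, and
#'   `zone_volumes_mm3` (analytic ellipsoid-shell volumes per habitat,
#'   speckles not included).
#' @export
generate_phantom <- function(spec, seed = 1L, subject_id = "phantom") {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  set.seed(seed)

  grid <- spec$grid
  sh <- grid$shape
  ax <- voxel_axis_coords(grid)
  les <- phantom_lesions(spec)
  label <- array(0L, dim = sh)
  zone_of <- array(0L, dim = sh)       # 1..5 shells, 6 halo, per lesion
  for (li in seq_len(nrow(les$centers))) {
    cen <- les$centers[li, ]; sc <- les$scales[li]
    # normalized elliptical radius (mm) per voxel
    rx <- (ax$x - cen[1]) / spec$axes_ratio[1]
    ry <- (ax$y - cen[2]) / spec$axes_ratio[2]
    rz <- (ax$z - cen[3]) / spec$axes_ratio[3]
    rr <- sqrt(outer(outer(rx^2, ry^2, "+"), rz^2, "+"))
    radii <- spec$zone_radii * sc
    halo_r <- (max(spec$zone_radii) + spec$halo_width) * sc
    prev <- 0
    for (z in seq_along(radii)) {
      sel <- rr > prev & rr <= radii[z] & label == 0L
      label[sel] <- spec$zone_habitats[z]
      zone_of[sel] <- z
      prev <- radii[z]
    }
    sel <- rr > prev & rr <= halo_r & label == 0L
    label[sel] <- spec$halo_habitat
    zone_of[sel] <- 6L
  }
  flair <- label > 0L
  ce_zones <- which(spec$zone_habitats %in% c(1L, 2L, 5L, 6L))
  ce_zones <- union(1L, ce_zones)      # core is always enhancing
  ce <- array(zone_of %in% ce_zones, dim = sh)

  # peripheral speckle blobs of habitats 3 and 4
  n_tumor <- sum(flair)
  target <- round(spec$speckle_fraction * n_tumor)
  if (target > 0) {
    peripheral <- which(flair & zone_of >= 3L)
    placed <- 0L; blob_r <- 2; next_hab <- 3L
    guard <- 0L
    while (placed < target && guard < 10000L) {
      guard <- guard + 1L
      cen_idx <- arrayInd(sample(peripheral, 1L), sh)
      cen_w <- as.numeric(voxel_to_world(grid, cen_idx - 1L))
      box <- lapply(1:3, function(d) {
        lo <- max(1L, cen_idx[d] - ceiling(blob_r / grid$spacing[d]))
        hi <- min(sh[d], cen_idx[d] + ceiling(blob_r / grid$spacing[d]))
        lo:hi
      })
      cand <- as.matrix(expand.grid(box[[1]], box[[2]], box[[3]]))
      w <- voxel_to_world(grid, cand - 1L)
      inside <- rowSums(sweep(w, 2, cen_w, "-")^2) <= blob_r^2
      cand <- cand[inside, , drop = FALSE]
      cand <- cand[flair[cand] & !(label[cand] %in% c(3L, 4L)), , drop = FALSE]
      if (nrow(cand) == 0L) next
      label[cand] <- next_hab
      placed <- placed + nrow(cand)
      next_hab <- if (next_hab == 3L) 4L else 3L
    }
  }

  # analytic shell volumes (mm^3) per habitat; speckles are carved at the
  # voxel level and intentionally not part of the analytic accounting
  vol_factor <- 4 / 3 * pi * prod(spec$axes_ratio)
  zone_vol <- stats::setNames(rep(0, 9), c(1:8, "halo_total"))
  for (li in seq_along(les$scales)) {
    sc3 <- les$scales[li]^3
    radii <- spec$zone_radii
    prev <- 0
    for (z in seq_along(radii)) {
      v <- vol_factor * (radii[z]^3 - prev^3) * sc3
      h <- as.character(spec$zone_habitats[z])
      zone_vol[h] <- zone_vol[h] + v
      prev <- radii[z]
    }
    halo_r <- max(radii) + spec$halo_width
    v <- vol_factor * (halo_r^3 - prev^3) * sc3
    h <- as.character(spec$halo_habitat)
    zone_vol[h] <- zone_vol[h] + v
  }
  zone_vol <- zone_vol[as.character(1:8)]
  names(zone_vol) <- paste0("habitat_", 1:8)

  defn <- habitat_definition()$label_table
  vols <- list()
  for (m in MODALITIES) {
    lv <- spec$level_means[[m]]; sdev <- spec$noise_sd[[m]]
    state <- array("L", dim = sh)
    inz <- label > 0L
    state[inz] <- defn[[m]][label[inz]]
    mu <- array(lv[1], dim = sh)
    mu[state == "H"] <- lv[2]
    vals <- mu + if (sdev > 0) stats::rnorm(length(mu), sd = sdev) else 0
    if (m == "MD") vals[vals < 0] <- 0
    vols[[m]] <- parametric_volume(array(vals, dim = sh), grid, modality = m,
                                   subject_id = subject_id)
  }

  truth <- structure(list(
    label = label,
    ce_mask = if (any(ce)) tumor_mask(ce, grid, "CE", subject_id) else NULL,
    flair_mask = tumor_mask(flair, grid, "FLAIR", subject_id),
    zone_volumes_mm3 = zone_vol,
    spec = spec, seed = seed), class = "phantom_truth")
  list(vp = vols$Vp, faza = vols$FAZA, md = vols$MD, truth = truth)
}

# per-axis world coordinates of voxel centres
voxel_axis_coords <- function(grid) {
  list(x = grid$origin[1] + (0:(grid$shape[1] - 1)) * grid$spacing[1],
       y = grid$origin[2] + (0:(grid$shape[2] - 1)) * grid$spacing[2],
       z = grid$origin[3] + (0:(grid$shape[3] - 1)) * grid$spacing[3])
}

#' Per-habitat Dice overlap between a computed and a truth label map
#'
#' `2|A ∩ B| / (|A| + |B|)` per habitat label; `NA` for habitats empty in
#' both maps, 0 when empty in exactly one.
#'
#' @param map a `habitat_map` (or integer label array).
#' @param truth a `phantom_truth` (or integer label array).
#' @return named numeric vector `habitat_1` ... `habitat_8`.
#' @export
habitat_dice <- function(map, truth) {
  a <- if (inherits(map, "habitat_map")) map$label else map
  b <- if (inherits(truth, "phantom_truth")) truth$label else truth
  if (!all(dim(a) == dim(b))) stop("label arrays differ in shape")
  out <- stats::setNames(rep(NA_real_, 8), paste0("habitat_", 1:8))
  for (h in 1:8) {
    na <- sum(a == h); nb <- sum(b == h)
    if (na + nb == 0L) next
    out[h] <- 2 * sum(a == h & b == h) / (na + nb)
  }
  out
}

#' Generate a phantom cohort with a pipeline-ready manifest
#'
#' Per-subject specs are jittered copies of `base_spec` (zone radii and
#' level means scaled by independent uniform factors in
#' `1 +/- jitter`), reproducible from `seed`. Volumes, masks and truth
#' labels are written as NIfTI under `dir` together with `manifest.csv`
#' (columns `subject_id`, `vp_path`, `faza_path`, `md_path`,
#' `mask_ce_path`, `mask_flair_path`, `truth_path`).
#'
#' @param n_subjects number of subjects (>= 1).
#' @param dir output directory (created if needed).
#' @param base_spec a [phantom_spec()].
#' @param jitter relative jitter amplitude (default 0.1).
#' @param seed integer seed.
#' @param compress write `.nii.gz` (default) or plain `.nii`.
#' @return the manifest data.frame (invisibly), with the per-subject
#'   specs attached as attribute `specs`.
#' @export
generate_cohort <- function(n_subjects, dir, base_spec = phantom_spec(),
                            jitter = 0.1, seed = 1L, compress = TRUE) {
  if (n_subjects < 1L) stop("n_subjects must be >= 1")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (compress) ".nii.gz" else ".nii"
  rows <- list(); specs <- list()
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  for (i in seq_len(n_subjects)) {
    sid <- sprintf("sub%02d", i)
    set.seed(seed + i)
    f_r <- stats::runif(1, 1 - jitter, 1 + jitter)
    lv <- lapply(base_spec$level_means, function(p)
      p * stats::runif(1, 1 - jitter, 1 + jitter))
    spec_i <- phantom_spec(grid = base_spec$grid,
                           tumor_center = base_spec$tumor_center,
                           zone_radii = base_spec$zone_radii * f_r,
                           zone_habitats = base_spec$zone_habitats,
                           halo_habitat = base_spec$halo_habitat,
                           halo_width = base_spec$halo_width,
                           axes_ratio = base_spec$axes_ratio,
                           level_means = lv,
                           separation = base_spec$separation,
                           speckle_fraction = base_spec$speckle_fraction,
                           lesion_count = base_spec$lesion_count)
    ph <- generate_phantom(spec_i, seed = seed + 1000L + i, subject_id = sid)
    paths <- c(vp_path = file.path(dir, paste0(sid, "_vp", ext)),
               faza_path = file.path(dir, paste0(sid, "_faza", ext)),
               md_path = file.path(dir, paste0(sid, "_md", ext)),
               mask_ce_path = file.path(dir, paste0(sid, "_mask_ce", ext)),
               mask_flair_path = file.path(dir, paste0(sid, "_mask_flair", ext)),
               truth_path = file.path(dir, paste0(sid, "_truth", ext)))
    write_volume(ph$vp, paths["vp_path"])
    write_volume(ph$faza, paths["faza_path"])
    write_volume(ph$md, paths["md_path"])
    write_volume(ph$truth$ce_mask, paths["mask_ce_path"])
    write_volume(ph$truth$flair_mask, paths["mask_flair_path"])
    RNifti::writeNifti(nifti_with_grid(ph$truth$label, spec_i$grid),
                       paths["truth_path"])
    rows[[i]] <- data.frame(subject_id = sid, t(paths), stringsAsFactors = FALSE)
    specs[[sid]] <- spec_i
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  attr(manifest, "specs") <- specs
  invisible(manifest)
}

#' Write / read a phantom spec as YAML
#' @param spec a [phantom_spec()].
#' @param path YAML file.
#' @export
write_phantom_spec <- function(spec, path) {
  x <- unclass(spec)
  x$grid <- list(shape = spec$grid$shape, spacing = spec$grid$spacing,
                 origin = spec$grid$origin)
  x$level_means <- lapply(x$level_means, function(p) list(L = unname(p[1]),
                                                          H = unname(p[2])))
  x$noise_sd <- as.list(x$noise_sd)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_phantom_spec
#' @export
read_phantom_spec <- function(path) {
  x <- yaml::read_yaml(path)
  phantom_spec(grid = image_grid(unlist(x$grid$shape), unlist(x$grid$spacing),
                                 unlist(x$grid$origin)),
               tumor_center = unlist(x$tumor_center),
               zone_radii = unlist(x$zone_radii),
               zone_habitats = unlist(x$zone_habitats),
               halo_habitat = x$halo_habitat,
               halo_width = x$halo_width,
               axes_ratio = unlist(x$axes_ratio),
               level_means = lapply(x$level_means, function(p)
                 c(L = p$L, H = p$H)),
               separation = x$separation,
               speckle_fraction = x$speckle_fraction,
               lesion_count = x$lesion_count)
}
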