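make_roi <- function(g, frac = 1) {
  member <- array(TRUE, dim = g$shape)
  tumor_mask(member, g, "FLAIR", "s1")
}

test_that("inclusion rule: constant maps, extreme outliers, normal tail mass", {
  g <- image_grid(c(10, 10, 10))
  roi <- make_roi(g)
  const <- parametric_volume(array(2.5, dim = g$shape), g, "Vp", "s1")
  inc <- inclusion_mask(const, roi)
  expect_true(all(inc))                      # sd = 0 keeps everything

  g2 <- image_grid(c(10, 10, 10))
  set.seed(1)
  vals <- array(runif(1000), dim = g2$shape)
  vals[1, 1, 1] <- 1e6
  vol <- parametric_volume(vals, g2, "FAZA", "s1")
  inc2 <- inclusion_mask(vol, make_roi(g2))
  expect_false(inc2[1, 1, 1])                # the single extreme voxel goes
  expect_equal(sum(!inc2), 1L)

  # standard-normal values: excluded fraction ~ 2*pnorm(-3) = 0.0027
  g3 <- image_grid(c(50, 50, 40))
  set.seed(2024)
  vol3 <- parametric_volume(array(rnorm(1e5), dim = g3$shape), g3, "Vp", "s1")
  inc3 <- inclusion_mask(vol3, make_roi(g3))
  expect_lt(abs(mean(!inc3) - 2 * pnorm(-3)), 1e-3)

  nav <- parametric_volume(array(NA_real_, dim = g$shape), g, "Vp", "s1")
  expect_error(inclusion_mask(nav, roi), "no finite")
})

test_that("binarization: boundary goes low, L/H/excluded partition the ROI", {
  g <- image_grid(c(8, 8, 8))
  roi <- make_roi(g)
  set.seed(3)
  vol <- parametric_volume(array(rnorm(512), dim = g$shape), g, "Vp", "s1")
  inc <- inclusion_mask(vol, roi)
  res <- otsu_threshold(vol$values[inc])
  b <- binarize(vol, roi, inc, res)
  n_l <- sum(b$label == 1L); n_h <- sum(b$label == 2L); n_x <- sum(b$label == 3L)
  expect_equal(n_l + n_h + n_x, sum(roi$member))
  expect_true(all(vol$values[b$label == 2L] > res$threshold))
  expect_true(all(vol$values[b$label == 1L] <= res$threshold))

  # a value exactly at the threshold is low
  vol$values[1, 1, 1] <- res$threshold
  b2 <- binarize(vol, roi, inc, res)
  expect_equal(b2$label[1, 1, 1], 1L)

  # all values below T is legal: H empty
  lowv <- parametric_volume(array(res$threshold - abs(vol$values), dim = g$shape),
                            g, "Vp", "s1")
  b3 <- binarize(lowv, roi, inc, res)
  expect_equal(sum(b3$label == 2L), 0L)
})

test_that("cluster intersection follows the fixed H/L label convention", {
  defn <- habitat_definition()
  expect_equal(habitat_label_of("H", "H", "H"), 1L)
  expect_equal(habitat_label_of("H", "H", "L"), 2L)
  expect_equal(habitat_label_of("H", "L", "H"), 3L)
  expect_equal(habitat_label_of("H", "L", "L"), 4L)
  expect_equal(habitat_label_of("L", "H", "H"), 5L)
  expect_equal(habitat_label_of("L", "H", "L"), 6L)
  expect_equal(habitat_label_of("L", "L", "H"), 7L)
  expect_equal(habitat_label_of("L", "L", "L"), 8L)
  tt <- defn$label_table
  expect_equal(habitat_label_of(tt$Vp, tt$FAZA, tt$MD), tt$label)

  g <- image_grid(c(12, 12, 12))
  roi <- make_roi(g)
  set.seed(4)
  mk <- function(mod) {
    vol <- parametric_volume(array(sample(c(0, 10), 1728, replace = TRUE),
                                   dim = g$shape), g, mod, "s1")
    inc <- inclusion_mask(vol, roi)
    binarize(vol, roi, inc, otsu_threshold(vol$values[inc]))
  }
  b_vp <- mk("Vp"); b_fz <- mk("FAZA"); b_md <- mk("MD")
  map <- combine_clusters(b_md, b_vp, b_fz)   # argument order is free
  # brute-force voxel loop oracle
  for (h in 1:8) {
    tr <- habitat_triple_of(h)
    want <- sum((b_vp$label == ifelse(tr$Vp == "H", 2L, 1L)) &
                (b_fz$label == ifelse(tr$FAZA == "H", 2L, 1L)) &
                (b_md$label == ifelse(tr$MD == "H", 2L, 1L)))
    expect_equal(sum(map$label == h), want)
  }
  expect_error(combine_clusters(b_vp, b_vp, b_md), "modality")
})

test_that("zero-noise phantom is recovered exactly; all-low maps are legal", {
  ph <- generate_phantom(small_phantom_spec(separation = 0), seed = 1)
  map <- compute_habitats(ph$vp, ph$faza, ph$md, ph$truth$flair_mask)
  d <- habitat_dice(map, ph$truth)
  expect_true(all(d[!is.na(d)] == 1))
  # every in-ROI voxel assigned, nothing labeled outside
  expect_true(all(map$label[!map$roi] == 0L))
  expect_true(all(map$label[map$roi] %in% 1:8))
})

test_that("habitat labels partition the included ROI voxels", {
  for (seed in c(11, 12)) {
    ph <- generate_phantom(small_phantom_spec(), seed = seed)
    map <- compute_habitats(ph$vp, ph$faza, ph$md, ph$truth$flair_mask)
    expect_true(all(map$label[!map$roi] == 0L))
    n_roi <- sum(map$roi)
    n_assigned <- sum(map$label %in% 1:8)
    n_zero <- sum(map$label == 0L & map$roi)
    expect_equal(n_assigned + n_zero, n_roi)
    fr <- habitat_fractions(map)
    expect_equal(sum(unlist(fr[paste0("frac_", 1:8)])), 100, tolerance = 1e-9)
  }
})

test_that("habitat maps are invariant to positive rescaling of any map", {
  ph <- generate_phantom(small_phantom_spec(), seed = 5)
  map <- compute_habitats(ph$vp, ph$faza, ph$md, ph$truth$flair_mask)
  scaled <- ph$vp
  scaled$values <- scaled$values * 37.5
  map2 <- compute_habitats(scaled, ph$faza, ph$md, ph$truth$flair_mask)
  expect_identical(map$label, map2$label)
  scaled_md <- ph$md
  scaled_md$values <- scaled_md$values * 1e3
  map3 <- compute_habitats(ph$vp, ph$faza, scaled_md, ph$truth$flair_mask)
  expect_identical(map$label, map3$label)
})

test_that("the pipeline is deterministic", {
  ph <- generate_phantom(small_phantom_spec(), seed = 8)
  m1 <- compute_habitats(ph$vp, ph$faza, ph$md, ph$truth$flair_mask)
  m2 <- compute_habitats(ph$vp, ph$faza, ph$md, ph$truth$flair_mask)
  expect_identical(m1$label, m2$label)
  expect_identical(m1$provenance$maps$Vp$threshold, m2$provenance$maps$Vp$threshold)
})

test_that("tiny ROIs and degenerate maps fail with subject context", {
  g <- image_grid(c(6, 6, 6))
  member <- array(FALSE, dim = g$shape); member[3, 3, 3] <- TRUE
  roi1 <- tumor_mask(member, g, "FLAIR", "subjX")
  set.seed(6)
  mk <- function(mod) parametric_volume(array(runif(216), dim = g$shape), g, mod, "subjX")
  expect_error(compute_habitats(mk("Vp"), mk("FAZA"), mk("MD"), roi1), "subjX")

  roi <- tumor_mask(array(TRUE, dim = g$shape), g, "FLAIR", "subjY")
  flat <- parametric_volume(array(1.0, dim = g$shape), g, "Vp", "subjY")
  expect_error(compute_habitats(flat, mk("FAZA"), mk("MD"), roi), "degenerate")
  cfg <- habitat_config(allow_degenerate = TRUE)
  map <- compute_habitats(flat, mk("FAZA"), mk("MD"), roi, cfg)
  # a forced-flat Vp map is all-low: only habitats 5..8 appear
  expect_true(all(map$label[map$label > 0L] %in% 5:8))
})

test_that("misaligned inputs are resampled onto a common 1 mm analysis grid", {
  ph <- generate_phantom(small_phantom_spec(), seed = 9)
  # put the FAZA map on a coarser grid
  coarse <- image_grid(c(32, 32, 32), spacing = c(2, 2, 2), origin = c(-32, -32, -32))
  faza2 <- resample_to_grid(ph$faza, coarse, "trilinear")
  map <- compute_habitats(ph$vp, ph$faza, ph$md, ph$truth$flair_mask)
  map2 <- compute_habitats(ph$vp, faza2, ph$md, ph$truth$flair_mask)
  expect_equal(map2$grid$spacing, c(1, 1, 1))
  expect_true(all(map2$label[!map2$roi] == 0L))
  # smoothing degrades but does not destroy agreement on the common region
  expect_gt(sum(map2$label > 0), 0.9 * sum(map$label > 0))
})

test_that("nearest-cluster policy reassigns excluded voxels to L or H", {
  g <- image_grid(c(10, 10, 10))
  roi <- tumor_mask(array(TRUE, dim = g$shape), g, "FLAIR", "s")
  set.seed(10)
  mk <- function(mod, out = NULL) {
    v <- array(c(rnorm(500, 0), rnorm(500, 8)), dim = g$shape)
    if (!is.null(out)) v[1, 1, 1] <- out
    parametric_volume(abs(v), g, mod, "s")
  }
  vp <- mk("Vp", out = 1e4)  # excluded by the 3-SD rule
  map_drop <- compute_habitats(vp, mk("FAZA"), mk("MD"), roi)
  expect_equal(map_drop$label[1, 1, 1], 0L)
  cfg <- habitat_config(excluded_policy = "nearest-cluster")
  map_nc <- compute_habitats(vp, mk("FAZA"), mk("MD"), roi, cfg)
  expect_true(map_nc$label[1, 1, 1] %in% 1:8)
  # the outlier is far above the high-cluster mean: assigned H on Vp
  expect_true(map_nc$label[1, 1, 1] %in% 1:4)
})
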