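fake_map <- function(labels, roi = labels >= 0) {
  g <- image_grid(dim(labels))
  structure(list(grid = g, label = labels, roi = roi, subject_id = "s1",
                 definition = habitat_definition(), provenance = NULL),
            class = "habitat_map")
}

test_that("habitat fractions are counts over assigned voxels, in percent", {
  lab <- array(8L, dim = c(10, 10, 10))
  fr <- habitat_fractions(fake_map(lab, array(TRUE, dim = dim(lab))))
  expect_equal(fr$frac_8, 100)
  expect_equal(sum(unlist(fr[paste0("frac_", 1:7)])), 0)

  lab2 <- array(0L, dim = c(10, 10, 10))
  lab2[1:300] <- 7L; lab2[301:1000] <- 8L
  fr2 <- habitat_fractions(fake_map(lab2, array(TRUE, dim = dim(lab2))))
  expect_equal(fr2$frac_7, 30)
  expect_equal(fr2$frac_8, 70)
  expect_equal(fr2$assigned_voxels, 1000L)

  none <- array(0L, dim = c(4, 4, 4))
  expect_error(habitat_fractions(fake_map(none, array(TRUE, dim = dim(none)))),
               "no assigned")
})

test_that("fractions track phantom zone volumes within voxelization error", {
  ph <- generate_phantom(small_phantom_spec(speckle_fraction = 0), seed = 21)
  lab <- ph$truth$label
  fr <- habitat_fractions(fake_map(lab, lab > 0L))
  analytic <- 100 * ph$truth$zone_volumes_mm3 / sum(ph$truth$zone_volumes_mm3)
  got <- unlist(fr[paste0("frac_", 1:8)])
  expect_lt(max(abs(got - unname(analytic))), 2)
})

test_that("per-habitat medians match a sort-based oracle; empty habitats are NA", {
  ph <- generate_phantom(small_phantom_spec(), seed = 22)
  map <- compute_habitats(ph$vp, ph$faza, ph$md, ph$truth$flair_mask)
  med <- habitat_medians(map, list(ph$md, ph$vp, ph$faza))
  for (h in as.character(c(1, 4, 7))) {
    sel <- map$label == as.integer(h)
    v <- sort(ph$vp$values[sel])
    n <- length(v)
    oracle <- if (n %% 2 == 1) v[(n + 1) / 2] else mean(v[n / 2 + 0:1])
    expect_equal(med$median[med$map == "Vp" & med$habitat == h], oracle)
  }
  # MD is reported x 10^3
  sel <- map$label == 7L
  expect_equal(med$median[med$map == "MD" & med$habitat == "7"],
               1e3 * median(ph$md$values[sel]))
  # whole-mask rows exist for the three maps
  expect_equal(sum(med$habitat == "whole"), 3L)

  # a constant map gives that constant for every non-empty habitat
  cg <- map$grid
  const <- parametric_volume(array(2.2, dim = cg$shape), cg, "FAZA", "s")
  med2 <- habitat_medians(map, list(ph$vp, const, ph$md))
  vals <- med2$median[med2$map == "FAZA" & med2$habitat != "whole"]
  expect_true(all(vals[!is.na(vals)] == 2.2))

  # an empty habitat is NA, not 0
  lab <- array(0L, dim = c(6, 6, 6)); lab[1:50] <- 1L
  m <- fake_map(lab, lab > 0L)
  vol <- parametric_volume(array(runif(216), dim = c(6, 6, 6)), m$grid, "Vp", "s1")
  volf <- parametric_volume(array(runif(216), dim = c(6, 6, 6)), m$grid, "FAZA", "s1")
  volm <- parametric_volume(array(runif(216), dim = c(6, 6, 6)), m$grid, "MD", "s1")
  med3 <- habitat_medians(m, list(vol, volf, volm))
  expect_true(is.na(med3$median[med3$map == "Vp" & med3$habitat == "5"]))
})

test_that("cohort table averages and single-subject degenerate case", {
  rows <- load_fixture("table2")
  ct <- cohort_table(rows)
  expect_equal(dim(ct$per_subject), c(17L, 8L))
  expect_equal(unname(ct$row_average[7]), mean(rows$frac_7))
  one <- cohort_table(rows[3, ])
  expect_equal(unname(one$row_average), unlist(rows[3, paste0("frac_", 1:8)],
                                              use.names = FALSE))
})

test_that("grouped summary with one all-inclusive group equals the cohort table", {
  rows <- load_fixture("table2")
  records <- data.frame(subject_id = rows$subject_id, idh1 = "wild-type",
                        stringsAsFactors = FALSE)
  gs <- grouped_summary(rows, records, "idh1")
  ct <- cohort_table(rows)
  expect_equal(gs$mean, unname(ct$row_average))
  # unknown-key subjects are dropped with a warning
  records$idh1[3] <- "unknown"
  expect_warning(gs2 <- grouped_summary(rows, records, "idh1"), "unknown")
  expect_equal(unique(gs2$n), 16L)
})

test_that("Mann-Whitney: exact enumeration, ties, and constant samples", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 0.1)      # 2/20 labelings as extreme
  expect_true(r$exact)

  same <- mann_whitney_u(c(2, 2, 2), c(2, 2, 2))
  expect_equal(same$p_value, 1)

  tied <- mann_whitney_u(c(1, 2, 2, 5), c(2, 3, 4))
  expect_false(tied$exact)
  expect_true(tied$p_value > 0 && tied$p_value <= 1)
  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")
})

test_that("Kruskal-Wallis H matches the rank-sum formula; identical groups give 0", {
  r <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))
  expect_equal(r$statistic, 7.2)
  expect_equal(kruskal_wallis(list(1:4, 1:4))$statistic, 0)
  expect_equal(kruskal_wallis(list(c(1, 1), c(1, 1)))$p_value, 1)
  # tie-corrected H equals the textbook formula on random tied data
  set.seed(30)
  for (i in 1:5) {
    samples <- lapply(1:3, function(j) sample(1:6, sample(4:8, 1), replace = TRUE))
    expect_equal(kruskal_wallis(samples)$statistic, kw_brute(samples),
                 tolerance = 1e-12)
  }
  # chi-square p is close to the permutation null away from the extremes
  set.seed(31)
  samples <- list(rnorm(4), rnorm(4, 0.8), rnorm(4, 0.4))
  h_obs <- kruskal_wallis(samples)$statistic
  pooled <- unlist(samples)
  perm <- replicate(20000, {
    x <- sample(pooled)
    kw_brute(list(x[1:4], x[5:8], x[9:12]))
  })
  p_perm <- mean(perm >= h_obs - 1e-12)
  expect_lt(abs(kruskal_wallis(samples)$p_value - p_perm), 0.05)
})

test_that("Dunn-Bonferroni z and adjustment match hand computation", {
  identical3 <- dunn_bonferroni(list(c(1, 2), c(1, 2), c(1, 2)))
  expect_true(all(identical3$p_adjusted == 1))

  # 3 groups of 4, hand-computed pooled ranks
  s <- list(a = c(1, 2, 3, 4), b = c(5, 6, 7, 8), c = c(9, 10, 11, 12))
  d <- dunn_bonferroni(s)
  N <- 12
  sigma2 <- N * (N + 1) / 12
  z_ab <- (mean(1:4) - mean(5:8)) / sqrt(sigma2 * (1 / 4 + 1 / 4))
  expect_equal(d$z[d$group_i == "a" & d$group_j == "b"], z_ab)
  expect_equal(d$p_adjusted, pmin(1, 3 * d$p_raw))
  expect_error(dunn_bonferroni(list(1:3, 4:6)), "3 groups")
})

test_that("descriptive cohort statistics: single record and ratio handling", {
  rec <- data.frame(subject_id = "a", age = 60, ce_volume = 10,
                    flair_volume = 40, os_weeks = 52)
  d <- descriptive_cohort(rec)
  expect_equal(d$mean[d$variable == "ce_volume"], 10)
  expect_equal(d$sd[d$variable == "ce_volume"], 0)
  expect_equal(d$mean[d$variable == "ce_flair_ratio"], 0.25)
  expect_error(descriptive_cohort(rec[0, ]), "no patient")
})
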