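# Independent brute-force oracles and small shared fixtures.

# Exhaustive Otsu: maximize the between-class variance of the *data*
# (not a histogram) over every threshold midway between consecutive
# distinct values. Ties toward the smallest threshold.
otsu_brute <- function(values) {
  v <- sort(unique(values[is.finite(values)]))
  stopifnot(length(v) >= 2)
  mids <- (v[-1] + v[-length(v)]) / 2
  n <- length(values)
  best <- -Inf; best_t <- mids[1]
  for (t in mids) {
    lo <- values[values <= t]; hi <- values[values > t]
    w0 <- length(lo) / n; w1 <- length(hi) / n
    sb <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (sb > best + 1e-12) { best <- sb; best_t <- t }
  }
  list(threshold = best_t, between_class_variance = best)
}

# Data-level between-class variance of the partition induced by t.
data_sigma_b <- function(values, t) {
  lo <- values[values <= t]; hi <- values[values > t]
  if (!length(lo) || !length(hi)) return(0)
  w0 <- length(lo) / length(values)
  w0 * (1 - w0) * (mean(lo) - mean(hi))^2
}

# Brute-force sphere membership: scan the full neighbourhood cube.
sphere_brute <- function(grid, center, diameter) {
  r <- diameter / 2
  idx <- as.matrix(expand.grid(i = 0:(grid$shape[1] - 1),
                               j = 0:(grid$shape[2] - 1),
                               k = 0:(grid$shape[3] - 1)))
  w <- sweep(sweep(idx, 2, grid$spacing, "*"), 2, grid$origin, "+")
  d2 <- rowSums(sweep(w, 2, center, "-")^2)
  idx[d2 <= r^2, , drop = FALSE] + 1L
}

# Direct trilinear evaluation at one world point (loop form).
trilinear_point <- function(arr, grid, w) {
  u <- (w - grid$origin) / grid$spacing
  f <- pmin(pmax(floor(u), 0), grid$shape - 2)
  d <- u - f
  acc <- 0
  for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
    wt <- (if (di) d[1] else 1 - d[1]) *
          (if (dj) d[2] else 1 - d[2]) *
          (if (dk) d[3] else 1 - d[3])
    acc <- acc + wt * arr[f[1] + di + 1, f[2] + dj + 1, f[3] + dk + 1]
  }
  acc
}

# Exact two-sided Mann-Whitney p by full enumeration of group labelings.
mw_enumerate <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled); na <- length(a)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  sets <- utils::combn(n, na)
  u_all <- apply(sets, 2, function(s) sum(r[s]) - na * (na + 1) / 2)
  min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
}

# Tie-corrected Kruskal-Wallis H from the textbook rank formula.
kw_brute <- function(samples) {
  x <- unlist(samples); g <- rep(seq_along(samples), lengths(samples))
  N <- length(x); r <- rank(x)
  h <- 12 / (N * (N + 1)) * sum(tapply(r, g, sum)^2 / lengths(samples)) - 3 * (N + 1)
  tie <- table(x)
  h / (1 - sum(tie^3 - tie) / (N^3 - N))
}

# Small phantom for fast tests: same zone proportions as the default,
# scaled onto a 64^3 grid.
small_phantom_spec <- function(...) {
  phantom_spec(grid = image_grid(c(64, 64, 64), origin = c(-32, -32, -32)),
               zone_radii = c(16, 21, 24, 27, 29) * 0.55,
               halo_width = 2, ...)
}

# Uniform random volume on a small grid, for resampling tests.
random_volume <- function(shape = c(12, 10, 9), spacing = c(1, 1, 1),
                          origin = c(0, 0, 0), seed = 1, modality = "Vp") {
  set.seed(seed)
  g <- image_grid(shape, spacing, origin)
  parametric_volume(array(runif(prod(shape)), dim = shape), g, modality,
                    subject_id = "test")
}
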