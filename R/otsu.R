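#' Otsu threshold of a set of intensities
#'
#' Builds an `n_bins` histogram over the data range and returns the
#' bin-edge threshold maximizing the between-class variance
#' \deqn{\sigma_b^2(t) = \omega_0(t)\,\omega_1(t)\,(\mu_0(t)-\mu_1(t))^2,}
#' which is equivalent to minimizing the intra-class intensity variance.
#' Class weights and means are computed from bin centres. Ties are broken
#' toward the smallest threshold, and the threshold is reported as the
#' upper edge of the selected bin, so a value `v` is "high" iff `v > T`.
#'
#' @param values numeric vector; non-finite entries are dropped.
#' @param n_bins number of histogram bins (default 256, the conventional
#'   grayscale choice).
#' @return an object of class `otsu_result` with fields `threshold`,
#'   `between_class_variance`, `n_bins`, `bin_edges_range`, `n_values`.
#' @export
otsu_threshold <- function(values, n_bins = 256) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 2L) stop("Otsu threshold needs at least 2 finite values")
  n_bins <- as.integer(n_bins)
  if (n_bins < 2L) stop("n_bins must be at least 2")
  lo <- min(values); hi <- max(values)
  if (hi - lo <= 0) stop("degenerate map: all values identical, cannot threshold")
  edges <- seq(lo, hi, length.out = n_bins + 1L)
  bin <- findInterval(values, edges, rightmost.closed = TRUE, all.inside = TRUE)
  p <- tabulate(bin, nbins = n_bins) / n
  centres <- (edges[-1L] + edges[-(n_bins + 1L)]) / 2
  # candidate threshold after bin b = upper edge of bin b, b = 1..n_bins-1
  w0 <- cumsum(p)[-n_bins]
  s0 <- cumsum(p * centres)[-n_bins]
  mu_total <- sum(p * centres)
  w1 <- 1 - w0
  sigma_b <- rep(0, n_bins - 1L)
  valid <- w0 > 0 & w1 > 0
  mu0 <- s0[valid] / w0[valid]
  mu1 <- (mu_total - s0[valid]) / w1[valid]
  sigma_b[valid] <- w0[valid] * w1[valid] * (mu0 - mu1)^2
  b <- which.max(sigma_b)  # first maximum = smallest threshold on ties
  structure(list(threshold = edges[b + 1L],
                 between_class_variance = sigma_b[b],
                 n_bins = n_bins,
                 bin_edges_range = c(lo, hi),
                 n_values = n),
            class = "otsu_result")
}

#' @export
print.otsu_result <- function(x, ...) {
  cat(sprintf("<otsu_result> T = %g (sigma_b^2 = %g), %d bins over [%g, %g], n = %d\n",
              x$threshold, x$between_class_variance, x$n_bins,
              x$bin_edges_range[1], x$bin_edges_range[2], x$n_values))
  invisible(x)
}
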