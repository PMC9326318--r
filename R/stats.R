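#' Per-subject habitat volume fractions
#'
#' The fraction of habitat h is `100 * n_h / n_assigned`, where the
#' denominator counts voxels with labels 1-8 (assigned voxels). In-ROI
#' voxels excluded by the inclusion rule (label 0) are reported separately
#' and do not enter the denominator.
#'
#' @param map a `habitat_map`.
#' @return one-row data.frame with `subject_id`, `assigned_voxels`,
#'   `label0_voxels`, and `frac_1` ... `frac_8` (percent, summing to 100).
#' @export
habitat_fractions <- function(map) {
  counts <- tabulate(map$label[map$label > 0L], nbins = 8L)
  assigned <- sum(counts)
  if (assigned == 0L)
    stop(sprintf("subject '%s': no assigned habitat voxels (all label 0)",
                 map$subject_id))
  out <- data.frame(subject_id = map$subject_id,
                    assigned_voxels = assigned,
                    label0_voxels = sum(map$roi) - assigned,
                    stringsAsFactors = FALSE)
  fr <- as.list(100 * counts / assigned)
  names(fr) <- paste0("frac_", 1:8)
  cbind(out, as.data.frame(fr))
}

#' Per-habitat median map values for one subject
#'
#' For each habitat (1-8) and each of the three maps, the median of the
#' map over voxels carrying that label, plus the whole-ROI median. MD is
#' reported multiplied by 10^3 (i.e. in 10^-3 mm^2/s) following the
#' conventional display scale. Empty habitats yield `NA`, not 0.
#'
#' @param map a `habitat_map`.
#' @param volumes list of the three [parametric_volume()]s (any order).
#' @return data.frame with columns `map`, `habitat` (`"1"`..`"8"`,
#'   `"whole"`), `median`.
#' @export
habitat_medians <- function(map, volumes) {
  tags <- vapply(volumes, function(v) v$modality, character(1))
  if (!setequal(tags, MODALITIES) || anyDuplicated(tags))
    stop("habitat_medians needs exactly one volume per modality")
  names(volumes) <- tags
  rows <- list()
  for (m in MODALITIES) {
    v <- volumes[[m]]
    if (!grids_equal(v$grid, map$grid))
      stop(sprintf("subject '%s': %s map grid does not match the habitat map",
                   map$subject_id, m))
    scale <- if (m == "MD") 1e3 else 1
    for (h in 1:8) {
      sel <- map$label == h
      med <- if (any(sel)) stats::median(v$values[sel], na.rm = TRUE) else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = map$subject_id, map = m, habitat = as.character(h),
        median = med * scale, stringsAsFactors = FALSE)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      subject_id = map$subject_id, map = m, habitat = "whole",
      median = stats::median(v$values[map$roi], na.rm = TRUE) * scale,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Cohort habitat-fraction table with per-habitat row averages
#'
#' @param rows data.frame of per-subject fraction rows (one per subject,
#'   columns `subject_id`, `frac_1`..`frac_8`), e.g. stacked
#'   [habitat_fractions()] output or the packaged cohort fixture.
#' @return list with `per_subject` (subjects x 8 matrix, percent) and
#'   `row_average` (length-8 unweighted mean across subjects).
#' @export
cohort_table <- function(rows) {
  if (nrow(rows) == 0L) stop("no fraction rows supplied")
  m <- as.matrix(rows[, paste0("frac_", 1:8)])
  rownames(m) <- rows$subject_id
  colnames(m) <- paste0("habitat_", 1:8)
  list(per_subject = m, row_average = colMeans(m))
}

#' Group-wise habitat fraction summaries
#'
#' Unweighted mean and median habitat fractions per group, grouping
#' subjects by a clinical key (IDH-1 status, WHO grade, or MGMT status).
#' Subjects with unknown key values are dropped with a warning; empty
#' groups are omitted.
#'
#' @param rows per-subject fraction rows (see [cohort_table()]).
#' @param records clinical records with `subject_id` and the key column
#'   (see [load_fixture()] `"table1"` for the schema).
#' @param key `"idh1"`, `"histology_grade"`, or `"mgmt"`.
#' @return long data.frame with columns `group`, `n`, `habitat`, `mean`,
#'   `median`.
#' @export
grouped_summary <- function(rows, records, key = c("idh1", "histology_grade", "mgmt")) {
  key <- match.arg(key)
  merged <- merge(rows, records[, c("subject_id", key)], by = "subject_id")
  if (nrow(merged) < nrow(rows))
    warning(sprintf("%d subject(s) without a clinical record dropped",
                    nrow(rows) - nrow(merged)))
  unknown <- is.na(merged[[key]]) | merged[[key]] == "unknown"
  if (any(unknown)) {
    warning(sprintf("%d subject(s) with unknown %s dropped", sum(unknown), key))
    merged <- merged[!unknown, , drop = FALSE]
  }
  if (nrow(merged) == 0L) stop("no subjects with a known grouping key")
  out <- list()
  for (g in unique(merged[[key]])) {
    sub <- merged[merged[[key]] == g, , drop = FALSE]
    for (h in 1:8) {
      x <- sub[[paste0("frac_", h)]]
      out[[length(out) + 1L]] <- data.frame(
        group = g, n = nrow(sub), habitat = h,
        mean = mean(x), median = stats::median(x), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

group_comparison <- function(method, groups, statistic, p_value,
                             adjusted = FALSE, exact = NA, detail = NULL) {
  structure(list(method = method, groups = groups,
                 statistic = unname(statistic), p_value = unname(p_value),
                 adjusted = adjusted, exact = exact, detail = detail),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<%s> statistic = %g, p = %g%s\n", x$method, x$statistic,
              x$p_value, if (isTRUE(x$adjusted)) " (adjusted)" else ""))
  invisible(x)
}

#' Mann-Whitney U test (independent samples, two-sided)
#'
#' Exact p-value from the full permutation null when both samples are
#' small (`max(n_a, n_b) <= exact_max_n`) and there are no cross-sample
#' ties; otherwise the normal approximation with tie correction (no
#' continuity correction). Two identical constant samples give p = 1.
#'
#' @param a,b numeric samples.
#' @param exact_max_n largest group size for the exact null (default 20).
#' @return a `group_comparison` with the U statistic of sample `a`.
#' @export
mann_whitney_u <- function(a, b, exact_max_n = 20) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) == 0L || length(b) == 0L) stop("both samples must be non-empty")
  groups <- list(a = length(a), b = length(b))
  pooled <- c(a, b)
  u_stat <- sum(rank(pooled)[seq_along(a)]) - length(a) * (length(a) + 1) / 2
  if (length(unique(pooled)) == 1L)
    return(group_comparison("mann_whitney_u", groups, u_stat, 1, exact = FALSE))
  ties <- any(duplicated(pooled))
  use_exact <- !ties && max(length(a), length(b)) <= exact_max_n
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = use_exact,
                                            correct = FALSE))
  group_comparison("mann_whitney_u", groups, u_stat, wt$p.value,
                   exact = use_exact)
}

#' Kruskal-Wallis rank test across k groups
#'
#' Tie-corrected H statistic with a chi-square p-value on k-1 degrees of
#' freedom. All-identical values give H = 0, p = 1.
#'
#' @param samples list of >= 2 non-empty numeric vectors.
#' @return a `group_comparison`.
#' @export
kruskal_wallis <- function(samples) {
  if (length(samples) < 2L) stop("need at least 2 groups")
  if (any(vapply(samples, length, integer(1)) == 0L))
    stop("all groups must be non-empty")
  groups <- lapply(samples, length)
  if (length(unique(unlist(samples))) == 1L)
    return(group_comparison("kruskal_wallis", groups, 0, 1, exact = FALSE))
  kt <- stats::kruskal.test(samples)
  group_comparison("kruskal_wallis", groups, kt$statistic, kt$p.value,
                   exact = FALSE)
}

#' Dunn's post hoc pairwise comparisons with Bonferroni correction
#'
#' Pairwise z statistics from pooled ranks,
#' `z = (Rbar_i - Rbar_j) / sqrt(sigma2 * (1/n_i + 1/n_j))` with
#' `sigma2 = N(N+1)/12 - sum(t^3 - t)/(12(N-1))` (tie correction), and
#' p-values adjusted by the factor k(k-1)/2, capped at 1.
#'
#' @param samples list of >= 3 non-empty numeric vectors (named or not).
#' @return data.frame with one row per pair: `group_i`, `group_j`, `z`,
#'   `p_raw`, `p_adjusted`.
#' @export
dunn_bonferroni <- function(samples) {
  k <- length(samples)
  if (k < 3L) stop("Dunn's procedure needs at least 3 groups")
  if (any(vapply(samples, length, integer(1)) == 0L))
    stop("all groups must be non-empty")
  nm <- names(samples)
  if (is.null(nm)) nm <- as.character(seq_len(k))
  n <- vapply(samples, length, integer(1))
  N <- sum(n)
  r <- rank(unlist(samples))
  grp <- rep(seq_len(k), times = n)
  rbar <- tapply(r, grp, mean)
  tie_tab <- table(unlist(samples))
  sigma2 <- N * (N + 1) / 12 - sum(tie_tab^3 - tie_tab) / (12 * (N - 1))
  m <- k * (k - 1) / 2
  out <- list()
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    se <- sqrt(sigma2 * (1 / n[i] + 1 / n[j]))
    z <- if (se > 0) (rbar[[i]] - rbar[[j]]) / se else 0
    p_raw <- 2 * stats::pnorm(-abs(z))
    out[[length(out) + 1L]] <- data.frame(
      group_i = nm[i], group_j = nm[j], z = z, p_raw = p_raw,
      p_adjusted = min(1, m * p_raw), stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Descriptive cohort statistics
#'
#' Mean, SD, median and range for age, CE tumor volume, FLAIR tumor
#' volume, per-patient CE/FLAIR volume ratio, and overall survival. The
#' ratio is computed per patient and then averaged.
#'
#' @param records clinical records (schema of [load_fixture()] `"table1"`).
#' @return data.frame with one row per variable: `variable`, `n`, `mean`,
#'   `sd`, `median`, `min`, `max`.
#' @export
descriptive_cohort <- function(records) {
  if (nrow(records) == 0L) stop("no patient records supplied")
  vars <- list(age = records$age,
               ce_volume = records$ce_volume,
               flair_volume = records$flair_volume,
               ce_flair_ratio = records$ce_volume / records$flair_volume,
               os_weeks = records$os_weeks)
  out <- lapply(names(vars), function(nm) {
    x <- vars[[nm]][is.finite(vars[[nm]])]
    data.frame(variable = nm, n = length(x), mean = mean(x),
               sd = if (length(x) > 1L) stats::sd(x) else 0,
               median = stats::median(x), min = min(x), max = max(x),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
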