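#' Bootstrap resampling indices
#'
#' Draws `n_rep` resamples of subject indices with replacement. Each subject
#' has equal inclusion probability, may appear more than once, and every
#' resample has the size of the original cohort.
#'
#' @param n_subjects Cohort size (>= 3; interregional correlation is
#'   degenerate below that).
#' @param n_rep Number of resamples (>= 1).
#' @param seed Integer seed; the result is deterministic given the seed.
#' @return Integer matrix of dimension `n_rep x n_subjects`; each row is one
#'   resample.
#' @export
bootstrap_resample <- function(n_subjects, n_rep, seed) {
  if (n_subjects < 3) {
    msync_abort("bootstrap resampling requires n_subjects >= 3",
                class = "microsync_validation_error")
  }
  if (n_rep < 1) {
    msync_abort("n_rep must be >= 1", class = "microsync_validation_error")
  }
  with_seed(seed, {
    matrix(sample.int(n_subjects, n_subjects * n_rep, replace = TRUE),
           nrow = n_rep, ncol = n_subjects)
  })
}

#' Fisher's R-to-Z transformation with boundary clipping
#'
#' `Z = arctanh(R)`, applied after clipping `|R|` to `1 - 1e-7`. Resampling
#' with replacement can yield `|R| = 1` exactly, whose Z is infinite and
#' would poison a bootstrap mean; the clip bound maps it to a large finite
#' value (about 8.41).
#'
#' @param r Numeric vector of correlation coefficients in `[-1, 1]`.
#' @return Fisher-Z values.
#' @export
fisher_z <- function(r) {
  bound <- 1 - 1e-7
  atanh(pmin(pmax(r, -bound), bound))
}

#' Bootstrapped interregional correlation (ICC) matrix
#'
#' For every unordered VOI pair, computes Pearson's correlation on each
#' bootstrap resample of subjects, transforms it with [fisher_z()], and
#' averages over valid resamples. That mean Fisher-Z value is the ICC.
#' Resamples in which either VOI of a pair has zero variance are excluded
#' from that pair's mean (the correlation is undefined there); a pair invalid
#' in more than half of the resamples is flagged degenerate and masked.
#'
#' p-values come from the two-sided Pearson test (t distribution,
#' `df = n - 2`) on the original, non-resampled cohort; the bootstrap only
#' stabilizes the correlation estimate.
#'
#' @param table A normalized [uptake_table()] with >= 3 subjects.
#' @param n_rep Number of bootstrap resamples (defaults used in practice:
#'   10000 for mouse cohorts, 1000 for human cohorts).
#' @param seed Integer seed driving the resampling.
#' @param identity_resample If `TRUE`, every "resample" is the identity
#'   permutation; with `n_rep = 1` the ICC then equals `arctanh` of the plain
#'   Pearson correlation (used for verification).
#' @param max_invalid_frac Fraction of invalid resamples above which a pair
#'   is masked.
#' @return An object of class `icc_matrix` with fields `vois`, `z_mean`
#'   (symmetric, diagonal `NA`), `p_values` (symmetric, diagonal `NA`),
#'   `n_subjects`, `n_rep`, `seed`, `n_invalid` (per-pair count of excluded
#'   resamples).
#' @export
compute_icc_matrix <- function(table, n_rep = 10000, seed = 1L,
                               identity_resample = FALSE,
                               max_invalid_frac = 0.5) {
  stopifnot(inherits(table, "uptake_table"))
  X <- table$values
  n <- nrow(X)
  p <- ncol(X)
  if (n < 3) {
    msync_abort("ICC requires at least 3 subjects",
                class = "microsync_validation_error")
  }
  if (p < 2) {
    msync_abort("ICC requires at least 2 VOIs",
                class = "microsync_validation_error")
  }
  idx <- if (identity_resample) {
    matrix(rep(seq_len(n), each = n_rep), nrow = n_rep)
  } else {
    bootstrap_resample(n, n_rep, seed)
  }
  z_sum <- matrix(0, p, p)
  z_cnt <- matrix(0L, p, p)
  ones <- matrix(1L, p, p)
  for (k in seq_len(n_rep)) {
    Xk <- X[idx[k, ], , drop = FALSE]
    R <- suppressWarnings(stats::cor(Xk))
    if (anyNA(R)) {
      ok <- is.finite(R)
      Z <- fisher_z(R)
      z_sum[ok] <- z_sum[ok] + Z[ok]
      z_cnt[ok] <- z_cnt[ok] + 1L
    } else {
      z_sum <- z_sum + fisher_z(R)
      z_cnt <- z_cnt + ones
    }
  }
  z_mean <- z_sum / z_cnt
  z_mean[!is.finite(z_mean)] <- NA_real_
  n_invalid <- n_rep - z_cnt
  degenerate <- n_invalid > max_invalid_frac * n_rep
  if (any(degenerate[upper.tri(degenerate)])) {
    msync_log("compute_icc_matrix: ",
              sum(degenerate[upper.tri(degenerate)]),
              " pair(s) degenerate (> ", round(100 * max_invalid_frac),
              "% invalid resamples); masked")
  }
  z_mean[degenerate] <- NA_real_
  diag(z_mean) <- NA_real_
  tot_invalid <- sum(n_invalid[upper.tri(n_invalid)])
  if (tot_invalid > 0) {
    msync_log("compute_icc_matrix: excluded ", tot_invalid,
              " zero-variance pair-resamples from the mean")
  }
  # Two-sided Pearson test on the original cohort.
  R0 <- suppressWarnings(stats::cor(X))
  r0 <- pmin(pmax(R0, -1), 1)
  tstat <- abs(r0) * sqrt((n - 2) / pmax(1 - r0^2, .Machine$double.xmin))
  p_values <- 2 * stats::pt(tstat, df = n - 2, lower.tail = FALSE)
  p_values[!is.finite(R0)] <- NA_real_
  diag(p_values) <- NA_real_
  dimnames(z_mean) <- dimnames(p_values) <- list(table$vois, table$vois)
  structure(
    list(vois = table$vois, z_mean = z_mean, p_values = p_values,
         n_subjects = n, n_rep = n_rep,
         seed = if (identity_resample) NA_integer_ else as.integer(seed),
         n_invalid = n_invalid),
    class = "icc_matrix"
  )
}

#' @export
print.icc_matrix <- function(x, ...) {
  cat(sprintf("<icc_matrix> %d VOIs, n = %d subjects, %d bootstrap resamples\n",
              length(x$vois), x$n_subjects, x$n_rep))
  invisible(x)
}

# Upper-triangle pair view of an icc_matrix: one row per unordered pair,
# pair members ordered lexicographically by VOI id.
icc_pairs <- function(icc) {
  stopifnot(inherits(icc, "icc_matrix"))
  ord <- order(icc$vois)
  z <- icc$z_mean[ord, ord, drop = FALSE]
  p <- icc$p_values[ord, ord, drop = FALSE]
  vois <- icc$vois[ord]
  ut <- which(upper.tri(z), arr.ind = TRUE)
  data.frame(
    voi_i = vois[ut[, 1]],
    voi_j = vois[ut[, 2]],
    z = z[ut],
    p = p[ut],
    stringsAsFactors = FALSE
  )
}

#' Significance-thresholded connection set
#'
#' A VOI pair is a significant connection when `|ICC| > z_threshold` and the
#' correlation p-value is below `p_threshold` (defaults: the mouse criteria
#' `|ICC| > 0.5`, `p < 0.005`; human cohorts use `p < 0.001`). Negative
#' correlations count via the magnitude rule. Each connection is classified
#' from the compartment labels of its two VOIs: equal labels give that label
#' (e.g. `cortical`), mixed labels give the hyphenated sorted pair (e.g.
#' `cortical-subcortical`, `parietal-temporal`).
#'
#' @param icc An `icc_matrix` from [compute_icc_matrix()].
#' @param atlas An [atlas_metadata()] covering all VOIs of `icc`.
#' @param z_threshold Magnitude threshold on the Fisher-Z scale.
#' @param p_threshold Correlation p-value threshold.
#' @return An object of class `connection_set`: `edges` (`data.frame` with
#'   `voi_i < voi_j` lexicographically, `z`, `p`, `class`), `z_threshold`,
#'   `p_threshold`, `class_counts` (named vector summing to `total`),
#'   `total`.
#' @export
significant_connections <- function(icc, atlas, z_threshold = 0.5,
                                    p_threshold = 0.005) {
  stopifnot(inherits(icc, "icc_matrix"))
  missing <- setdiff(icc$vois, atlas$voi_id)
  if (length(missing) > 0) {
    msync_abort("atlas does not cover VOI(s): ",
                paste(missing, collapse = ", "),
                class = "microsync_validation_error")
  }
  pairs <- icc_pairs(icc)
  keep <- !is.na(pairs$z) & !is.na(pairs$p) &
    abs(pairs$z) > z_threshold & pairs$p < p_threshold
  edges <- pairs[keep, , drop = FALSE]
  comp <- stats::setNames(atlas$compartment, atlas$voi_id)
  cls <- function(a, b) {
    if (a == b) a else paste(sort(c(a, b)), collapse = "-")
  }
  edges$class <- if (nrow(edges) > 0) {
    mapply(cls, comp[edges$voi_i], comp[edges$voi_j], USE.NAMES = FALSE)
  } else {
    character(0)
  }
  rownames(edges) <- NULL
  counts <- if (nrow(edges) > 0) table(edges$class) else table(character(0))
  structure(
    list(edges = edges, z_threshold = z_threshold, p_threshold = p_threshold,
         class_counts = stats::setNames(as.integer(counts), names(counts)),
         total = nrow(edges)),
    class = "connection_set"
  )
}

#' @export
print.connection_set <- function(x, ...) {
  cat(sprintf("<connection_set> %d connections (|Z| > %g, p < %g)\n",
              x$total, x$z_threshold, x$p_threshold))
  if (length(x$class_counts)) {
    cat(paste0("  ", names(x$class_counts), ": ", x$class_counts,
               collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Connection number ratio
#'
#' Standardizes connection counts across experiments by dividing the count in
#' a cohort by the count in its reference cohort. Reported to two decimals in
#' tabular outputs; the returned value is unrounded.
#'
#' @param cohort_count,reference_count Non-negative connection counts;
#'   `reference_count` must be positive.
#' @return `cohort_count / reference_count`.
#' @export
connection_ratio <- function(cohort_count, reference_count) {
  if (reference_count <= 0) {
    msync_abort("reference cohort has no connections; ratio undefined",
                class = "microsync_degenerate_error")
  }
  cohort_count / reference_count
}

#' Quartiles of the absolute ICC distribution
#'
#' Summarizes an ICC matrix by the quartiles of `|ICC|` over all unmasked
#' unordered pairs (each pair counted once). The median (second quartile) is
#' the headline cohort-synchronicity figure.
#'
#' @param icc An `icc_matrix`.
#' @return A list with `q1`, `q2`, `q3` and `n_pairs`.
#' @export
median_abs_icc <- function(icc) {
  vals <- abs(icc_pairs(icc)$z)
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0) {
    msync_abort("all pairs masked; summary undefined",
                class = "microsync_degenerate_error")
  }
  q <- stats::quantile(vals, probs = c(0.25, 0.5, 0.75), names = FALSE)
  list(q1 = q[1], q2 = q[2], q3 = q[3], n_pairs = length(vals))
}

#' Compare two cohorts' absolute ICC distributions
#'
#' Two-tailed Wilcoxon signed-rank test on the paired `|ICC|` vectors of two
#' cohorts over the same VOI pairs (ICC distributions are non-Gaussian, hence
#' the rank test). Zero-difference pairs are dropped per the standard
#' procedure; if every pair is identical the test is reported with `p = 1`
#' and flagged.
#'
#' @param icc_a,icc_b `icc_matrix` objects over identical VOI sets.
#' @return A list: `statistic`, `p_value`, `n_pairs` (non-zero differences),
#'   `summary_a`, `summary_b` (quartile summaries from [median_abs_icc()]),
#'   `all_equal` flag.
#' @export
compare_icc_distributions <- function(icc_a, icc_b) {
  if (!setequal(icc_a$vois, icc_b$vois)) {
    msync_abort("cohorts must share an identical VOI set",
                class = "microsync_validation_error")
  }
  pa <- icc_pairs(icc_a)
  pb <- icc_pairs(icc_b)
  stopifnot(identical(pa$voi_i, pb$voi_i), identical(pa$voi_j, pb$voi_j))
  a <- abs(pa$z)
  b <- abs(pb$z)
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]
  b <- b[ok]
  if (length(a) == 0) {
    msync_abort("no jointly unmasked pairs", class = "microsync_degenerate_error")
  }
  d <- a - b
  if (all(d == 0)) {
    return(list(statistic = NA_real_, p_value = 1, n_pairs = 0L,
                summary_a = median_abs_icc(icc_a),
                summary_b = median_abs_icc(icc_b),
                all_equal = TRUE))
  }
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, paired = TRUE, alternative = "two.sided",
                       exact = FALSE, correct = TRUE)
  )
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       n_pairs = sum(d != 0),
       summary_a = median_abs_icc(icc_a),
       summary_b = median_abs_icc(icc_b),
       all_equal = FALSE)
}
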