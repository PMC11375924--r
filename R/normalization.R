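#' Global mean scaling to SUVR
#'
#' Divides each subject's row by that subject's mean uptake over all VOIs in
#' the table, the standard normalization of injected activity for tracer
#' uptake tables. The global mean is the unweighted mean over the table's VOI
#' set, an approximation to the image-space whole-brain mean. After scaling,
#' every subject's row mean equals 1 and the table is tagged `global_mean`.
#'
#' @param table A raw [uptake_table()].
#' @return The scaled [uptake_table()] (SUVR).
#' @export
global_mean_scale <- function(table) {
  stopifnot(inherits(table, "uptake_table"))
  gm <- rowMeans(table$values)
  uptake_table(table$values / gm, normalization = "global_mean")
}

#' Scale by an external per-subject reference value
#'
#' Divides each subject's row by a subject-specific positive reference value,
#' e.g. myocardium uptake (a brain-independent quantification) or uptake in a
#' best reference region.
#'
#' @param table An [uptake_table()].
#' @param reference_values Named numeric vector of positive reference values,
#'   one per table subject (matched by name).
#' @param tag Normalization tag to record, `"myocardium"` or
#'   `"best_reference"`.
#' @return The scaled [uptake_table()].
#' @export
external_reference_scale <- function(table, reference_values,
                                     tag = c("myocardium", "best_reference")) {
  stopifnot(inherits(table, "uptake_table"))
  tag <- match.arg(tag)
  if (is.null(names(reference_values))) {
    if (length(reference_values) != length(table$subjects)) {
      msync_abort("unnamed reference values must match the number of subjects",
                  class = "microsync_validation_error")
    }
    names(reference_values) <- table$subjects
  }
  missing <- setdiff(table$subjects, names(reference_values))
  if (length(missing) > 0) {
    msync_abort("missing reference value for subject(s): ",
                paste(missing, collapse = ", "),
                class = "microsync_validation_error")
  }
  ref <- reference_values[table$subjects]
  if (any(!is.finite(ref) | ref <= 0)) {
    msync_abort("reference values must be positive and finite",
                class = "microsync_validation_error")
  }
  uptake_table(table$values / ref, normalization = tag)
}

#' Cohen's d between two groups
#'
#' Standardized mean difference `(mean_a - mean_b) / s_pooled`, with the
#' pooled standard deviation computed from Bessel-corrected group variances:
#' `s_pooled^2 = ((n_a - 1) s_a^2 + (n_b - 1) s_b^2) / (n_a + n_b - 2)`.
#'
#' @param group_a,group_b Numeric vectors, each of length >= 2.
#' @return Signed effect size (group A minus group B).
#' @export
cohens_d <- function(group_a, group_b) {
  if (length(group_a) < 2 || length(group_b) < 2 ||
      !all(is.finite(group_a)) || !all(is.finite(group_b))) {
    msync_abort("each group needs >= 2 finite values",
                class = "microsync_validation_error")
  }
  na <- length(group_a); nb <- length(group_b)
  sp2 <- ((na - 1) * stats::var(group_a) + (nb - 1) * stats::var(group_b)) /
    (na + nb - 2)
  if (sp2 <= 0) {
    msync_abort("pooled SD is zero; effect size undefined",
                class = "microsync_degenerate_error")
  }
  (mean(group_a) - mean(group_b)) / sqrt(sp2)
}

#' Select the best reference region between two cohorts
#'
#' The best reference region (BR) is the VOI with the smallest absolute
#' Cohen's d between the two cohorts on global-mean-scaled uptake: the region
#' least affected by the group contrast, hence a suitable normalization
#' denominator. Ties are broken by lexicographic VOI id with a logged
#' warning.
#'
#' @param cohort_a,cohort_b Global-mean-scaled [uptake_table()]s over
#'   identical VOI sets.
#' @return A list with `voi_id` (the selected BR) and `effect_sizes`, a
#'   `data.frame` with one row per VOI (`voi_id`, `cohens_d`, group means and
#'   SDs).
#' @export
select_best_reference <- function(cohort_a, cohort_b) {
  stopifnot(inherits(cohort_a, "uptake_table"), inherits(cohort_b, "uptake_table"))
  if (!setequal(cohort_a$vois, cohort_b$vois)) {
    msync_abort("cohorts must share an identical VOI set",
                class = "microsync_validation_error")
  }
  vois <- sort(cohort_a$vois)
  a <- cohort_a$values[, vois, drop = FALSE]
  b <- cohort_b$values[, vois, drop = FALSE]
  d <- vapply(vois, function(v) cohens_d(a[, v], b[, v]), numeric(1))
  report <- data.frame(
    voi_id = vois,
    cohens_d = unname(d),
    mean_a = colMeans(a), mean_b = colMeans(b),
    sd_a = apply(a, 2, stats::sd), sd_b = apply(b, 2, stats::sd),
    row.names = NULL, stringsAsFactors = FALSE
  )
  best <- which(abs(report$cohens_d) == min(abs(report$cohens_d)))
  if (length(best) > 1) {
    msync_log("select_best_reference: tie on |d|, broken by lexicographic VOI id")
  }
  list(voi_id = report$voi_id[best[1]], effect_sizes = report)
}
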