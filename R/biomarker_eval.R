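#' Group-level inference on the desynchronization index
#'
#' Per VOI: Shapiro-Wilk normality check within each group, one-way ANOVA
#' across the three groups, and all three pairwise two-tailed unpaired
#' t-tests (Student by default, Welch by flag). A VOI is flagged significant
#' when its ANOVA p-value is below 0.05. VOIs where any group has zero
#' variance are flagged and their tests skipped.
#'
#' @param di A `di_table`.
#' @param manifest A [cohort_manifest()] covering all scored subjects.
#' @param groups Character vector of exactly three cohort labels, each with
#'   >= 3 scored subjects.
#' @param var_equal Use the equal-variance Student t-test (default); `FALSE`
#'   gives Welch.
#' @return A `data.frame` with one row per VOI: `voi_id`, per-group
#'   `shapiro_p_*`, `anova_F`, `anova_p`, per-pair `t_*` and `p_*`,
#'   `significant`, `degenerate`.
#' @export
di_group_stats <- function(di, manifest, groups, var_equal = TRUE) {
  stopifnot(inherits(di, "di_table"), length(groups) == 3)
  rows <- manifest[match(di$subjects, manifest$subject_id), , drop = FALSE]
  if (anyNA(rows$subject_id)) {
    msync_abort("scored subject(s) absent from manifest",
                class = "microsync_validation_error")
  }
  members <- lapply(groups, function(g) which(rows$cohort == g))
  names(members) <- groups
  if (any(vapply(members, length, integer(1)) < 3)) {
    msync_abort("each group needs >= 3 scored subjects",
                class = "microsync_validation_error")
  }
  pair_idx <- utils::combn(3, 2)
  res <- lapply(di$vois, function(v) {
    y <- di$values[, v]
    by_g <- lapply(members, function(ix) y[ix])
    out <- list(voi_id = v)
    degenerate <- any(vapply(by_g, function(x) stats::sd(x) == 0, logical(1)))
    for (g in groups) {
      out[[paste0("shapiro_p_", g)]] <-
        if (degenerate) NA_real_ else stats::shapiro.test(by_g[[g]])$p.value
    }
    if (degenerate) {
      out$anova_F <- NA_real_
      out$anova_p <- NA_real_
    } else {
      aovr <- stats::oneway.test(y ~ g, var.equal = TRUE,
                                 data = data.frame(
                                   y = unlist(by_g, use.names = FALSE),
                                   g = factor(rep(groups, vapply(by_g, length, integer(1))))))
      out$anova_F <- unname(aovr$statistic)
      out$anova_p <- aovr$p.value
    }
    for (k in seq_len(ncol(pair_idx))) {
      g1 <- groups[pair_idx[1, k]]
      g2 <- groups[pair_idx[2, k]]
      nm <- paste0(g1, "_vs_", g2)
      if (degenerate) {
        out[[paste0("t_", nm)]] <- NA_real_
        out[[paste0("p_", nm)]] <- NA_real_
      } else {
        tt <- stats::t.test(by_g[[g1]], by_g[[g2]], var.equal = var_equal,
                            alternative = "two.sided")
        out[[paste0("t_", nm)]] <- unname(tt$statistic)
        out[[paste0("p_", nm)]] <- tt$p.value
      }
    }
    out$significant <- !degenerate && out$anova_p < 0.05
    out$degenerate <- degenerate
    as.data.frame(out, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' First principal component of the desynchronization index
#'
#' Computes PC1 scores of the column-standardized index sub-matrix over a
#' VOI subset (typically the top-rated VOIs by ANOVA F), as a single
#' per-subject read-out. Constant columns are dropped with a warning. The
#' sign is oriented so that PC1 correlates non-negatively with the
#' per-subject mean index, making higher scores mean more desynchronization.
#'
#' @param di A `di_table` with >= 3 subjects.
#' @param voi_subset >= 2 VOI ids.
#' @return A list: `scores` (named per-subject PC1), `loadings`,
#'   `var_explained` (fraction in \[0, 1\]), `vois_used`.
#' @export
pc1_of_di <- function(di, voi_subset) {
  stopifnot(inherits(di, "di_table"), length(voi_subset) >= 2)
  missing <- setdiff(voi_subset, di$vois)
  if (length(missing) > 0) {
    msync_abort("VOI(s) not scored: ", paste(missing, collapse = ", "),
                class = "microsync_validation_error")
  }
  X <- di$values[, voi_subset, drop = FALSE]
  if (nrow(X) < 3) {
    msync_abort("PCA requires >= 3 subjects", class = "microsync_validation_error")
  }
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    warning("dropping constant VOI column(s): ",
            paste(colnames(X)[sds == 0], collapse = ", "))
    X <- X[, sds > 0, drop = FALSE]
    if (ncol(X) < 2) {
      msync_abort("fewer than 2 non-constant columns",
                  class = "microsync_degenerate_error")
    }
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  scores <- pc$x[, 1]
  loadings <- pc$rotation[, 1]
  anchor <- rowMeans(di$values[, voi_subset, drop = FALSE])
  if (stats::sd(anchor) > 0 && stats::cor(scores, anchor) < 0) {
    scores <- -scores
    loadings <- -loadings
  }
  list(scores = stats::setNames(scores, rownames(X)),
       loadings = loadings,
       var_explained = unname(pc$sdev[1]^2 / sum(pc$sdev^2)),
       vois_used = colnames(X))
}

#' Correlate the desynchronization index with a cognition score
#'
#' Per VOI: Pearson's r between the per-subject index and the cognition
#' score (e.g. MMSE, CDR-SOB), the two-sided correlation p-value, and the
#' least-squares slope/intercept of the index regressed on the score (the
#' fit drawn in index-versus-score plots). p-values are adjusted across the
#' VOI list with the Benjamini-Hochberg false-discovery-rate step-up
#' procedure; `p_fdr < 0.05` flags a significant correlation.
#'
#' @param di A `di_table`.
#' @param scores Named numeric vector of cognition scores covering every
#'   scored subject (>= 4 subjects, non-constant).
#' @param voi_list VOI ids to test; default all scored VOIs.
#' @return A `data.frame`: `voi_id`, `r`, `p`, `p_fdr`, `slope`,
#'   `intercept`, `significant`.
#' @export
correlate_di_cognition <- function(di, scores, voi_list = NULL) {
  stopifnot(inherits(di, "di_table"))
  voi_list <- voi_list %||% di$vois
  missing <- setdiff(di$subjects, names(scores))
  if (length(missing) > 0) {
    msync_abort("missing cognition score for subject(s): ",
                paste(missing, collapse = ", "),
                class = "microsync_validation_error")
  }
  s <- scores[di$subjects]
  if (length(s) < 4) {
    msync_abort("correlation requires >= 4 subjects",
                class = "microsync_validation_error")
  }
  if (stats::sd(s) == 0) {
    msync_abort("cognition scores are constant; correlation undefined",
                class = "microsync_degenerate_error")
  }
  res <- lapply(voi_list, function(v) {
    y <- di$values[, v]
    if (stats::sd(y) == 0) {
      return(data.frame(voi_id = v, r = NA_real_, p = NA_real_,
                        slope = 0, intercept = mean(y),
                        stringsAsFactors = FALSE))
    }
    ct <- stats::cor.test(y, s, method = "pearson",
                          alternative = "two.sided")
    fit <- stats::lm.fit(cbind(1, s), y)$coefficients
    data.frame(voi_id = v, r = unname(ct$estimate), p = ct$p.value,
               slope = unname(fit[2]), intercept = unname(fit[1]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_fdr <- stats::p.adjust(out$p, method = "BH")
  out$significant <- !is.na(out$p_fdr) & out$p_fdr < 0.05
  out[, c("voi_id", "r", "p", "p_fdr", "slope", "intercept", "significant")]
}

#' Discriminability of the index versus conventional uptake ratios
#'
#' For each VOI, forms the ratio of the test cohort's mean to the reference
#' cohort's mean, separately for SUVR and for the desynchronization index
#' (reference index values typically come from leave-one-out referencing).
#' A higher ratio indicates a greater ability to distinguish normal from
#' abnormal cohorts. The two ratio profiles are compared with a paired
#' two-tailed t-test across VOIs, plus Cohen's d of the paired differences
#' (`mean(diff) / sd(diff)`).
#'
#' @param di A `di_table` covering both cohorts' subjects.
#' @param suvr An [uptake_table()] covering both cohorts' subjects.
#' @param manifest A [cohort_manifest()].
#' @param test_cohort,reference_cohort Cohort labels.
#' @return A list: `per_voi` (`data.frame` with `voi_id`, `suvr_ratio`,
#'   `di_ratio`), `paired_t`, `paired_p`, `cohens_d_diff`,
#'   `mean_suvr_ratio`, `mean_di_ratio`, `degenerate` flag (constant paired
#'   differences: no p reported).
#' @export
di_vs_suvr <- function(di, suvr, manifest, test_cohort, reference_cohort) {
  stopifnot(inherits(di, "di_table"), inherits(suvr, "uptake_table"))
  vois <- intersect(di$vois, suvr$vois)
  if (length(vois) < 2) {
    msync_abort("need >= 2 common VOIs", class = "microsync_validation_error")
  }
  subj_of <- function(cohort) manifest$subject_id[manifest$cohort == cohort]
  mean_by <- function(mat, ids, who) {
    ids <- intersect(ids, rownames(mat))
    if (length(ids) == 0) {
      msync_abort("no ", who, " subjects available",
                  class = "microsync_validation_error")
    }
    colMeans(mat[ids, vois, drop = FALSE])
  }
  di_test <- mean_by(di$values, subj_of(test_cohort), "test-cohort index")
  di_ref <- mean_by(di$values, subj_of(reference_cohort), "reference-cohort index")
  su_test <- mean_by(suvr$values, subj_of(test_cohort), "test-cohort SUVR")
  su_ref <- mean_by(suvr$values, subj_of(reference_cohort), "reference-cohort SUVR")
  if (any(di_ref == 0) || any(su_ref == 0)) {
    msync_abort("zero reference mean; ratio undefined",
                class = "microsync_degenerate_error")
  }
  per_voi <- data.frame(voi_id = vois,
                        suvr_ratio = unname(su_test / su_ref),
                        di_ratio = unname(di_test / di_ref),
                        stringsAsFactors = FALSE)
  diffs <- per_voi$di_ratio - per_voi$suvr_ratio
  degenerate <- stats::sd(diffs) == 0
  if (degenerate) {
    tt <- list(statistic = NA_real_, p.value = NA_real_)
  } else {
    tt <- stats::t.test(per_voi$di_ratio, per_voi$suvr_ratio, paired = TRUE,
                        alternative = "two.sided")
  }
  list(per_voi = per_voi,
       paired_t = unname(tt$statistic),
       paired_p = tt$p.value,
       cohens_d_diff = if (degenerate) NA_real_ else mean(diffs) / stats::sd(diffs),
       mean_suvr_ratio = mean(per_voi$suvr_ratio),
       mean_di_ratio = mean(per_voi$di_ratio),
       degenerate = degenerate)
}
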