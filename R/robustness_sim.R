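#' RMSE between two ICC matrices
#'
#' Root mean square difference over the jointly unmasked unordered VOI
#' pairs, each pair counted once:
#' `sqrt(sum((z_a - z_b)^2) / n_pairs)`.
#'
#' @param icc_a,icc_b `icc_matrix` objects over identical VOI sets.
#' @return Non-negative RMSE.
#' @export
icc_rmse <- function(icc_a, icc_b) {
  if (!setequal(icc_a$vois, icc_b$vois)) {
    msync_abort("ICC matrices must share an identical VOI set",
                class = "microsync_validation_error")
  }
  pa <- icc_pairs(icc_a)
  pb <- icc_pairs(icc_b)
  ok <- !is.na(pa$z) & !is.na(pb$z)
  if (!any(ok)) {
    msync_abort("no jointly unmasked pairs; RMSE undefined",
                class = "microsync_degenerate_error")
  }
  sqrt(mean((pa$z[ok] - pb$z[ok])^2))
}

#' Subject-dropping robustness curve
#'
#' Assesses how the contrast between two cohorts' ICC matrices depends on
#' cohort size. For each step `n` from the full (common) size down to
#' `min_n`, both cohorts are randomly subsampled to `n` subjects (`n_draws`
#' independent draws; a single draw reproduces the one-mouse-at-a-time
#' procedure, more draws stabilize the curve), both ICC matrices are
#' recomputed with `n_boot` resamples, and their RMSE is averaged over
#' draws. Per-region Cohen's d between the subsampled cohorts' uptake is
#' averaged alongside. At the full size the cohorts are used as-is, so a
#' single-draw first step equals the full-cohort RMSE exactly.
#'
#' The result records the derived ICC seeds per step and draw, making every
#' entry independently recomputable.
#'
#' @param cohort_a,cohort_b [uptake_table()]s (normalized).
#' @param min_n Smallest cohort size to descend to (>= 4).
#' @param n_draws Random draws per step (default 20).
#' @param n_boot Bootstrap resamples per ICC matrix.
#' @param seed Integer base seed.
#' @return A `data.frame` with one row per (step, draw): `n_subjects`,
#'   `draw`, `rmse`, `seed_a`, `seed_b`, plus an attribute `per_region_d`
#'   (list of per-step mean Cohen's d vectors, named by `n_subjects`) and
#'   `summary` (per-step mean RMSE with a knee heuristic: the smallest `n`
#'   whose mean RMSE is within 10% of the full-size RMSE).
#' @export
subject_drop_curve <- function(cohort_a, cohort_b, min_n, n_draws = 20,
                               n_boot = 1000, seed = 1L) {
  stopifnot(inherits(cohort_a, "uptake_table"), inherits(cohort_b, "uptake_table"))
  if (!setequal(cohort_a$vois, cohort_b$vois)) {
    msync_abort("cohorts must share an identical VOI set",
                class = "microsync_validation_error")
  }
  na <- length(cohort_a$subjects)
  nb <- length(cohort_b$subjects)
  full_n <- min(na, nb)
  if (min_n < 4 || full_n < min_n) {
    msync_abort("need full cohort size >= min_n >= 4",
                class = "microsync_validation_error")
  }
  steps <- seq.int(as.integer(full_n), as.integer(min_n), by = -1L)
  rows <- list()
  d_by_step <- list()
  k <- 0L
  for (n in steps) {
    d_acc <- NULL
    for (dr in seq_len(n_draws)) {
      seed_sub <- as.integer(seed) + 100000L + 7L * k
      seed_a <- as.integer(seed) + 2L * k + 1L
      seed_b <- as.integer(seed) + 2L * k + 2L
      k <- k + 1L
      if (n == full_n) {
        ia <- seq_len(na)[seq_len(n)]
        ib <- seq_len(nb)[seq_len(n)]
      } else {
        ia <- with_seed(seed_sub, sample.int(na, n))
        ib <- with_seed(seed_sub + 1L, sample.int(nb, n))
      }
      sub_a <- uptake_table(cohort_a$values[ia, , drop = FALSE],
                            normalization = cohort_a$normalization)
      sub_b <- uptake_table(cohort_b$values[ib, , drop = FALSE],
                            normalization = cohort_b$normalization)
      rmse <- tryCatch({
        icc_a <- compute_icc_matrix(sub_a, n_rep = n_boot, seed = seed_a)
        icc_b <- compute_icc_matrix(sub_b, n_rep = n_boot, seed = seed_b)
        icc_rmse(icc_a, icc_b)
      }, microsync_degenerate_error = function(e) {
        msync_log("subject_drop_curve: draw skipped (", conditionMessage(e), ")")
        NA_real_
      })
      vois <- sort(cohort_a$vois)
      d_reg <- vapply(vois, function(v) {
        cohens_d(sub_a$values[, v], sub_b$values[, v])
      }, numeric(1))
      d_acc <- if (is.null(d_acc)) d_reg else d_acc + d_reg
      rows[[length(rows) + 1L]] <- data.frame(
        n_subjects = n, draw = dr, rmse = rmse,
        seed_a = seed_a, seed_b = seed_b)
    }
    d_by_step[[as.character(n)]] <- d_acc / n_draws
  }
  out <- do.call(rbind, rows)
  mean_rmse <- tapply(out$rmse, out$n_subjects, mean, na.rm = TRUE)
  mean_rmse <- mean_rmse[as.character(steps)]
  full_rmse <- mean_rmse[[1]]
  within <- steps[mean_rmse <= 1.1 * full_rmse]
  summary <- data.frame(n_subjects = steps, mean_rmse = unname(mean_rmse))
  attr(out, "per_region_d") <- d_by_step
  attr(out, "summary") <- summary
  attr(out, "knee_n") <- if (length(within)) min(within) else NA_integer_
  out
}
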