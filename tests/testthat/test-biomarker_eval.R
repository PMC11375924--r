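make_di <- function(vals, subjects, vois) {
  dimnames(vals) <- list(subjects, vois)
  di_table(vals)
}

three_group_manifest <- function(n_per = 5, labels = c("G1", "G2", "G3")) {
  cohort_manifest(sprintf("s%02d", seq_len(3 * n_per)),
                  rep(labels, each = n_per))
}

test_that("identical groups yield a null ANOVA and unchanged statistics under permutation", {
  n <- 5
  block <- matrix(c(1.1, 2.3, 0.7, 1.9, 1.4,
                    0.5, 1.2, 2.2, 1.8, 0.9), n, 2)
  vals <- rbind(block, block, block)  # three identical groups
  di <- make_di(vals, sprintf("s%02d", 1:15), c("vA", "vB"))
  man <- three_group_manifest(n)
  gs <- di_group_stats(di, man, c("G1", "G2", "G3"))
  expect_equal(gs$anova_F, c(0, 0))
  expect_equal(gs$anova_p, c(1, 1))
  expect_false(any(gs$significant))

  # permuting subjects within a group leaves all statistics unchanged
  vals2 <- vals
  vals2[1:5, ] <- vals[c(3, 1, 5, 2, 4), ]
  gs2 <- di_group_stats(make_di(vals2, di$subjects, di$vois), man,
                        c("G1", "G2", "G3"))
  expect_equal(gs2[, -1], gs[, -1])
})

test_that("a three-sd group separation is detected with overwhelming power", {
  n <- 17
  man <- three_group_manifest(n)
  hits <- 0L
  for (rep in 1:20) {
    vals <- with_fixed_seed(3000 + rep, {
      cbind(v1 = c(rnorm(n, 10), rnorm(n, 10), rnorm(n, 13)))
    })
    di <- make_di(vals, sprintf("s%02d", 1:(3 * n)), "v1")
    gs <- di_group_stats(di, man, c("G1", "G2", "G3"))
    hits <- hits + (gs$anova_p < 1e-6)
    expect_true(all(c("t_G1_vs_G2", "p_G2_vs_G3") %in% names(gs)))
  }
  expect_gte(hits, 19L)
})

test_that("zero-variance groups are flagged and skipped", {
  n <- 4
  vals <- cbind(v1 = c(rep(2, n), 1 + (1:n) / 10, 2 + (1:n) / 10))
  di <- make_di(vals, sprintf("s%02d", 1:12), "v1")
  gs <- di_group_stats(di, three_group_manifest(n), c("G1", "G2", "G3"))
  expect_true(gs$degenerate)
  expect_true(is.na(gs$anova_p))
  expect_false(gs$significant)
})

test_that("PC1 of the index is sign-anchored and captures a dominant factor", {
  # two perfectly correlated columns: PC1 explains all variance
  base <- c(1, 3, 2, 5, 4, 6)
  vals <- cbind(vA = base, vB = 2 * base)
  di <- make_di(vals, paste0("s", 1:6), c("vA", "vB"))
  pc <- pc1_of_di(di, c("vA", "vB"))
  expect_equal(pc$var_explained, 1)
  expect_equal(abs(cor(pc$scores, base)), 1)
  expect_gte(cor(pc$scores, rowMeans(vals)), 0)  # sign convention

  # constant column dropped with a warning
  vals2 <- cbind(vals, vC = rep(1, 6))
  di2 <- make_di(vals2, paste0("s", 1:6), c("vA", "vB", "vC"))
  expect_warning(pc2 <- pc1_of_di(di2, c("vA", "vB", "vC")), "vC")
  expect_identical(pc2$vois_used, c("vA", "vB"))

  # dominant latent factor recovery
  sim <- with_fixed_seed(404, {
    latent <- rnorm(46)
    list(latent = latent,
         vals = 5 + outer(latent, rep(0.9, 10)) + matrix(rnorm(460, sd = sqrt(1 - 0.81)), 46, 10))
  })
  di3 <- make_di(pmax(sim$vals, 0), sprintf("s%02d", 1:46), sprintf("v%02d", 1:10))
  pc3 <- pc1_of_di(di3, di3$vois)
  expect_gt(abs(cor(pc3$scores, sim$latent)), 0.95)
})

test_that("cognition correlations report r, fits and BH-adjusted p-values", {
  scores <- stats::setNames(c(30, 28, 26, 24, 22, 20), paste0("s", 1:6))
  # index exactly linear in the score with negative slope
  vals <- cbind(v1 = 10 - 0.25 * scores, v2 = 5 + abs(rnorm(6)))
  di <- make_di(vals, paste0("s", 1:6), c("v1", "v2"))
  res <- correlate_di_cognition(di, scores)
  r1 <- res[res$voi_id == "v1", ]
  expect_equal(r1$r, -1)
  expect_lt(r1$p, 1e-10)
  expect_equal(r1$slope, -0.25)
  expect_equal(r1$intercept, 10)
  expect_true(all(res$p_fdr >= res$p))

  expect_error(correlate_di_cognition(di, stats::setNames(rep(1, 6), paste0("s", 1:6))),
               class = "microsync_degenerate_error")
})

test_that("BH adjustment follows the step-up formula", {
  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.03), "BH"), rep(0.03, 3))
})

test_that("index-vs-SUVR discriminability compares per-region ratio profiles", {
  atlas <- synthetic_mouse_atlas()
  ctx <- atlas$voi_id[atlas$compartment == "cortical"]
  healthy <- synthetic_config(atlas = atlas, n_subjects = 12, seed = 9)
  # region-restricted desynchronization with a uniform (and hence global-mean
  # removed) uptake elevation of 5%
  disease <- synthetic_config(atlas = atlas, n_subjects = 12,
                              baseline_mean = 1.05 *
                                ifelse(grepl("ctx", atlas$voi_id), 1.1, 0.95),
                              desync_regions = ctx,
                              desync_loading_drop = 0.5,
                              desync_noise_inflation = 2.5, seed = 10)
  ref <- generate_cohort(healthy, "REF")
  dis <- generate_cohort(disease, "AD")
  suvr <- global_mean_scale(uptake_table(rbind(ref$uptake$values,
                                               dis$uptake$values)))
  manifest <- rbind(ref$manifest, dis$manifest)

  ref_suvr <- cohort_table(suvr, manifest, "REF")
  di_ref <- loo_reference_di(ref_suvr, n_rep = 200, seed = 3)
  model <- fit_pair_models(ref_suvr, n_rep = 200, seed = 3)
  di_ad <- score_subjects(cohort_table(suvr, manifest, "AD"), model)
  di_all <- rbind_di(di_ref, di_ad)

  rep_ <- di_vs_suvr(di_all, suvr, manifest, "AD", "REF")
  expect_gt(rep_$mean_di_ratio, rep_$mean_suvr_ratio)
  expect_lt(rep_$paired_p, 0.05)
  expect_equal(rep_$cohens_d_diff,
               mean(rep_$per_voi$di_ratio - rep_$per_voi$suvr_ratio) /
                 stats::sd(rep_$per_voi$di_ratio - rep_$per_voi$suvr_ratio),
               tolerance = 1e-12)

  # test cohort identical to the reference: every ratio is exactly 1
  same <- di_vs_suvr(di_all, suvr, manifest, "REF", "REF")
  expect_equal(same$per_voi$suvr_ratio, rep(1, 21))
  expect_equal(same$per_voi$di_ratio, rep(1, 21))
  expect_true(same$degenerate)

  # degenerate (zero-variance) differences report no p
  expect_true(is.na(same$paired_p))
})
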