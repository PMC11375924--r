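test_that("bootstrap resampling is seeded, sized and uniform", {
  idx1 <- bootstrap_resample(14, 50, seed = 9)
  idx2 <- bootstrap_resample(14, 50, seed = 9)
  expect_identical(idx1, idx2)
  expect_equal(dim(idx1), c(50, 14))
  expect_true(all(idx1 >= 1 & idx1 <= 14))
  expect_error(bootstrap_resample(1, 10, 1), class = "microsync_validation_error")
  expect_error(bootstrap_resample(14, 0, 1), class = "microsync_validation_error")

  # closed-form inclusion probability 1 - (1 - 1/n)^n at n = 14
  idx <- bootstrap_resample(14, 10000, seed = 123)
  incl <- sapply(1:14, function(s) mean(apply(idx, 1, function(r) s %in% r)))
  expect_equal(mean(incl), 1 - (1 - 1 / 14)^14, tolerance = 0.01 / 0.645)
})

test_that("Fisher transformation matches arctanh and clips the boundary", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), atanh(0.5))
  expect_equal(fisher_z(0.5), 0.5493, tolerance = 1e-4)
  expect_equal(fisher_z(1), atanh(1 - 1e-7))
  expect_equal(fisher_z(-1), -atanh(1 - 1e-7))
  expect_equal(fisher_z(1), 8.4056, tolerance = 1e-4)  # 0.5*log(2/1e-7)
})

test_that("the ICC matrix is symmetric, masked on the diagonal and seed-stable", {
  tab <- random_table(10, 5, seed = 2)
  icc <- compute_icc_matrix(tab, n_rep = 200, seed = 5)
  expect_identical(icc$z_mean, t(icc$z_mean))
  expect_identical(icc$p_values, t(icc$p_values))
  expect_true(all(is.na(diag(icc$z_mean))))
  icc2 <- compute_icc_matrix(tab, n_rep = 200, seed = 5)
  expect_identical(icc$z_mean, icc2$z_mean)
})

test_that("perfect collinearity drives ICC to the clip bound with p ~ 0", {
  x <- c(1, 2, 3, 4.5, 6, 8)
  vals <- cbind(A = x, B = 2 * x)
  rownames(vals) <- paste0("s", 1:6)
  icc <- compute_icc_matrix(uptake_table(vals), n_rep = 50, seed = 1)
  expect_equal(icc$z_mean["A", "B"], atanh(1 - 1e-7))
  expect_lt(icc$p_values["A", "B"], 1e-12)
})

test_that("single-replicate identity resampling reproduces plain Pearson", {
  tab <- random_table(14, 21, seed = 31)
  icc <- compute_icc_matrix(tab, n_rep = 1, identity_resample = TRUE)
  expected <- fisher_z(stats::cor(tab$values))
  diag(expected) <- NA_real_
  expect_equal(icc$z_mean, expected, tolerance = 1e-12)
  # p-values equal the two-sided Pearson test on the original cohort
  ct <- stats::cor.test(tab$values[, 1], tab$values[, 3])
  expect_equal(icc$p_values[1, 3], ct$p.value, tolerance = 1e-12)
})

test_that("independent regions give near-zero mean Fisher Z at large n", {
  vals <- with_fixed_seed(77, matrix(10 + rnorm(200), 100, 2))
  dimnames(vals) <- list(paste0("s", 1:100), c("A", "B"))
  icc <- compute_icc_matrix(uptake_table(vals), n_rep = 1000, seed = 4)
  expect_lt(abs(icc$z_mean["A", "B"]), 0.1)  # SE ~ 1/sqrt(n-3) ~ 0.1
})

test_that("connection thresholding applies the joint magnitude and p rule", {
  atlas <- atlas_metadata(c("A", "B"), c("cortical", "subcortical"))
  one <- function(z, p) significant_connections(
    manual_icc(c("A", "B"), z, p), atlas, 0.5, 0.005)

  expect_equal(one(0.6, 0.001)$total, 1)
  expect_equal(one(0.6, 0.01)$total, 0)   # p fails
  expect_equal(one(0.4, 0.001)$total, 0)  # |z| fails
  neg <- one(-0.55, 1e-4)                 # negative correlations count
  expect_equal(neg$total, 1)
  expect_identical(neg$edges$class, "cortical-subcortical")

  bad_atlas <- atlas_metadata("A", "cortical")
  expect_error(significant_connections(manual_icc(c("A", "B"), 0.6, 0.001),
                                       bad_atlas),
               class = "microsync_validation_error")
})

test_that("connection classes partition the edges and sum to the total", {
  atlas <- tiny_atlas()  # A,B cortical; C subcortical
  icc <- manual_icc(c("A", "B", "C"), c(0.9, 0.8, -0.7), c(1e-5, 1e-5, 1e-5))
  cs <- significant_connections(icc, atlas, 0.5, 0.005)
  expect_equal(cs$total, 3)
  expect_equal(sum(cs$class_counts), cs$total)
  expect_equal(unname(cs$class_counts[c("cortical", "cortical-subcortical")]),
               c(1L, 2L))
  # canonical ordering: voi_i < voi_j lexicographically, each pair once
  expect_true(all(cs$edges$voi_i < cs$edges$voi_j))
  expect_false(anyDuplicated(paste(cs$edges$voi_i, cs$edges$voi_j)) > 0)
})

test_that("connection ratios divide cohort counts by reference counts", {
  expect_equal(connection_ratio(0, 10), 0)
  expect_equal(connection_ratio(7, 14), 0.5)
  expect_error(connection_ratio(5, 0), class = "microsync_degenerate_error")
})

test_that("absolute-ICC summaries report quartiles over unordered pairs", {
  icc <- manual_icc(c("A", "B", "C"), c(0.2, -0.5, 0.7), c(0.5, 0.5, 0.5))
  s <- median_abs_icc(icc)
  expect_equal(s$q2, 0.5)
  expect_equal(s$n_pairs, 3)
  expect_true(s$q1 <= s$q2 && s$q2 <= s$q3)

  flat <- manual_icc(c("A", "B", "C"), rep(-0.3, 3), rep(0.5, 3))
  sf <- median_abs_icc(flat)
  expect_equal(c(sf$q1, sf$q2, sf$q3), rep(0.3, 3))

  tab <- random_table(14, 21, seed = 8)
  icc21 <- compute_icc_matrix(tab, n_rep = 20, seed = 1)
  expect_equal(median_abs_icc(icc21)$n_pairs, 21 * 20 / 2)
})

test_that("paired Wilcoxon comparison of |ICC| detects a uniform reduction", {
  tab <- random_table(14, 21, seed = 12)
  icc_a <- compute_icc_matrix(tab, n_rep = 100, seed = 3)

  same <- compare_icc_distributions(icc_a, icc_a)
  expect_true(same$all_equal)
  expect_equal(same$p_value, 1)

  icc_b <- icc_a
  icc_b$z_mean <- sign(icc_a$z_mean) * pmax(abs(icc_a$z_mean) - 0.2, 0)
  res <- compare_icc_distributions(icc_a, icc_b)
  expect_lt(res$p_value, 0.001)
  expect_gt(res$summary_a$q2, res$summary_b$q2)

  # invariant to VOI ordering
  perm <- sample(21)
  icc_p <- icc_b
  icc_p$vois <- icc_b$vois[perm]
  icc_p$z_mean <- icc_b$z_mean[perm, perm]
  icc_p$p_values <- icc_b$p_values[perm, perm]
  res2 <- compare_icc_distributions(icc_a, icc_p)
  expect_equal(res2$p_value, res$p_value)
  expect_equal(res2$statistic, res$statistic)

  icc_c <- compute_icc_matrix(random_table(10, 4, seed = 1), n_rep = 10, seed = 1)
  expect_error(compare_icc_distributions(icc_a, icc_c),
               class = "microsync_validation_error")
})
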