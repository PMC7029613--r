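test_that("spearman handles monotone, reversed, tied and constant input", {
  expect_equal(spearman(c(1, 2, 3), c(10, 20, 30)), 1)
  expect_equal(spearman(c(1, 2, 3), c(3, 2, 1)), -1)
  expect_true(is.na(spearman(c(1, 1, 1), c(1, 2, 3))))
  expect_error(spearman(1:2, 2:3), "3")

  ## ties: brute-force average-rank-then-Pearson oracle
  x <- c(1, 1, 2, 3); y <- c(4, 5, 6, 7)
  expect_equal(spearman(x, y), spearman_oracle(x, y))
  set.seed(4)
  for (i in 1:10) {
    a <- sample(1:4, 12, replace = TRUE)
    b <- sample(1:5, 12, replace = TRUE)
    if (sd(a) == 0 || sd(b) == 0) next
    expect_equal(spearman(a, b), spearman_oracle(a, b))
  }
})

test_that("spearman p-values are calibrated in both regimes", {
  ## exact enumeration regime (n < 10) agrees with cor.test where ties absent
  set.seed(1)
  x <- rnorm(7); y <- rnorm(7)
  ours <- spearman_test(x, y)
  ref <- suppressWarnings(cor.test(x, y, method = "spearman", exact = TRUE))
  expect_equal(ours$rho, unname(ref$estimate))
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)

  ## t-approximation regime is monotone in |rho| and in [0, 1]
  big <- spearman_test(1:20, c(2, 1, 4, 3, 6, 5, 8, 7, 10, 9,
                               12, 11, 14, 13, 16, 15, 18, 17, 20, 19))
  expect_lt(big$p_value, 0.001)
  expect_true(is.na(spearman_test(rep(1, 12), rnorm(12))$p_value))
})

test_that("sample and feature correlations recover identity and rank invariance", {
  set.seed(12)
  obs <- random_table(20, 8, seed = 12, role = "functional")
  self_s <- sample_correlations(obs, obs)
  expect_equal(unname(self_s), rep(1, 8))
  self_f <- feature_correlations(obs, obs)
  expect_equal(unname(self_f), rep(1, 20))

  mono <- feature_table(exp(obs$values / max(obs$values)), role = "functional")
  expect_equal(unname(sample_correlations(mono, obs)), rep(1, 8))
  expect_equal(unname(feature_correlations(mono, obs)), rep(1, 20))

  partial <- feature_table(obs$values[1:5, 1:4], role = "functional")
  expect_length(sample_correlations(partial, obs), 4)
  expect_length(feature_correlations(partial, obs), 5)
  expect_error(sample_correlations(feature_table(obs$values[1:2, ],
                                                 role = "functional"), obs),
               "3")
})

test_that("correlations against independent noise stay near zero", {
  rhos <- vapply(1:50, function(s) {
    inferred <- random_table(200, 6, seed = s, role = "functional")
    observed <- random_table(200, 6, seed = s + 1000, role = "functional")
    mean(abs(sample_correlations(inferred, observed)))
  }, numeric(1))
  expect_lte(mean(rhos), 0.15)
})

test_that("bootstrap splits partition the samples and the result is reproducible", {
  d <- simulate_paired(n_taxa = 40, n_functions = 12, n_samples = 12,
                       depth = 2000, seed = 30)
  cfg <- validation_config(0.5, n_iterations = 2, seed = 99)
  v <- bootstrap_validate(d$functional_true, d$taxa_counts, d$taxa_counts,
                          d$functional_true, cfg)
  ## per iteration, exactly the query half carries correlations
  n_obs <- rowSums(!is.na(v$per_iteration_sample_rho))
  expect_equal(unname(n_obs), c(6, 6))
  expect_true(all(v$per_iteration_feature_rho >= -1 &
                    v$per_iteration_feature_rho <= 1, na.rm = TRUE))

  v2 <- bootstrap_validate(d$functional_true, d$taxa_counts, d$taxa_counts,
                           d$functional_true, cfg)
  expect_identical(v$per_iteration_feature_rho, v2$per_iteration_feature_rho)
  expect_identical(v$per_iteration_sample_rho, v2$per_iteration_sample_rho)

  expect_error(bootstrap_validate(d$functional_true, d$taxa_counts,
                                  d$taxa_counts, d$functional_true,
                                  validation_config(0.9, 1)),
               "< 3")
})

test_that("coverage binning applies fixed and quantile conventions", {
  cov <- ft(matrix(c(0.005, 0.05, 0.5), 3, 1,
                   dimnames = list(c("a", "b", "c"), "mean")),
            role = "coverage")
  bins <- bin_by_coverage(cov, "fixed", low_cut = 0.01, high_cut = 0.1)
  expect_equal(as.character(bins$assignment), c("low", "medium", "high"))
  expect_equal(unname(unclass(bins$counts)), c(1, 1, 1), ignore_attr = TRUE)

  ## degenerate distribution: one bin under the quantile scheme
  same <- ft(matrix(0.4, 5, 2), role = "coverage")
  b2 <- bin_by_coverage(same, "quantile")
  expect_equal(length(unique(as.character(b2$assignment))), 1)

  ## uniform means split approximately 25/25/50 at the default quantiles
  set.seed(8)
  u <- ft(matrix(runif(1000), 1000, 1), role = "coverage")
  b3 <- bin_by_coverage(u, "quantile", q_low = 0.25, q_high = 0.5)
  expect_lt(abs(b3$counts[["low"]] - 250), 4 * sqrt(1000 * 0.25 * 0.75))
  expect_lt(abs(b3$counts[["medium"]] - 250), 4 * sqrt(1000 * 0.25 * 0.75))
  expect_lt(abs(b3$counts[["high"]] - 500), 4 * sqrt(1000 * 0.25))

  expect_error(bin_by_coverage(ft(matrix(1.2, 1, 1), role = "coverage")),
               "\\[0, 1\\]")
  expect_error(bin_by_coverage(cov, "fixed", low_cut = 0.5, high_cut = 0.1),
               "low_cut")
})

test_that("metabolite association finds self-pairs and adjusts by BH step-up", {
  set.seed(40)
  fv <- random_table(5, 12, seed = 40, role = "functional")
  mv <- feature_table(fv$values[1:2, , drop = FALSE] * 3 + 1,
                      feature_ids = c("m1", "m2"),
                      sample_ids = fv$sample_ids, role = "metabolite")
  res <- associate_with_metadata(fv, mv)
  self <- res[res$function_id == "f01" & res$metabolite_id == "m1", ]
  expect_equal(self$rho, 1)
  expect_equal(self$direction, 1)
  expect_true(all(res$p_adjusted >= res$p_value - 1e-15))

  ## adjusted p-values match an independent BH step-up of the raw ones
  expect_equal(res$p_adjusted, bh_oracle(res$p_value), tolerance = 1e-12)
  ## the spec'd worked example of the step-up
  expect_equal(bh_oracle(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  ## BH monotonicity
  o <- order(res$p_value)
  expect_true(all(diff(res$p_adjusted[o]) >= -1e-15))
})

test_that("association null keeps the false discovery fraction near alpha", {
  fracs <- vapply(1:50, function(s) {
    fv <- random_table(20, 10, seed = 5000 + s, role = "functional")
    set.seed(9000 + s)
    mv <- feature_table(abs(matrix(rnorm(10 * 10), 10, 10)),
                        feature_ids = sprintf("m%d", 1:10),
                        sample_ids = fv$sample_ids, role = "metabolite")
    res <- associate_with_metadata(fv, mv, alpha = 0.05)
    mean(res$significant)
  }, numeric(1))
  expect_lte(mean(fracs), 0.05)
})
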