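test_that("z-scoring centres, scales and is shift-invariant", {
  expect_equal(zscore(c(1, 2, 3)), c(-1, 0, 1))
  x <- rlnorm(100, 2, 0.7)
  z <- zscore(x)
  expect_lt(abs(mean(z)), 1e-12)
  expect_equal(sd(z), 1)
  expect_equal(zscore(x + 77), z)
  expect_error(zscore(rep(4, 10)), "variance")
  expect_error(zscore(3), "at least 2")
})

test_that("EDSS change classification follows the clinical rules", {
  expect_equal(classify_edss_change(3.0, 4.0), "worsening")
  expect_equal(classify_edss_change(5.5, 6.0), "worsening")
  expect_equal(classify_edss_change(2.0, 2.5), "stable")
  expect_equal(classify_edss_change(2.0, 2.0), "stable")
  expect_equal(classify_edss_change(4.0, 3.0), "improving")
  expect_equal(classify_edss_change(6.0, 5.5), "improving")
  # rule gap at high baseline with no change
  expect_equal(classify_edss_change(6.0, 6.0), "unclassified")
  expect_error(classify_edss_change(3.25, 4), "half-point")
  expect_error(classify_edss_change(3, 11), "half-point")
  # vectorised
  expect_equal(classify_edss_change(c(1, 6), c(2.5, 6)),
               c("worsening", "unclassified"))
})

test_that("the NfL outlier rule is one-sided, single-pass and exact", {
  expect_length(remove_nfl_outliers(rep(5, 10))$removed, 0L)
  # a symmetric low outlier is kept
  x <- c(rep(10, 20), 0.01)
  expect_length(remove_nfl_outliers(x)$removed, 0L)
  # injected extremes are exactly the removals
  set.seed(4)
  base <- rlnorm(96, 2, 0.4)
  vals <- c(base, rep(max(base) * 20, 4))
  out <- remove_nfl_outliers(vals)
  expect_equal(out$removed, 97:100)
  expect_equal(out$threshold, mean(vals) + 3 * sd(vals))
  # single pass: re-running on the kept set may remove more (known
  # non-property of the one-pass rule)
  expect_true(length(remove_nfl_outliers(out$kept)$removed) >= 0L)
})

test_that("GD-T2LV association recovers exact linear and quadratic structure", {
  t2 <- seq(0.5, 40, length.out = 50)
  rec_lin <- data.frame(gd = 0.1 + 0.01 * t2, t2lv = t2)
  expect_equal(gd_t2lv_association(rec_lin)$r, 1)
  rec_quad <- data.frame(gd = 0.05 + 0.02 * t2 - 2e-4 * t2^2, t2lv = t2)
  fit <- gd_t2lv_association(rec_quad)
  expect_equal(fit$coef, c(0.05, 0.02, -2e-4), tolerance = 1e-8)
  # independence: correlation near zero
  set.seed(10)
  rec_null <- data.frame(gd = rnorm(1000), t2lv = rlnorm(1000, 2, 0.5))
  expect_lt(abs(gd_t2lv_association(rec_null)$r), 0.1)
  expect_error(gd_t2lv_association(data.frame(gd = rep(1, 5),
                                              t2lv = 1:5)), "variance")
})

test_that("the synthetic cohort produces a strong curved GD-T2LV association", {
  sim <- generate_cohort(cohort_sim_config(n_subjects = 300L, seed = 17L))
  base <- sim$cohort[sim$cohort$timepoint == "baseline", ]
  a <- gd_t2lv_association(base)
  expect_gt(a$r, 0.5)
  # the quadratic term is genuinely nonzero for the lognormal volume scale
  expect_gt(abs(a$coef[3]) * stats::sd(base$t2lv)^2, 1e-4)
})

test_that("cross-sectional OLS matches the normal-equations oracle and recovers planted effects", {
  set.seed(23)
  sim <- generate_cohort(cohort_sim_config(n_subjects = 120L, seed = 23L))
  base <- sim$cohort[sim$cohort$timepoint == "baseline", ]
  res <- fit_cross_sectional(base, "gd")
  X <- model.matrix(res$fit)
  y <- model.response(model.frame(res$fit))
  expect_equal(res$table$estimate, drop(ols_oracle(X, y)),
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_true(all(c("snfl_z", "treatmenteffective", "centerOslo") %in%
                    res$table$term))
  # planted noiseless linear data: exact recovery
  base2 <- base
  base2$gd <- 2 + 0.5 * zscore(base2$snfl) - 0.25 * zscore(base2$age)
  res2 <- suppressWarnings(fit_cross_sectional(base2, "gd",
                                               scale_response = FALSE))
  expect_equal(res2$table$estimate[res2$table$term == "snfl_z"], 0.5,
               tolerance = 1e-8)
  expect_equal(res2$table$estimate[res2$table$term == "age_z"], -0.25,
               tolerance = 1e-8)
  # rank deficiency is reported with the aliased column
  base3 <- base
  base3$disease_duration <- base3$age
  expect_error(fit_cross_sectional(base3, "gd"), "aliased")
})

test_that("cross-sectional type-I error is near nominal on null data", {
  set.seed(41)
  pvals <- replicate(150, {
    sim <- generate_cohort(cohort_sim_config(n_subjects = 60L,
                                             beta_nfl_gd = 0,
                                             beta_time = 0,
                                             beta_interaction = 0,
                                             center_shifts = rep(0, 4),
                                             subject_sd = 0, noise_sd = 1,
                                             seed = sample.int(1e6, 1)))
    base <- sim$cohort[sim$cohort$timepoint == "baseline", ]
    res <- fit_cross_sectional(base, "gd")
    res$table$p[res$table$term == "snfl_z"]
  })
  # exact binomial 99% band around 0.05 with 150 replicates
  expect_gte(sum(pvals < 0.05), qbinom(0.005, 150, 0.05))
  expect_lte(sum(pvals < 0.05), qbinom(0.995, 150, 0.05))
})
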