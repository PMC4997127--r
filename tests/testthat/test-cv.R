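test_that("metrics recompute exactly from confusion counts", {
  m <- compute_metrics(list(TP = 46, FN = 6, TN = 44, FP = 8))
  expect_equal(m$accuracy, 100 * 90 / 104)
  expect_equal(round(m$accuracy, 2), 86.54)
  expect_equal(round(m$sensitivity, 2), 88.46)
  expect_equal(round(m$specificity, 2), 84.62)
  perfect <- compute_metrics(list(TP = 52, TN = 52, FP = 0, FN = 0))
  expect_equal(c(perfect$accuracy, perfect$sensitivity, perfect$specificity),
               c(100, 100, 100))
  # all predicted H with a 52/52 split
  allh <- compute_metrics(list(TP = 0, FN = 52, TN = 52, FP = 0))
  expect_equal(c(allh$accuracy, allh$sensitivity, allh$specificity),
               c(50, 0, 100))
  # an empty class flags the undefined metric instead of reporting 0
  und <- compute_metrics(list(TP = 0, FN = 0, TN = 3, FP = 1))
  expect_true(is.na(und$sensitivity))
  expect_false(is.na(und$specificity))
})

test_that("McNemar comparison matches closed-form and exact oracles", {
  truth <- rep(c("H", "D"), each = 20)
  # identical predictions: zero discordance, p = 1
  run_a <- make_run(truth, truth)
  expect_equal(mcnemar_compare(run_a, run_a)$p_value, 1)
  # b = 10, c = 2, chi-squared branch forced:
  # (|10-2|-1)^2/12 = 49/12 ~ 4.083, p ~ 0.0433
  pred_a <- truth; pred_b <- truth
  pred_b[1:10] <- ifelse(truth[1:10] == "H", "D", "H")  # a correct, b wrong
  pred_a[11:12] <- ifelse(truth[11:12] == "H", "D", "H")  # a wrong, b correct
  res <- mcnemar_compare(make_run(truth, pred_a), make_run(truth, pred_b),
                         method = "chisq")
  expect_equal(res$b, 10); expect_equal(res$c, 2)
  expect_equal(res$statistic, 49 / 12, tolerance = 1e-12)
  expect_equal(res$p_value, pchisq(49 / 12, 1, lower.tail = FALSE))
  expect_equal(round(res$statistic, 3), 4.083)
  expect_equal(round(res$p_value, 4), 0.0433)
  # b = 5, c = 0: exact two-sided binomial p = 2 * (1/2)^5 = 0.0625
  pred_b2 <- truth; pred_b2[1:5] <- ifelse(truth[1:5] == "H", "D", "H")
  res2 <- mcnemar_compare(make_run(truth, truth), make_run(truth, pred_b2))
  expect_equal(res2$method, "exact")
  expect_equal(res2$p_value, 0.0625)
  # mismatched subjects rejected
  expect_error(mcnemar_compare(make_run(truth, truth),
                               make_run(rev(truth), rev(truth))),
               "identical subjects")
})

test_that("one-sided binomial test against chance matches the tail oracle", {
  truth <- rep(c("H", "D"), each = 20)
  all_right <- make_run(truth, truth)
  expect_equal(binomial_vs_chance(all_right)$p_value, 0.5^40)
  # 20/40 correct
  pred <- truth; pred[1:20] <- ifelse(truth[1:20] == "H", "D", "H")
  half <- make_run(truth, pred)
  expect_equal(binomial_vs_chance(half)$p_value,
               sum(dbinom(20:40, 40, 0.5)), tolerance = 1e-12)
  # 0/40 correct: tail from below, p ~ 1
  wrong <- make_run(truth, ifelse(truth == "H", "D", "H"))
  expect_equal(binomial_vs_chance(wrong)$p_value, 1, tolerance = 1e-12)
})

test_that("folds partition the subjects and counts are consistent", {
  g <- generate_cohort(synthetic_spec(
    box_geometry(c(4, 4, 4)), n_per_class = c(6, 6),
    clusters = list(list(center = c(2, 2, 2), radius = 1, delta = 4)),
    smoothing_fwhm = 0, seed = 8))
  run <- loocv_rc(g$cohort, reducer_ttest(0.05), classifier_lda(), seed = 3)
  expect_equal(sort(run$folds$subject), 1:12)
  cc <- run$confusion
  expect_equal(sum(cc), 12)
  expect_equal(cc[["TP"]] + cc[["FN"]], 6)
  expect_equal(cc[["TN"]] + cc[["FP"]], 6)
  # metrics from stored counts equal re-derivation from fold records
  m <- compute_metrics(run)
  expect_equal(m$accuracy, 100 * mean(run$folds$correct))
  # selection counts bounded by the number of folds
  expect_true(all(run$selection_counts >= 0 & run$selection_counts <= 12))
})

test_that("a perfectly separable cohort classifies perfectly in both designs", {
  g <- generate_cohort(synthetic_spec(
    box_geometry(c(5, 5, 5)), n_per_class = c(8, 8),
    clusters = list(list(center = c(3, 3, 3), radius = 1.5, delta = 8)),
    smoothing_fwhm = 0, seed = 14))
  for (design_fun in list(loocv_c, loocv_rc)) {
    run <- design_fun(g$cohort, reducer_ttest(0.01), classifier_lda(), seed = 5)
    expect_equal(compute_metrics(run)$accuracy, 100)
  }
})

test_that("designs coincide for the identity reduction", {
  coh <- generate_null_cohort(box_geometry(c(4, 4, 4)), c(6, 6),
                              smoothing_fwhm = 0, seed = 19)
  rc <- loocv_c(coh, reducer_none(), classifier_lda(), seed = 7)
  rrc <- loocv_rc(coh, reducer_none(), classifier_lda(), seed = 7)
  expect_equal(rc$folds$predicted, rrc$folds$predicted)
  expect_equal(rc$confusion, rrc$confusion)
  # design c marks every selected feature in all n folds
  expect_equal(unname(rc$selection_counts), rep(12, 64))
})

test_that("runs are deterministic in the root seed", {
  g <- generate_cohort(synthetic_spec(
    box_geometry(c(4, 4, 4)), n_per_class = c(6, 6),
    clusters = list(list(center = c(2, 2, 2), radius = 1, delta = 2)),
    smoothing_fwhm = 0, seed = 23))
  a <- loocv_rc(g$cohort, reducer_plda(lambda = 1, K = 8), classifier_lda(),
                seed = 11)
  b <- loocv_rc(g$cohort, reducer_plda(lambda = 1, K = 8), classifier_lda(),
                seed = 11)
  expect_identical(a$folds, b$folds)
  expect_identical(a$selection_counts, b$selection_counts)
  expect_identical(a$mean_weights, b$mean_weights)
})

test_that("empty selections fall back with a message or error on request", {
  coh <- generate_null_cohort(box_geometry(c(4, 4, 4)), c(6, 6),
                              smoothing_fwhm = 0, seed = 29)
  # absurdly strict threshold: no feature survives, fallback must engage
  expect_message(
    run <- loocv_c(coh, reducer_ttest(1e-12), classifier_lda(), seed = 2),
    "falling back")
  expect_gte(min(run$folds$n_selected), 1)
  expect_error(
    loocv_c(coh, reducer_ttest(1e-12, on_empty = "error"), classifier_lda(),
            seed = 2),
    "no features")
})
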