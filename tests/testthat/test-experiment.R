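test_that("an experiment covers the Cartesian grid of cells", {
  g <- generate_cohort(synthetic_spec(
    box_geometry(c(4, 4, 4)), n_per_class = c(6, 6),
    clusters = list(list(center = c(2, 2, 2), radius = 1, delta = 3)),
    smoothing_fwhm = 0, seed = 2))
  cfg <- experiment_config(
    g$cohort,
    reducers = list(reducer_plda(lambda = c(0.5, 1, 2), K = 5L)),
    classifiers = list(classifier_lda(), classifier_svm()),
    designs = c("c", "rc"), seed = 4)
  res <- run_experiment(cfg)
  expect_equal(nrow(res$summary), 3 * 2 * 2)
  expect_setequal(unique(res$summary$lambda), c(0.5, 1, 2))
  expect_true(all(is.na(res$summary$error)))
})

test_that("reruns with the same config and seed are identical, including on disk", {
  coh <- generate_null_cohort(box_geometry(c(4, 4, 4)), c(6, 6),
                              smoothing_fwhm = 0, seed = 31)
  make_cfg <- function(dir) experiment_config(
    coh,
    reducers = list(reducer_ttest(0.05), reducer_plda(lambda = 1, K = 5L)),
    classifiers = list(classifier_lda()),
    designs = c("c", "rc"), seed = 99, output_dir = dir)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  r1 <- suppressMessages(run_experiment(make_cfg(d1)))
  r2 <- suppressMessages(run_experiment(make_cfg(d2)))
  expect_identical(r1$summary, r2$summary)
  expect_identical(r1$manifest$config_hash, r2$manifest$config_hash)
  expect_identical(readBin(file.path(d1, "summary.csv"), "raw", 1e6),
                   readBin(file.path(d2, "summary.csv"), "raw", 1e6))
  expect_true(file.exists(file.path(d1, "manifest.json")))
  expect_true(file.exists(file.path(d1, "report.json")))
})

test_that("a non-convergent lambda is flagged while the sweep completes", {
  g <- generate_cohort(synthetic_spec(
    box_geometry(c(4, 4, 4)), n_per_class = c(6, 6),
    clusters = list(list(center = c(2, 2, 2), radius = 1, delta = 3)),
    smoothing_fwhm = 0, seed = 2))
  lam_hi <- plda_lambda_max(g$cohort) * 5
  cfg <- experiment_config(
    g$cohort,
    reducers = list(reducer_plda(lambda = c(0.5, lam_hi), K = 5L)),
    classifiers = list(classifier_lda()), designs = "c", seed = 1)
  res <- suppressMessages(run_experiment(cfg))
  expect_equal(nrow(res$summary), 2)
  # the huge lambda collapses every subsample fit to zero; the fallback kicks
  # in and the cell still reports a result
  expect_true(all(!is.na(res$summary$accuracy) | !is.na(res$summary$error)))
})

test_that("invalid configurations fail before any computation", {
  coh <- generate_null_cohort(box_geometry(c(3, 3, 3)), c(5, 5),
                              smoothing_fwhm = 0, seed = 1)
  expect_error(experiment_config(coh, list(reducer_plda(c(2, 1))),
                                 list(classifier_lda())),
               "strictly increasing")
  expect_error(experiment_config(coh, list(reducer_ttest()), list(),
                                 designs = "z"),
               "designs")
})

test_that("NIfTI maps round-trip through write_map and readNifti", {
  geom <- ellipsoid_geometry(dims = c(8, 8, 8))
  set.seed(5)
  vals <- rnorm(geom$p)
  path <- withr::local_tempfile(fileext = ".nii.gz")
  write_map(vals, geom, path)
  back <- RNifti::readNifti(path)
  arr <- array(as.numeric(back), dim = dim(back))
  expect_equal(drop(volumes_to_matrix(arr, geom)), vals, tolerance = 1e-12)
  # out-of-mask voxels carry the background value
  expect_true(all(arr[!geom$mask] == 0))
  # integer-valued selection counts stay integers
  path2 <- withr::local_tempfile(fileext = ".nii.gz")
  write_map(sample(0:12, geom$p, replace = TRUE), geom, path2)
  arr2 <- array(as.numeric(RNifti::readNifti(path2)), dim = geom$dims)
  expect_equal(arr2, round(arr2))
})

test_that("cohorts round-trip through NIfTI volumes and a labels CSV", {
  g <- generate_cohort(synthetic_spec(
    ellipsoid_geometry(dims = c(7, 7, 7)), n_per_class = c(3, 3),
    smoothing_fwhm = 0, seed = 3))
  dir <- withr::local_tempdir()
  write_cohort(g$cohort, dir)
  rc <- read_cohort(dir, file.path(dir, "labels.csv"),
                    file.path(dir, "mask.nii.gz"))
  expect_equal(rc$cohort$X, g$cohort$X, tolerance = 1e-12)
  expect_equal(rc$cohort$labels, g$cohort$labels)
  expect_equal(rc$geometry$coords, g$cohort$geometry$coords)
  # unknown label values are rejected with the offending row
  bad <- data.frame(subject_id = g$cohort$subject_ids,
                    label = c("H", "X", "D", "D", "H", "D"))
  badcsv <- withr::local_tempfile(fileext = ".csv")
  write.csv(bad, badcsv, row.names = FALSE)
  expect_error(read_cohort(dir, badcsv, file.path(dir, "mask.nii.gz")),
               "row 2")
})

test_that("tidiers and plots expose results in tabular and graphical form", {
  g <- generate_cohort(synthetic_spec(
    box_geometry(c(4, 4, 4)), n_per_class = c(6, 6),
    clusters = list(list(center = c(2, 2, 2), radius = 1, delta = 3)),
    smoothing_fwhm = 0, seed = 2))
  fit <- plda_fit(g$cohort, 1)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 64)
  expect_equal(sum(td$active), length(fit$active_set))
  gl <- glance(fit)
  expect_equal(gl$n_active, length(fit$active_set))
  prof <- run_stability(g$cohort, 1, K = 5, seed = 1)
  expect_s3_class(autoplot(prof), "ggplot")
  run <- loocv_rc(g$cohort, reducer_ttest(0.05), classifier_lda(), seed = 2)
  expect_s3_class(tidy(run), "tbl_df")
  expect_equal(glance(run)$accuracy, compute_metrics(run)$accuracy)
  expect_s3_class(plot_map_slice(run$selection_counts, g$cohort$geometry),
                  "ggplot")
})
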