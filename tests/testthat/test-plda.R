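test_that("class statistics match hand arithmetic (sum-of-squares form)", {
  st <- compute_class_stats(toy_cohort())
  expect_equal(st$m_H, c(1, 0))
  expect_equal(st$m_D, c(5, 2))
  expect_equal(st$d, c(-4, -2))
  expect_equal(st$s2, c(4, 2))
  # single feature, H = {0,2}, D = {10,12}
  st1 <- compute_class_stats(
    feature_cohort(matrix(c(0, 2, 10, 12), ncol = 1), c("H", "H", "D", "D")))
  expect_equal(st1$d, -10)
  expect_equal(st1$s2, 4)
  # identical classes give a zero difference vector
  X <- rbind(c(1, 2), c(3, 4), c(1, 2), c(3, 4))
  st2 <- compute_class_stats(feature_cohort(X, c("H", "H", "D", "D")))
  expect_equal(st2$d, c(0, 0))
  one_H <- feature_cohort(rbind(c(1, 2), c(3, 4), c(1, 2), c(3, 4)),
                          c("H", "D", "D", "D"))
  expect_error(compute_class_stats(one_H), "at least 2")
})

test_that("penalized objective follows the rank-1 identity and hand example", {
  st <- make_stats(d = c(-4, -2), s2 = c(4, 2))
  expect_equal(penalized_objective(c(0, 0), st, 5), 0)
  expect_equal(penalized_objective(c(-0.5, 0), st, 1), 3)
  v <- c(0.3, -0.2)
  expect_equal(penalized_objective(v, st, 0), drop(crossprod(st$d, v))^2)
})

test_that("the unpenalized direction is the closed-form constrained maximizer", {
  # p = 1: magnitude forced by the constraint, sign by d.v >= 0
  st1 <- make_stats(d = 3, s2 = 4)
  expect_equal(unpenalized_direction(st1)$v, 1 / 2)
  # zero mean-difference coordinate gets exactly zero loading
  st2 <- make_stats(d = c(3, 0), s2 = c(4, 5))
  v2 <- unpenalized_direction(st2)$v
  expect_equal(v2[2], 0)
  expect_gte(sum(st2$d * v2), 0)
  # Monte-Carlo maximality on a random p = 4 instance
  set.seed(42)
  st4 <- make_stats(d = rnorm(4), s2 = runif(4, 0.5, 2))
  v4 <- unpenalized_direction(st4)$v
  expect_equal(sum(st4$s2 * v4^2), 1, tolerance = 1e-10)
  obj <- penalized_objective(v4, st4, 0)
  rand <- matrix(rnorm(4 * 1e4), ncol = 4)
  rand <- rand / sqrt(rowSums(sweep(rand^2, 2, st4$s2, "*")))
  rand_obj <- (rand %*% st4$d)^2
  expect_gte(obj, max(rand_obj))
  expect_error(unpenalized_direction(make_stats(c(1, 1), c(1, 0))), "constant")
})

test_that("one MM step reproduces the hand soft-threshold example and fixed points", {
  st <- make_stats(d = c(2, 1), s2 = c(1, 1))
  v_new <- mm_step(c(1, 0), st, lambda = 2)
  expect_equal(v_new, c(6, 2) / sqrt(40))
  # lambda = 0: the unpenalized direction is a fixed point
  v0 <- unpenalized_direction(st)$v
  expect_equal(mm_step(v0, st, 0), v0, tolerance = 1e-12)
  # lambda large enough that |b_j| <= lambda s_j for all j: zero vector
  b <- 2 * st$d * sum(st$d * c(1, 0))
  lam_big <- max(abs(b) / st$s) + 1
  expect_equal(mm_step(c(1, 0), st, lam_big), c(0, 0))
  # exact tie at the threshold zeroes the coefficient
  st1 <- make_stats(d = 1, s2 = 1)
  v0 <- unpenalized_direction(st1)$v
  expect_equal(mm_step(v0, st1, lambda = abs(2 * st1$d * sum(st1$d * v0))), 0)
})

test_that("plda_fit converges, respects the constraint, and zeroes out at lambda_max", {
  g <- generate_cohort(synthetic_spec(
    box_geometry(c(4, 4, 4)), n_per_class = c(8, 8),
    clusters = list(list(center = c(2, 2, 2), radius = 1, delta = 3)),
    smoothing_fwhm = 0, seed = 5))
  coh <- g$cohort
  # lambda = 0 converges almost immediately to the closed form
  f0 <- plda_fit(coh, 0)
  expect_lte(f0$n_iter, 2)
  expect_true(f0$converged)
  st <- compute_class_stats(coh)
  expect_equal(f0$v, unpenalized_direction(st)$v, tolerance = 1e-10)
  # constraint holds at any lambda with a nonzero solution
  f1 <- plda_fit(coh, 1)
  if (length(f1$active_set) > 0)
    expect_equal(sum(st$s2 * f1$v^2), 1, tolerance = 1e-8)
  expect_equal(f1$active_set, which(f1$v != 0))
  expect_gte(sum(st$d * f1$v), 0)
  # lambda >= lambda_max collapses to the zero vector with empty active set
  fmax <- plda_fit(coh, plda_lambda_max(coh) * 1.0001)
  expect_equal(fmax$v, rep(0, ncol(coh$X)))
  expect_length(fmax$active_set, 0)
  expect_true(fmax$converged)
})

test_that("the MM iteration never decreases the penalized objective", {
  set.seed(8)
  for (rep in 1:5) {
    st <- make_stats(d = rnorm(20), s2 = runif(20, 0.2, 3))
    lam <- runif(1, 0, plda_lambda_max(st))
    v <- unpenalized_direction(st)$v
    obj <- penalized_objective(v, st, lam)
    for (it in 1:50) {
      v <- mm_step(v, st, lam)
      obj_new <- penalized_objective(v, st, lam)
      expect_gte(obj_new, obj - 1e-10)
      obj <- obj_new
      if (all(v == 0)) break
    }
  }
})

test_that("fitted objective matches brute-force grid maximization (p <= 3)", {
  # draw lambdas in the range where the fit stays nonzero, so the comparison
  # is against the maximum over the constraint ellipsoid itself
  fit_nonzero <- function(st, lam) {
    fit <- plda_fit(st, lam)
    while (length(fit$active_set) == 0L) {
      lam <- lam / 2
      fit <- plda_fit(st, lam)
    }
    list(fit = fit, lam = lam)
  }
  set.seed(21)
  for (p in c(2L, 3L)) {
    for (rep in 1:4) {
      st <- make_stats(d = rnorm(p), s2 = runif(p, 0.5, 2))
      res <- fit_nonzero(st, runif(1, 0, 0.8 * plda_lambda_max(st)))
      expect_equal(penalized_objective(res$fit$v, st, res$lam),
                   grid_objective_max(st, res$lam), tolerance = 1e-4)
    }
  }
})

test_that("selection is invariant under feature rescaling (penalty self-scales)", {
  g <- generate_cohort(synthetic_spec(
    box_geometry(c(4, 4, 4)), n_per_class = c(6, 6),
    clusters = list(list(center = c(2, 2, 2), radius = 1, delta = 2)),
    smoothing_fwhm = 0, seed = 9))
  coh <- g$cohort
  f <- plda_fit(coh, 0.8)
  scaled <- feature_cohort(coh$X * 3.7, coh$labels)
  fs <- plda_fit(scaled, 0.8)
  expect_equal(fs$active_set, f$active_set)
  expect_equal(penalized_objective(fs$v, compute_class_stats(scaled), 0.8),
               penalized_objective(f$v, compute_class_stats(coh), 0.8),
               tolerance = 1e-8)
})

test_that("constant features are dropped with a warning and get zero weight", {
  X <- cbind(rbind(c(0, 1), c(2, 0), c(4, 1), c(6, 3))[, 1:2], 5)
  coh <- feature_cohort(X, c("H", "H", "D", "D"))
  expect_warning(f <- plda_fit(coh, 0), "constant")
  expect_equal(f$v[3], 0)
})
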