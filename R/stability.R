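#' Stability selection for the penalized discriminant direction
#'
#' Repeatedly fits [plda_fit()] on stratified random half-samples of the
#' cohort and records, per feature, the fraction of subsamples in which its
#' coefficient was nonzero: the selection probability
#' `P_j(lambda) = (1/K) * sum_k c_j^(k)(lambda)`, where `c_j^(k)` indicates a
#' nonzero coefficient in subsample `k`. Features whose probability reaches a
#' threshold (0.99 by default, inclusive) form the selected set.
#'
#' Subsamples are stratified without replacement with
#' `floor(subsample_fraction * n_c)` subjects per class. A subsample on which
#' the fit collapses to the zero vector contributes all-zero indicators.
#' Features constant within a subsample are dropped for that subsample only
#' (indicator 0). Per-subsample seeds are pre-drawn from `seed`, so results are
#' identical for a fixed seed regardless of evaluation order.
#'
#' @param cohort a [feature_cohort()].
#' @param lambda regularization parameter passed to [plda_fit()].
#' @param K number of random subsamples (the study default is 100).
#' @param subsample_fraction fraction of each class retained per subsample
#'   (default 0.5, i.e. half-samples); each subsample must keep >= 2 subjects
#'   per class.
#' @param seed integer root seed.
#' @param keep_indicators retain the K x p indicator matrix (memory permitting).
#' @param tol,max_iter passed to [plda_fit()].
#' @return An object of class `selection_profile`: `P` (length-p selection
#'   probabilities, integer multiples of 1/K), `K`, `lambda`, `per_subset_iters`,
#'   `per_subset_converged`, `n_zero_collapses`, `weight_mean` (per-feature mean
#'   of nonzero coefficients over the subsamples where the feature was active;
#'   NA where never active), `indicator_matrix` (if kept) and the subsample
#'   scheme descriptor.
#' @export
run_stability <- function(cohort, lambda, K = 100L, subsample_fraction = 0.5,
                          seed = 1L, keep_indicators = FALSE,
                          tol = 1e-6, max_iter = 1000L) {
  stopifnot(K >= 1L)
  labels <- cohort$labels
  hi <- which(labels == "H")
  di <- which(labels == "D")
  k_H <- floor(subsample_fraction * length(hi))
  k_D <- floor(subsample_fraction * length(di))
  if (k_H < 2L || k_D < 2L)
    stop(sprintf("subsample would keep %d H and %d D subjects; need >= 2 per class",
                 k_H, k_D))
  p <- ncol(cohort$X)
  child_seeds <- draw_child_seeds(seed, K)

  counts <- numeric(p)
  weight_sum <- numeric(p)
  weight_n <- numeric(p)
  iters <- integer(K)
  conv <- logical(K)
  n_zero <- 0L
  ind <- if (keep_indicators) matrix(0L, K, p) else NULL

  for (k in seq_len(K)) {
    idx <- with_seed(child_seeds[k], c(sample(hi, k_H), sample(di, k_D)))
    fit <- plda_fit(subset_cohort(cohort, idx), lambda,
                    tol = tol, max_iter = max_iter)
    iters[k] <- fit$n_iter
    conv[k] <- fit$converged
    act <- fit$active_set
    if (length(act) == 0L) n_zero <- n_zero + 1L
    counts[act] <- counts[act] + 1
    weight_sum[act] <- weight_sum[act] + fit$v[act]
    weight_n[act] <- weight_n[act] + 1
    if (keep_indicators) ind[k, act] <- 1L
  }

  weight_mean <- ifelse(weight_n > 0, weight_sum / pmax(weight_n, 1), NA_real_)
  structure(
    list(P = counts / K, K = as.integer(K), lambda = lambda,
         per_subset_iters = iters, per_subset_converged = conv,
         n_zero_collapses = n_zero,
         weight_mean = weight_mean,
         indicator_matrix = ind,
         subsample_scheme = list(fraction = subsample_fraction,
                                 n_per_class = c(H = k_H, D = k_D),
                                 seed = as.integer(seed))),
    class = "selection_profile"
  )
}

#' @export
print.selection_profile <- function(x, ...) {
  cat(sprintf(
    "<selection_profile> p = %d, K = %d, lambda = %g; %d features with P >= 0.99\n",
    length(x$P), x$K, x$lambda, sum(x$P >= 0.99)))
  invisible(x)
}

#' Threshold a selection profile
#'
#' Returns the indices of features whose selection probability reaches the
#' threshold (inclusive: `P_j >= threshold`), in canonical feature order. An
#' empty result is a valid value; callers decide how to handle it.
#'
#' @param profile a [run_stability()] result.
#' @param threshold selection-probability cutoff in (0, 1]; default 0.99.
#' @return integer vector of selected feature indices (possibly empty).
#' @export
select_features <- function(profile, threshold = 0.99) {
  stopifnot(threshold > 0, threshold <= 1)
  which(profile$P >= threshold)
}
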