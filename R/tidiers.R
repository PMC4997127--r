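#' Tidy a fitted discriminant direction
#'
#' @param x a `direction_vector` from [plda_fit()].
#' @param ... unused.
#' @return A tibble with `feature`, `weight` and `active`.
#' @export
tidy.direction_vector <- function(x, ...) {
  tibble::tibble(feature = seq_along(x$v), weight = x$v, active = x$v != 0)
}

#' @rdname tidy.direction_vector
#' @return For `glance()`: a one-row tibble with `lambda`, `n_active`,
#'   `n_iter`, `converged`.
#' @export
glance.direction_vector <- function(x, ...) {
  tibble::tibble(lambda = x$lambda, n_active = length(x$active_set),
                 n_iter = x$n_iter, converged = x$converged)
}

#' Tidy a stability-selection profile
#'
#' @param x a `selection_profile` from [run_stability()].
#' @param ... unused.
#' @return A tibble with `feature`, `selection_probability` and
#'   `mean_nonzero_weight`.
#' @export
tidy.selection_profile <- function(x, ...) {
  tibble::tibble(feature = seq_along(x$P), selection_probability = x$P,
                 mean_nonzero_weight = x$weight_mean)
}

#' @rdname tidy.selection_profile
#' @return For `glance()`: one row with `lambda`, `K`, `n_selected_0.99`,
#'   `mean_iterations`, `n_zero_collapses`.
#' @export
glance.selection_profile <- function(x, ...) {
  tibble::tibble(lambda = x$lambda, K = x$K,
                 n_selected_0.99 = sum(x$P >= 0.99),
                 mean_iterations = mean(x$per_subset_iters),
                 n_zero_collapses = x$n_zero_collapses)
}

#' Tidy a cross-validation run
#'
#' @param x a `cv_run` from [loocv_c()] or [loocv_rc()].
#' @param ... unused.
#' @return The per-fold tibble (fold, subject, truth, predicted, correct,
#'   n_selected).
#' @export
tidy.cv_run <- function(x, ...) x$folds

#' @rdname tidy.cv_run
#' @return For `glance()`: one row with the design, metrics (percent),
#'   confusion counts and feature-count summary.
#' @export
glance.cv_run <- function(x, ...) {
  m <- compute_metrics(x)
  tibble::tibble(design = x$design, accuracy = m$accuracy,
                 sensitivity = m$sensitivity, specificity = m$specificity,
                 TP = m$TP, TN = m$TN, FP = m$FP, FN = m$FN,
                 n_features = x$n_features$mean,
                 n_features_sd = x$n_features$sd)
}

#' Turn a cohort into a long tibble
#'
#' @param x a [feature_cohort()].
#' @param ... unused.
#' @return A tibble with `subject`, `label`, `feature`, `value`.
#' @export
tidy.cohort <- function(x, ...) {
  tibble::tibble(
    subject = rep(x$subject_ids, each = ncol(x$X)),
    label = rep(as.character(x$labels), each = ncol(x$X)),
    feature = rep(seq_len(ncol(x$X)), times = nrow(x$X)),
    value = as.vector(t(x$X))
  )
}

#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @export
glance <- function(x, ...) UseMethod("glance")
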