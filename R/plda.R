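#' Per-feature class statistics for two-class discriminant analysis
#'
#' Computes the quantities the sparse discriminant problem needs without ever
#' materializing a p x p scatter matrix: class mean vectors, their difference
#' `d = m_H - m_D` (the between-class scatter is the rank-1 outer product of
#' `d`), and the diagonal of the within-class scatter in sum-of-squares form,
#' `s2_j = sum_{i in H} (x_ij - m_Hj)^2 + sum_{i in D} (x_ij - m_Dj)^2`
#' (no degrees-of-freedom normalization).
#'
#' @param cohort a [feature_cohort()] (or any list with `X` and `labels`).
#' @return An object of class `class_stats`: `m_H`, `m_D`, `n_H`, `n_D`, `d`,
#'   `s2`, `s` (= sqrt(s2)) and `constant` (logical, features with `s2 == 0`).
#' @export
compute_class_stats <- function(cohort) {
  X <- cohort$X
  labels <- cohort$labels
  hi <- which(labels == "H")
  di <- which(labels == "D")
  if (length(hi) < 2L || length(di) < 2L)
    stop("each class needs at least 2 members to compute within-class scatter")
  m_H <- colMeans(X[hi, , drop = FALSE])
  m_D <- colMeans(X[di, , drop = FALSE])
  ss <- function(rows, m) {
    Z <- sweep(X[rows, , drop = FALSE], 2L, m)
    colSums(Z * Z)
  }
  s2 <- ss(hi, m_H) + ss(di, m_D)
  structure(
    list(m_H = m_H, m_D = m_D, n_H = length(hi), n_D = length(di),
         d = m_H - m_D, s2 = s2, s = sqrt(s2), constant = s2 == 0),
    class = "class_stats"
  )
}

#' Penalized discriminant objective
#'
#' The lasso-penalized Fisher objective for two classes,
#' `(d . v)^2 - lambda * sum_j s_j |v_j|`, using the rank-1 identity
#' `v' S_B v = (d . v)^2`.
#'
#' @param v numeric length-p direction vector.
#' @param stats a [compute_class_stats()] result.
#' @param lambda regularization parameter, >= 0.
#' @return scalar objective value.
#' @export
penalized_objective <- function(v, stats, lambda) {
  drop(crossprod(stats$d, v))^2 - lambda * sum(stats$s * abs(v))
}

#' Unpenalized (lambda = 0) discriminant direction
#'
#' Closed-form maximizer of `(d . v)^2` under the diagonal within-class
#' constraint `sum_j s2_j v_j^2 = 1`: `v_j` proportional to `d_j / s2_j`,
#' normalized to the constraint, sign fixed so `d . v >= 0`.
#'
#' @inheritParams penalized_objective
#' @return A `direction_vector` (see [plda_fit()]).
#' @export
unpenalized_direction <- function(stats) {
  if (any(stats$s2 == 0))
    stop("constant features (s2 = 0) present; drop them before fitting")
  v <- stats$d / stats$s2
  v <- normalize_direction(v, stats)
  new_direction(v, lambda = 0, n_iter = 0L, converged = TRUE)
}

# scale to sum(s2 v^2) = 1 and fix sign so d.v >= 0; zero vector passes through
normalize_direction <- function(v, stats) {
  nrm <- sqrt(sum(stats$s2 * v^2))
  if (nrm == 0) return(v)
  v <- v / nrm
  if (drop(crossprod(stats$d, v)) < 0) v <- -v
  v
}

new_direction <- function(v, lambda, n_iter, converged) {
  structure(
    list(v = v, lambda = lambda, n_iter = n_iter, converged = converged,
         active_set = which(v != 0)),
    class = "direction_vector"
  )
}

#' @export
print.direction_vector <- function(x, ...) {
  cat(sprintf(
    "<direction_vector> p = %d, active = %d, lambda = %g, %d MM iterations%s\n",
    length(x$v), length(x$active_set), x$lambda, x$n_iter,
    if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' One minorization-maximization step of the penalized discriminant problem
#'
#' Minorizes `(d . v)^2` at `v_old` by its tangent, whose constrained maximum
#' has the closed form: with `b_j = 2 d_j (d . v_old)`,
#' `u_j = soft(b_j, lambda * s_j) / s2_j` where `soft(z, g) = sign(z) *
#' max(|z| - g, 0)`; if `u` is identically zero the zero vector is returned
#' (the penalty dominates), otherwise `u` is normalized to the constraint with
#' sign fixed so `d . u >= 0`. A coefficient exactly at the threshold
#' (`|b_j| = lambda * s_j`) is set to 0.
#'
#' @param v_old current direction (length p).
#' @inheritParams penalized_objective
#' @return numeric length-p updated direction.
#' @export
mm_step <- function(v_old, stats, lambda) {
  b <- 2 * stats$d * drop(crossprod(stats$d, v_old))
  u <- sign(b) * pmax(abs(b) - lambda * stats$s, 0) / stats$s2
  if (all(u == 0)) return(u)
  normalize_direction(u, stats)
}

#' Fit the lasso-penalized linear discriminant direction
#'
#' Iterates [mm_step()] from the closed-form unpenalized direction until the
#' relative change in [penalized_objective()] drops below `tol`, the direction
#' collapses to zero (penalty dominates), or `max_iter` is reached. The MM
#' update never decreases the objective. Non-convergence is reported through
#' the `converged` flag, not an error, so lambda-grid sweeps always complete.
#'
#' @param x a [feature_cohort()] or a [compute_class_stats()] result. Constant
#'   features (zero within-class scatter) are dropped with a warning and get
#'   coefficient 0.
#' @param lambda regularization parameter, >= 0; 0 imposes no penalty (all
#'   features active), large values zero out every coefficient.
#' @param tol relative objective-change convergence tolerance.
#' @param max_iter maximum MM iterations.
#' @return A `direction_vector`: `v` (length p, satisfying
#'   `sum(s2 * v^2) = 1` unless identically zero), `lambda`, `n_iter`,
#'   `converged`, `active_set` (indices with nonzero coefficient).
#' @export
plda_fit <- function(x, lambda, tol = 1e-6, max_iter = 1000L) {
  if (lambda < 0) stop("lambda must be >= 0")
  stats <- if (inherits(x, "class_stats")) x else compute_class_stats(x)
  p <- length(stats$d)
  keep <- !stats$constant
  if (!all(keep)) {
    warning(sprintf("dropping %d constant feature(s) (zero within-class scatter)",
                    sum(!keep)))
    sub <- structure(
      list(m_H = stats$m_H[keep], m_D = stats$m_D[keep],
           n_H = stats$n_H, n_D = stats$n_D,
           d = stats$d[keep], s2 = stats$s2[keep], s = stats$s[keep],
           constant = rep(FALSE, sum(keep))),
      class = "class_stats")
    fit <- plda_fit(sub, lambda, tol = tol, max_iter = max_iter)
    v <- numeric(p)
    v[keep] <- fit$v
    return(new_direction(v, lambda, fit$n_iter, fit$converged))
  }

  v <- unpenalized_direction(stats)$v
  obj <- penalized_objective(v, stats, lambda)
  n_iter <- 0L
  converged <- FALSE
  while (n_iter < max_iter) {
    n_iter <- n_iter + 1L
    v_new <- mm_step(v, stats, lambda)
    if (all(v_new == 0)) {
      v <- v_new
      converged <- TRUE
      break
    }
    obj_new <- penalized_objective(v_new, stats, lambda)
    rel <- abs(obj_new - obj) / max(abs(obj), 1e-12)
    v <- v_new
    obj <- obj_new
    if (rel < tol) {
      converged <- TRUE
      break
    }
  }
  new_direction(v, lambda, n_iter, converged)
}

#' Smallest lambda that zeroes the first MM step
#'
#' At the unpenalized initialization `v0`, the soft-threshold condition gives
#' `lambda_max = max_j |2 d_j (d . v0)| / s_j`; for `lambda >= lambda_max` the
#' first MM step (and hence the fit) collapses to the zero vector.
#'
#' @param x a [feature_cohort()] or [compute_class_stats()] result.
#' @return scalar lambda upper bound.
#' @export
plda_lambda_max <- function(x) {
  stats <- if (inherits(x, "class_stats")) x else compute_class_stats(x)
  keep <- !stats$constant
  d <- stats$d[keep]; s <- stats$s[keep]; s2 <- stats$s2[keep]
  v0 <- d / s2
  nrm <- sqrt(sum(s2 * v0^2))
  if (nrm == 0) return(0)
  v0 <- v0 / nrm
  max(abs(2 * d * sum(d * v0)) / s)
}
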