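#' Mass-univariate t-test feature selection
#'
#' Per-feature two-sided two-sample Student's t test (pooled variance,
#' `df = n - 2`); features with raw p-value below `p_threshold` are selected,
#' or with Benjamini-Hochberg adjusted p-value below it when
#' `correction = "fdr"`. Features constant in both classes have no defined t
#' statistic and are never selected.
#'
#' @param cohort a [feature_cohort()].
#' @param p_threshold significance threshold in (0, 1); the comparison is
#'   strict (`p < p_threshold`).
#' @param correction `"none"` for raw p-values or `"fdr"` for
#'   Benjamini-Hochberg adjustment.
#' @return An object of class `reduction_result` with `method = "ttest"`,
#'   `selected` (feature indices), `statistic` and `p_value` (length-p, NA for
#'   constant features) and the parameters used.
#' @export
ttest_select <- function(cohort, p_threshold = 0.01,
                         correction = c("none", "fdr")) {
  correction <- match.arg(correction)
  stopifnot(p_threshold > 0, p_threshold < 1)
  st <- compute_class_stats(cohort)
  n <- st$n_H + st$n_D
  df <- n - 2
  # pooled variance from the within-class sum of squares
  sp2 <- st$s2 / df
  se <- sqrt(sp2 * (1 / st$n_H + 1 / st$n_D))
  tstat <- ifelse(se > 0, st$d / se, NA_real_)
  pval <- 2 * pt(abs(tstat), df = df, lower.tail = FALSE)
  padj <- if (correction == "fdr") p.adjust(pval, method = "BH") else pval
  selected <- which(!is.na(padj) & padj < p_threshold)
  new_reduction("ttest", selected = selected,
                params = list(p_threshold = p_threshold, correction = correction),
                statistic = tstat, p_value = pval)
}

#' Principal-component feature extraction
#'
#' Centers on the training mean and extracts the right singular directions of
#' the centered training matrix with nonzero singular values (at most
#' `n_train - 1` components); training and test rows are projected onto them.
#' Class labels are never used (unsupervised).
#'
#' @param train a [feature_cohort()] or matrix of training rows (n >= 3).
#' @param test optional matrix of test rows to project.
#' @return A `reduction_result` with `method = "pca"`, `transform` (list with
#'   `center`, `loadings` p x r, `singular_values`), `train_scores` and, when
#'   `test` is given, `test_scores`.
#' @export
pca_extract <- function(train, test = NULL) {
  Xtr <- if (inherits(train, "cohort")) train$X else as.matrix(train)
  if (nrow(Xtr) < 3L) stop("PCA extraction needs at least 3 training rows")
  ctr <- colMeans(Xtr)
  Z <- sweep(Xtr, 2L, ctr)
  sv <- svd(Z)
  tol <- max(dim(Z)) * .Machine$double.eps * max(sv$d, 0)
  r <- sum(sv$d > max(tol, 1e-12))
  if (r < 1L) stop("training rows are all identical: rank < 1, no components")
  loadings <- sv$v[, seq_len(r), drop = FALSE]
  res <- new_reduction(
    "pca", transform = list(center = ctr, loadings = loadings,
                            singular_values = sv$d[seq_len(r)]),
    params = list(rank = r))
  res$train_scores <- Z %*% loadings
  if (!is.null(test))
    res$test_scores <- sweep(as.matrix(test), 2L, ctr) %*% loadings
  res
}

#' Identity (no) reduction
#'
#' Selects every feature; composes with any classifier unchanged.
#'
#' @param cohort a [feature_cohort()] or matrix.
#' @return A `reduction_result` with `method = "none"` and all features
#'   selected.
#' @export
no_reduction <- function(cohort) {
  p <- if (inherits(cohort, "cohort")) ncol(cohort$X) else ncol(cohort)
  new_reduction("none", selected = seq_len(p), params = list())
}

new_reduction <- function(method, selected = NULL, transform = NULL,
                          params = list(), ...) {
  structure(
    list(method = method, selected = selected, transform = transform,
         params = params, ...),
    class = "reduction_result"
  )
}

#' @export
print.reduction_result <- function(x, ...) {
  what <- if (!is.null(x$transform))
    sprintf("%d components", x$params$rank)
  else sprintf("%d features selected", length(x$selected))
  cat(sprintf("<reduction_result> method = %s, %s\n", x$method, what))
  invisible(x)
}

# Apply a fitted reduction to new rows (matrix in, matrix out).
apply_reduction <- function(reduction, X) {
  X <- as.matrix(X)
  if (!is.null(reduction$transform)) {
    tr <- reduction$transform
    sweep(X, 2L, tr$center) %*% tr$loadings
  } else {
    X[, reduction$selected, drop = FALSE]
  }
}
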