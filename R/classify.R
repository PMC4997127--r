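#' Train a two-class linear discriminant classifier (p >> n safe)
#'
#' Gaussian equal-covariance discriminant with equal priors. The pooled
#' within-class covariance is inverted through its pseudo-inverse computed in
#' the subspace spanned by the within-class-centered training rows (rank at
#' most `n - 2`), so no p x p matrix is ever formed and singular covariances
#' (p >> n) are handled; when the pooled covariance is full rank this reduces
#' to classical LDA. The decision hyperplane is `w = S+ (m_D - m_H)` with the
#' intercept at the midpoint of the projected class means; a decision value of
#' exactly 0 (tie) is assigned to class `"H"`. `diagonal = TRUE` switches to a
#' diagonal-covariance variant for sensitivity analysis.
#'
#' @param X numeric `n x q` training matrix (reduced features).
#' @param labels length-n labels over `{"H", "D"}`, each class >= 2 members.
#' @param diagonal use only the diagonal of the pooled covariance.
#' @return An object of class `trained_classifier` (`kind = "lda"`) with
#'   weight vector `w`, intercept `b` and training metadata; predict D iff
#'   `w . x + b > 0`.
#' @export
lda_train <- function(X, labels, diagonal = FALSE) {
  X <- as.matrix(X)
  labels <- factor(as.character(labels), levels = c("H", "D"))
  hi <- which(labels == "H"); di <- which(labels == "D")
  if (length(hi) < 2L || length(di) < 2L)
    stop("each class needs at least 2 training members")
  n <- nrow(X)
  m_H <- colMeans(X[hi, , drop = FALSE])
  m_D <- colMeans(X[di, , drop = FALSE])
  Z <- X
  Z[hi, ] <- sweep(X[hi, , drop = FALSE], 2L, m_H)
  Z[di, ] <- sweep(X[di, , drop = FALSE], 2L, m_D)
  dm <- m_D - m_H
  if (diagonal) {
    s2 <- colSums(Z * Z) / (n - 2)
    if (any(s2 == 0)) s2[s2 == 0] <- .Machine$double.eps
    w <- dm / s2
  } else {
    # pooled covariance S = Z'Z/(n-2) = V diag(d^2/(n-2)) V'; pseudo-inverse in
    # the row span of Z
    sv <- svd(Z, nu = 0)
    tol <- max(dim(Z)) * .Machine$double.eps * max(sv$d, 0)
    keep <- sv$d > max(tol, 1e-12)
    if (!any(keep)) {
      w <- numeric(ncol(X))  # degenerate: all rows equal within class
    } else {
      V <- sv$v[, keep, drop = FALSE]
      inv_eig <- (n - 2) / sv$d[keep]^2
      w <- V %*% (inv_eig * crossprod(V, dm))
      w <- drop(w)
    }
  }
  b <- -sum(w * (m_H + m_D)) / 2
  new_classifier("lda", w = w, b = b,
                 meta = list(n_features = ncol(X),
                             n_per_class = c(H = length(hi), D = length(di)),
                             diagonal = diagonal))
}

#' Train a soft-margin linear support-vector machine
#'
#' Linear-kernel SVM with hinge loss and cost `C`, solved by libsvm (through
#' e1071); no feature scaling, no inner hyperparameter tuning. The fitted
#' hyperplane is extracted as an explicit weight vector and intercept so that
#' prediction uses the same sign rule (tie to `"H"`) as the discriminant
#' classifier.
#'
#' @param X numeric `n x q` training matrix.
#' @param labels length-n labels over `{"H", "D"}`, both classes non-empty.
#' @param cost penalty parameter C (default 1).
#' @return A `trained_classifier` (`kind = "linsvm"`); predict D iff
#'   `w . x + b > 0`.
#' @export
svm_train <- function(X, labels, cost = 1) {
  X <- as.matrix(X)
  labels <- factor(as.character(labels), levels = c("H", "D"))
  if (any(table(labels) == 0L))
    stop("both classes must be non-empty")
  fit <- tryCatch(
    e1071::svm(x = X, y = labels, kernel = "linear", cost = cost,
               scale = FALSE, type = "C-classification"),
    error = function(e) stop("linear SVM solver failed: ", conditionMessage(e))
  )
  w <- drop(crossprod(fit$SV, fit$coefs))
  b <- -fit$rho
  # libsvm orients decision values toward whichever class it saw first; align
  # the hyperplane with our convention (positive score = class "D") by
  # matching libsvm's own training predictions
  pred <- predict(fit, X)
  score <- drop(X %*% w) + b
  agree <- mean((score > 0) == (pred == "D"))
  if (agree < 0.5) { w <- -w; b <- -b }
  new_classifier("linsvm", w = w, b = b,
                 meta = list(n_features = ncol(X),
                             n_per_class = table(labels), cost = cost))
}

new_classifier <- function(kind, w, b, meta) {
  structure(list(kind = kind, w = as.numeric(w), b = as.numeric(b), meta = meta),
            class = "trained_classifier")
}

#' @export
print.trained_classifier <- function(x, ...) {
  cat(sprintf("<trained_classifier> %s on %d features\n",
              x$kind, x$meta$n_features))
  invisible(x)
}

#' Predict class labels with a trained linear classifier
#'
#' Applies the sign rule `predict "D" iff w . x + b > 0`; a decision value of
#' exactly 0 goes to `"H"` (deterministic tie-break). Test labels are never
#' consulted.
#'
#' @param object a [lda_train()] or [svm_train()] result.
#' @param newdata numeric matrix (or single row) with the training feature
#'   count.
#' @param ... unused.
#' @return factor of predicted labels over `{"H", "D"}`.
#' @export
predict.trained_classifier <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (ncol(X) == 1L && length(object$w) > 1L && nrow(X) == length(object$w))
    X <- t(X)
  if (ncol(X) != length(object$w))
    stop(sprintf("newdata has %d features but the model was trained on %d",
                 ncol(X), length(object$w)))
  score <- drop(X %*% object$w) + object$b
  factor(ifelse(score > 0, "D", "H"), levels = c("H", "D"))
}
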