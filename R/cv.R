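#' Reducer and classifier specifications
#'
#' Lightweight specs naming a reduction or classification method plus its
#' parameters; the cross-validation engine fits them on whatever training rows
#' a design dictates.
#'
#' * `reducer_plda()` — stability selection over [plda_fit()] half-sample
#'   refits, thresholded at `threshold` (inclusive). If no feature reaches the
#'   threshold in some fit, `on_empty = "fallback"` selects the features
#'   attaining the maximum selection probability (logged via a message);
#'   `"error"` aborts instead.
#' * `reducer_ttest()` — [ttest_select()]; an empty selected set falls back to
#'   the single smallest-p feature under `"fallback"`.
#' * `reducer_pca()` — [pca_extract()] (all components with nonzero singular
#'   value, at most n_train - 1).
#' * `reducer_none()` — [no_reduction()].
#'
#' @param lambda,K,subsample_fraction,threshold stability-selection parameters
#'   (see [run_stability()], [select_features()]).
#' @param p_threshold,correction t-test parameters (see [ttest_select()]).
#' @param on_empty `"fallback"` or `"error"` for empty selected sets.
#' @param cost SVM cost parameter.
#' @param diagonal use the diagonal-covariance LDA variant (see [lda_train()]).
#' @return a `reducer_spec` or `classifier_spec` object.
#' @name specs
NULL

#' @rdname specs
#' @export
reducer_plda <- function(lambda, K = 100L, subsample_fraction = 0.5,
                         threshold = 0.99, on_empty = c("fallback", "error")) {
  structure(list(method = "plda", lambda = lambda, K = as.integer(K),
                 subsample_fraction = subsample_fraction, threshold = threshold,
                 on_empty = match.arg(on_empty)),
            class = "reducer_spec")
}

#' @rdname specs
#' @export
reducer_ttest <- function(p_threshold = 0.01, correction = c("none", "fdr"),
                          on_empty = c("fallback", "error")) {
  structure(list(method = "ttest", p_threshold = p_threshold,
                 correction = match.arg(correction),
                 on_empty = match.arg(on_empty)),
            class = "reducer_spec")
}

#' @rdname specs
#' @export
reducer_pca <- function() {
  structure(list(method = "pca"), class = "reducer_spec")
}

#' @rdname specs
#' @export
reducer_none <- function() {
  structure(list(method = "none"), class = "reducer_spec")
}

#' @rdname specs
#' @export
classifier_lda <- function(diagonal = FALSE) {
  structure(list(kind = "lda", diagonal = diagonal), class = "classifier_spec")
}

#' @rdname specs
#' @export
classifier_svm <- function(cost = 1) {
  structure(list(kind = "linsvm", cost = cost), class = "classifier_spec")
}

# Fit a reducer spec on a training cohort; returns a reduction_result plus
# bookkeeping (selection profile for plda).
fit_reducer <- function(spec, train, seed) {
  switch(
    spec$method,
    plda = {
      prof <- run_stability(train, lambda = spec$lambda, K = spec$K,
                            subsample_fraction = spec$subsample_fraction,
                            seed = seed)
      sel <- select_features(prof, spec$threshold)
      if (length(sel) == 0L) {
        if (spec$on_empty == "error")
          stop("no feature reached the stability-selection threshold")
        pmax_val <- max(prof$P)
        sel <- if (pmax_val > 0) which(prof$P == pmax_val) else integer(0)
        if (length(sel) == 0L)
          stop("stability selection produced all-zero probabilities; cannot fall back")
        message(sprintf(
          "no feature reached P >= %g; falling back to %d feature(s) at max P = %g",
          spec$threshold, length(sel), pmax_val))
      }
      red <- new_reduction("plda", selected = sel,
                           params = list(lambda = spec$lambda, K = spec$K,
                                         threshold = spec$threshold))
      red$profile <- prof
      red
    },
    ttest = {
      red <- ttest_select(train, p_threshold = spec$p_threshold,
                          correction = spec$correction)
      if (length(red$selected) == 0L) {
        if (spec$on_empty == "error")
          stop("t-test selected no features at the given threshold")
        sel <- which.min(red$p_value)
        message(sprintf(
          "t-test selected no features at p < %g; falling back to the smallest-p feature",
          spec$p_threshold))
        red$selected <- sel
      }
      red
    },
    pca = pca_extract(train),
    none = no_reduction(train),
    stop("unknown reducer method: ", spec$method)
  )
}

fit_classifier <- function(spec, X, labels) {
  switch(spec$kind,
         lda = lda_train(X, labels, diagonal = spec$diagonal),
         linsvm = svm_train(X, labels, cost = spec$cost),
         stop("unknown classifier kind: ", spec$kind))
}

reducer_label <- function(spec) {
  switch(spec$method,
         plda = sprintf("plda(lambda=%g)", spec$lambda),
         ttest = sprintf("ttest(p<%g%s)", spec$p_threshold,
                         if (spec$correction == "fdr") ", fdr" else ""),
         spec$method)
}

# shared post-processing: assemble a cv_run from fold records
build_cv_run <- function(design, folds, labels, p, selection_counts,
                         weight_sum, weight_n, n_feat_per_fold, iter_summary) {
  truth <- labels
  pred <- factor(vapply(folds, `[[`, "", "predicted"), levels = c("H", "D"))
  TP <- sum(truth == "D" & pred == "D")
  TN <- sum(truth == "H" & pred == "H")
  FP <- sum(truth == "H" & pred == "D")
  FN <- sum(truth == "D" & pred == "H")
  fold_tbl <- tibble::tibble(
    fold = seq_along(folds),
    subject = vapply(folds, `[[`, 1L, "subject"),
    truth = truth,
    predicted = pred,
    correct = truth == pred,
    n_selected = n_feat_per_fold
  )
  structure(
    list(design = design, folds = fold_tbl,
         confusion = c(TP = TP, TN = TN, FP = FP, FN = FN),
         selection_counts = selection_counts,
         mean_weights = ifelse(weight_n > 0, weight_sum / pmax(weight_n, 1),
                               NA_real_),
         n_features = list(mean = mean(n_feat_per_fold),
                           sd = if (length(unique(n_feat_per_fold)) == 1L) 0
                                else sd(n_feat_per_fold)),
         iterations = iter_summary),
    class = "cv_run"
  )
}

#' @export
print.cv_run <- function(x, ...) {
  m <- compute_metrics(x)
  cat(sprintf(
    "<cv_run> LOOCV(%s): n = %d, accuracy %.1f%%, sensitivity %.1f%%, specificity %.1f%%\n",
    x$design, nrow(x$folds), m$accuracy, m$sensitivity, m$specificity))
  invisible(x)
}

#' Leave-one-out cross-validation with reduction fit on all data (biased)
#'
#' The non-nested design under critique: the reduction is fit ONCE on all `n`
#' subjects — supervised reducers therefore see the test subjects' labels —
#' and only the classifier is cross-validated over the `n` leave-one-out
#' folds. On data with no class signal this design produces optimistically
#' biased accuracy for label-using reducers; [loocv_rc()] is the correct
#' design.
#'
#' @param cohort a [feature_cohort()].
#' @param reducer a `reducer_spec` (see [reducer_plda()] and friends).
#' @param classifier a `classifier_spec` ([classifier_lda()] /
#'   [classifier_svm()]).
#' @param seed integer root seed; fold and subsample child seeds are pre-drawn
#'   from it so reruns are identical.
#' @return A `cv_run`: per-fold tibble, confusion counts, per-feature
#'   selection counts (here `n * indicator(selected)`), mean nonzero pLDA
#'   weights where applicable, feature-count and MM-iteration summaries.
#' @export
loocv_c <- function(cohort, reducer, classifier, seed = 1L) {
  n <- nrow(cohort$X)
  p <- ncol(cohort$X)
  seeds <- draw_child_seeds(seed, 1L)
  red <- fit_reducer(reducer, cohort, seeds[1])
  Xr <- apply_reduction(red, cohort$X)
  n_sel <- if (!is.null(red$transform)) red$params$rank else length(red$selected)

  folds <- vector("list", n)
  for (i in seq_len(n)) {
    model <- fit_classifier(classifier, Xr[-i, , drop = FALSE],
                            cohort$labels[-i])
    folds[[i]] <- list(subject = i,
                       predicted = as.character(
                         predict(model, Xr[i, , drop = FALSE])))
  }

  selection_counts <- numeric(p)
  if (!is.null(red$selected)) selection_counts[red$selected] <- n
  weight_sum <- numeric(p); weight_n <- numeric(p)
  if (!is.null(red$profile)) {
    act <- which(!is.na(red$profile$weight_mean))
    weight_sum[act] <- red$profile$weight_mean[act]
    weight_n[act] <- 1
  }
  iter_summary <- if (!is.null(red$profile))
    list(mean = mean(red$profile$per_subset_iters),
         sd = sd(red$profile$per_subset_iters))
  else list(mean = NA_real_, sd = NA_real_)

  run <- build_cv_run("c", folds, cohort$labels, p, selection_counts,
                      weight_sum, weight_n, rep(n_sel, n), iter_summary)
  run$reduction <- red
  run
}

#' Leave-one-out cross-validation nested over reduction and classification
#'
#' The correct design: in every fold the reduction (including stability
#' selection with its K subsamples) is fit on the `n - 1` training subjects
#' only; the held-out subject is reduced with that fold's selection/transform
#' and then classified. Per-fold selected sets are accumulated into the
#' selection-count map and the mean nonzero-weight map.
#'
#' @inheritParams loocv_c
#' @return A `cv_run` (see [loocv_c()]); `n_features` holds the mean and SD of
#'   the per-fold selected-feature counts.
#' @export
loocv_rc <- function(cohort, reducer, classifier, seed = 1L) {
  n <- nrow(cohort$X)
  p <- ncol(cohort$X)
  seeds <- draw_child_seeds(seed, n)

  folds <- vector("list", n)
  selection_counts <- numeric(p)
  weight_sum <- numeric(p); weight_n <- numeric(p)
  n_feat <- numeric(n)
  iters <- numeric(0)

  for (i in seq_len(n)) {
    train <- subset_cohort(cohort, setdiff(seq_len(n), i))
    red <- fit_reducer(reducer, train, seeds[i])
    Xr <- apply_reduction(red, train$X)
    xt <- apply_reduction(red, cohort$X[i, , drop = FALSE])
    model <- fit_classifier(classifier, Xr, train$labels)
    folds[[i]] <- list(subject = i,
                       predicted = as.character(predict(model, xt)))
    if (!is.null(red$selected)) {
      selection_counts[red$selected] <- selection_counts[red$selected] + 1
      n_feat[i] <- length(red$selected)
    } else {
      n_feat[i] <- red$params$rank
    }
    if (!is.null(red$profile)) {
      act <- which(!is.na(red$profile$weight_mean))
      weight_sum[act] <- weight_sum[act] + red$profile$weight_mean[act]
      weight_n[act] <- weight_n[act] + 1
      iters <- c(iters, red$profile$per_subset_iters)
    }
  }
  iter_summary <- if (length(iters))
    list(mean = mean(iters), sd = sd(iters))
  else list(mean = NA_real_, sd = NA_real_)

  build_cv_run("rc", folds, cohort$labels, p, selection_counts,
               weight_sum, weight_n, n_feat, iter_summary)
}

#' Accuracy, sensitivity and specificity of a cross-validation run
#'
#' Recomputed purely from the confusion counts: accuracy
#' `(TP + TN) / (TP + TN + FP + FN)`, sensitivity `TP / (TP + FN)` (true
#' positives among patients), specificity `TN / (TN + FP)` (true negatives
#' among controls), all in percent. A class with no members makes the
#' corresponding metric `NA` (flagged, never silently 0).
#'
#' @param run a `cv_run`, or a named numeric vector / list with `TP`, `TN`,
#'   `FP`, `FN`.
#' @return A one-row tibble: `accuracy`, `sensitivity`, `specificity`
#'   (percent) plus the confusion counts and `n`.
#' @export
compute_metrics <- function(run) {
  cc <- if (inherits(run, "cv_run")) run$confusion else unlist(run)
  TP <- cc[["TP"]]; TN <- cc[["TN"]]; FP <- cc[["FP"]]; FN <- cc[["FN"]]
  n <- TP + TN + FP + FN
  tibble::tibble(
    accuracy = 100 * (TP + TN) / n,
    sensitivity = if (TP + FN == 0) NA_real_ else 100 * TP / (TP + FN),
    specificity = if (TN + FP == 0) NA_real_ else 100 * TN / (TN + FP),
    TP = TP, TN = TN, FP = FP, FN = FN, n = n
  )
}

#' McNemar's test between two cross-validation runs
#'
#' Compares per-subject correctness of two runs on the same subjects in the
#' same order via the discordant pairs `b` (first correct, second wrong) and
#' `c` (first wrong, second correct). With 25 or fewer discordant pairs the
#' exact two-sided binomial form is used; otherwise the continuity-corrected
#' chi-squared statistic `(|b - c| - 1)^2 / (b + c)` on 1 df. Zero discordant
#' pairs give p = 1.
#'
#' @param run_a,run_b `cv_run` objects on identical subjects.
#' @param method `"auto"` (exact when `b + c <= 25`), `"exact"`, or `"chisq"`.
#' @return A list with `b`, `c`, `statistic` (NA for the exact branch),
#'   `p_value` and `method`.
#' @export
mcnemar_compare <- function(run_a, run_b, method = c("auto", "exact", "chisq")) {
  method <- match.arg(method)
  fa <- run_a$folds; fb <- run_b$folds
  if (!identical(fa$subject, fb$subject) ||
      !identical(as.character(fa$truth), as.character(fb$truth)))
    stop("runs must be on identical subjects in identical order")
  b <- sum(fa$correct & !fb$correct)
  cc <- sum(!fa$correct & fb$correct)
  nd <- b + cc
  if (method == "auto") method <- if (nd <= 25) "exact" else "chisq"
  if (nd == 0)
    return(list(b = b, c = cc, statistic = NA_real_, p_value = 1,
                method = method))
  if (method == "exact") {
    p <- binom.test(b, nd, p = 0.5)$p.value
    list(b = b, c = cc, statistic = NA_real_, p_value = p, method = "exact")
  } else {
    stat <- (abs(b - cc) - 1)^2 / nd
    p <- pchisq(stat, df = 1, lower.tail = FALSE)
    list(b = b, c = cc, statistic = stat, p_value = p, method = "chisq")
  }
}

#' One-sample binomial test of a run against chance
#'
#' One-sided exact binomial test of the number of correct classifications out
#' of `n` against success probability 0.5 (alternative: better than chance).
#'
#' @param run a `cv_run`.
#' @return A list with `n_correct`, `n` and `p_value`.
#' @export
binomial_vs_chance <- function(run) {
  k <- sum(run$folds$correct)
  n <- nrow(run$folds)
  list(n_correct = k, n = n,
       p_value = binom.test(k, n, p = 0.5, alternative = "greater")$p.value)
}
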