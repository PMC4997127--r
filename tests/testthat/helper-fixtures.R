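# Shared fixtures and independent oracles, built in code at test time.

# hand-computable 2-feature cohort: H rows {(0,0),(2,0)}, D rows {(4,1),(6,3)}
toy_cohort <- function() {
  feature_cohort(rbind(c(0, 0), c(2, 0), c(4, 1), c(6, 3)),
                 c("H", "H", "D", "D"))
}

# class_stats built directly from given d and s2 (class means immaterial for
# the direction-fitting algebra)
make_stats <- function(d, s2) {
  structure(list(m_H = d, m_D = rep(0, length(d)), n_H = 2L, n_D = 2L,
                 d = d, s2 = s2, s = sqrt(s2), constant = s2 == 0),
            class = "class_stats")
}

# strong-signal fixture: one planted cluster, effect 5x noise sd, on the
# desk-scale ellipsoid geometry
strong_signal_fixture <- function(seed = 11) {
  geom <- ellipsoid_geometry()
  spec <- synthetic_spec(
    geom, n_per_class = c(20, 20),
    clusters = list(list(center = c(12, 12, 12), radius = 2.5, delta = 5)),
    noise_sd = 1, smoothing_fwhm = 3, variance_heterogeneity = 0.2,
    seed = seed)
  generate_cohort(spec)
}
strong_signal_lambda <- 200

# minimal cv_run wrapper so metric/comparison oracles can be fed crafted
# prediction vectors
make_run <- function(truth, predicted, design = "rc") {
  truth <- factor(truth, levels = c("H", "D"))
  predicted <- factor(predicted, levels = c("H", "D"))
  folds <- tibble::tibble(
    fold = seq_along(truth), subject = seq_along(truth),
    truth = truth, predicted = predicted, correct = truth == predicted,
    n_selected = NA_real_)
  structure(
    list(design = design, folds = folds,
         confusion = c(TP = sum(truth == "D" & predicted == "D"),
                       TN = sum(truth == "H" & predicted == "H"),
                       FP = sum(truth == "H" & predicted == "D"),
                       FN = sum(truth == "D" & predicted == "H")),
         selection_counts = numeric(0),
         mean_weights = numeric(0),
         n_features = list(mean = NA_real_, sd = NA_real_),
         iterations = list(mean = NA_real_, sd = NA_real_)),
    class = "cv_run")
}

# Independent brute-force maximizer of the penalized discriminant objective
# over the constraint ellipsoid, for p = 2 or 3: exhaustive angular grid with
# iterative zoom refinement (no MM mathematics shared with the implementation).
grid_objective_max <- function(stats, lambda, n_grid = 400L, n_zoom = 4L) {
  p <- length(stats$d)
  stopifnot(p %in% c(2L, 3L))
  eval_dirs <- function(U) {
    nrm <- sqrt(colSums(U^2 * stats$s2))
    V <- sweep(U, 2L, nrm, "/")
    drop(crossprod(stats$d, V))^2 - lambda * drop(crossprod(stats$s, abs(V)))
  }
  if (p == 2L) {
    lo <- 0; hi <- pi  # v and -v give equal objective
    width <- hi - lo
    best_th <- NA
    for (z in seq_len(n_zoom)) {
      th <- seq(lo, hi, length.out = n_grid)
      U <- rbind(cos(th), sin(th))
      obj <- eval_dirs(U)
      best_th <- th[which.max(obj)]
      width <- width / n_grid * 4
      lo <- best_th - width / 2; hi <- best_th + width / 2
    }
    best <- max(eval_dirs(rbind(cos(best_th), sin(best_th))))
  } else {
    lo_t <- 0; hi_t <- pi; lo_p <- 0; hi_p <- pi
    best <- -Inf
    for (z in seq_len(n_zoom)) {
      th <- seq(lo_t, hi_t, length.out = n_grid)
      ph <- seq(lo_p, hi_p, length.out = n_grid)
      g <- expand.grid(th = th, ph = ph)
      U <- rbind(sin(g$ph) * cos(g$th), sin(g$ph) * sin(g$th), cos(g$ph))
      obj <- eval_dirs(U)
      i <- which.max(obj)
      best <- obj[i]
      wt <- (hi_t - lo_t) / n_grid * 4
      wp <- (hi_p - lo_p) / n_grid * 4
      lo_t <- g$th[i] - wt / 2; hi_t <- g$th[i] + wt / 2
      lo_p <- g$ph[i] - wp / 2; hi_p <- g$ph[i] + wp / 2
    }
  }
  best
}
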