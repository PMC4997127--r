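#' Labeled feature matrix (cohort) constructor
#'
#' Bundles an `n x p` feature matrix with binary class labels (`"H"` healthy
#' controls, `"D"` diseased/patients) and, optionally, the [volume_geometry()]
#' its columns are indexed by.
#'
#' @param X numeric `n x p` matrix, subjects in rows, masked-voxel features in
#'   columns, no missing values.
#' @param labels character/factor of length `n` over `{"H", "D"}`.
#' @param geometry optional [volume_geometry()] with `p` features.
#' @param subject_ids optional subject identifiers (default `S1..Sn`).
#' @return An object of class `cohort`.
#' @export
feature_cohort <- function(X, labels, geometry = NULL, subject_ids = NULL) {
  X <- as.matrix(X)
  labels <- factor(as.character(labels), levels = c("H", "D"))
  if (anyNA(labels))
    stop("labels must all be \"H\" or \"D\"")
  if (nrow(X) != length(labels))
    stop("nrow(X) must equal length(labels)")
  if (nrow(X) < 4L)
    stop("a cohort needs at least 4 subjects")
  if (any(table(labels) == 0L))
    stop("both classes must be non-empty")
  if (anyNA(X))
    stop("X must not contain missing values")
  if (!is.null(geometry) && geometry$p != ncol(X))
    stop(sprintf("geometry has p = %d features but X has %d columns",
                 geometry$p, ncol(X)))
  structure(
    list(
      X = X,
      labels = labels,
      geometry = geometry,
      subject_ids = subject_ids %||% paste0("S", seq_len(nrow(X)))
    ),
    class = "cohort"
  )
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d subjects (%d H, %d D) x %d features\n",
              nrow(x$X), sum(x$labels == "H"), sum(x$labels == "D"), ncol(x$X)))
  invisible(x)
}

#' @export
dim.cohort <- function(x) dim(x$X)

# row subset keeping labels aligned
subset_cohort <- function(cohort, idx) {
  feature_cohort(cohort$X[idx, , drop = FALSE], cohort$labels[idx],
                 geometry = cohort$geometry,
                 subject_ids = cohort$subject_ids[idx])
}

#' Specification of a synthetic two-class volume cohort
#'
#' Describes a cohort of masked 3-D scalar volumes emulating smoothed
#' gray-matter-volume maps or log-Jacobian deformation maps: spatially smooth
#' Gaussian noise with heterogeneous per-voxel scale, plus spherical
#' discriminative clusters planted in the patient class.
#'
#' Noise model per subject: white Gaussian noise over the grid, scaled by a
#' per-voxel factor drawn once as lognormal(0, `variance_heterogeneity`),
#' Gaussian-smoothed with `smoothing_fwhm` (voxels, sigma = FWHM/2.3548), then
#' masked. The class-D mean is shifted by the true effect vector (`delta` at
#' every voxel of each cluster), so the planted effect size is exact in
#' expectation.
#'
#' @param geometry a [volume_geometry()].
#' @param n_per_class integer length-2, `c(n_H, n_D)`, each at least 2.
#' @param clusters list of clusters, each a list with `center` (voxel triple),
#'   `radius` (voxels), `delta` (effect size, intensity units) and optional
#'   `sign` (+1/-1, default +1). All cluster voxels must be in-mask.
#' @param noise_sd pre-smoothing noise standard deviation.
#' @param smoothing_fwhm full width at half maximum of spatial smoothing, in
#'   voxels (0 = no smoothing).
#' @param variance_heterogeneity sd of the log per-voxel noise-scale factor
#'   (0 = homogeneous variance).
#' @param baseline constant added to every voxel (use > 0 for gray-matter-like
#'   positive intensities, 0 for signed log-Jacobian-like maps).
#' @param seed integer seed; identical specs give bit-identical cohorts.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(geometry,
                           n_per_class = c(20, 20),
                           clusters = list(),
                           noise_sd = 1,
                           smoothing_fwhm = 3,
                           variance_heterogeneity = 0.2,
                           baseline = 0,
                           seed = 1L) {
  stopifnot(inherits(geometry, "volume_geometry"))
  n_per_class <- as.integer(n_per_class)
  if (length(n_per_class) != 2L || any(n_per_class < 2L))
    stop("n_per_class must be two integers, each >= 2")
  if (variance_heterogeneity < 0)
    stop("variance_heterogeneity must be >= 0")
  structure(
    list(geometry = geometry, n_per_class = n_per_class, clusters = clusters,
         noise_sd = noise_sd, smoothing_fwhm = smoothing_fwhm,
         variance_heterogeneity = variance_heterogeneity,
         baseline = baseline, seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

# True per-feature effect vector and support implied by a spec's clusters.
cluster_effect_vector <- function(spec) {
  geom <- spec$geometry
  effect <- numeric(geom$p)
  if (length(spec$clusters) == 0L)
    return(effect)
  # feature index lookup volume
  idx_vol <- array(NA_integer_, dim = geom$dims)
  idx_vol[geom$coords] <- seq_len(geom$p)
  for (ci in seq_along(spec$clusters)) {
    cl <- spec$clusters[[ci]]
    ctr <- as.numeric(cl$center)
    r <- cl$radius
    sgn <- cl$sign %||% 1
    lo <- pmax(floor(ctr - r), 1)
    hi <- pmin(ceiling(ctr + r), geom$dims)
    g <- expand.grid(x = lo[1]:hi[1], y = lo[2]:hi[2], z = lo[3]:hi[3])
    d2 <- (g$x - ctr[1])^2 + (g$y - ctr[2])^2 + (g$z - ctr[3])^2
    inside <- d2 <= r^2
    if (!any(inside))
      stop(sprintf("cluster %d contains no voxels", ci))
    vox <- as.matrix(g[inside, , drop = FALSE])
    j <- idx_vol[vox]
    if (anyNA(j))
      stop(sprintf("cluster %d (center %s, radius %g) extends outside the mask",
                   ci, paste(ctr, collapse = ","), r))
    effect[j] <- effect[j] + sgn * cl$delta
  }
  effect
}

#' Generate a synthetic two-class cohort with known ground truth
#'
#' Draws a cohort according to a [synthetic_spec()]: per-voxel noise scales are
#' drawn once, then one smoothed noise volume per subject (class H first, then
#' class D), the class-D expectation shifted by the planted effect vector.
#' Identical specs (including seed) produce bit-identical output.
#'
#' @param spec a [synthetic_spec()].
#' @return A list with elements `cohort` (a [feature_cohort()]) and
#'   `ground_truth` (list with `effect`, length-p true effect vector, and
#'   `support`, the indices where it is nonzero).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  geom <- spec$geometry
  effect <- cluster_effect_vector(spec)
  n_H <- spec$n_per_class[1]
  n_D <- spec$n_per_class[2]
  n <- n_H + n_D

  X <- with_seed(spec$seed, {
    nvox <- prod(geom$dims)
    log_scale <- rnorm(nvox, 0, spec$variance_heterogeneity)
    scale_vol <- array(spec$noise_sd * exp(log_scale), dim = geom$dims)
    rows <- matrix(0, n, geom$p)
    for (i in seq_len(n)) {
      noise <- array(rnorm(nvox), dim = geom$dims) * scale_vol
      noise <- smooth_gaussian_3d(noise, spec$smoothing_fwhm)
      rows[i, ] <- noise[geom$coords]
    }
    rows
  })
  X <- X + spec$baseline
  if (n_D > 0 && any(effect != 0))
    X[(n_H + 1):n, ] <- X[(n_H + 1):n, ] +
      matrix(effect, n_D, geom$p, byrow = TRUE)

  labels <- c(rep("H", n_H), rep("D", n_D))
  list(
    cohort = feature_cohort(X, labels, geometry = geom),
    ground_truth = list(effect = effect, support = which(effect != 0))
  )
}

#' Generate a null cohort (no class signal)
#'
#' Equivalent to [generate_cohort()] with an empty cluster list: both classes
#' are draws from the same distribution, so any apparent class separation is
#' sampling noise. Used to demonstrate the optimistic bias of non-nested
#' feature selection.
#'
#' @param geometry a [volume_geometry()].
#' @param n_per_class integer length-2 `c(n_H, n_D)`.
#' @param noise_sd,smoothing_fwhm,variance_heterogeneity,baseline,seed as in
#'   [synthetic_spec()].
#' @return A [feature_cohort()].
#' @export
generate_null_cohort <- function(geometry, n_per_class = c(20, 20),
                                 noise_sd = 1, smoothing_fwhm = 3,
                                 variance_heterogeneity = 0.2,
                                 baseline = 0, seed = 1L) {
  spec <- synthetic_spec(geometry, n_per_class = n_per_class,
                         clusters = list(), noise_sd = noise_sd,
                         smoothing_fwhm = smoothing_fwhm,
                         variance_heterogeneity = variance_heterogeneity,
                         baseline = baseline, seed = seed)
  generate_cohort(spec)$cohort
}
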