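# Deterministic seed fan-out: a root seed pre-draws one child seed per unit of
# work (fold, subsample, ...) so serial and parallel execution agree bit for
# bit. Child seeds stay below 2^31 - 1.
draw_child_seeds <- function(root_seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(root_seed))
  sample.int(.Machine$integer.max - 1L, n)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Gaussian kernel with sigma in voxels, truncated at 3 sigma, renormalized.
gaussian_kernel_1d <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

# Separable 3-D Gaussian smoothing by shift-and-add along each axis with zero
# padding (values beyond the grid contribute 0, matching convolution of a
# zero-extended field). FWHM is in voxels; sigma = FWHM / 2.3548.
smooth_gaussian_3d <- function(vol, fwhm) {
  if (fwhm <= 0) return(vol)
  sigma <- fwhm / 2.3548
  k <- gaussian_kernel_1d(sigma)
  r <- (length(k) - 1L) / 2L
  if (r == 0L) return(vol)
  d <- dim(vol)
  for (axis in 1:3) {
    out <- array(0, dim = d)
    n <- d[axis]
    for (t in seq(-r, r)) {
      w <- k[t + r + 1L]
      src <- seq_len(n) + t
      keep <- src >= 1L & src <= n
      if (!any(keep)) next
      dst <- seq_len(n)[keep]
      src <- src[keep]
      if (axis == 1L) {
        out[dst, , ] <- out[dst, , ] + w * vol[src, , ]
      } else if (axis == 2L) {
        out[, dst, ] <- out[, dst, ] + w * vol[, src, ]
      } else {
        out[, , dst] <- out[, , dst] + w * vol[, , src]
      }
    }
    vol <- out
  }
  vol
}

`%||%` <- function(a, b) if (is.null(a)) b else a
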