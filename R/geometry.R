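#' Volume geometry: a brain mask and its voxel-to-feature mapping
#'
#' A `volume_geometry` ties a binary 3-D mask to a fixed linearization of its
#' in-mask voxels: feature `j` is the j-th in-mask voxel when voxel coordinates
#' `(x, y, z)` are ordered row-major (x slowest, z fastest). Every feature
#' matrix, direction vector, selection profile and weight map in the package is
#' indexed by this order, so volumes and flat feature vectors can be converted
#' back and forth without ambiguity.
#'
#' @param mask logical (or 0/1) 3-D array; `TRUE` marks in-brain voxels.
#' @param voxel_size numeric length-3, voxel edge lengths in mm.
#'
#' @return An object of class `volume_geometry` with elements `dims`,
#'   `voxel_size`, `mask`, `coords` (p x 3 integer matrix, 1-based voxel
#'   coordinates of features in feature order) and `p` (number of features).
#' @examples
#' mask <- array(TRUE, dim = c(2, 2, 2))
#' geom <- volume_geometry(mask)
#' geom$p
#' @export
volume_geometry <- function(mask, voxel_size = c(1, 1, 1)) {
  if (length(dim(mask)) != 3L)
    stop("`mask` must be a 3-D array")
  storage.mode(mask) <- "logical"
  mask[is.na(mask)] <- FALSE
  p <- sum(mask)
  if (p == 0L)
    stop("empty mask: no in-mask voxels, p = 0")
  coords <- which(mask, arr.ind = TRUE)
  dimnames(coords) <- NULL
  # row-major over (x, y, z): x slowest, z fastest
  ord <- order(coords[, 1L], coords[, 2L], coords[, 3L])
  coords <- coords[ord, , drop = FALSE]
  structure(
    list(
      dims = dim(mask),
      voxel_size = as.numeric(voxel_size),
      mask = mask,
      coords = coords,
      p = p
    ),
    class = "volume_geometry"
  )
}

#' @export
print.volume_geometry <- function(x, ...) {
  cat(sprintf(
    "<volume_geometry> %d x %d x %d grid, %d in-mask features, voxel %s mm\n",
    x$dims[1], x$dims[2], x$dims[3], x$p,
    paste(format(x$voxel_size), collapse = " x ")
  ))
  invisible(x)
}

#' An ellipsoidal mask on a cubic grid
#'
#' Convenience constructor for the desk-scale default geometry: an ellipsoid
#' inscribed in a `dims` grid, with semi-axes `semiaxes` (voxels) about the
#' grid centre. With the defaults it yields roughly 4,600 in-mask features.
#'
#' @param dims integer length-3 grid size.
#' @param semiaxes numeric length-3 ellipsoid semi-axes in voxels; default
#'   scales to 85% of the half-grid.
#' @param voxel_size voxel edge lengths in mm.
#' @return A [volume_geometry()].
#' @export
ellipsoid_geometry <- function(dims = c(24, 24, 24),
                               semiaxes = (dims - 1) / 2 * 0.85,
                               voxel_size = c(1, 1, 1)) {
  ctr <- (dims + 1) / 2
  g <- expand.grid(x = seq_len(dims[1]), y = seq_len(dims[2]), z = seq_len(dims[3]))
  r2 <- ((g$x - ctr[1]) / semiaxes[1])^2 +
    ((g$y - ctr[2]) / semiaxes[2])^2 +
    ((g$z - ctr[3]) / semiaxes[3])^2
  mask <- array(r2 <= 1, dim = dims)
  volume_geometry(mask, voxel_size = voxel_size)
}

#' Rectangular (all-true) mask geometry
#'
#' @param dims integer length-3 grid size; all voxels are in-mask, so
#'   `p = prod(dims)`.
#' @param voxel_size voxel edge lengths in mm.
#' @return A [volume_geometry()].
#' @export
box_geometry <- function(dims, voxel_size = c(1, 1, 1)) {
  volume_geometry(array(TRUE, dim = dims), voxel_size = voxel_size)
}

#' Flatten volumes to feature-matrix rows
#'
#' Extracts the in-mask voxels of each volume in canonical feature order and
#' stacks them as rows of a matrix, the reverse of [matrix_to_volume()].
#'
#' @param volumes a single 3-D array or a list of 3-D arrays, all matching
#'   `geometry$dims`.
#' @param geometry a [volume_geometry()].
#' @return numeric matrix with one row per volume and `geometry$p` columns.
#' @export
volumes_to_matrix <- function(volumes, geometry) {
  if (is.array(volumes) && length(dim(volumes)) == 3L)
    volumes <- list(volumes)
  idx <- geometry$coords
  rows <- lapply(seq_along(volumes), function(i) {
    v <- volumes[[i]]
    if (!identical(dim(v), as.integer(geometry$dims)))
      stop(sprintf("volume %d has dims (%s), expected (%s)", i,
                   paste(dim(v), collapse = ","),
                   paste(geometry$dims, collapse = ",")))
    v[idx]
  })
  out <- do.call(rbind, rows)
  dimnames(out) <- NULL
  out
}

#' Restore a feature vector to a 3-D volume
#'
#' @param values numeric length-`p` vector in feature order.
#' @param geometry a [volume_geometry()].
#' @param background value written at out-of-mask voxels (0 or NA).
#' @return 3-D array of `geometry$dims`.
#' @export
matrix_to_volume <- function(values, geometry, background = 0) {
  if (length(values) != geometry$p)
    stop(sprintf("length(values) = %d but geometry has p = %d",
                 length(values), geometry$p))
  vol <- array(background, dim = geometry$dims)
  vol[geometry$coords] <- values
  vol
}
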