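#' Read a cohort from NIfTI volumes, a labels table and a brain mask
#'
#' Loads one NIfTI volume per subject, applies the binary mask and flattens
#' the in-mask voxels in canonical feature order into an `n x p` matrix.
#' Labels are read from a two-column CSV (`subject_id,label`) and mapped to
#' `{"H", "D"}` through `label_map`; a volume file `<subject_id>.nii` (or
#' `.nii.gz`) must exist for every subject.
#'
#' @param volume_dir directory containing one NIfTI file per subject.
#' @param labels_csv path to a CSV with columns `subject_id` and `label`.
#' @param mask_path path to a NIfTI binary mask with the same dims as the
#'   volumes.
#' @param label_map named character vector mapping label values in the CSV to
#'   `"H"`/`"D"`.
#' @return A list: `cohort` (a [feature_cohort()]) and `geometry`
#'   (the [volume_geometry()] built from the mask).
#' @export
read_cohort <- function(volume_dir, labels_csv, mask_path,
                        label_map = c(H = "H", D = "D")) {
  mask_img <- RNifti::readNifti(mask_path)
  mask <- array(as.logical(mask_img > 0), dim = dim(mask_img))
  pix <- RNifti::pixdim(mask_img)
  geometry <- volume_geometry(mask, voxel_size = pix[seq_len(3)])

  tab <- read.csv(labels_csv, stringsAsFactors = FALSE)
  if (!all(c("subject_id", "label") %in% names(tab)))
    stop("labels CSV must have columns subject_id and label")
  mapped <- unname(label_map[as.character(tab$label)])
  bad <- which(is.na(mapped) | !mapped %in% c("H", "D"))
  if (length(bad))
    stop(sprintf("row %d of the labels table has label \"%s\" outside the H/D mapping",
                 bad[1], tab$label[bad[1]]))

  volumes <- lapply(seq_len(nrow(tab)), function(i) {
    base <- file.path(volume_dir, tab$subject_id[i])
    fn <- paste0(base, c(".nii", ".nii.gz"))
    fn <- fn[file.exists(fn)]
    if (length(fn) == 0L)
      stop(sprintf("missing volume for subject \"%s\" in %s",
                   tab$subject_id[i], volume_dir))
    img <- RNifti::readNifti(fn[1])
    arr <- array(as.numeric(img), dim = dim(img))
    if (!identical(dim(arr), as.integer(geometry$dims)))
      stop(sprintf("volume for subject \"%s\" has dims (%s), mask has (%s)",
                   tab$subject_id[i], paste(dim(arr), collapse = ","),
                   paste(geometry$dims, collapse = ",")))
    arr
  })
  X <- volumes_to_matrix(volumes, geometry)
  list(cohort = feature_cohort(X, mapped, geometry = geometry,
                               subject_ids = as.character(tab$subject_id)),
       geometry = geometry)
}

#' Write a per-feature map as a NIfTI volume
#'
#' Expands a length-p feature vector (selection counts, selection
#' probabilities, mean discriminative weights, ...) to a full 3-D volume in
#' the geometry's grid, with out-of-mask voxels set to `background`, and
#' writes it as NIfTI. Reading the file back and re-masking restores the
#' in-mask values exactly (up to float storage precision; use
#' `datatype = "double"` for exact round trips).
#'
#' @param values numeric length-`geometry$p` vector in feature order.
#' @param geometry a [volume_geometry()].
#' @param path output file path (`.nii` or `.nii.gz`).
#' @param background value at out-of-mask voxels (0 or NA).
#' @param datatype NIfTI storage datatype (see [RNifti::writeNifti()]).
#' @return the path, invisibly.
#' @export
write_map <- function(values, geometry, path, background = 0,
                      datatype = "double") {
  vol <- matrix_to_volume(values, geometry, background = background)
  img <- RNifti::asNifti(vol)
  RNifti::pixdim(img) <- geometry$voxel_size
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Write a cohort as NIfTI volumes plus labels CSV
#'
#' The inverse of [read_cohort()]: one volume per subject (out-of-mask voxels
#' 0), a mask volume, and `labels.csv` with `subject_id,label`. Useful for
#' exporting synthetic cohorts to tools expecting imaging input.
#'
#' @param cohort a [feature_cohort()] carrying a geometry.
#' @param dir output directory (created if needed).
#' @param datatype NIfTI storage datatype.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, datatype = "double") {
  geometry <- cohort$geometry
  if (is.null(geometry))
    stop("cohort carries no geometry; cannot write volumes")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(nrow(cohort$X)))
    write_map(cohort$X[i, ], geometry,
              file.path(dir, paste0(cohort$subject_ids[i], ".nii.gz")),
              datatype = datatype)
  mask_img <- RNifti::asNifti(array(as.integer(geometry$mask),
                                    dim = geometry$dims))
  RNifti::pixdim(mask_img) <- geometry$voxel_size
  RNifti::writeNifti(mask_img, file.path(dir, "mask.nii.gz"),
                     datatype = "int16")
  write.csv(data.frame(subject_id = cohort$subject_ids,
                       label = as.character(cohort$labels)),
            file.path(dir, "labels.csv"), row.names = FALSE)
  invisible(dir)
}
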