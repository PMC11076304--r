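# Pick n voxel positions forming a compact disc around the slice centre.
# Returned in ascending linear-index order so that writing values and
# reading them back by which(mask > 0) preserves the value order exactly.
disc_indices <- function(nx, ny, n) {
  cx <- (nx + 1) / 2
  cy <- (ny + 1) / 2
  xs <- rep(seq_len(nx), times = ny)
  ys <- rep(seq_len(ny), each = nx)
  d2 <- (xs - cx)^2 + (ys - cy)^2
  ord <- order(d2, seq_along(d2))
  sort(ord[seq_len(n)])
}

#' Generate a digital phantom volume with ground truth
#'
#' Builds a 3-D HU volume and ROI label mask realizing a synthetic cohort:
#' each (lesion, slice) sample occupies one axial slice of the grid as a
#' compact disc of ROI voxels over a lung-like background. The returned
#' truth table holds the exact voxel values placed in each slice, so
#' [extract_slice_stats()] on the phantom must reproduce the truth-table
#' statistics exactly (the round-trip oracle for the extraction code).
#'
#' @param spec a [cohort_spec()].
#' @param grid_shape integer triple `c(nx, ny, nz)`; `nz` must be at least
#'   the total number of slices in the cohort and `nx * ny` at least the
#'   largest per-slice voxel count.
#' @param slice_thickness_mm axial voxel size in mm (metadata only).
#' @param background_hu HU value outside all ROIs (default -800, aerated
#'   lung).
#' @return A list of class `ct_phantom`: `hu_volume` (integer array),
#'   `roi_mask` (integer array, 0 = background, k = k-th lesion),
#'   `truth_table` (`slice_samples` with `slice_index` set to the 0-based
#'   volume slice), `truth_stats` (its [slice_stats()]), `lesion_ids`
#'   (label -> lesion id), `slice_thickness_mm`.
#' @export
generate_phantom <- function(spec, grid_shape = NULL, slice_thickness_mm = 3,
                             background_hu = -800L) {
  samples <- generate_cohort(spec)
  n_samp <- nrow(samples)
  max_vox <- max(lengths(samples$hu_values))
  if (is.null(grid_shape)) {
    side <- ceiling(sqrt(max_vox)) + 2L
    grid_shape <- c(side, side, n_samp)
  }
  if (length(grid_shape) != 3 || any(grid_shape < 1)) {
    abort("grid_shape: must be a positive integer triple")
  }
  nx <- grid_shape[1]; ny <- grid_shape[2]; nz <- grid_shape[3]
  if (n_samp > nz) {
    abort(sprintf("grid too small: %d lesion slices need nz >= %d (got %d)",
                  n_samp, n_samp, nz), "lunghist_sizing_error")
  }
  if (max_vox > nx * ny) {
    abort(sprintf("grid too small: a slice ROI of %d voxels does not fit in a %dx%d plane",
                  max_vox, nx, ny), "lunghist_sizing_error")
  }

  vol <- array(as.integer(background_hu), dim = c(nx, ny, nz))
  mask <- array(0L, dim = c(nx, ny, nz))
  lesion_ids <- unique(samples$lesion_id)
  labels <- match(samples$lesion_id, lesion_ids)
  for (i in seq_len(n_samp)) {
    v <- samples$hu_values[[i]]
    sel <- disc_indices(nx, ny, length(v))
    plane <- vol[, , i]
    plane[sel] <- v
    vol[, , i] <- plane
    mplane <- mask[, , i]
    mplane[sel] <- labels[i]
    mask[, , i] <- mplane
  }
  truth <- samples
  truth$slice_index <- seq_len(n_samp) - 1L

  structure(list(hu_volume = vol, roi_mask = mask,
                 truth_table = truth, truth_stats = slice_stats(truth),
                 lesion_ids = lesion_ids,
                 slice_thickness_mm = slice_thickness_mm),
            class = "ct_phantom")
}

#' Binary mask of one lesion in a phantom
#'
#' @param phantom a `ct_phantom`.
#' @param lesion_id one of `phantom$lesion_ids`.
#' @return An integer 0/1 array of the phantom grid.
#' @export
lesion_mask <- function(phantom, lesion_id) {
  lab <- match(lesion_id, phantom$lesion_ids)
  if (is.na(lab)) abort(sprintf("lesion_id: '%s' not present in phantom", lesion_id))
  array(as.integer(phantom$roi_mask == lab), dim = dim(phantom$roi_mask))
}

#' Write a phantom as NIfTI volume plus per-lesion binary masks
#'
#' Writes `volume.nii.gz` and one `mask_<lesion_id>.nii.gz` per lesion
#' (one lesion per mask file), all on the same grid with the phantom's
#' slice thickness in the affine pixdim.
#'
#' @param phantom a `ct_phantom`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_phantom_nifti <- function(phantom, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pd <- c(1, 1, phantom$slice_thickness_mm)
  vol_path <- file.path(dir, "volume.nii.gz")
  img <- RNifti::asNifti(phantom$hu_volume)
  RNifti::pixdim(img) <- pd
  RNifti::writeNifti(img, vol_path)
  paths <- vol_path
  for (id in phantom$lesion_ids) {
    m <- RNifti::asNifti(lesion_mask(phantom, id))
    RNifti::pixdim(m) <- pd
    p <- file.path(dir, sprintf("mask_%s.nii.gz", id))
    RNifti::writeNifti(m, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
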