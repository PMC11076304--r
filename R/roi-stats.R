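STATS_CSV_COLUMNS <- c("lesion_id", "group", "slice_index", "n_voxels",
                       "mean_hu", "min_hu", "max_hu", "sd_hu")

#' Convert stored CT values to Hounsfield units
#'
#' Applies the linear rescale `HU = stored * slope + intercept` used by CT
#' DICOM (RescaleSlope / RescaleIntercept) and by the NIfTI scl fields.
#'
#' @param stored numeric stored pixel values.
#' @param slope,intercept rescale parameters.
#' @return Numeric HU values.
#' @examples
#' stored_to_hu(1024, slope = 1, intercept = -1024)  # 0 HU
#' @export
stored_to_hu <- function(stored, slope = 1, intercept = 0) {
  stored * slope + intercept
}

#' Load a CT volume and co-registered ROI mask from NIfTI
#'
#' Reads a CT volume and a binary ROI mask on the same voxel grid. NIfTI
#' scl_slope / scl_inter rescaling is applied so the returned volume is in
#' true Hounsfield units. Any positive mask value counts as ROI (0/1 and
#' 0/255 dialects both work), but a mask with more than one distinct
#' positive value is rejected: one lesion per mask file.
#'
#' @param ct_path path to the CT volume (.nii / .nii.gz).
#' @param mask_path path to the ROI mask on the same grid.
#' @return A list: `hu_volume` (numeric array, HU), `roi_mask` (logical
#'   array), `metadata` (list with `kvp`, `slice_thickness_mm`,
#'   `modality`).
#' @export
load_ct_and_mask <- function(ct_path, mask_path) {
  img <- RNifti::readNifti(ct_path)
  msk <- RNifti::readNifti(mask_path)
  if (!identical(dim(img), dim(msk))) {
    abort(sprintf("mask grid (%s) does not match volume grid (%s)",
                  paste(dim(msk), collapse = "x"),
                  paste(dim(img), collapse = "x")),
          "lunghist_alignment_error")
  }
  hdr <- RNifti::niftiHeader(img)
  vol <- as.array(img)
  slope <- hdr$scl_slope
  inter <- hdr$scl_inter
  if (is.finite(slope) && slope != 0 && (slope != 1 || inter != 0)) {
    vol <- stored_to_hu(vol, slope, inter)
  }
  mvals <- as.array(msk)
  if (any(!is.finite(mvals)) || any(mvals < 0)) {
    abort("mask: values must be finite and non-negative")
  }
  pos <- unique(mvals[mvals > 0])
  if (length(pos) > 1) {
    abort(sprintf("mask: not binary (%d distinct positive values)", length(pos)))
  }
  pd <- RNifti::pixdim(img)
  list(hu_volume = vol,
       roi_mask = mvals > 0,
       metadata = list(kvp = NA_real_,
                       slice_thickness_mm = if (length(pd) >= 3) pd[3] else NA_real_,
                       modality = "CT"))
}

#' Extract per-slice ROI statistics from a volume and mask
#'
#' For every axial slice (third array axis, 0-based `slice_index`) with at
#' least one ROI voxel, records the mean, minimum, maximum and sample
#' standard deviation (divisor n - 1; 0 when the slice has one voxel) of
#' the HU values under the mask. Any positive mask value counts as ROI; a
#' voxel is in or out, with no partial-volume weighting.
#'
#' @param hu_volume 3-D numeric array in HU.
#' @param roi_mask 3-D array on the same grid; positive values mark the ROI.
#' @param lesion_id identifier recorded on every row.
#' @param group one of `"benign"`, `"malignant"`, `"unknown"`.
#' @return A `slice_stats` data frame ordered by `slice_index`.
#' @export
extract_slice_stats <- function(hu_volume, roi_mask,
                                lesion_id = "lesion", group = "unknown") {
  if (!identical(dim(hu_volume), dim(roi_mask))) {
    abort("roi_mask: grid does not match hu_volume", "lunghist_alignment_error")
  }
  if (length(dim(hu_volume)) != 3) abort("hu_volume: expected a 3-D array")
  group <- match.arg(group, c(GROUPS, "unknown"))
  if (!any(roi_mask > 0)) {
    abort("roi_mask: no ROI voxels anywhere in the volume", "lunghist_empty_roi_error")
  }
  nz <- dim(hu_volume)[3]
  rows <- vector("list", nz)
  for (z in seq_len(nz)) {
    sel <- which(roi_mask[, , z] > 0)
    if (length(sel) == 0) next
    v <- as.numeric(hu_volume[, , z][sel])
    rows[[z]] <- data.frame(
      lesion_id = lesion_id, group = group, slice_index = z - 1L,
      n_voxels = length(v), mean_hu = mean(v),
      min_hu = min(v), max_hu = max(v),
      sd_hu = if (length(v) > 1) sd(v) else 0,
      stringsAsFactors = FALSE)
  }
  new_slice_stats(do.call(rbind, rows[!vapply(rows, is.null, TRUE)]))
}

fmt_sig6 <- function(x) {
  vapply(x, function(v) format(signif(v, 6), trim = TRUE, scientific = FALSE), "")
}

#' Read and write the per-slice statistics interchange CSV
#'
#' The interchange format has the exact header
#' `lesion_id,group,slice_index,n_voxels,mean_hu,min_hu,max_hu,sd_hu`.
#' Real-valued columns (`mean_hu`, `sd_hu`) are serialized with 6
#' significant digits; `min_hu` / `max_hu` are integers on the HU scale.
#' Reading validates the schema (a missing column is an error naming the
#' column) and each row (`min_hu > max_hu` is an error naming the row).
#'
#' @param path CSV file path.
#' @return `read_stats_csv()`: a `slice_stats` data frame.
#' @export
read_stats_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(STATS_CSV_COLUMNS, names(df))
  if (length(missing) > 0) {
    abort(sprintf("stats CSV schema: missing column(s) %s",
                  paste(sprintf("'%s'", missing), collapse = ", ")),
          "lunghist_schema_error")
  }
  df <- df[STATS_CSV_COLUMNS]
  df$lesion_id <- as.character(df$lesion_id)
  df$group <- as.character(df$group)
  check_groups(df, allow_unknown = TRUE)
  bad <- which(df$min_hu > df$max_hu)
  if (length(bad) > 0) {
    abort(sprintf("stats CSV row %d: min_hu (%g) exceeds max_hu (%g)",
                  bad[1], df$min_hu[bad[1]], df$max_hu[bad[1]]))
  }
  bad <- which(df$n_voxels < 1 | df$sd_hu < 0)
  if (length(bad) > 0) {
    abort(sprintf("stats CSV row %d: n_voxels must be >= 1 and sd_hu >= 0", bad[1]))
  }
  new_slice_stats(df)
}

#' @rdname read_stats_csv
#' @param records a `slice_stats` data frame.
#' @export
write_stats_csv <- function(records, path) {
  out <- data.frame(
    lesion_id = records$lesion_id,
    group = records$group,
    slice_index = as.integer(records$slice_index),
    n_voxels = as.integer(records$n_voxels),
    mean_hu = fmt_sig6(records$mean_hu),
    min_hu = as.integer(round(records$min_hu)),
    max_hu = as.integer(round(records$max_hu)),
    sd_hu = fmt_sig6(records$sd_hu),
    stringsAsFactors = FALSE)
  write.table(out, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}
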