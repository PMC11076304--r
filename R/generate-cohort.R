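# Truncated normal via inverse-CDF sampling; exact, no rejection loop.
# Degenerate sd = 0 collapses to the (clipped) mean.
rnorm_trunc <- function(n, mean, sd, lo, hi) {
  if (n == 0) return(numeric(0))
  if (sd <= 0) return(rep(min(max(mean, lo), hi), n))
  plo <- pnorm(lo, mean, sd)
  phi <- pnorm(hi, mean, sd)
  x <- qnorm(runif(n, plo, phi), mean, sd)
  pmin(pmax(x, lo), hi)
}

runif_interval <- function(n, interval) {
  if (interval[1] == interval[2]) rep(interval[1], n)
  else runif(n, interval[1], interval[2])
}

sample_int_interval <- function(n, interval) {
  if (interval[1] == interval[2]) rep(as.integer(interval[1]), n)
  else sample(seq.int(interval[1], interval[2]), n, replace = TRUE)
}

# Lesion-level draws: one row per lesion, parameters shared by its slices.
lesion_table <- function(spec) {
  nb <- spec$n_lesions_benign
  nm <- spec$n_lesions_malignant
  ids <- c(sprintf("B%02d", seq_len(nb)), sprintf("M%02d", seq_len(nm)))
  group <- rep(GROUPS, c(nb, nm))

  # Draw both mixture components up front so the RNG stream does not depend
  # on the component assignment.
  low_comp <- runif(nb) < spec$benign_mean_hu$weight_low
  lows <- runif_interval(nb, spec$benign_mean_hu$low)
  highs <- runif_interval(nb, spec$benign_mean_hu$high)
  benign_means <- ifelse(low_comp, lows, highs)

  data.frame(
    lesion_id = ids,
    group = group,
    lesion_mean = c(benign_means,
                    runif_interval(nm, spec$malignant_mean_hu)),
    within_sd = c(runif_interval(nb, spec$benign_within_slice_sd),
                  runif_interval(nm, spec$malignant_within_slice_sd)),
    n_slices = sample_int_interval(nb + nm, spec$slices_per_lesion),
    stringsAsFactors = FALSE)
}

# One slice's ROI voxel values: a truncated-normal core around the slice
# mean plus uniform low/high contamination tails, rounded to integer HU and
# clipped to the physical CT range.
make_slice_values <- function(n_vox, slice_mean, within_sd, tail) {
  u <- runif(n_vox)
  n_lo <- sum(u < tail$frac_low)
  n_hi <- sum(u >= tail$frac_low & u < tail$frac_low + tail$frac_high)
  n_core <- n_vox - n_lo - n_hi
  vals <- c(
    rnorm_trunc(n_core, slice_mean, within_sd, tail$hu_range[1], tail$hu_range[2]),
    runif_interval(n_lo, tail$low_range),
    runif_interval(n_hi, tail$high_range))
  as.integer(pmin(pmax(round(vals), HU_MIN), HU_MAX))
}

#' Generate a synthetic per-slice ROI cohort
#'
#' Draws a two-group cohort of lesions according to a [cohort_spec()]. Each
#' lesion's mean HU location and within-slice SD are drawn once and shared
#' across its slices; each slice then gets a jittered slice mean and a set
#' of integer HU voxel values (truncated-normal core plus tail
#' contamination, see [default_tail_model()]).
#'
#' @param spec a [cohort_spec()].
#' @return A data frame of class `slice_samples` with one row per
#'   (lesion, slice): columns `lesion_id`, `group`, `slice_index` (0-based
#'   within lesion), and the list-column `hu_values` (integer HU vectors).
#' @examples
#' spec <- cohort_spec(n_lesions_benign = 2, n_lesions_malignant = 2,
#'                     slices_per_lesion = c(3, 3),
#'                     voxels_per_slice = c(20, 30), seed = 42)
#' samples <- generate_cohort(spec)
#' nrow(samples)  # 12 slices
#' @export
generate_cohort <- function(spec) {
  validate_cohort_spec(spec)
  withr::with_seed(as.integer(spec$seed), {
    lesions <- lesion_table(spec)
    out <- vector("list", sum(lesions$n_slices))
    k <- 0L
    for (i in seq_len(nrow(lesions))) {
      les <- lesions[i, ]
      tail <- spec$tail_model[[les$group]]
      n_vox <- sample_int_interval(les$n_slices, spec$voxels_per_slice)
      for (s in seq_len(les$n_slices)) {
        slice_mean <- les$lesion_mean + rnorm(1, 0, spec$slice_jitter_sd)
        k <- k + 1L
        out[[k]] <- list(
          lesion_id = les$lesion_id, group = les$group,
          slice_index = s - 1L,
          hu_values = make_slice_values(n_vox[s], slice_mean,
                                        les$within_sd, tail))
      }
    }
    samples <- data.frame(
      lesion_id = vapply(out, `[[`, "", "lesion_id"),
      group = vapply(out, `[[`, "", "group"),
      slice_index = vapply(out, `[[`, 0L, "slice_index"),
      stringsAsFactors = FALSE)
    samples$hu_values <- lapply(out, `[[`, "hu_values")
    class(samples) <- c("slice_samples", "data.frame")
    samples
  })
}

#' Per-slice ROI statistics from raw samples
#'
#' Reduces each slice's HU voxel values to the four recorded first-order
#' statistics: mean, minimum, maximum and sample standard deviation
#' (divisor n - 1; defined as 0 when a slice has a single voxel).
#'
#' @param samples a `slice_samples` data frame from [generate_cohort()] or
#'   a phantom truth table.
#' @return A `slice_stats` data frame with the interchange columns
#'   `lesion_id, group, slice_index, n_voxels, mean_hu, min_hu, max_hu,
#'   sd_hu`.
#' @export
slice_stats <- function(samples) {
  if (!is.data.frame(samples) || is.null(samples$hu_values)) {
    abort("samples: expected a slice_samples data frame with a hu_values column")
  }
  vals <- samples$hu_values
  new_slice_stats(data.frame(
    lesion_id = samples$lesion_id,
    group = samples$group,
    slice_index = samples$slice_index,
    n_voxels = lengths(vals),
    mean_hu = vapply(vals, function(v) mean(as.numeric(v)), 0),
    min_hu = vapply(vals, function(v) as.numeric(min(v)), 0),
    max_hu = vapply(vals, function(v) as.numeric(max(v)), 0),
    sd_hu = vapply(vals, function(v) if (length(v) > 1) sd(as.numeric(v)) else 0, 0),
    stringsAsFactors = FALSE))
}

new_slice_stats <- function(df) {
  rownames(df) <- NULL
  class(df) <- c("slice_stats", "data.frame")
  df
}

#' Write raw cohort samples to a long-format CSV
#'
#' One row per voxel with columns `lesion_id,group,slice_index,hu`.
#'
#' @param samples a `slice_samples` data frame.
#' @param path output file path.
#' @export
write_samples_csv <- function(samples, path) {
  long <- data.frame(
    lesion_id = rep(samples$lesion_id, lengths(samples$hu_values)),
    group = rep(samples$group, lengths(samples$hu_values)),
    slice_index = rep(samples$slice_index, lengths(samples$hu_values)),
    hu = unlist(samples$hu_values),
    stringsAsFactors = FALSE)
  write.table(long, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}
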