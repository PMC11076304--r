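#' Default per-group tail model for the synthetic cohort
#'
#' The tail model controls how extreme the minimum and maximum HU values of
#' each group's ROIs can become. Each group carries a truncation range for
#' the core (truncated-normal) voxel distribution plus optional low/high
#' contamination components drawn uniformly from fixed HU ranges.
#'
#' Defaults emulate the contrast the analysis relies on: benign lesions are
#' heterogeneous, with air-like/necrotic low tails reaching below -30 HU and
#' fibrocalcific high tails exceeding 100-150 HU, while malignant
#' soft-tissue lesions are compact, with voxel values confined to roughly
#' \[-25, 115\] HU so that per-slice minima sit near \[-20, 0\] and maxima
#' near \[90, 110\].
#'
#' @param benign,malignant lists with elements `frac_low`, `low_range`,
#'   `frac_high`, `high_range`, `hu_range` (core truncation bounds).
#' @return A list with components `benign` and `malignant`.
#' @export
default_tail_model <- function(
    benign = list(frac_low = 0.02, low_range = c(-300, -50),
                  frac_high = 0.02, high_range = c(120, 400),
                  hu_range = c(HU_MIN, HU_MAX)),
    malignant = list(frac_low = 0, low_range = c(-300, -50),
                     frac_high = 0, high_range = c(120, 400),
                     hu_range = c(-25, 115))) {
  list(benign = benign, malignant = malignant)
}

#' Specify a synthetic two-group lesion cohort
#'
#' Defines the statistical structure of a simulated cohort of benign and
#' malignant lung lesions measured slice-by-slice on unenhanced CT. The
#' generator is hierarchical: lesion-level parameters (mean HU location and
#' within-slice SD) are drawn once per lesion, then per-slice values are
#' drawn around them, because the slice is the analysis unit but the lesion
#' is the clinical unit.
#'
#' Defaults emulate a 20-lesion cohort (10 benign, 10 malignant) producing
#' roughly 430 slice records: malignant per-slice mean HU clusters inside
#' \[30, 50\]; benign lesion means fall outside that window (a bimodal
#' mixture below 30 and above 50); benign within-slice SD exceeds malignant
#' SD; benign tails reach below -30 and above 120 HU (see
#' [default_tail_model()]).
#'
#' @param n_lesions_benign,n_lesions_malignant lesion counts per group.
#' @param slices_per_lesion integer interval `c(lo, hi)`; slice count per
#'   lesion is drawn uniformly from it. Default `c(15, 28)` gives an
#'   expected 430 slices for 20 lesions.
#' @param voxels_per_slice integer interval for ROI voxel count per slice.
#' @param malignant_mean_hu HU interval for malignant lesion-level means
#'   (drawn uniformly), default `c(30, 50)`.
#' @param benign_mean_hu list with components `low` and `high` (HU intervals
#'   for the two mixture components placing benign lesion means below 30 and
#'   above 50) and `weight_low` (mixing weight of the low component).
#' @param malignant_within_slice_sd,benign_within_slice_sd HU intervals for
#'   the lesion-level within-slice SD, drawn uniformly.
#' @param slice_jitter_sd SD (HU) of the per-slice shift of the slice mean
#'   around the lesion mean.
#' @param tail_model per-group tail/truncation parameters, see
#'   [default_tail_model()].
#' @param seed integer seed; identical spec + seed reproduces the cohort
#'   byte-for-byte.
#' @return An object of class `cohort_spec`.
#' @seealso [generate_cohort()], [generate_phantom()]
#' @export
cohort_spec <- function(n_lesions_benign = 10L,
                        n_lesions_malignant = 10L,
                        slices_per_lesion = c(15L, 28L),
                        voxels_per_slice = c(100L, 400L),
                        malignant_mean_hu = c(30, 50),
                        benign_mean_hu = list(low = c(-20, 25),
                                              high = c(55, 70),
                                              weight_low = 0.5),
                        malignant_within_slice_sd = c(10, 20),
                        benign_within_slice_sd = c(20, 35),
                        slice_jitter_sd = 2.5,
                        tail_model = default_tail_model(),
                        seed = 1L) {
  spec <- structure(
    list(n_lesions_benign = n_lesions_benign,
         n_lesions_malignant = n_lesions_malignant,
         slices_per_lesion = slices_per_lesion,
         voxels_per_slice = voxels_per_slice,
         malignant_mean_hu = malignant_mean_hu,
         benign_mean_hu = benign_mean_hu,
         malignant_within_slice_sd = malignant_within_slice_sd,
         benign_within_slice_sd = benign_within_slice_sd,
         slice_jitter_sd = slice_jitter_sd,
         tail_model = tail_model,
         seed = seed),
    class = "cohort_spec")
  validate_cohort_spec(spec)
  spec
}

is_count <- function(x) {
  length(x) == 1 && is.numeric(x) && is.finite(x) && x >= 1 && x == round(x)
}

is_interval <- function(x, lo = -Inf, hi = Inf) {
  length(x) == 2 && is.numeric(x) && all(is.finite(x)) &&
    x[1] <= x[2] && x[1] >= lo && x[2] <= hi
}

check_tail_component <- function(tm, group) {
  need <- c("frac_low", "low_range", "frac_high", "high_range", "hu_range")
  if (!is.list(tm) || !all(need %in% names(tm))) {
    abort(sprintf("tail_model$%s: must be a list with elements %s",
                  group, paste(need, collapse = ", ")))
  }
  for (f in c("frac_low", "frac_high")) {
    v <- tm[[f]]
    if (!(length(v) == 1 && is.numeric(v) && is.finite(v) && v >= 0 && v < 1)) {
      abort(sprintf("tail_model$%s$%s: must be a fraction in [0, 1)", group, f))
    }
  }
  for (f in c("low_range", "high_range", "hu_range")) {
    if (!is_interval(tm[[f]], HU_MIN, HU_MAX)) {
      abort(sprintf(
        "tail_model$%s$%s: must be an ordered HU interval within [%d, %d]",
        group, f, HU_MIN, HU_MAX))
    }
  }
  invisible(tm)
}

#' @rdname cohort_spec
#' @param spec a `cohort_spec` object.
#' @export
validate_cohort_spec <- function(spec) {
  if (!inherits(spec, "cohort_spec")) abort("spec: not a cohort_spec object")
  if (!is_count(spec$n_lesions_benign)) {
    abort("n_lesions_benign: must be a single integer >= 1")
  }
  if (!is_count(spec$n_lesions_malignant)) {
    abort("n_lesions_malignant: must be a single integer >= 1")
  }
  for (f in c("slices_per_lesion", "voxels_per_slice")) {
    v <- spec[[f]]
    if (!is_interval(v, 1) || any(v != round(v))) {
      abort(sprintf("%s: must be an integer interval c(lo, hi) with 1 <= lo <= hi", f))
    }
  }
  for (f in c("malignant_mean_hu", "malignant_within_slice_sd",
              "benign_within_slice_sd")) {
    if (!is_interval(spec[[f]], HU_MIN, HU_MAX)) {
      abort(sprintf("%s: must be an ordered HU interval within [%d, %d]",
                    f, HU_MIN, HU_MAX))
    }
  }
  if (spec$malignant_within_slice_sd[1] < 0 || spec$benign_within_slice_sd[1] < 0) {
    abort("within_slice_sd: must be non-negative")
  }
  bm <- spec$benign_mean_hu
  if (!is.list(bm) || !all(c("low", "high", "weight_low") %in% names(bm))) {
    abort("benign_mean_hu: must be a list with elements low, high, weight_low")
  }
  if (!is_interval(bm$low, HU_MIN, HU_MAX) || !is_interval(bm$high, HU_MIN, HU_MAX)) {
    abort("benign_mean_hu: low and high must be ordered HU intervals")
  }
  w <- bm$weight_low
  if (!(length(w) == 1 && is.numeric(w) && is.finite(w) && w >= 0 && w <= 1)) {
    abort("benign_mean_hu$weight_low: must be a weight in [0, 1]")
  }
  j <- spec$slice_jitter_sd
  if (!(length(j) == 1 && is.numeric(j) && is.finite(j) && j >= 0)) {
    abort("slice_jitter_sd: must be a single non-negative number")
  }
  if (!is.list(spec$tail_model) ||
      !all(c("benign", "malignant") %in% names(spec$tail_model))) {
    abort("tail_model: must be a list with components benign and malignant")
  }
  check_tail_component(spec$tail_model$benign, "benign")
  check_tail_component(spec$tail_model$malignant, "malignant")
  s <- spec$seed
  if (!(length(s) == 1 && is.numeric(s) && is.finite(s) && s == round(s))) {
    abort("seed: must be a single integer")
  }
  invisible(spec)
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("Synthetic CT lesion cohort specification\n")
  cat(sprintf("  lesions: %d benign + %d malignant\n",
              x$n_lesions_benign, x$n_lesions_malignant))
  cat(sprintf("  slices/lesion: [%d, %d]; voxels/slice: [%d, %d]\n",
              x$slices_per_lesion[1], x$slices_per_lesion[2],
              x$voxels_per_slice[1], x$voxels_per_slice[2]))
  cat(sprintf("  malignant mean HU: [%g, %g], within-slice SD: [%g, %g]\n",
              x$malignant_mean_hu[1], x$malignant_mean_hu[2],
              x$malignant_within_slice_sd[1], x$malignant_within_slice_sd[2]))
  cat(sprintf("  benign mean HU: [%g, %g] | [%g, %g] (weight low %g), SD: [%g, %g]\n",
              x$benign_mean_hu$low[1], x$benign_mean_hu$low[2],
              x$benign_mean_hu$high[1], x$benign_mean_hu$high[2],
              x$benign_mean_hu$weight_low,
              x$benign_within_slice_sd[1], x$benign_within_slice_sd[2]))
  cat(sprintf("  seed: %d\n", as.integer(x$seed)))
  invisible(x)
}
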