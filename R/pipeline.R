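#' Full histogram analysis of one statistic
#'
#' Convenience wrapper chaining [build_histogram()],
#' [cumulative_distribution()], [find_crossings()],
#' [compute_bin_probabilities()] and [derive_dominance_regions()] for one
#' slice statistic.
#'
#' @inheritParams build_histogram
#' @inheritParams derive_dominance_regions
#' @return A list of class `hu_analysis`: `statistic`, `histograms`,
#'   `curves`, `crossings`, `bins`, `regions`.
#' @export
analyze_statistic <- function(records, statistic = c("mean", "min", "max", "sd"),
                              bin_width = 5, origin = 0, cutoff = 0.9,
                              min_records_per_bin = 3, per_lesion = FALSE) {
  statistic <- match.arg(statistic)
  hists <- build_histogram(records, statistic, bin_width, origin, per_lesion)
  curves <- cumulative_distribution(records, statistic, per_lesion)
  crossings <- find_crossings(curves$benign, curves$malignant)
  bins <- compute_bin_probabilities(hists)
  regions <- derive_dominance_regions(bins, cutoff, min_records_per_bin)
  structure(list(statistic = statistic, histograms = hists, curves = curves,
                 crossings = crossings, bins = bins, regions = regions),
            class = "hu_analysis")
}

#' Derive a candidate rule set from a cohort
#'
#' Runs the per-bin probability analysis on all four statistics and
#' summarizes the dominance regions into a data-derived candidate
#' [threshold_rules()] via [summarize_rule_candidates()].
#'
#' @inheritParams analyze_statistic
#' @param statistics statistics to analyze (the mean is required).
#' @return A `threshold_rules` candidate, with attribute `support`.
#' @export
derive_rules_from_cohort <- function(records, bin_width = 5, origin = 0,
                                     cutoff = 0.9, min_records_per_bin = 3,
                                     statistics = STAT_NAMES) {
  regions <- lapply(statistics, function(s) {
    analyze_statistic(records, s, bin_width, origin, cutoff,
                      min_records_per_bin)$regions
  })
  names(regions) <- statistics
  summarize_rule_candidates(regions)
}

#' @export
print.hu_analysis <- function(x, ...) {
  cat(sprintf("Histogram analysis of the %s HU statistic\n", x$statistic))
  print(x$histograms)
  ncross <- nrow(x$crossings)
  if (ncross > 0) {
    cat(sprintf("  CDF crossings: %s\n",
                paste(sprintf("%.1f HU @ %.1f%%%s", x$crossings$hu,
                              100 * x$crossings$fraction,
                              ifelse(x$crossings$non_unique, " (non-unique)", "")),
                      collapse = "; ")))
  } else {
    cat("  CDF crossings: none\n")
  }
  if (nrow(x$regions) > 0) {
    for (i in seq_len(nrow(x$regions))) {
      r <- x$regions[i, ]
      cat(sprintf("  %s dominance in [%g, %g) HU (%d bins, %d records, min prob %.2f)\n",
                  r$dominant_class, r$hu_lo, r$hu_hi, r$n_bins, r$n_records,
                  r$min_probability))
    }
  } else {
    cat("  no dominance regions at the chosen cutoff\n")
  }
  invisible(x)
}
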