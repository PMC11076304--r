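#' Per-bin class-conditional probabilities
#'
#' For every shared HU bin, counts `Np` (benign records) and `Nq`
#' (malignant records), their total `N = Np + Nq`, and the empirical class
#' probabilities `p = Np / N` and `q = Nq / N` (so `p + q = 1` on every
#' occupied bin). Bins with `N = 0` carry `NA` probabilities and are
#' flagged `empty`. The percentage forms `100 p` / `100 q` are a
#' presentation-layer scaling and are never used in computation.
#'
#' @param hist_benign,hist_malignant `stat_histogram` objects on identical
#'   bin edges and the same statistic (as produced by [build_histogram()]),
#'   or a single `stat_histogram_pair` passed as the first argument.
#' @return A data frame of class `bin_probability` with columns `bin_lo`,
#'   `bin_hi`, `Np`, `Nq`, `N`, `p`, `q`, `empty` and attribute
#'   `statistic`.
#' @export
compute_bin_probabilities <- function(hist_benign, hist_malignant = NULL) {
  if (inherits(hist_benign, "stat_histogram_pair") && is.null(hist_malignant)) {
    hist_malignant <- hist_benign$malignant
    hist_benign <- hist_benign$benign
  }
  if (!inherits(hist_benign, "stat_histogram") ||
      !inherits(hist_malignant, "stat_histogram")) {
    abort("expected stat_histogram inputs")
  }
  if (!identical(hist_benign$statistic, hist_malignant$statistic)) {
    abort("histograms are on different statistics", "lunghist_alignment_error")
  }
  if (!isTRUE(all.equal(hist_benign$bin_edges, hist_malignant$bin_edges))) {
    abort("histograms do not share bin edges", "lunghist_alignment_error")
  }
  edges <- hist_benign$bin_edges
  Np <- hist_benign$counts
  Nq <- hist_malignant$counts
  N <- Np + Nq
  p <- ifelse(N > 0, Np / N, NA_real_)
  q <- ifelse(N > 0, Nq / N, NA_real_)
  out <- data.frame(bin_lo = edges[-length(edges)], bin_hi = edges[-1],
                    Np = Np, Nq = Nq, N = N, p = p, q = q, empty = N == 0)
  attr(out, "statistic") <- hist_benign$statistic
  class(out) <- c("bin_probability", "data.frame")
  out
}

#' Dominance regions of one class over contiguous HU bins
#'
#' A dominance region is a maximal run of consecutive bins on which one
#' class's probability is at least `cutoff` and the bin holds at least
#' `min_records_per_bin` records. Empty bins inside a run are bridged (they
#' do not break the region but contribute no records, no bins and no
#' probability); occupied bins that fail the criterion break the run.
#' Non-monotonic probability profiles therefore yield several regions
#' rather than one forced interval.
#'
#' @param bins a `bin_probability` data frame sorted by `bin_lo`.
#' @param cutoff dominance threshold, in (0.5, 1\]. Default 0.9, the
#'   "greater than 90%" working definition of dominance.
#' @param min_records_per_bin minimum `N` for a bin to qualify (default 3;
#'   set to 1 to let single-record bins define regions).
#' @param bridge_empty whether empty bins inside a run are bridged
#'   (default `TRUE`).
#' @return A data frame of class `dominance_regions` with columns
#'   `statistic`, `dominant_class`, `hu_lo`, `hu_hi`, `min_probability`
#'   (smallest qualifying-bin probability in the region), `n_bins`
#'   (qualifying bins), `n_records`, ordered by `hu_lo`.
#' @export
derive_dominance_regions <- function(bins, cutoff = 0.9,
                                     min_records_per_bin = 3,
                                     bridge_empty = TRUE) {
  if (!inherits(bins, "bin_probability")) {
    abort("bins: expected a bin_probability table")
  }
  if (!(length(cutoff) == 1 && is.finite(cutoff) && cutoff > 0.5 && cutoff <= 1)) {
    abort("cutoff: dominance is undefined at or below 0.5; need 0.5 < cutoff <= 1")
  }
  if (is.unsorted(bins$bin_lo)) abort("bins: must be sorted by bin_lo")
  statistic <- attr(bins, "statistic")

  regions <- list()
  for (cls in GROUPS) {
    prob <- if (cls == "benign") bins$p else bins$q
    qual <- !bins$empty & bins$N >= min_records_per_bin &
      !is.na(prob) & prob >= cutoff
    blocker <- if (bridge_empty) !bins$empty & !qual else !qual
    i <- 1; n <- nrow(bins)
    while (i <= n) {
      if (!qual[i]) { i <- i + 1; next }
      j <- i
      last_qual <- i
      while (j < n && !blocker[j + 1]) {
        j <- j + 1
        if (qual[j]) last_qual <- j
      }
      idx <- which(qual[i:last_qual]) + i - 1
      regions[[length(regions) + 1]] <- data.frame(
        statistic = statistic, dominant_class = cls,
        hu_lo = bins$bin_lo[i], hu_hi = bins$bin_hi[last_qual],
        min_probability = min(prob[idx]),
        n_bins = length(idx), n_records = sum(bins$N[idx]),
        stringsAsFactors = FALSE)
      i <- last_qual + 1
    }
  }
  out <- if (length(regions) == 0) {
    data.frame(statistic = character(0), dominant_class = character(0),
               hu_lo = numeric(0), hu_hi = numeric(0),
               min_probability = numeric(0), n_bins = integer(0),
               n_records = integer(0), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, regions)
  }
  out <- out[order(out$hu_lo), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("dominance_regions", "data.frame")
  out
}

region_span <- function(regions, cls) {
  sel <- regions[regions$dominant_class == cls, , drop = FALSE]
  if (nrow(sel) == 0) return(NULL)
  list(interval = c(min(sel$hu_lo), max(sel$hu_hi)),
       n_records = sum(sel$n_records))
}

#' Summarize dominance regions into a candidate threshold rule set
#'
#' Converts per-statistic dominance regions into a data-derived
#' [threshold_rules()] candidate: the malignant-consistent mean interval is
#' the span of the malignant dominance region(s) of the mean statistic; the
#' maximum-HU upper bound is the lower edge of the topmost benign dominance
#' region of the maximum statistic (above it, benign dominates); the
#' minimum and SD intervals are the spans of the malignant regions of those
#' statistics. Each emitted rule is tagged with its supporting record
#' count. With no malignant mean region the rule set is empty and a
#' warning (not an error) is raised.
#'
#' @param regions_by_stat named list mapping statistic name
#'   (`"mean"`, `"min"`, `"max"`, `"sd"`) to a `dominance_regions` table.
#' @return A `threshold_rules` object with attribute `support` (record
#'   counts behind each rule).
#' @export
summarize_rule_candidates <- function(regions_by_stat) {
  if (!is.list(regions_by_stat) || !("mean" %in% names(regions_by_stat))) {
    abort("regions_by_stat: need at least the 'mean' statistic's regions")
  }
  support <- list()

  mean_span <- region_span(regions_by_stat$mean, "malignant")
  if (is.null(mean_span)) {
    warning("no malignant dominance region for the mean statistic; ",
            "emitting an empty rule set")
    return(threshold_rules(mean = NULL, max_lt = NULL, min = NULL, sd = NULL))
  }
  support$mean <- mean_span$n_records

  max_lt <- NULL
  if (!is.null(regions_by_stat$max)) {
    reg <- regions_by_stat$max
    ben <- reg[reg$dominant_class == "benign", , drop = FALSE]
    mal <- reg[reg$dominant_class == "malignant", , drop = FALSE]
    # the candidate bound is the lower edge of the benign high-HU dominance
    # zone: the first benign region above the malignant max regions
    if (nrow(mal) > 0) ben <- ben[ben$hu_lo >= max(mal$hu_hi), , drop = FALSE]
    if (nrow(ben) > 0) {
      first <- ben[which.min(ben$hu_lo), ]
      max_lt <- first$hu_lo
      support$max <- sum(ben$n_records)
    }
  }
  min_span <- if (!is.null(regions_by_stat$min)) {
    region_span(regions_by_stat$min, "malignant")
  }
  if (!is.null(min_span)) support$min <- min_span$n_records
  sd_span <- if (!is.null(regions_by_stat$sd)) {
    region_span(regions_by_stat$sd, "malignant")
  }
  if (!is.null(sd_span)) support$sd <- sd_span$n_records

  rules <- threshold_rules(
    mean = mean_span$interval,
    max_lt = max_lt,
    min = if (!is.null(min_span)) min_span$interval,
    sd = if (!is.null(sd_span)) sd_span$interval)
  attr(rules, "support") <- support
  rules
}
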