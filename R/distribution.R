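stat_values <- function(records, statistic) {
  records[[stat_column(statistic)]]
}

# Pool slice records into one pseudo-record per lesion (pooled aggregation)
# so the distribution machinery can run at the clinical unit.
lesion_records <- function(records) {
  split_les <- split(seq_len(nrow(records)), records$lesion_id)
  rows <- lapply(names(split_les), function(id) {
    sub <- records[split_les[[id]], , drop = FALSE]
    agg <- aggregate_lesion_stats(sub, mode = "pooled")
    data.frame(lesion_id = id, group = sub$group[1], slice_index = 0L,
               n_voxels = agg$n_voxels, mean_hu = agg$mean_hu,
               min_hu = agg$min_hu, max_hu = agg$max_hu, sd_hu = agg$sd_hu,
               stringsAsFactors = FALSE)
  })
  new_slice_stats(do.call(rbind, rows))
}

new_stat_histogram <- function(statistic, group, bin_edges, counts) {
  structure(list(statistic = statistic, group = group,
                 bin_edges = bin_edges, counts = as.integer(counts),
                 total = sum(as.integer(counts))),
            class = "stat_histogram")
}

#' Per-group histograms of one slice statistic
#'
#' Bins one of the four per-slice statistics for the benign and malignant
#' groups on a shared grid of half-open bins `[e_i, e_{i+1})` aligned to
#' `origin + k * bin_width` and spanning the pooled data range (the last
#' bin is closed at its upper edge; with aligned edges this matters only
#' when the maximum falls exactly on an edge). A shared grid is required
#' downstream by [compute_bin_probabilities()].
#'
#' @param records a `slice_stats` data frame; every record must carry group
#'   `"benign"` or `"malignant"`.
#' @param statistic one of `"mean"`, `"min"`, `"max"`, `"sd"`.
#' @param bin_width bin width in HU (default 5, fine enough to resolve the
#'   30-50 HU malignant window at cohort scale).
#' @param origin alignment origin of the bin grid (default 0).
#' @param per_lesion if `TRUE`, pool records per lesion first and bin the
#'   lesion-level statistics instead of the slice-level ones.
#' @return A list of class `stat_histogram_pair` with components `benign`
#'   and `malignant`, each a `stat_histogram` (fields `statistic`, `group`,
#'   `bin_edges`, `counts`, `total`).
#' @export
build_histogram <- function(records, statistic = c("mean", "min", "max", "sd"),
                            bin_width = 5, origin = 0, per_lesion = FALSE) {
  statistic <- match.arg(statistic)
  if (!is.data.frame(records) || nrow(records) == 0) {
    abort("records: must be a nonempty slice_stats data frame")
  }
  check_groups(records)
  if (!(length(bin_width) == 1 && is.finite(bin_width) && bin_width > 0)) {
    abort("bin_width: must be a single positive number")
  }
  if (per_lesion) records <- lesion_records(records)
  v <- stat_values(records, statistic)
  k_lo <- floor((min(v) - origin) / bin_width)
  k_hi <- floor((max(v) - origin) / bin_width) + 1
  edges <- origin + seq(k_lo, k_hi) * bin_width
  hists <- lapply(GROUPS, function(g) {
    vg <- v[records$group == g]
    counts <- if (length(vg) == 0) {
      integer(length(edges) - 1)
    } else {
      graphics::hist(vg, breaks = edges, right = FALSE,
                     include.lowest = TRUE, plot = FALSE)$counts
    }
    new_stat_histogram(statistic, g, edges, counts)
  })
  names(hists) <- GROUPS
  class(hists) <- "stat_histogram_pair"
  hists
}

new_cumulative_curve <- function(statistic, group, support, cum_fraction) {
  structure(list(statistic = statistic, group = group,
                 support = support, cum_fraction = cum_fraction),
            class = "cumulative_curve")
}

#' Per-group normalized cumulative distributions
#'
#' The exact empirical CDF of one slice statistic per group: a step
#' function evaluated at the sorted distinct values, with
#' `cum_fraction_k = #(records <= support_k) / total`. Using the exact
#' ECDF rather than a cumulated histogram avoids any bin-width dependence.
#'
#' @inheritParams build_histogram
#' @return A list of class `cumulative_curve_pair` with components
#'   `benign` and `malignant`.
#' @export
cumulative_distribution <- function(records,
                                    statistic = c("mean", "min", "max", "sd"),
                                    per_lesion = FALSE) {
  statistic <- match.arg(statistic)
  if (!is.data.frame(records) || nrow(records) == 0) {
    abort("records: must be a nonempty slice_stats data frame")
  }
  check_groups(records)
  if (per_lesion) records <- lesion_records(records)
  v <- stat_values(records, statistic)
  curves <- lapply(GROUPS, function(g) {
    vg <- v[records$group == g]
    if (length(vg) == 0) {
      return(new_cumulative_curve(statistic, g, numeric(0), numeric(0)))
    }
    Fn <- ecdf(vg)
    support <- sort(unique(vg))
    new_cumulative_curve(statistic, g, support, Fn(support))
  })
  names(curves) <- GROUPS
  class(curves) <- "cumulative_curve_pair"
  curves
}

curve_fun <- function(curve) {
  if (length(curve$support) == 1) {
    val <- curve$cum_fraction
    function(x) rep(val, length(x))
  } else {
    approxfun(curve$support, curve$cum_fraction, rule = 2)
  }
}

#' Crossings of two cumulative curves
#'
#' Finds the points where the piecewise-linear interpolants through the
#' two empirical CDFs' support points intersect with a sign change, over
#' the HU range common to both curves. Intervals on which the two
#' interpolants coincide are reported once, at their midpoint, flagged
#' `non_unique`. Tangential touches without a sign change and the trivial
#' meeting of the two curves at the boundary of the common range are not
#' reported as crossings.
#'
#' @param curve_a,curve_b `cumulative_curve` objects on the same statistic.
#' @return A data frame with columns `hu`, `fraction`, `non_unique`,
#'   ordered by increasing `hu` (zero rows if the curves never cross).
#' @export
find_crossings <- function(curve_a, curve_b) {
  if (!inherits(curve_a, "cumulative_curve") || !inherits(curve_b, "cumulative_curve")) {
    abort("curve_a/curve_b: expected cumulative_curve objects")
  }
  if (!identical(curve_a$statistic, curve_b$statistic)) {
    abort("curves must be on the same statistic")
  }
  if (length(curve_a$support) == 0 || length(curve_b$support) == 0) {
    abort("cannot intersect an empty cumulative curve")
  }
  lo <- max(min(curve_a$support), min(curve_b$support))
  hi <- min(max(curve_a$support), max(curve_b$support))
  empty <- data.frame(hu = numeric(0), fraction = numeric(0),
                      non_unique = logical(0))
  if (lo > hi) return(empty)

  fa <- curve_fun(curve_a)
  fb <- curve_fun(curve_b)
  xs <- sort(unique(c(lo, hi,
                      curve_a$support[curve_a$support >= lo & curve_a$support <= hi],
                      curve_b$support[curve_b$support >= lo & curve_b$support <= hi])))
  d <- fa(xs) - fb(xs)
  eps <- 1e-12
  zero <- abs(d) < eps
  sgn <- sign(d)
  sgn[zero] <- 0

  if (all(zero)) {
    mid <- (lo + hi) / 2
    return(data.frame(hu = mid, fraction = fa(mid), non_unique = TRUE))
  }

  hu <- numeric(0); frac <- numeric(0); nonuq <- logical(0)
  n <- length(xs)
  i <- 1
  while (i <= n) {
    if (zero[i]) {
      j <- i
      while (j < n && zero[j + 1]) j <- j + 1
      if (j > i) {
        # coincident run over [xs[i], xs[j]]
        mid <- (xs[i] + xs[j]) / 2
        hu <- c(hu, mid); frac <- c(frac, fa(mid)); nonuq <- c(nonuq, TRUE)
      } else {
        # isolated zero: a crossing only with a sign change across it,
        # which requires neighbours on both sides
        if (i > 1 && i < n && sgn[i - 1] * sgn[i + 1] < 0) {
          hu <- c(hu, xs[i]); frac <- c(frac, fa(xs[i])); nonuq <- c(nonuq, FALSE)
        }
      }
      i <- j + 1
    } else {
      if (i < n && !zero[i + 1] && sgn[i] * sgn[i + 1] < 0) {
        # linear root inside (xs[i], xs[i+1]); both interpolants are linear
        # on this segment because xs contains every support point
        x1 <- xs[i]; x2 <- xs[i + 1]
        d1 <- d[i]; d2 <- d[i + 1]
        root <- x1 - d1 * (x2 - x1) / (d2 - d1)
        hu <- c(hu, root); frac <- c(frac, fa(root)); nonuq <- c(nonuq, FALSE)
      }
      i <- i + 1
    }
  }
  data.frame(hu = hu, fraction = frac, non_unique = nonuq)
}

#' @export
print.stat_histogram_pair <- function(x, ...) {
  cat(sprintf("Histogram pair of %s HU statistic: %d bins [%g, %g), width %g\n",
              x$benign$statistic, length(x$benign$counts),
              min(x$benign$bin_edges), max(x$benign$bin_edges),
              x$benign$bin_edges[2] - x$benign$bin_edges[1]))
  cat(sprintf("  benign: %d records; malignant: %d records\n",
              x$benign$total, x$malignant$total))
  invisible(x)
}

#' Histogram pair as a tidy data frame
#'
#' @param hists a `stat_histogram_pair` from [build_histogram()].
#' @return Data frame with `bin_lo`, `bin_hi`, `count_benign`,
#'   `count_malignant`.
#' @export
histogram_table <- function(hists) {
  edges <- hists$benign$bin_edges
  data.frame(bin_lo = edges[-length(edges)], bin_hi = edges[-1],
             count_benign = hists$benign$counts,
             count_malignant = hists$malignant$counts)
}
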