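#' Plot a per-group histogram pair
#'
#' Side-by-side bars of benign and malignant counts per HU bin, mirroring
#' the usual presentation of a two-group HU histogram.
#'
#' @param hists a `stat_histogram_pair` from [build_histogram()].
#' @return A ggplot object.
#' @export
plot_histogram <- function(hists) {
  tab <- histogram_table(hists)
  df <- data.frame(
    hu = rep((tab$bin_lo + tab$bin_hi) / 2, 2),
    count = c(tab$count_benign, tab$count_malignant),
    group = rep(c("benign (group 1)", "malignant (group 2)"),
                each = nrow(tab)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$hu, y = .data$count,
                                   fill = .data$group)) +
    ggplot2::geom_col(position = "dodge",
                      width = 0.9 * (tab$bin_hi[1] - tab$bin_lo[1])) +
    ggplot2::labs(x = sprintf("%s HU", hists$benign$statistic),
                  y = "frequency", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a pair of normalized cumulative distributions
#'
#' @param curves a `cumulative_curve_pair` from [cumulative_distribution()].
#' @param crossings optional data frame from [find_crossings()]; crossing
#'   points are marked.
#' @return A ggplot object.
#' @export
plot_cdf <- function(curves, crossings = NULL) {
  df <- do.call(rbind, lapply(curves, function(cv) {
    if (length(cv$support) == 0) return(NULL)
    data.frame(hu = cv$support, fraction = cv$cum_fraction, group = cv$group)
  }))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$hu, y = .data$fraction,
                                        colour = .data$group)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = sprintf("%s HU", curves$benign$statistic),
                  y = "normalized cumulative fraction", colour = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(crossings) && nrow(crossings) > 0) {
    p <- p + ggplot2::geom_point(
      data = data.frame(hu = crossings$hu, fraction = crossings$fraction),
      mapping = ggplot2::aes(x = .data$hu, y = .data$fraction),
      inherit.aes = FALSE, shape = 4, size = 3)
  }
  p
}

#' Scatter plot of per-bin class probabilities
#'
#' Benign probability `p` and malignant probability `q` per HU bin, the
#' scatter-diagram view on which dominance regions are read off.
#'
#' @param bins a `bin_probability` table from [compute_bin_probabilities()].
#' @param cutoff optional dominance cutoff drawn as a horizontal line.
#' @return A ggplot object.
#' @export
plot_bin_probabilities <- function(bins, cutoff = NULL) {
  occ <- bins[!bins$empty, , drop = FALSE]
  mid <- (occ$bin_lo + occ$bin_hi) / 2
  df <- data.frame(hu = rep(mid, 2),
                   probability = c(occ$p, occ$q),
                   class = rep(c("p (benign)", "q (malignant)"),
                               each = nrow(occ)))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$hu, y = .data$probability,
                                        colour = .data$class)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = sprintf("%s HU bin midpoint", attr(bins, "statistic")),
                  y = "per-bin class probability", colour = NULL) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
  if (!is.null(cutoff)) {
    p <- p + ggplot2::geom_hline(yintercept = cutoff, linetype = "dashed")
  }
  p
}
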