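#' Aggregate per-slice statistics to the lesion level
#'
#' Pooled aggregation combines a lesion's slice records so that the lesion
#' mean and SD equal those computed from all ROI voxels at once: the mean
#' is the voxel-count-weighted mean of slice means; the minimum/maximum are
#' the extrema over slices; the SD follows the law of total variance, with
#' total sum of squares
#' `SS = sum((n_i - 1) * sd_i^2 + n_i * (mean_i - mean)^2)` and
#' `sd = sqrt(SS / (n - 1))` for `n` pooled voxels.
#'
#' @param records `slice_stats` rows of a single lesion (at least one).
#' @param mode `"pooled"` (the only mode that aggregates;
#'   `"per-slice-majority"` defers aggregation to [classify_lesion()]).
#' @return A list: `n_voxels`, `n_slices`, `mean_hu`, `min_hu`, `max_hu`,
#'   `sd_hu`.
#' @export
aggregate_lesion_stats <- function(records, mode = c("pooled", "per-slice-majority")) {
  mode <- match.arg(mode)
  if (!is.data.frame(records) || nrow(records) == 0) {
    abort("records: no slice records for the lesion")
  }
  if (mode == "per-slice-majority") {
    abort("per-slice-majority mode does not aggregate; use classify_lesion()")
  }
  n <- sum(records$n_voxels)
  m <- sum(records$n_voxels * records$mean_hu) / n
  ss <- sum((records$n_voxels - 1) * records$sd_hu^2 +
              records$n_voxels * (records$mean_hu - m)^2)
  list(n_voxels = n,
       n_slices = nrow(records),
       mean_hu = m,
       min_hu = min(records$min_hu),
       max_hu = max(records$max_hu),
       sd_hu = if (n > 1) sqrt(ss / (n - 1)) else 0)
}

# One row of rule outcomes for a (mean, min, max, sd) tuple.
eval_rules <- function(rules, mean_hu, min_hu, max_hu, sd_hu) {
  c(mean = if (is.null(rules$mean)) NA else
      mean_hu >= rules$mean[1] & mean_hu <= rules$mean[2],
    max = if (is.null(rules$max_lt)) NA else max_hu < rules$max_lt,
    min = if (is.null(rules$min)) NA else
      min_hu >= rules$min[1] & min_hu <= rules$min[2],
    sd = if (is.null(rules$sd)) NA else
      sd_hu >= rules$sd[1] & sd_hu <= rules$sd[2])
}

#' Classify one lesion against a threshold rule set
#'
#' Evaluates each enabled rule and labels the lesion
#' `"malignant-consistent"` iff every enabled criterion holds (any single
#' violation suffices for `"benign-suggestive"`); the 0..k score counts
#' satisfied criteria for graded use. In `"pooled"` mode the rules are
#' applied to the [aggregate_lesion_stats()] tuple; in
#' `"per-slice-majority"` mode each rule is evaluated on every slice and a
#' criterion holds iff more than 50% of slices satisfy it. Interval bounds
#' are inclusive; the maximum bound is exclusive (`max_hu < max_lt`). The
#' label is a consistency statement, not a diagnosis.
#'
#' @param records `slice_stats` rows of one lesion.
#' @param rules a [threshold_rules()] object; at least one rule enabled.
#' @param mode `"pooled"` or `"per-slice-majority"`.
#' @return A list of class `classification_result`: `lesion_id`, `group`,
#'   `per_criterion` (named logical, `NA` for disabled rules), `score`,
#'   `label`, `aggregation`.
#' @export
classify_lesion <- function(records, rules = published_rules(),
                            mode = c("pooled", "per-slice-majority")) {
  mode <- match.arg(mode)
  if (!inherits(rules, "threshold_rules")) abort("rules: expected threshold_rules")
  if (length(enabled_rules(rules)) == 0) {
    abort("all rules disabled: nothing to classify", "lunghist_config_error")
  }
  if (!is.data.frame(records) || nrow(records) == 0) {
    abort("records: no slice records for the lesion")
  }
  if (length(unique(records$lesion_id)) > 1) {
    abort("records: classify_lesion expects a single lesion")
  }
  per_criterion <- if (mode == "pooled") {
    agg <- aggregate_lesion_stats(records, "pooled")
    eval_rules(rules, agg$mean_hu, agg$min_hu, agg$max_hu, agg$sd_hu)
  } else {
    per_slice <- t(mapply(function(m, mn, mx, s) eval_rules(rules, m, mn, mx, s),
                          records$mean_hu, records$min_hu,
                          records$max_hu, records$sd_hu))
    apply(per_slice, 2, function(col) {
      if (all(is.na(col))) NA else mean(col) > 0.5
    })
  }
  active <- per_criterion[!is.na(per_criterion)]
  structure(list(lesion_id = records$lesion_id[1],
                 group = records$group[1],
                 per_criterion = per_criterion,
                 score = sum(active),
                 label = if (all(active)) "malignant-consistent" else "benign-suggestive",
                 aggregation = mode),
            class = "classification_result")
}

#' Classify every lesion of a cohort
#'
#' Applies [classify_lesion()] per `lesion_id`. When every lesion carries a
#' known group label, a confusion summary is attached: sensitivity is the
#' fraction of malignant lesions labelled malignant-consistent,
#' specificity the fraction of benign lesions labelled benign-suggestive.
#'
#' @param records `slice_stats` for one or more lesions.
#' @inheritParams classify_lesion
#' @return A data frame of class `cohort_classification` with columns
#'   `lesion_id, group, mean_ok, max_ok, min_ok, sd_ok, score, label` and,
#'   when groups are known, attribute `confusion` (list with
#'   `sensitivity`, `specificity`, `table`).
#' @export
classify_cohort <- function(records, rules = published_rules(),
                            mode = c("pooled", "per-slice-majority")) {
  mode <- match.arg(mode)
  if (!is.data.frame(records) || nrow(records) == 0) {
    abort("records: empty cohort")
  }
  gpl <- unique(records[, c("lesion_id", "group")])
  dup <- gpl$lesion_id[duplicated(gpl$lesion_id)]
  if (length(dup) > 0) {
    abort(sprintf("lesion_id '%s' appears under more than one group", dup[1]),
          "lunghist_consistency_error")
  }
  results <- lapply(split(records, records$lesion_id),
                    classify_lesion, rules = rules, mode = mode)
  out <- do.call(rbind, lapply(results, function(r) {
    data.frame(lesion_id = r$lesion_id, group = r$group,
               mean_ok = r$per_criterion[["mean"]],
               max_ok = r$per_criterion[["max"]],
               min_ok = r$per_criterion[["min"]],
               sd_ok = r$per_criterion[["sd"]],
               score = r$score, label = r$label,
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$lesion_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("cohort_classification", "data.frame")
  if (all(out$group %in% GROUPS)) {
    mal <- out$group == "malignant"
    pos <- out$label == "malignant-consistent"
    attr(out, "confusion") <- list(
      sensitivity = mean(pos[mal]),
      specificity = mean(!pos[!mal]),
      table = table(group = out$group, label = out$label))
  }
  out
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("Lesion %s [%s]: %s (score %d/%d, %s aggregation)\n",
              x$lesion_id, x$group, x$label, x$score,
              sum(!is.na(x$per_criterion)), x$aggregation))
  invisible(x)
}

#' @export
print.cohort_classification <- function(x, ...) {
  cat(sprintf("Cohort classification: %d lesions, %d malignant-consistent\n",
              nrow(x), sum(x$label == "malignant-consistent")))
  print.data.frame(x, ...)
  cf <- attr(x, "confusion")
  if (!is.null(cf)) {
    cat(sprintf("sensitivity %.3f, specificity %.3f (vs. known groups)\n",
                cf$sensitivity, cf$specificity))
  }
  invisible(x)
}
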