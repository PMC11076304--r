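#' Threshold rule set for lesion classification
#'
#' A rule set holds the HU intervals within which a lesion's aggregated
#' statistics are considered malignant-consistent. A `NULL` rule is
#' disabled. Interval rules are inclusive at both bounds; the maximum rule
#' is exclusive at its bound (malignant-consistent iff `max_hu < max_lt`).
#'
#' @param mean closed HU interval for the lesion mean, or `NULL`.
#' @param max_lt strict upper bound for the lesion maximum, or `NULL`.
#' @param min closed HU interval for the lesion minimum, or `NULL`.
#' @param sd closed HU interval for the lesion SD, or `NULL` (disabled).
#' @return An object of class `threshold_rules`.
#' @seealso [published_rules()] for the reference rule set,
#'   [classify_lesion()] for how rules are applied.
#' @export
threshold_rules <- function(mean = c(30, 50), max_lt = 150,
                            min = c(-30, 20), sd = NULL) {
  check_rule_interval <- function(x, name) {
    if (is.null(x)) return(invisible(NULL))
    if (!(length(x) == 2 && is.numeric(x) && all(is.finite(x)) && x[1] <= x[2])) {
      abort(sprintf("%s rule: must be an ordered interval c(lo, hi)", name))
    }
  }
  check_rule_interval(mean, "mean")
  check_rule_interval(min, "min")
  check_rule_interval(sd, "sd")
  if (!is.null(max_lt) &&
      !(length(max_lt) == 1 && is.numeric(max_lt) && is.finite(max_lt))) {
    abort("max rule: max_lt must be a single finite HU value")
  }
  structure(list(mean = mean, max_lt = max_lt, min = min, sd = sd),
            class = "threshold_rules")
}

#' The published benign/malignant threshold rule set
#'
#' Malignant-consistent lesions have a mean HU in \[30, 50\], a maximum HU
#' strictly below 150, and a minimum HU in \[-30, 20\]. The SD rule
#' (malignant SD in \[10, 20\]) is available but disabled by default
#' because SD showed poor discriminating ability at cohort level.
#'
#' @param include_sd enable the SD rule with interval \[10, 20\].
#' @return A `threshold_rules` object.
#' @export
published_rules <- function(include_sd = FALSE) {
  threshold_rules(mean = c(30, 50), max_lt = 150, min = c(-30, 20),
                  sd = if (include_sd) c(10, 20))
}

enabled_rules <- function(rules) {
  names(which(!vapply(unclass(rules), is.null, TRUE)))
}

#' Read and write rule sets as JSON
#'
#' JSON form: `{"mean":[30,50],"max_lt":150,"min":[-30,20],"sd":null}`.
#'
#' @param path JSON file path.
#' @return `read_rules_json()`: a `threshold_rules` object.
#' @export
read_rules_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  threshold_rules(mean = if (!is.null(x$mean)) as.numeric(x$mean),
                  max_lt = if (!is.null(x$max_lt)) as.numeric(x$max_lt),
                  min = if (!is.null(x$min)) as.numeric(x$min),
                  sd = if (!is.null(x$sd)) as.numeric(x$sd))
}

#' @rdname read_rules_json
#' @param rules a `threshold_rules` object.
#' @export
write_rules_json <- function(rules, path) {
  jsonlite::write_json(unclass(rules), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @export
print.threshold_rules <- function(x, ...) {
  cat("Threshold rule set (malignant-consistent when):\n")
  fmt <- function(name, txt) cat(sprintf("  %-4s %s\n", name, txt))
  if (!is.null(x$mean)) fmt("mean", sprintf("in [%g, %g] HU", x$mean[1], x$mean[2]))
  if (!is.null(x$max_lt)) fmt("max", sprintf("< %g HU", x$max_lt))
  if (!is.null(x$min)) fmt("min", sprintf("in [%g, %g] HU", x$min[1], x$min[2]))
  if (!is.null(x$sd)) fmt("sd", sprintf("in [%g, %g] HU", x$sd[1], x$sd[2]))
  if (length(enabled_rules(x)) == 0) cat("  (no rules enabled)\n")
  invisible(x)
}
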