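# Independent brute-force oracles. These deliberately avoid the package's
# code paths: explicit per-voxel loops, explicit <=/bin counting, and
# approxfun/uniroot root finding.

oracle_slice_stats <- function(vol, mask) {
  d <- dim(vol)
  rows <- list()
  for (z in seq_len(d[3])) {
    vals <- c()
    for (y in seq_len(d[2])) {
      for (x in seq_len(d[1])) {
        if (mask[x, y, z] > 0) vals <- c(vals, vol[x, y, z])
      }
    }
    if (length(vals) == 0) next
    n <- length(vals)
    m <- sum(vals) / n
    s <- if (n > 1) sqrt(sum((vals - m)^2) / (n - 1)) else 0
    rows[[length(rows) + 1]] <- c(slice_index = z - 1, n_voxels = n,
                                  mean_hu = m, min_hu = min(vals),
                                  max_hu = max(vals), sd_hu = s)
  }
  do.call(rbind, rows)
}

# Half-open bins [e_i, e_{i+1}), last bin closed at the top.
oracle_hist_counts <- function(values, edges) {
  nb <- length(edges) - 1
  counts <- integer(nb)
  for (v in values) {
    for (b in seq_len(nb)) {
      hit <- if (b < nb) v >= edges[b] && v < edges[b + 1]
             else v >= edges[b] && v <= edges[b + 1]
      if (hit) { counts[b] <- counts[b] + 1; break }
    }
  }
  counts
}

oracle_cdf <- function(values, support) {
  vapply(support, function(s) sum(values <= s) / length(values), 0)
}

# Sign-change search on the dense union of both supports, refined by
# uniroot on each bracketing segment; coincident runs reduced to midpoints.
oracle_crossings <- function(curve_a, curve_b, n_grid = 200) {
  fa <- approxfun(curve_a$support, curve_a$cum_fraction, rule = 2)
  fb <- approxfun(curve_b$support, curve_b$cum_fraction, rule = 2)
  lo <- max(min(curve_a$support), min(curve_b$support))
  hi <- min(max(curve_a$support), max(curve_b$support))
  if (lo >= hi) return(numeric(0))
  xs <- sort(unique(c(curve_a$support, curve_b$support,
                      seq(lo, hi, length.out = n_grid))))
  xs <- xs[xs >= lo & xs <= hi]
  d <- fa(xs) - fb(xs)
  roots <- c()
  for (i in seq_len(length(xs) - 1)) {
    if (d[i] * d[i + 1] < 0) {
      r <- uniroot(function(x) fa(x) - fb(x), c(xs[i], xs[i + 1]),
                   tol = 1e-12)$root
      roots <- c(roots, r)
    }
  }
  sort(roots)
}

# A small random cohort of slice statistics, direct and independent of the
# generator module.
random_stats_records <- function(n, seed, hu_range = c(-100, 200)) {
  set.seed(seed)
  mean_hu <- runif(n, hu_range[1], hu_range[2])
  spread <- runif(n, 1, 40)
  new_records(
    lesion_id = sprintf("L%03d", sample(seq_len(max(2, n %/% 4)), n, replace = TRUE)),
    group = sample(c("benign", "malignant"), n, replace = TRUE,
                   prob = c(0.5, 0.5)),
    slice_index = seq_len(n) - 1L,
    n_voxels = sample(5:50, n, replace = TRUE),
    mean_hu = mean_hu,
    min_hu = floor(mean_hu - spread),
    max_hu = ceiling(mean_hu + spread),
    sd_hu = runif(n, 0, 30))
}

# Assemble a slice_stats-shaped data frame from vectors.
new_records <- function(...) {
  df <- data.frame(..., stringsAsFactors = FALSE)
  class(df) <- c("slice_stats", "data.frame")
  df
}

# Records from explicit voxel vectors (one slice each), computed with base
# arithmetic rather than the package's slice_stats().
records_from_voxels <- function(voxel_sets, lesion_id, group) {
  rows <- lapply(seq_along(voxel_sets), function(i) {
    v <- voxel_sets[[i]]
    data.frame(lesion_id = lesion_id, group = group, slice_index = i - 1L,
               n_voxels = length(v), mean_hu = sum(v) / length(v),
               min_hu = min(v), max_hu = max(v),
               sd_hu = if (length(v) > 1) sd(v) else 0,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  class(df) <- c("slice_stats", "data.frame")
  df
}

# Single-row lesion record with chosen aggregate statistics.
mk_lesion <- function(id, group, mean_hu, min_hu, max_hu, sd_hu = 15) {
  new_records(lesion_id = id, group = group, slice_index = 0L,
              n_voxels = 50L, mean_hu = mean_hu, min_hu = min_hu,
              max_hu = max_hu, sd_hu = sd_hu)
}

tiny_spec <- function(seed = 1, ...) {
  cohort_spec(n_lesions_benign = 2, n_lesions_malignant = 2,
              slices_per_lesion = c(2L, 4L), voxels_per_slice = c(10L, 30L),
              seed = seed, ...)
}

# One-lesion, constant-HU spec: every ROI voxel equals `value`.
constant_spec <- function(value = 40, n_slices = 1, n_vox = 25, seed = 1) {
  cohort_spec(
    n_lesions_benign = 1, n_lesions_malignant = 1,
    slices_per_lesion = c(as.integer(n_slices), as.integer(n_slices)),
    voxels_per_slice = c(as.integer(n_vox), as.integer(n_vox)),
    malignant_mean_hu = c(value, value),
    benign_mean_hu = list(low = c(value, value), high = c(value, value),
                          weight_low = 1),
    malignant_within_slice_sd = c(0, 0),
    benign_within_slice_sd = c(0, 0),
    slice_jitter_sd = 0,
    tail_model = default_tail_model(
      benign = list(frac_low = 0, low_range = c(-300, -50),
                    frac_high = 0, high_range = c(120, 400),
                    hu_range = c(-1024, 3071))),
    seed = seed)
}
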