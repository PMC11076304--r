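test_that("per-bin probabilities follow the Np/N, Nq/N formulas", {
  rec <- new_records(lesion_id = "L1", group = c(rep("benign", 3), "malignant"),
                     slice_index = 0:3, n_voxels = 5,
                     mean_hu = c(32, 33, 34, 31), min_hu = 0, max_hu = 60,
                     sd_hu = 2)
  bins <- compute_bin_probabilities(build_histogram(rec, "mean", bin_width = 5))
  occ <- bins[!bins$empty, ]
  expect_equal(nrow(occ), 1)
  expect_equal(occ$Np, 3)
  expect_equal(occ$Nq, 1)
  expect_equal(occ$N, 4)
  expect_equal(occ$p, 0.75)
  expect_equal(occ$q, 0.25)
})

test_that("conservation and p + q = 1 hold on every occupied bin", {
  for (seed in c(1, 4, 7)) {
    rec <- random_stats_records(120, seed)
    for (statistic in c("mean", "max")) {
      bins <- compute_bin_probabilities(build_histogram(rec, statistic))
      expect_true(all(bins$N == bins$Np + bins$Nq))
      expect_equal(sum(bins$N), nrow(rec))
      expect_equal(sum(bins$Np), sum(rec$group == "benign"))
      occ <- bins[!bins$empty, ]
      expect_true(all(abs(occ$p + occ$q - 1) <= 1e-12))
      expect_true(all(is.na(bins$p[bins$empty])))
    }
  }
})

test_that("a perfectly separated cohort yields pure bins", {
  mal <- new_records(lesion_id = "M1", group = "malignant", slice_index = 0:19,
                     n_voxels = 5, mean_hu = seq(30, 49.5, length.out = 20),
                     min_hu = 0, max_hu = 60, sd_hu = 2)
  ben <- new_records(lesion_id = "B1", group = "benign", slice_index = 0:19,
                     n_voxels = 5,
                     mean_hu = c(seq(0, 25, length.out = 10),
                                 seq(55, 80, length.out = 10)),
                     min_hu = -10, max_hu = 60, sd_hu = 2)
  rec <- rbind(mal, ben)
  bins <- compute_bin_probabilities(build_histogram(rec, "mean", bin_width = 5))
  occ <- bins[!bins$empty, ]
  inside <- occ$bin_lo >= 30 & occ$bin_hi <= 50
  expect_true(all(occ$q[inside] == 1))
  expect_true(all(occ$p[!inside] == 1))
})

test_that("histograms on different grids cannot be combined", {
  h1 <- build_histogram(random_stats_records(30, 1), "mean", bin_width = 5)
  h2 <- build_histogram(random_stats_records(30, 2), "mean", bin_width = 10)
  expect_error(compute_bin_probabilities(h1$benign, h2$malignant),
               class = "lunghist_alignment_error")
  h3 <- build_histogram(random_stats_records(30, 1), "sd", bin_width = 5)
  expect_error(compute_bin_probabilities(h1$benign, h3$malignant),
               class = "lunghist_alignment_error")
})

test_that("uniform dominance yields a single spanning region", {
  rec <- new_records(lesion_id = "M1", group = "malignant", slice_index = 0:9,
                     n_voxels = 5, mean_hu = c(seq(10, 24, length.out = 5),
                                               seq(41, 55, length.out = 5)),
                     min_hu = 0, max_hu = 60, sd_hu = 2)
  bins <- compute_bin_probabilities(build_histogram(rec, "mean", bin_width = 5))
  reg <- derive_dominance_regions(bins, cutoff = 0.9, min_records_per_bin = 1)
  expect_equal(nrow(reg), 1)
  expect_equal(reg$dominant_class, "malignant")
  expect_equal(reg$hu_lo, 10)
  expect_equal(reg$hu_hi, 60)   # empty interior bins are bridged
  expect_equal(reg$n_records, 10)
})

test_that("alternating pure bins are never merged", {
  vals <- c(2.5, 7.5, 12.5, 17.5)
  rec <- new_records(lesion_id = "L", group = c("benign", "malignant",
                                                "benign", "malignant"),
                     slice_index = 0:3, n_voxels = 5, mean_hu = vals,
                     min_hu = 0, max_hu = 30, sd_hu = 1)
  bins <- compute_bin_probabilities(build_histogram(rec, "mean", bin_width = 5))
  reg <- derive_dominance_regions(bins, cutoff = 0.9, min_records_per_bin = 1)
  expect_equal(nrow(reg), 4)
  expect_true(all(reg$n_bins == 1))
  expect_equal(reg$dominant_class, c("benign", "malignant",
                                     "benign", "malignant"))
})

test_that("an empty bin inside a dominant run is bridged (hand-traced case)", {
  # occupied malignant-dominant bins [30,35), [35,40), [45,50); [40,45) empty;
  # benign-dominant bins below 30
  mal <- new_records(lesion_id = "M", group = "malignant", slice_index = 0:29,
                     n_voxels = 5,
                     mean_hu = rep(c(32, 37, 47), each = 10),
                     min_hu = 0, max_hu = 60, sd_hu = 2)
  ben <- new_records(lesion_id = "B", group = "benign", slice_index = 0:11,
                     n_voxels = 5,
                     mean_hu = c(rep(c(12, 17, 22), each = 3),
                                 32, 37, 47),
                     min_hu = -10, max_hu = 60, sd_hu = 2)
  rec <- rbind(mal, ben)
  bins <- compute_bin_probabilities(build_histogram(rec, "mean", bin_width = 5))
  # q = 10/11 >= 0.9 on the three occupied malignant bins
  reg <- derive_dominance_regions(bins, cutoff = 0.9, min_records_per_bin = 3)
  mreg <- reg[reg$dominant_class == "malignant", ]
  expect_equal(nrow(mreg), 1)
  expect_equal(mreg$hu_lo, 30)
  expect_equal(mreg$hu_hi, 50)
  expect_equal(mreg$n_bins, 3)
  expect_equal(mreg$n_records, 33)
  # without bridging, the empty [40,45) bin splits the region
  reg2 <- derive_dominance_regions(bins, cutoff = 0.9, min_records_per_bin = 3,
                                   bridge_empty = FALSE)
  expect_equal(nrow(reg2[reg2$dominant_class == "malignant", ]), 2)
})

test_that("dominance below 0.5 is rejected and regions stay disjoint", {
  bins <- compute_bin_probabilities(
    build_histogram(random_stats_records(100, 9), "mean"))
  expect_error(derive_dominance_regions(bins, cutoff = 0.5), "cutoff")
  reg <- derive_dominance_regions(bins, cutoff = 0.6, min_records_per_bin = 1)
  for (cls in c("benign", "malignant")) {
    r <- reg[reg$dominant_class == cls, ]
    if (nrow(r) > 1) expect_true(all(r$hu_lo[-1] >= r$hu_hi[-nrow(r)]))
  }
})

test_that("rule candidates summarize the dominance regions", {
  mk <- function(cls, lo, hi, n) {
    data.frame(statistic = "x", dominant_class = cls, hu_lo = lo, hu_hi = hi,
               min_probability = 0.95, n_bins = 2L, n_records = n,
               stringsAsFactors = FALSE)
  }
  regions <- list(
    mean = mk("malignant", 30, 50, 200),
    max = rbind(mk("malignant", 60, 110, 150), mk("benign", 150, 400, 120)),
    min = mk("malignant", -30, 20, 180),
    sd = mk("malignant", 10, 20, 160))
  rules <- summarize_rule_candidates(regions)
  expect_equal(rules$mean, c(30, 50))
  expect_equal(rules$max_lt, 150)
  expect_equal(rules$min, c(-30, 20))
  expect_equal(rules$sd, c(10, 20))
  expect_equal(attr(rules, "support")$mean, 200)

  expect_warning(out <- summarize_rule_candidates(
    list(mean = mk("benign", 0, 10, 5)[0, ])), "empty rule set")
  expect_null(out$mean)
  expect_null(out$max_lt)
})

test_that("dominance recovery finds the malignant mean window on the default cohort", {
  rec <- slice_stats(generate_cohort(cohort_spec(seed = 1)))
  reg <- analyze_statistic(rec, "mean", cutoff = 0.9)$regions
  mal <- reg[reg$dominant_class == "malignant", ]
  expect_gte(nrow(mal), 1)
  expect_lte(abs(min(mal$hu_lo) - 30), 5)
  expect_lte(abs(max(mal$hu_hi) - 50), 5)
})
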