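test_that("pooled aggregation matches hand arithmetic", {
  rec <- new_records(lesion_id = "L1", group = "malignant", slice_index = 0:1,
                     n_voxels = c(10, 10), mean_hu = c(30, 50),
                     min_hu = c(-10, -40), max_hu = c(80, 120),
                     sd_hu = c(5, 5))
  agg <- aggregate_lesion_stats(rec)
  expect_equal(agg$mean_hu, 40)
  expect_equal(agg$min_hu, -40)
  expect_equal(agg$max_hu, 120)
  expect_equal(agg$n_voxels, 20)

  # voxel-count weighting
  rec$n_voxels <- c(30, 10)
  expect_equal(aggregate_lesion_stats(rec)$mean_hu, 35)
})

test_that("pooled mean and SD equal the all-voxel statistics exactly", {
  set.seed(42)
  for (case in 1:10) {
    voxel_sets <- lapply(seq_len(sample(2:6, 1)), function(i) {
      round(rnorm(sample(3:40, 1), mean = runif(1, -50, 80),
                  sd = runif(1, 1, 30)))
    })
    rec <- records_from_voxels(voxel_sets, "L1", "malignant")
    agg <- aggregate_lesion_stats(rec)
    allv <- unlist(voxel_sets)
    expect_equal(agg$mean_hu, mean(allv), tolerance = 1e-12)
    expect_equal(agg$sd_hu, sd(allv), tolerance = 1e-9)
    expect_equal(agg$min_hu, min(allv))
    expect_equal(agg$max_hu, max(allv))
  }
})

test_that("pooled aggregation matches raw generator voxels", {
  samples <- generate_cohort(tiny_spec(seed = 13))
  rec <- slice_stats(samples)
  for (id in unique(samples$lesion_id)) {
    allv <- as.numeric(unlist(samples$hu_values[samples$lesion_id == id]))
    agg <- aggregate_lesion_stats(rec[rec$lesion_id == id, ])
    expect_equal(agg$mean_hu, mean(allv), tolerance = 1e-12)
    expect_equal(agg$sd_hu, sd(allv), tolerance = 1e-9)
  }
})

test_that("the published rules label a consistent tuple malignant-consistent", {
  res <- classify_lesion(mk_lesion("L1", "unknown", 40, 0, 120))
  expect_equal(res$label, "malignant-consistent")
  expect_equal(res$score, 3)
  expect_equal(unname(res$per_criterion[c("mean", "max", "min")]),
               c(TRUE, TRUE, TRUE))
  expect_true(is.na(res$per_criterion[["sd"]]))

  # a benign-typical mean of 70 violates only the mean criterion
  res70 <- classify_lesion(mk_lesion("L2", "unknown", 70, 0, 120))
  expect_equal(res70$label, "benign-suggestive")
  expect_equal(res70$score, 2)
  expect_false(res70$per_criterion[["mean"]])
})

test_that("interval bounds are inclusive and the max bound exclusive", {
  expect_equal(classify_lesion(mk_lesion("L", "unknown", 30, 0, 120))$label,
               "malignant-consistent")
  expect_equal(classify_lesion(mk_lesion("L", "unknown", 50, 0, 120))$label,
               "malignant-consistent")
  at150 <- classify_lesion(mk_lesion("L", "unknown", 40, 0, 150))
  expect_false(at150$per_criterion[["max"]])
  expect_equal(at150$label, "benign-suggestive")
  expect_true(classify_lesion(mk_lesion("L", "unknown", 40, -30, 120))$per_criterion[["min"]])
  expect_true(classify_lesion(mk_lesion("L", "unknown", 40, 20, 120))$per_criterion[["min"]])
  expect_false(classify_lesion(mk_lesion("L", "unknown", 40, 21, 120))$per_criterion[["min"]])
})

test_that("per-slice majority requires more than half the slices", {
  rec <- new_records(lesion_id = "L", group = "unknown", slice_index = 0:2,
                     n_voxels = 10, mean_hu = c(40, 42, 70),
                     min_hu = 0, max_hu = 100, sd_hu = 10)
  res <- classify_lesion(rec, mode = "per-slice-majority")
  expect_true(res$per_criterion[["mean"]])  # 2/3 slices inside [30, 50]
  expect_equal(res$label, "malignant-consistent")

  rec$mean_hu <- c(40, 70, 70)
  res2 <- classify_lesion(rec, mode = "per-slice-majority")
  expect_false(res2$per_criterion[["mean"]])

  rec$mean_hu <- c(40, 40, 70)
  rec2 <- rec[c(2, 3, 1), ]  # exactly half is not a majority when even
  rec2 <- rbind(rec2, rec[1, ])
  rec2$mean_hu <- c(40, 40, 70, 70)
  res3 <- classify_lesion(rec2, mode = "per-slice-majority")
  expect_false(res3$per_criterion[["mean"]])
})

test_that("classification ignores slice order and record splitting", {
  v <- round(rnorm(40, 45, 12))
  halves <- records_from_voxels(list(v[1:17], v[18:40]), "L1", "unknown")
  halves$slice_index <- c(0L, 0L)  # the same slice split across records
  whole <- records_from_voxels(list(v), "L1", "unknown")
  expect_equal(classify_lesion(halves)$per_criterion,
               classify_lesion(whole)$per_criterion)

  rec <- slice_stats(generate_cohort(tiny_spec(seed = 21)))
  one <- rec[rec$lesion_id == rec$lesion_id[1], ]
  shuffled <- one[rev(seq_len(nrow(one))), ]
  expect_equal(classify_lesion(one)$score, classify_lesion(shuffled)$score)
})

test_that("tightening a rule never converts benign-suggestive to malignant-consistent", {
  set.seed(99)
  rules <- published_rules(include_sd = TRUE)
  tighter <- threshold_rules(mean = c(35, 45), max_lt = 120,
                             min = c(-20, 10), sd = c(12, 18))
  for (i in 1:50) {
    les <- mk_lesion("L", "unknown", runif(1, 0, 90), runif(1, -60, 25),
                     runif(1, 60, 200), runif(1, 5, 30))
    lab <- classify_lesion(les, rules)$label
    lab_tight <- classify_lesion(les, tighter)$label
    if (lab == "benign-suggestive") {
      expect_equal(lab_tight, "benign-suggestive")
    }
  }
})

test_that("cohort classification reports a confusion summary and validates input", {
  mal <- do.call(rbind, lapply(1:3, function(i) {
    mk_lesion(sprintf("M%d", i), "malignant", 40 + i, 0, 100 + i)
  }))
  ben <- do.call(rbind, lapply(1:3, function(i) {
    mk_lesion(sprintf("B%d", i), "benign", 70 + i, -50, 200 + i)
  }))
  res <- classify_cohort(rbind(mal, ben))
  cf <- attr(res, "confusion")
  expect_equal(cf$sensitivity, 1)
  expect_equal(cf$specificity, 1)
  expect_equal(nrow(res), 6)
  expect_named(res, c("lesion_id", "group", "mean_ok", "max_ok", "min_ok",
                      "sd_ok", "score", "label"))

  expect_error(classify_cohort(mal[0, ]), "empty")
  dup <- rbind(mal, mk_lesion("M1", "benign", 70, -50, 200))
  expect_error(classify_cohort(dup), class = "lunghist_consistency_error")
  expect_error(classify_cohort(mal, threshold_rules(mean = NULL, max_lt = NULL,
                                                    min = NULL, sd = NULL)),
               class = "lunghist_config_error")
})

test_that("rule sets round-trip through JSON", {
  rules <- published_rules()
  path <- withr::local_tempfile(fileext = ".json")
  write_rules_json(rules, path)
  expect_match(paste(readLines(path), collapse = ""), "\"sd\":null")
  back <- read_rules_json(path)
  expect_equal(back$mean, c(30, 50))
  expect_equal(back$max_lt, 150)
  expect_equal(back$min, c(-30, 20))
  expect_null(back$sd)
})
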