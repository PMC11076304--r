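# lunghist

Histogram analysis (HA) of Hounsfield-unit (HU) distributions for
characterizing lung lesions on **unenhanced** chest CT.

Pulmonary nodules without specific imaging features (calcification,
necrosis, contrast enhancement) can be hard to call benign or malignant by
visual inspection alone, and the fallback — biopsy — is invasive. A
quantitative alternative is to characterize the lesion by the first-order
statistics of the HU values inside a free-hand region of interest (ROI)
drawn on every slice through the lesion: the per-slice **mean**,
**minimum**, **maximum** and **standard deviation**. `lunghist` implements
that analysis as a tested pipeline for radiologists and imaging
researchers:

1. **ROI statistics** — extract per-slice `mean/min/max/sd` of HU from a
   CT volume plus binary ROI mask (NIfTI), or exchange them as a simple
   CSV table.
2. **Distribution analysis** — per-group histograms and exact normalized
   cumulative distributions of any statistic, with detection of the points
   where the two groups' cumulative curves cross.
3. **Per-bin class probabilities** — for each HU bin, the benign count
   `Np`, malignant count `Nq`, total `N = Np + Nq`, and empirical class
   probabilities `p = Np/N`, `q = Nq/N` (so `p + q = 1` on every occupied
   bin), plus **dominance regions**: contiguous HU ranges where one
   class's probability stays above a cutoff (default 0.9).
4. **Threshold-rule classification** — a lesion is *malignant-consistent*
   when its aggregated statistics satisfy every enabled rule of a
   threshold rule set. The default, published rule set is

   mean ∈ [30, 50] HU  and  max < 150 HU  and  min ∈ [−30, 20] HU

   with an optional SD ∈ [10, 20] rule (disabled by default). Any
   violation makes the lesion *benign-suggestive* — deliberately not a
   diagnosis.
5. **Synthetic cohorts and phantoms** — a seeded two-level generator
   (lesion-level mean/SD, then per-slice voxel values) emulating a
   20-lesion, ~430-slice two-group cohort, plus digital phantom volumes
   with exact ground truth, so every stage is testable without patient
   data.

## Worked example

```r
library(lunghist)

spec    <- cohort_spec(seed = 1)              # default two-group cohort
records <- slice_stats(generate_cohort(spec)) # 418 slice records, 20 lesions

analyze_statistic(records, "mean")
#> Histogram analysis of the mean HU statistic
#> Histogram pair of mean HU statistic: 19 bins [-20, 75), width 5
#>   benign: 218 records; malignant: 200 records
#>   CDF crossings: 40.7 HU @ 44.9%
#>   benign dominance in [-15, 25) HU (7 bins, 96 records, min prob 0.91)
#>   malignant dominance in [30, 50) HU (4 bins, 199 records, min prob 0.92)
#>   benign dominance in [55, 75) HU (4 bins, 98 records, min prob 1.00)

derive_rules_from_cohort(records)
#> Threshold rule set (malignant-consistent when):
#>   mean in [30, 50] HU
#>   max  < 245 HU
#>   min  in [-25, 25] HU
#>   sd   in [10, 20] HU

res <- classify_cohort(records, published_rules())
attr(res, "confusion")$table
#>            label
#> group       benign-suggestive malignant-consistent
#>   benign                   10                    0
#>   malignant                 0                   10
```

Reading the output: the two groups' mean-HU cumulative curves cross at
40.7 HU (at cumulative fraction 44.9%); the malignant class dominates
(q ≥ 0.9) exactly on the generator's 30–50 HU window, so the data-derived
candidate mean rule recovers [30, 50]; and the published rule set
separates the 20 synthetic lesions perfectly (sensitivity and specificity
1.0 on this cohort). The derived `max < 245` bound is the lower edge of
the benign dominance zone of the maximum statistic in this particular
cohort — sparser than the mean analysis because maxima spread over a wide
tail.

A thin command-line wrapper covers the same steps
(`system.file("exec/lunghist", package = "lunghist")`):

```sh
lunghist simulate --seed 1 --out cohort/
lunghist extract  --ct volume.nii.gz --mask mask.nii.gz --lesion-id L1 --group unknown --out stats.csv
lunghist analyze  --stats cohort/stats.csv --statistic mean --out out/
lunghist probs    --stats cohort/stats.csv --statistic mean --cutoff 0.9 --out out/
lunghist classify --stats cohort/stats.csv --out results.csv
```

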