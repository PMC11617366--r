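# cowcollar

Analytics for wearable neck-collar sensors in precision livestock farming.
Collar devices on cattle record 9-channel inertial data (tri-axial
accelerometer in g, gyroscope in deg/s, magnetometer) and infrared neck skin
temperature. From those streams, `cowcollar` answers three husbandry
questions: *what is the animal doing* (behaviour classification), *how much
is it moving* (step counting, an early indicator of lameness, metabolic
disease and estrus), and *is its temperature normal* (skin temperature
against a rectal reference). A seeded simulator generates
behaviour-annotated collar recordings so the whole pipeline can be developed
and validated without field data.

## Methods at a glance

* **Temperature.** Raw infrared thermography is noisy and artifact-prone
  (blinks, head shakes, contact loss). A centered 1-s rolling median
  removes transient spikes; summaries report empirical quantiles (type 7)
  and the skin-vs-rectal error `e_t = T_rectal − T_skin(t)` (median and
  IQR per animal).
* **Behaviour.** Streams are cut into 10-s windows; each window is labeled
  by the behaviour covering a strict majority of its duration and
  represented by seven features per channel — mean (F1), population
  variance (F2), RMS (F3), skewness (F4), excess kurtosis (F5), energy
  `Σx²` (F6) and integral of absolute value `Σ|x|·Δt` (F8) — a 63-length
  vector. Six classifier families (kNN, naive Bayes, MLP, multi-class SVM,
  binary classification tree, random forest) are compared on identical
  grouped-by-animal folds and scored per class by sensitivity
  `CSen = TP/(TP+FN)` and precision `CPre = TP/(TP+FP)` with unweighted
  macro averages.
* **Steps.** A binary RBF-SVM flags 1-s walking windows; one step is
  counted per dominant peak of the dynamic acceleration magnitude inside
  each run of positive windows. Accuracy per animal is
  `100·(1 − |identified − actual|/actual)`, aggregated as a pooled
  (summed-count) accuracy and an unweighted per-animal mean.

## Worked example

```r
library(cowcollar)

cfg <- sim_config()                       # 20 Hz IMU, 1.5 Hz gait, 38.3 C rectal baseline
ds  <- simulate_dataset(cfg, duration_s = 3600, seed = 1)
ds
#> Synthetic collar dataset [C1]: 3600.0 s, 31 behavior bouts, 424 true steps

# temperature: smooth, summarize, compare to the rectal baseline
sm <- rolling_median(ds$temperature, window_s = 5)
skin_rectal_error(sm)
#> Skin vs rectal error [C1]: median 1.11 C, IQR 0.20 C (3600 samples)

# behaviour classification with grouped (leave-one-animal-out) CV
cohort <- generate_cohort(4, cfg, 1800, base_seed = 0)
fm <- build_feature_matrix(lapply(cohort, function(d)
  segment_windows(d$stream, d$schedule, length_s = 10)))
cross_validate(fm, "svm", seed = 1)
#> Classification report [svm]
#>             class sensitivity_pct precision_pct  tp fn fp support
#>           feeding           98.57         97.87 138  2  3     140
#>           grazing           95.65         96.70  88  4  3      92
#>           walking           94.03         98.44  63  4  1      67
#>     lying_resting           97.84         97.84 272  6  6     278
#>  standing_resting           96.32         94.24 131  5  8     136
#> Average: sensitivity 96.48%, precision 97.02%

# step counting with a binary SVM detector
train <- generate_cohort(3, cfg, 3600, base_seed = 10)
det <- train_step_detector(build_feature_matrix(lapply(train, function(d)
  segment_windows(d$stream, d$schedule, length_s = 1))), seed = 1)
ev <- count_steps(det, ds$stream)
c(identified = ev$step_count, actual = true_step_count(ds))
#> identified     actual
#>        419        424
step_accuracy(ev$step_count, true_step_count(ds))
#> [1] 98.82075
```

The per-class table reads like a confusion-matrix summary: e.g. walking
sensitivity 94.03% means 63 of 67 true walking windows were recognised;
its precision 98.44% means 1 of the 64 windows predicted as walking was
something else. The step example recovers 419 of 424 simulated steps
(98.8% accuracy).

`run_pipeline()` (or `inst/cli/cowcollar.R` from a shell) chains the stages
and writes CSV/JSON artifacts stamped with the seed and a config hash;
identical config + seed reproduce byte-identical outputs.

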