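---
title: "Collar-sensor analytics: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Collar-sensor analytics: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cowcollar)
```

`cowcollar` analyses recordings from wearable neck collars on cattle: a
9-channel inertial measurement unit (IMU) sampled continuously, and an
infrared skin-temperature sensor aimed at the neck. This vignette documents
the models behind each stage, the parameters that matter, and the design
decisions taken where more than one defensible choice existed. It states no
empirical result beyond what the package's own tests and
`scripts/acceptance.R` compute.

## 1. The synthetic collar-data generator

Field recordings of collared cattle are rarely shareable, so every stage of
the pipeline is developed and validated against a generator whose
statistical structure mirrors what collar IMUs actually record. The
generator is first-class, tested code, not a fixture: all of its output is
reproducible bit-for-bit from one root seed per animal, with per-component
child seeds derived by fixed offsets so the schedule, the IMU stream and the
temperature trace can be regenerated independently.

### 1.1 Behaviour schedules

Cattle activity is modelled as a semi-Markov chain over a seven-class
ethogram: feeding, grazing, walking, lying resting, standing resting, and
the two posture transitions (stand-to-lie, lie-to-stand). A semi-Markov
formulation — explicit dwell times per bout, rather than per-sample state
changes — matches the multi-second-to-minute bouts visible in annotated
collar data.

Dwell times are gamma-distributed with shape 4 and the configured mean,
concentrating bout lengths around their mean: an exponential dwell would
produce many sub-second bouts that no real ethogram contains. Default means
(feeding 180 s, grazing 180 s, walking 60 s, lying rest 300 s, standing
rest 120 s) are in the range reported for housed cattle; all are
configurable. Whenever the sampled move crosses posture families, the
matching transition class is inserted for a fixed 3 s. The initial bout is
drawn proportionally to average inbound transition probability, so
degenerate matrices (e.g. a single absorbing state) start where they force
the chain.

### 1.2 IMU signal models

The accelerometer reports specific force in g. Conventions: upright posture
puts gravity on +z (`az ≈ 1`), lying rotates gravity onto +y, and head-down
postures (grazing strongly, feeding mildly) pitch it towards −x. Per
behaviour:

* **Resting classes** — the posture's gravity vector plus Gaussian noise
  (sd `rest_noise_g`, default 0.02 g).
* **Walking** — a periodic gait component at `gait_frequency_hz`
  (default 1.5 Hz, a typical cattle step rate) with amplitude
  `gait_amplitude_g` (default 0.4 g) on z and half that, in quadrature, on
  x; one ground-truth step event is emitted per gait cycle at the vertical
  acceleration peak (`steps_per_cycle = 2` gives a per-leg convention).
* **Grazing/feeding** — a slow head-bob oscillation (default 0.35 Hz,
  0.15 g) on the same axes.
* **Transitions** — the gravity vector ramps linearly between postures over
  the bout, with a matching constant angular rate on the gyroscope x axis.

Active behaviours carry accelerometer noise `imu_noise_g` (default 0.05 g);
gyroscope noise is ten times the accelerometer sd (in deg/s), and the
magnetometer is a constant heading vector plus noise — the package makes no
claim to magnetometer physics. With all noise set to zero every behaviour
reduces exactly to its closed-form model, which the test suite asserts per
sample.

The IMU sampling rate defaults to 20 Hz — typical for collar accelerometry,
and giving an even 200 samples per 10-s analysis window; it is a
configuration knob, not an inference, as is the collar orientation
convention.

### 1.3 Skin temperature

Neck skin temperature is modelled as a rectal baseline (38.3 °C, the
standard comparative reference in livestock monitoring) minus a skin offset
(default 1.1 °C — epidermal temperature of homeotherms runs below core),
plus a slow sinusoidal drift (0.1 °C amplitude, 1 h period, standing in for
circadian and environmental trends), stationary AR(1) noise (sd 0.15 °C,
coefficient 0.9 — infrared readings are strongly autocorrelated), and
Poisson-placed artifact spikes of 1–3 samples (0.5 per minute, ±1 °C)
emulating blinks, head shakes and momentary loss of sensor contact. Under
these defaults the bulk of samples falls in the 36.5–37.5 °C band expected
of healthy housed cattle, and per-animal median skin-vs-rectal errors land
inside the fraction-of-a-degree range reported in the field. Fever or
disease dynamics are deliberately out of scope.

## 2. Temperature smoothing and error analysis

Raw infrared thermography is artifact-prone, so the pipeline smooths with a
**centered rolling median** of `window_s` seconds (default 1 s). The window
size in samples is `round(window_s × rate)` forced to the nearest odd
integer, making the window symmetric and the median unambiguous. At the
edges the window shrinks symmetrically (odd sizes down to one sample)
rather than padding: no temperatures are fabricated, monotone stretches
pass through unchanged (which also makes the filter idempotent there), and
every output value is bounded by its window's extrema. Whether such a
filter should be centered or trailing is a genuine toss-up for offline
analysis; centered is the default for its symmetric latency, and
`align = "trailing"` is available for streaming-style use.

Quantile summaries use linear interpolation between order statistics
(R's type 7) — the convention is stated because quantile definitions differ
across software. Skin-vs-rectal error treats the rectal temperature as a
per-animal constant baseline; time-varying rectal series are out of scope.

## 3. Window features

Behaviour classification uses 10-s windows (non-overlapping by default).
Each window is labeled by the behaviour covering a **strict majority** of
its duration; exact ties and straddles stay unlabeled rather than being
broken arbitrarily into training data. Note a 3-s posture transition can
never cover a strict majority of a 10-s window, so transition classes
vanish from window-level evaluation — consistent with field practice of
scoring the five main behaviours.

Seven features are computed per channel (63 per window): mean (F1),
variance (F2), RMS (F3), skewness (F4), kurtosis (F5), energy (F6) and
integral of absolute value (F8). Conventions, chosen to be standard and
degenerate-safe where the literature leaves them open:

* moments use the population (1/n) normalisation; skewness is Fisher's
  `m3/m2^{3/2}` and kurtosis is excess `m4/m2² − 3`, both defined as 0 for
  constant windows;
* energy is the plain time-domain `Σx²` (no FFT), so `F6 = n·F3²` and
  `F3² = F1² + F2` hold as exact identities the tests assert;
* the integral of absolute value is `Σ|x|·Δt`, making it invariant to the
  sampling rate rather than proportional to it.

The seven listed features make a 9 × 7 representation; an optional eighth
per-channel slot is deliberately not invented.

## 4. Behaviour classification

Six classifier families sit behind one training interface: kNN (k = 5),
Gaussian naive Bayes, a single-hidden-layer perceptron (64 units, 500
iterations), an RBF-kernel SVM (C = 10, γ = 1/63), a pruned binary
classification tree (cp = 0.01) and a random forest (200 trees). None of
these hyperparameters is claimed optimal; they are sensible field defaults
and all are exposed. Per-feature z-scoring is fitted on training rows only
and enabled by default for the scale-sensitive models (SVM, kNN, MLP), off
for trees and naive Bayes.

Evaluation is **grouped by animal** — leave-one-animal-out by default — so
no individual contributes windows to both training and test; window-level
random splits leak within-animal correlation and flatter every model.
Held-out predictions are pooled across folds before scoring, and
`compare_classifiers()` reuses one fold assignment across families so
comparisons are paired. Scores are per-class sensitivity
`100·TP/(TP+FN)` and precision `100·TP/(TP+FP)` with unweighted macro
averages over the classes present; a class never predicted has undefined
precision and is excluded from (not zeroed into) the macro mean.

## 5. Step counting

A binary RBF-SVM is trained to flag walking windows of 1 s — short enough
to localise walking bouts, long enough (20 samples at 20 Hz) for stable
features. Windows are featurized through *the same code path* as the
behaviour pipeline (asserted bit-identical in the tests). Consecutive
positive windows form runs, optionally bridging gaps of
`merge_gap_windows`.

Three counting rules are provided. The default, `"peaks"`, counts one step
per dominant peak of the detrended acceleration magnitude within each run
(minimum height half the run's RMS, 0.3 s refractory separation, i.e. a
3.3 steps/s ceiling): event-level pedometry whose count is independent of
the window length. The alternatives — one step per positive window
(`"per_window"`) and one per run (`"per_run"`) — are retained as config
options but cannot recover true counts in general: at a 1.5 Hz gait, 1-s
positive windows contain 1.5 steps on average, so per-window counting
saturates at ~67% accuracy by construction. Equating each detected step
event with one step is also what the field's box-plot-per-step reporting
convention implies.

Accuracy is `100·(1 − |identified − actual|/actual)` — symmetric in over-
and under-counting and 100 only at equality. Cohorts aggregate two ways:
*pooled* accuracy from summed counts (robust to per-animal count
imbalance) and the unweighted *mean* of per-animal accuracies; both are
reported because they answer different questions.

## 6. Numerical and degenerate-input choices

* Uniform sampling is enforced within a 10⁻⁶ relative tolerance on
  timestamp spacing; non-monotone or NA-bearing CSVs are rejected.
* Strict-majority window labeling uses a 10⁻⁹ slack on the comparison so
  floating-point bout boundaries cannot flip a tie.
* Degenerate feature moments (constant windows) map skewness/kurtosis to 0;
  zero-variance features get unit scale in the z-scorer.
* All stochastic components (schedules, noise, fold assignment, RF/MLP/kNN
  internals) run under derived seeds and restore the caller's RNG state;
  identical `(config, seed)` pipeline runs produce byte-identical
  artifacts, verified by hashing in the tests.

## 7. What the synthetic validation does and does not show

Test and acceptance problem sizes, chosen as the package's own validation
conditions: operator-level oracle checks run on ~1,000 random windows;
behaviour-classification recovery uses 6 animals × 30 min with
leave-one-animal-out CV; the step-counting surrogate uses 10 test animals ×
3 h plus 3 training animals, mirroring a 10-head field cohort.

Passing these checks shows the pipeline recovers the structure its
generator encodes — separable posture/dynamics regimes, a clean periodic
gait, stationary noise. Real collar data adds confounds the generator
deliberately omits: biomechanically irregular gaits and surface effects,
behaviour idiosyncrasies between animals, magnetometer physics, sensor
drift and mounting slip, and rare behaviours (drinking, scratching) outside
the seven-class ethogram. Synthetic recovery rates are therefore an upper
bound on, not an estimate of, field performance; the classifier comparison
machinery, not any particular accuracy number, is the transferable result.

## 8. Known limitations

* The step detector learns the walking signature of the training cohort;
  gait frequencies far from the configured range would need retraining.
* Rectal temperature is a constant reference; no skin-to-core correction
  model is provided.
* No frequency-domain or wavelet features, no hyperparameter search, no
  deep models — all deliberate scope boundaries.
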