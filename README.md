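# glucotyper

Classification of continuous glucose monitoring (CGM) traces into
**glycemic-signature classes** — low, moderate, and severe variability —
and subject-level **glucotypes**, together with the standard suite of
glycemic-variability metrics and ADA-threshold diagnostic summaries.

Standard diabetes diagnostics (HbA1c, fasting glucose, 2-h OGTT) summarize
glycemia with one or two numbers and miss how glucose *fluctuates* through
the day. `glucotyper` instead compares the **shape** of glucose dynamics:
a multi-day CGM trace is cut into overlapping 2.5-hour windows, each
window is smoothed and z-normalized, and all windows across all subjects
are compared with a complexity-invariant dynamic time warping
dissimilarity and clustered spectrally. The class in which a subject
spends the most time is their glucotype. The package is aimed at
researchers analyzing CGM cohorts and at methodologists studying
time-series phenotyping of wearable-sensor data.

## Method at its core

For two equal-length normalized windows *a*, *b*:

- **DTW**: minimal cumulative cost over monotone warping paths with local
  cost |aᵢ − bⱼ| and the classical symmetric step pattern (diagonal steps
  weighted 2), restricted to a Sakoe-Chiba band of 10% of the window
  length.
- **Complexity correction**: CE(x) = √Σᵢ(xᵢ − xᵢ₊₁)² and
  CID-DTW(a,b) = DTW(a,b) · max(CE(a),CE(b)) / min(CE(a),CE(b)),
  penalizing pairs of unequal waveform complexity.
- **Spectral clustering**: a symmetrized k-nearest-neighbor graph is built
  with the smallest *n* for which the graph is connected (unique zero
  eigenvalue of the unnormalized Laplacian L = D − W); the number of
  classes comes from the eigengap of the ascending Laplacian spectrum, and
  the rows of the first-k eigenvectors are partitioned with seeded
  k-means. Classes are ranked into low/moderate/severe by mean raw
  glucose.
- **Out-of-sample classification**: new windows are rescaled with the
  training pool's global mean/SD, their CID-DTW distances to a
  density-weighted reference subset (≥ 200 windows) are converted to
  affinities wᵢⱼ = exp(−d²ᵢⱼ / (σ·εᵢⱼ)) with a locally scaled kernel,
  projected onto the reference spectral embedding, and assigned to the
  nearest class centroid.
- **Variability metrics**: MAGE by iterative turning-point elimination
  (excursions ≥ 1 SD), J index 0.001·(mean + SD)², MODD at 06:00 anchors,
  distance traveled, coefficient of variation, rates of change, and time
  in the prediabetic (140, 200] and diabetic (> 200 mg/dL) ranges.

## Worked example

Everything is testable without real recordings via the built-in cohort
simulator, which generates multi-day, multi-subject traces with known
variability regimes, meal annotations, and clinical records:

```r
library(glucotyper)

cfg     <- sim_config(n_subjects = 6, days = 3, seed = 2024)
cohort  <- simulate_cohort(cfg)
windows <- preprocess_cohort(cohort$series)   # impute, segment, equalize
model   <- glucotype_fit(windows, k = 3, seed = 7)
model
#> <glucotype_model> k = 3, 588 training windows, metric cid_dtw
#> class mean glucose (mg/dL): low 93.3, moderate 116.5, severe 151.4

labels  <- data.frame(
  subject_id = vapply(model$windows, function(w) w$subject_id, character(1)),
  class      = model$classes)
glucotype_summary(labels, series_list = cohort$series)
#>   subject_id frac_low frac_moderate frac_severe glucotype frac_prediabetic_range frac_diabetic_range
#> 1      sim01   0.9592        0.0408           0       low                  0.000               0.000
#> 2      sim02   0.0102        0.9898           0  moderate                  0.116               0.000
#> 3      sim03   0.0000        0.0000           1    severe                  0.300               0.165
#> 4      sim04   0.9694        0.0306           0       low                  0.000               0.000
#> 5      sim05   0.0000        1.0000           0  moderate                  0.140               0.000
#> 6      sim06   0.0000        0.0000           1    severe                  0.287               0.167
```

Each row gives the fraction of a subject's windows in each class; the
glucotype is the majority class, and the last two columns are the
fraction of readings in the prediabetic and diabetic glycemic ranges —
here the two severe-glucotype subjects spend ~30% of their recordings
above 140 mg/dL.

Variability metrics for a single trace:

```r
vr <- variability_report(cohort$series$sim03$glucose)
#> sim03: mean 151.6 mg/dL, sd 39.7, MAGE 103.1, J index 36.6, CV 0.262
```

A command-line entry point wrapping the same functions is installed as
`exec/glucotyper` (`glucotyper run --cgm cgm.tsv --out artifacts/`), and
`run_pipeline()` chains ingest → window → distances → cluster → classify
→ summarize with a JSON manifest of every parameter and seed.

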