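---
title: "Glycemic-signature classification: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Glycemic-signature classification: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glucotyper)
```

This vignette is the package's own account of the science it implements:
the model and its assumptions, the parameters that matter, the numerical
choices made where the design was genuinely open, and what the synthetic
cohorts do and do not demonstrate about real data.

## The problem and the model

Continuous glucose monitors report interstitial glucose roughly every 5
minutes for weeks. Summaries like mean glucose or HbA1c collapse this
record to a point estimate and discard the dynamics: two subjects with
the same mean can differ dramatically in how often, how fast, and how
high their glucose swings. The package phenotypes these dynamics in four
steps.

1. **Windowing.** Each trace is resampled to a uniform 5-minute grid,
   gaps strictly shorter than 15 minutes are linearly interpolated, and
   the trace is cut into sliding windows of 2.5 hours — roughly the
   duration of a postprandial response — with 75% overlap. Windows
   touching an unfilled gap are dropped. Subjects are then equalized to
   the first *N* windows each, *N* being the smallest per-subject count,
   so no subject dominates the clustering.
2. **Normalization.** Windows are smoothed with a Savitzky-Golay filter
   and z-scored with their own mean and sample SD, so that clustering
   sees *shape*, not level or amplitude. Flat (zero-variance) windows are
   flagged degenerate and excluded.
3. **Dissimilarity.** Pairs of normalized windows are compared with
   complexity-invariant dynamic time warping: the symmetric-step DTW cost
   (diagonal weight 2, local cost the absolute difference), constrained
   to a Sakoe-Chiba band of 10% of the window length, multiplied by the
   ratio of the larger to the smaller first-difference energy
   CE(x) = sqrt(sum(diff(x)^2)). DTW absorbs small temporal
   misalignments; the complexity factor prevents a smooth curve from
   matching a jagged one cheaply.
4. **Spectral clustering.** A binary symmetrized k-nearest-neighbor graph
   is built with the smallest neighbor count that connects the graph
   (unique zero eigenvalue of the unnormalized Laplacian). The number of
   classes is read off the eigengap of the ascending Laplacian spectrum;
   the rows of the first-k eigenvectors are partitioned by seeded k-means
   with 50 restarts. Classes are ordered by the mean raw glucose of their
   member windows and named low / moderate / severe; a subject's
   glucotype is the class holding the plurality of their windows, ties
   resolving to the more severe class.

The central assumption is that glycemic dysregulation expresses itself in
the *texture* of 2.5-hour windows — sharpness, frequency, and relative
roughness of excursions — consistently enough that windows cluster by
subject physiology rather than by time of day.

## Tunable parameters

| Parameter | Default | Units | Notes |
|---|---|---|---|
| `window_hours` | 2.5 | h | postprandial time scale; 30 samples at 5 min |
| `overlap_fraction` | 0.75 | — | implies a 37.5-min shift (see below) |
| `max_gap_min` | 15 | min | strict bound: a gap of exactly 15 min is not imputed |
| `smooth_window`, `smooth_order` | 5, 3 | samples, — | Savitzky-Golay; 25-min support |
| `band_fraction` | 0.10 | — | Sakoe-Chiba half-width `ceiling(0.1 m)` = 3 samples |
| `k` | `"auto"` (eigengap) | — | search bounds 2 ≤ k < W/2 |
| k-means restarts | 50 | — | label stability across seeds |
| `kernel_knn` | 20 | — | neighbor count in the local kernel scale |
| reference size | max(200, #new) | windows | out-of-sample classification |

Three of these deserve comment.

**The 37.5-minute shift.** A 75% overlap of a 150-minute window is a
37.5-minute shift, which is off the 5-minute sampling grid. By default
the cumulative window starts are snapped to the grid,
`round(i * 37.5 / 5) * 5`, producing alternating 40/35-minute shifts that
preserve the average overlap; a fixed 35- or 40-minute shift can be
forced with `shift_min`.

**Smoothing before normalization.** The filter runs on raw mg/dL values
and the z-scoring follows, so the normalized shape is a smoothed shape.
Smoothing parameters are configuration-exposed because "polynomial
smoothing" admits many operating points; order 3 over 5 samples tracks
postprandial rises without flattening them.

**Sample SD everywhere.** All standard deviations are the n−1 sample
version, for consistency with common statistical software.

## Out-of-sample classification

New windows are *not* z-scored individually. They are centered and scaled
with the global mean and SD of the entire training pool, stored in the
model, so a new window's level and amplitude survive scaling. Distances
from each new window to a reference subset of training windows are
converted to affinities with the locally scaled Gaussian kernel

w(i,j) = exp(−d²ᵢⱼ / (σ·εᵢⱼ)),  εᵢⱼ = (mean of i's 20-NN distances +
mean of j's 20-NN distances + dᵢⱼ) / 3,

the new windows are embedded by the affinity-weighted combination of the
reference Laplacian eigenvectors, each embedded row is normalized to unit
length, and the label is the class of the nearest reference-class
centroid, ties resolving toward the more severe class. Design choices
that were genuinely open:

- **σ estimation.** σ is precomputed at training as the value making the
  median training-pair affinity equal 0.5, calibrated on the
  globally-scaled training pool — the same scale on which classification
  distances are later computed.
- **Reference selection.** References are sampled per class
  (proportional allocation, every class represented) with probability
  proportional to a Gaussian product-kernel density (Scott bandwidth) of
  the training points in the embedding space, with a fixed seed. This
  keeps the subset concentrated where each class actually lives rather
  than on its fringes.
- **Consistent scaling on both sides.** The reference windows entering
  the classification distances are rescaled with the same global
  constants as the new windows. Mixing per-window z-scores (references)
  with globally scaled values (new windows) would compare incommensurate
  geometries.

On the synthetic cohorts below, reclassifying the training windows
through this path reproduces the training labels for ≥ 99% of windows;
the contract tested is ≥ 95%.

## Variability metrics

- **MAGE** uses turning-point elimination: candidate extrema are located
  on the smoothed trace, then extrema whose excursions on both sides fall
  below 1 × SD of the whole trace are deleted iteratively (weakest
  first, re-merging same-direction runs) until all retained excursions
  clear the threshold; amplitudes are read from the *original* values at
  the retained points. Ascending-only and descending-only means are
  reported alongside the headline mean of all qualifying excursions,
  since conventions differ between laboratories.
- **Threshold counts** (above 140, above 200 mg/dL) count upward
  *crossings* — entries into the range — not samples, since fractions of
  readings are reported separately.
- **MODD** anchors at 06:00 with a ±15-minute tolerance (sensor grids
  jitter) and pairs consecutive calendar days only.
- **Time in ranges** uses prediabetic (140, 200] and diabetic (200, ∞)
  mg/dL; the guideline thresholds of 140 and 200 do not state interval
  closure, so the half-open convention is fixed here and documented.
- The ADA-style diagnosis uses diabetes at HbA1c ≥ 6.5%, fasting glucose
  ≥ 126, or 2-h OGTT ≥ 200 mg/dL, and prediabetes at HbA1c strictly
  between 5.7 and 6.5, fasting 100–125, or OGTT 140–199. The strict
  "> 5.7" lower bound is deliberate (ADA's own documents use ≥); the
  difference affects only the exact value 5.7.

## The synthetic cohort generator

`simulate_cohort()` produces traces as baseline + circadian sinusoid +
a train of log-normal-shaped excursions + AR(1) noise, clipped to the
40–400 mg/dL device range, with Poisson sensor gaps. The AR(1)
autocorrelation (ρ = 0.7) matters: white noise makes warping distances
trivially easy.

The three regimes are graded along the axes that per-window z-scoring
preserves: excursion amplitude (20 / 50 / 110 mg/dL), spacing between
excursion onsets (180 / 80 / 42 min), time-to-peak (60 / 25 / 11 min,
i.e. sharpness), short-term fluctuation SD (1 / 5 / 7 mg/dL), and
baseline (80 / 95 / 115 mg/dL). The defaults were chosen so that every
2.5-hour window carries its subject's regime texture — gentle slow waves
for `low`, brisk intermediate pulses for `moderate`, tall sharp frequent
spikes for `severe` — because window-level regime recovery is the
property the clustering is specified to deliver on well-separated
regimes. Two caveats follow directly:

- Real cohorts are *not* well separated: real subjects mix textures
  across the day (meals, nights, exercise), and their windows spread
  across classes, which is precisely why the class-time *fractions*
  rather than a hard subject label are the primary phenotype. Passing
  the recovery tests therefore demonstrates correctness of the machinery
  on its design conditions, not that real cohorts separate this cleanly.
- The generator is phenomenological. It does not model insulin-glucose
  feedback (no minimal model), sensor drift or recalibration artifacts,
  or behavioral covariates; clinical records are drawn with a simple
  severity gradient merely to exercise diagnosis-by-glucotype tables.

## Numerical choices and degenerate inputs

- Distance-based sums of squares use the pairwise form
  SS = Σᵢ<ⱼ d²ᵢⱼ / n per group, which reproduces the Euclidean
  decomposition exactly and generalizes it to arbitrary dissimilarities;
  entropy uses natural logarithms; a singleton cluster's silhouette is 0.
- kNN ties at the n-th neighbor break by window-id order, making graph
  construction deterministic.
- The complexity factor guards against flat windows with ε = 1e-12
  (CF = 1 when both energies are below ε); flat windows are excluded
  upstream anyway.
- Duplicate timestamps keep the first observation (sensor
  re-transmissions are common); timestamps are timezone-naive and
  handled in a fixed UTC representation.
- Connectivity can be checked via the zero-eigenvalue count of the
  Laplacian or via graph traversal; the two are mathematically identical
  (the multiplicity of eigenvalue 0 equals the number of components),
  and the implementation switches to traversal above 400 windows purely
  for speed. The clustering itself uses the unnormalized Laplacian; the
  symmetric normalized variant is available behind a flag.
- k-means empty-cluster events trigger reseeded retries (up to 5) before
  erroring.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run entirely on simulated data:
a 6-subject, 3-day cohort (~600 windows) for the unit-level contracts
and a 12-subject, 7-day cohort (~3,000 windows, ~250 windows per
subject) for end-to-end regime recovery and reclassification. At these
sizes a full fit — pairwise CID-DTW, connectivity scan, eigengap,
partition — takes on the order of one to two minutes on a single core;
the compiled banded-DTW kernel makes the pairwise stage linear in the
band width rather than quadratic in the window length.

## Known limitations

- The eigengap heuristic is reliable when classes are balanced and
  well-separated; on heterogeneous graphs it can overshoot, which is why
  `glucotype_fit()` accepts a fixed `k` and reports the full spectrum
  for audit.
- With k ≠ 3 the severity map falls back to generic ordinal names and
  the three-class subject summaries do not apply.
- CID-DTW is not a metric (the triangle inequality can fail), which is
  harmless for graph-based clustering but precludes metric-tree
  indexing.
- MODD requires 06:00 anchors on consecutive days; sparse or gappy
  recordings yield `NA` rather than a value extrapolated from other
  anchor times.
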