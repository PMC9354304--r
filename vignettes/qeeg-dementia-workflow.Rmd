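---
title: "Quantitative EEG reactivity biomarkers and dementia classification with qeegdx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative EEG reactivity biomarkers and dementia classification with qeegdx}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qeegdx)
```

## The problem

Dementia with Lewy bodies (DLB) is frequently misdiagnosed as Alzheimer's
disease (AD), and DLB and Parkinson's disease dementia (PDD) shade into one
another clinically. Resting-state EEG is an inexpensive, non-invasive probe
of the cortical dynamics these conditions disturb, and quantitative EEG
(qEEG) — numbers extracted from the EEG power spectrum — has repeatedly
shown group-level differences between healthy ageing and the dementias.
Most of that work uses only the eyes-closed (EC) resting state. qeegdx
implements a complete pipeline built around the idea that the eyes-open
(EO) recording, acquired routinely in clinical neurophysiology but rarely
analysed, carries complementary discriminative information — in particular
through *reactivity*: how spectral dynamics change between the EC and EO
states.

The pipeline has five stages, each exposed as ordinary functions over data
frames:

1. **Synthetic cohort generation** — seeded EC/EO recording pairs for
   HC/AD/DLB/PDD cohorts (`make_cohort()`), so every downstream stage is
   testable without clinical recordings.
2. **Preprocessing** — baseline subtraction, zero-phase band-pass,
   spherical-spline bad-channel interpolation, common-average reference,
   overlapping 2-s segmentation (`preprocess_recording()`,
   `segment_windows()`).
3. **Spectral features** — Welch periodograms and the qEEG feature set
   (`build_feature_table()`).
4. **Group statistics** — four-group ANOVA / Kruskal–Wallis with
   Bonferroni post hoc pairs (`compare_features()`).
5. **Feature selection and classification** — NCA-ranked wrapper selection
   (`wrapper_select()`) and cross-validated cosine-KNN / logistic /
   quadratic-SVM classifiers (`cross_validate()`, `two_step_classify()`).

## Spectral feature definitions

Each preprocessed recording is cut into 2-s windows advancing by 1 s
(consecutive windows share half their samples). Each 2048-sample window is
Hamming-tapered, zero-padded to an FFT length of $2^{13}$, and normalized
as a one-sided power spectral density; at the nominal 1024 Hz sampling rate
the frequency grid has a spacing of exactly $1024 / 2^{13} = 0.125$ Hz.
Because the windows themselves overlap by 50%, the across-window mean of
these periodograms is exactly a Welch PSD estimate with Hamming taper and
50% segment overlap — one estimator read two ways, which the suite checks
against an independent single-call oracle.

From the per-window spectra the package computes, per channel and then
averaged within frontal/central/temporal/parietal/occipital regions:

* **Relative band power** for delta (0.5–4 Hz), theta (4–5.5), high theta
  (5.5–8), alpha (8–13) and beta (13–30), each integrated over the mean
  spectrum and divided by total 0.5–30 Hz power. Band intervals are
  half-open `[low, high)` with beta closing at 30 Hz, so the five fractions
  sum to 1 by construction.
* **Dominant frequency (DF)**: the argmax frequency bin in 4–15 Hz of each
  window's spectrum (ties to the lower bin), averaged over windows.
* **Dominant frequency variance (DFV)**: the sample (n−1) standard
  deviation of those per-window argmax values. The per-window argmax is
  taken first and then summarized — not the argmax of the mean spectrum —
  because a variance across windows requires per-window values.
* **Theta–alpha ratio (TAR)**: high-theta relative power over alpha
  relative power. The numerator is configurable (`theta`, `theta_broad`)
  because the two natural conventions differ only in which theta range is
  used; high theta is the default as it is where a slowed dominant rhythm
  lands.
* **EC/EO DFV ratio**: the reactivity biomarker, DFV in EC divided by DFV
  in EO, one value per region for subjects with both conditions.

DF and DFV are computed per channel and then region-averaged (rather than
on region-averaged spectra); with a clear oscillatory peak the two orders
agree, and the per-channel route degrades more gracefully when a single
channel is noisy.

## The synthetic cohort model

Clinical EEG cannot ship with a package, so qeegdx includes a generative
model whose spectral structure embodies the qualitative group contrasts the
pipeline is designed to detect:

* a $1/f^{\chi}$ background (spectrally shaped white noise, $\chi = 1$ by
  default, 6 µV SD), independent per channel;
* one shared oscillation whose amplitude is region-weighted (largest
  occipitally: 20 µV, parietal 15 µV, elsewhere 7–8 µV) and attenuated by
  an eyes-open factor in the EO condition;
* a per-epoch dominant frequency: once per non-overlapping 2-s epoch the
  oscillator frequency is redrawn from
  $\mathcal{N}(\mathrm{DF}_\mathrm{mean}, \sigma_\mathrm{jitter})$, with
  phase kept continuous across epoch boundaries. The epoch grid matches the
  analysis windows, so injected jitter maps directly onto estimated DFV;
* a per-subject offset on the centre frequency (SD 0.4 Hz) modelling
  stable inter-individual differences.

The default group parameters (`default_group_params()`) are package design
choices, not measurements: healthy controls oscillate at 9.5 Hz with
0.3 Hz jitter in EC and 1.0 Hz in EO (their EC/EO DFV ratio therefore sits
well below 1), while the dementia groups are slowed into the high-theta
range (AD 7.5 Hz, DLB 6.8 Hz, PDD 7.0 Hz) with equal 0.6–0.7 Hz jitter in
both conditions (ratio near 1). Eye opening attenuates the healthy alpha
rhythm strongly (factor 0.4) and the dementia rhythm weakly (0.8),
reflecting blunted alpha reactivity in dementia. One documented
contradiction in the source literature concerns the *direction* of the
healthy reactivity effect; the package follows the reading under which
healthy DFV is higher in EO (ratio < 1), and both directions are
representable through the parameters.

What the generator does *not* model: ocular and muscle artefacts, line
noise, inter-channel phase structure, or non-stationarities beyond the
frequency jitter. Passing tests on synthetic cohorts therefore demonstrate
that the *mechanism* — extraction, statistics, selection, classification —
behaves correctly on data with known ground truth; they say nothing about
classification accuracy on clinical recordings.

```{r cohort, eval = FALSE}
montage <- default_montage("reduced")
spec <- cohort_spec(
  group_sizes = c(HC = 15, AD = 12, DLB = 21, PDD = 17),
  duration_s = 150, montage = montage, seed = 1
)
cohort <- make_cohort(spec)
features <- build_feature_table(cohort, montage)
plot_dfv_ratio(features)
```

## Preprocessing choices

* *Band-pass.* The "phase invariant" 0.3–54 Hz Butterworth band-pass is
  realized as an order-2 high-pass cascaded with an order-2 low-pass, each
  run forward and backward (`filtfilt`), i.e. zero phase with the squared
  magnitude response of the design. The cascade form is used because a
  single order-2 band-pass in transfer-function form is numerically
  ill-conditioned at a normalized cutoff of 0.3/512. Channel means are
  removed before filtering and any residual numerical DC after it.
* *Bad channels* are re-estimated by spherical-spline interpolation
  (order $m = 4$, 7 Legendre terms, ridge $10^{-5}$ on the fitting
  system) from the good channels on the unit-sphere montage.
* *Reference.* Recordings are re-referenced to the common average; the
  original acquisition reference channel (Fz by default) is deleted first
  and not restored, configurable via `drop_reference`.
* *Inclusion rule.* Subjects need at least 20 s of usable EEG. The default
  reads this as EC + EO *combined*; `rule = "each"` requires both
  conditions separately. Both readings are defensible; the combined sum is
  the default because the wording "combined" suggests addition.
* Manual artefact-segment rejection and ICA cleaning are deliberately out
  of scope: they require human inspection, and the package's inputs
  (synthetic or pre-cleaned exports) do not need them.

## Group statistics

`compare_groups()` runs a classic equal-variance one-way ANOVA across the
four groups when every group passes a normality screen, and Kruskal–Wallis
otherwise. The visual Q-Q inspection that motivates the screen is automated
as a per-group Shapiro–Wilk test at $\alpha = 0.05$ — a reproducible proxy
for the same decision. Post hoc pairwise comparisons use unpaired
two-sample t-tests (rank-sum tests on the non-parametric branch) with a
Bonferroni factor of 6, the number of group pairs; corrected p-values are
capped at 1. No correction is applied *across* features — correction is
within each feature's post hoc family only, which mirrors standard qEEG
reporting practice and is worth remembering when scanning many features.

## Feature selection

`nca_fit()` implements neighbourhood component analysis: nonnegative
per-feature weights $w$ maximize the regularized expected leave-one-out
assignment objective

$$\sum_i \sum_{j \neq i,\, y_j = y_i} p_{ij} - \lambda \sum_f w_f^2,
\qquad
p_{ij} = \frac{\exp(-d_{ij})}{\sum_{k \neq i} \exp(-d_{ik})},
\qquad
d_{ij} = \sum_f w_f^2 (x_{if} - x_{jf})^2,$$

by gradient ascent with a backtracking line search (the objective trace is
non-decreasing by construction; default at most 200 iterations, stopping
when the objective improves by less than $10^{-6}$). The inner evaluation
is implemented in C++ for speed. $\lambda$ is chosen once per dataset by
5-fold cross-validation over $\{0, 0.25, 0.5, 1\}/n$.

`wrapper_select()` then runs the repeated wrapper protocol: in each of 100
runs the data is split 70/30 (stratified), features are z-scored with
training statistics only, NCA ranks them, and a greedy forward pass keeps a
feature iff adding it *strictly* improves the held-out accuracy of the
reference cosine-KNN classifier. The pass starts from the empty model
(accuracy 0): under cosine distance a single standardized feature carries
only sign information and can never strictly beat a majority-class
baseline, so seeding from the empty model — as forward selection
conventionally does — is what makes the strict-improvement rule operable.
Features picked in at least 95% of runs are retained. Each run re-splits
the data; this measures selection stability under sampling variation, which
is what repeating the runs is for.

The packaged selection-stability fixture
(`simulate_selection_features()`) gives each sample one of three latent
subtypes and shifts that subtype's informative feature by ±4 SD with the
class. Each informative feature then contributes a distinct, large
held-out accuracy gain — the regime in which a strict-improvement wrapper
picks all of them consistently while noise features, once accuracy
saturates, can no longer earn a place.

## Classification

Three classifiers are provided with the conventions their presets imply:
cosine KNN (10 neighbours by default, distance $1 - \cos$, distance ties
broken by training order and vote ties by the nearest neighbour; operates
on features as given, since cosine distance is scale-invariant), ridge-
stabilized logistic regression, and a degree-2 polynomial-kernel SVM (box
constraint 1); the latter two z-score features with training-fold
statistics. `cross_validate()` uses seeded stratified 10-fold CV and pools
out-of-fold predictions into one confusion table. Reported per task:
accuracy, sensitivity (recall of the positive class), specificity, each
with a 95% Wald half-width $1.96\sqrt{p(1-p)/n}$ where $n$ is the task
size for accuracy and the class sizes for sensitivity/specificity, and the
prevalence-weighted mean of per-class trapezoidal AUCs. Positive-class
conventions follow the clinical question: dementia for HC-D, DLB for
AD-DLB, PDD for DLB-PDD.

`two_step_classify()` emulates the clinical triage route: step 1 filters
healthy controls from non-healthy participants (cross-validated HC vs
rest); step 2 evaluates each dementia group one-vs-rest *among the
subjects predicted non-healthy at step 1* (configurable to use true
non-healthy instead). Subjects predicted healthy appear in no step-2
evaluation. `compare_feature_sets()` reuses one fold assignment across
feature sets so that EC-only vs EC+EO differences are attributable to the
features, not the partitioning.

## Packaged experiments and problem sizes

Four seeded experiments wrap the pipeline end to end; the acceptance script
(`scripts/acceptance.R`) and the test suite run them at these sizes, chosen
to make each mechanism measurable with comfortable margins while keeping a
full run in the minutes range:

* `jitter_recovery_experiment()` — 2 occipital channels, 30-s recordings,
  50 replicates per jitter level in {0.1, 0.3, 0.6, 1.0} Hz. With zero
  background noise and zero jitter the DF estimate equals the injected
  frequency exactly (the oscillator sits on the 0.125 Hz grid) and DFV is
  exactly 0; with noise, mean estimated DFV must increase with injected
  jitter.
* `dfv_reactivity_experiment()` — 20 cohorts at the 15/12/21/17 group
  sizes, one electrode per region, 24 s per condition. Summarises the
  parietal EC/EO DFV ratio medians and whether HC differs from each
  dementia group at Bonferroni-corrected p < 0.05.
* `selection_stability_experiment()` — 20 repeats of the full 100-run
  wrapper on 3 informative + 20 noise features, n = 60 per class.
* `ec_eo_benefit_experiment()` — 20 cohorts of 15 + 15 subjects whose
  groups share identical EC physiology and differ only in EO jitter, so
  the discriminative signal lives exclusively in EO/ratio features;
  EC-only and EC+EO classification reuse identical folds.

## Numerical conventions and edge cases

* Argmax ties in the DF search band resolve to the lowest frequency bin.
* DFV is undefined (`NA`) with fewer than two windows; the EC/EO ratio is
  `NA` when the EO DFV is zero or missing.
* Windows that would overrun the recording are dropped, keeping every
  window at exactly `window_s * sampling_rate` samples.
* Band-power integration uses the rectangle rule on the 0.125 Hz grid.
* EDF export quantizes to 16 bits over a per-channel physical range padded
  by 1%, so round-trip error is bounded by about one quantum; argmax-based
  features survive the round trip exactly in practice, band powers to
  roughly $10^{-3}$ relative.
* Identical configuration + seed gives bit-identical cohorts, selection
  reports and pipeline outputs; per-subject and per-run substreams derive
  from the master seed.

## Limitations

The synthetic cohort is a mechanism testbed, not a patient simulator:
real EEG has artefacts, inter-channel dependence, broadband reactivity and
within-group heterogeneity the generator does not attempt. Classification
numbers obtained on synthetic cohorts characterize the pipeline, not any
clinical population. The NCA leave-one-out objective can overfit pure
noise at small n — weight concentration alone is not evidence of signal,
which is exactly why the wrapper protocol validates every candidate
feature against held-out accuracy across repeated splits.
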