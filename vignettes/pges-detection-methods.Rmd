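---
title: "Detecting the end of postictal generalized EEG suppression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting the end of postictal generalized EEG suppression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgesdetect)
```

## The problem

Postictal generalized EEG suppression (PGES) is the diffuse attenuation of
scalp EEG — background activity below about 10 µV — that can follow a
generalized tonic–clonic seizure. Prolonged PGES (beyond roughly 50 s) has
been reported as a risk marker for sudden unexpected death in epilepsy, so
measuring PGES duration matters clinically. The end of PGES is marked by the
return of intermittent slow waves (ISW): low-frequency (0.5–5 Hz) bursts
that break the suppressed background.

Reading the end of PGES off the raw trace is harder than the 10 µV
definition suggests, because epilepsy-monitoring-unit recordings carry
high-amplitude physiological artifacts — breathing-coupled rhythms, muscle
activity, body and bed movements — that imitate or mask slow-wave activity.
The central failure mode of automated detectors is mistaking a low-frequency
artifact for the first ISW.

`pgesdetect` implements a hybrid unsupervised/supervised detector for
multi-channel scalp EEG (18 bipolar channels, 200 Hz, 5-minute postictal
windows):

1. **Feature extraction.** Each 1-second epoch is described by time-domain
   statistics and Hjorth parameters, low-band spectral powers, wavelet
   energies, inter-channel correlations, and an empirical-mode-decomposition
   (EMD) / Hilbert-spectrum amplitude feature.
2. **Artifact clustering.** Each recording is summarized by an 18 × T map of
   low-frequency (0.5–5 Hz) Hilbert amplitude over time; K-means groups
   recordings with similar spatiotemporal artifact patterns.
3. **Cluster-oriented classification.** One sample-weighted random forest is
   trained per cluster, with epochs from the focal cluster's recordings
   up-weighted; a new recording is routed to its nearest cluster's forest.
   Per-epoch suppression/non-suppression labels pass through a
   confidence-based correction, and the predicted PGES end is the start of
   the first non-suppression epoch after suppression.

Evaluation is recording-based rather than epoch-based: the quantity that
matters clinically is the time distance `TD_r = |P_end − T_end|` between the
predicted and annotated PGES end, aggregated as its mean `TD_avg` and the
fractions of recordings within 5 s (`Acc_5s`) and 10 s (`Acc_10s`),
tolerances inclusive.

## Empirical mode decomposition and the Hilbert spectrum

EMD decomposes a signal `x(t)` into intrinsic mode functions (IMFs) plus a
residual trend, `x(t) = Σ IMF_i(t) + r_N(t)`, by *sifting*: find the local
extrema, interpolate upper and lower envelopes through them, subtract the
envelope mean, and repeat until the candidate satisfies the IMF criteria —
extrema and zero-crossing counts differing by at most one, and near-zero
envelope mean. Each accepted IMF is removed and sifting restarts on the
remainder until no further mode can be extracted. Modes emerge ordered from
high to low frequency. Applying the Hilbert transform to each mode yields
instantaneous amplitude and frequency — the Hilbert spectrum — which, unlike
Fourier or wavelet coefficients, follows frequency changes sample by sample.

Numerical choices (the IMF definition itself fixes none of these):

* **Envelopes**: natural cubic splines through the extrema, mirror-extended
  by two extrema at each boundary to tame end swings.
* **Sifting stop**: Cauchy criterion `Σ m² / Σ y² < 0.2` *and* the
  extrema/zero-crossing count rule, or 50 iterations. Requiring the count
  rule as well costs a few extra passes but makes every returned mode a
  valid IMF by the counting definition.
* **Envelope-mean tolerance** for `is_imf()`: RMS of the envelope mean below
  0.05 × signal RMS.
* **Mode cap**: 10 modes (real traces typically decompose into ~8), which
  stops over-sifting of residual noise.
* Sifting is implemented in C++; a 300-s channel decomposes in tens of
  milliseconds, which is what makes leave-one-out experiments tractable.

The reconstruction identity holds to machine precision by construction and
is asserted for every decomposition in the test suite.

Two features come out of this analysis:

* **Per-epoch HHT feature** — the summed Hilbert amplitude of all modes of a
  1-second epoch of the 0.5–30 Hz filtered signal, one value per channel.
* **Artifact feature map** — per channel, the Hilbert amplitude of every
  mode of the *whole* recording accumulated into 1-second bins, but only
  where the instantaneous frequency falls in 0.5–5 Hz. The map is the
  clustering representation: it localizes low-frequency (artifact and ISW)
  energy in channel × time.

The map is normalized by its own 95th percentile so that clustering compares
spatiotemporal patterns, not absolute amplitude or recording gain. A
limitation worth knowing: when broadband noise rides on a tone, EMD may
split energy across two beating modes, and the per-bin amplitude sum then
redistributes between bins even though the map's total and pattern stay
stable (the tests assert <10% change of the gated total and pattern
correlation >0.9 under added 20–30 Hz content, not bin-level equality).

## Preprocessing and the feature bank

Two zero-phase 4th-order Butterworth band-passes are applied to the
postictal window (reflective padding, forward–backward filtering so epoch
timing is not shifted): 0.5–30 Hz for the EMD features and 0.5–5 Hz for
everything else, the band where intermittent slow waves live. Epochs are
non-overlapping 1-second segments, `[i, i+1)` seconds, 0-based; predicted
times are reported as epoch starts in whole seconds.

Per channel and epoch the feature bank holds: mean, skewness, excess
kurtosis, Hjorth activity/mobility/complexity (population variances;
degenerate epochs report 0), periodogram power in 0.5–1, 1–4 and 4–5 Hz
(band edges inclusive at the 1 Hz resolution of a 1-s epoch; bands above
5 Hz would only measure filter stopband leakage and are omitted), and
db4 wavelet energies over 4 levels. Epochs are zero-padded to 256 samples so
the periodized transform stays orthonormal (200 is not divisible by 2⁴);
coefficient energy then equals signal energy exactly. Across channels, all
153 pairwise Pearson correlations are added. With the HHT feature this gives
18 × 15 + 153 = 423 features per epoch.

Epoch labels derive from the annotation: `suppression` when the epoch start
precedes the annotated PGES end, `non_suppression` otherwise; recordings
without PGES contribute only non-suppression epochs.

## Clustering and the sample-weighted forests

Flattened artifact maps are clustered by K-means (k-means++ seeding, Lloyd
iterations, 10 restarts, best inertia kept; deterministic given the seed).
`K` is a configuration knob: 7 by default, and the pipeline runs unchanged
for K in {7, 20, 50, 100} at dataset scale.

For each non-empty cluster a probability random forest (100 trees, unlimited
depth, √p features per split) is trained on *all* epochs, with sample weight
`boost` (default 2) on epochs from the focal cluster's recordings and 1
elsewhere. The forest therefore specializes toward its cluster's artifact
regime without discarding the rest of the data. When every weight is 1 the
weights are omitted entirely, so `K = 1, boost = 1` reproduces a plain
random forest bit for bit — that reduction is asserted in the tests and is
the baseline in the hybrid-vs-baseline comparison.

Per epoch, the predicted label is the majority tree vote and the confidence
is the vote fraction. The correction rule then absorbs implausible state
flips: any run of identical labels shorter than `min_run` (default 3) epochs
whose mean confidence is below `conf_thresh` (default 0.8) takes the label
of the preceding run (the first run takes the following run's label),
scanning left to right until a fixpoint. Runs of length ≥ `min_run`, and
confident short runs, are never changed. The exact correction rules of the
prior recording-based evaluation work are not public; this rule implements
their stated intent — suppressing sudden, low-confidence state changes — and
is deliberately simple and order-deterministic.

The predicted PGES end is the start time of the first non-suppression epoch
following at least one suppression epoch; a recording with no suppressed
epoch reports "no suppression detected", and one that never resumes reports
the window end, flagged.

Recordings without PGES are scored against `T_end = 0` (suppression ends
immediately), so a detector that finds no suppression scores `TD_r = 0`
there; such folds are flagged in the report. Within every leave-one-out
fold, both the cluster model and the forests are refit on the training
recordings only.

## The synthetic study data

The study data behind the published method are not public, so the package
generates postictal recordings with exact ground truth; every downstream
stage is tested against the generator, and the generator itself is tested
against independent periodogram oracles.

A simulated recording is: band-limited (0.5–30 Hz) Gaussian noise at
`suppression_sigma` (default 1.0 µV RMS — per-epoch peak-to-peak stays below
the 10 µV criterion on all 18 channels) during the suppression interval;
from the PGES end onward, background noise at `background_sigma` (default
10 µV RMS) plus ISW bursts — raised-cosine-windowed 0.5–5 Hz sinusoids with
jittered frequency, phase, duration (0.75–1.5 s) and amplitude (default
40 µV ± 20%), arriving as a Poisson process (default 0.5/s) with the first
burst pinned exactly at the annotated PGES end so ground truth is exact.

Artifact archetypes superimpose channel- and time-localized waveforms:

* **breathing** — a 0.25–0.4 Hz non-sinusoidal rhythm with harmonics
  (respiration-coupled artifacts are peaked, not sinusoidal), so energy
  reaches into the 0.5–2 Hz band the detector actually watches;
* **muscle** — 20–30 Hz band-limited noise (inside the 0.5–30 Hz analysis
  band but gated out of the 0.5–5 Hz artifact map);
* **movement** — repeated sharp Gaussian transients (0.1–0.4 s wide).

Dataset generation stratifies archetypes over recordings by
largest-remainder allocation (deterministic), draws PGES durations from a
lognormal with median ≈ 40 s (configurable, or uniform via `pges_range`),
and tags each recording with its generating archetype — the tag is hidden
from the pipeline and used only as clustering ground truth.

What the generator does *not* emulate: physiological EEG rhythms and their
postictal evolution, ictal activity, electrode artifacts, inter-patient
variability, or mixed/overlapping artifact classes. Passing tests on this
data demonstrate that the machinery is correct and that the hybrid design
behaves as intended under controlled artifact structure — not clinical
performance on real EMU recordings.

## Study sizes and reproducibility

The packaged experiments (tests and `scripts/acceptance.R`) use: 200 random
two-second signals for EMD validity; 40 recordings of 100 s (two
disjoint-channel archetypes at high intensity) for exact cluster recovery;
60 artifact-light recordings of 135 s with PGES durations 20–120 s for the
leave-one-out recovery experiment (K = 2; Acc_10s ≥ 0.8 and median TD ≤ 2 s
expected); and 24 recordings of 120 s with three archetypes for the
hybrid (K = 3, boost = 2) vs baseline (K = 1, boost = 1) comparison on
identical folds. Every stochastic step takes an explicit seed; reruns with
the same configuration are byte-identical, and all reported numbers are
recomputed at run time.

## Known limitations

* EMD mode splitting under noise limits bin-level stability of the artifact
  map (discussed above); clustering uses whole-map patterns and is robust to
  it in practice.
* The correction rule is an interpretation of an unpublished procedure;
  its parameters (`min_run`, `conf_thresh`) are exposed.
* The muscle archetype is invisible to the 0.5–5 Hz artifact map by design;
  clustering can only separate artifact classes that leave low-frequency
  signatures.
* The no-PGES scoring convention (`T_end = 0`) is a choice the published
  metrics leave open; it rewards detectors that correctly report "no
  suppression" and penalizes false suppression intervals.

## A minimal session

```{r example, eval = FALSE}
library(pgesdetect)

archs <- list(
  artifact_archetype("breath-temporal", 1:8, "breathing", 10, 25, 150))
ds <- simulate_dataset(12, archs, seed = 42,
                       params = simulation_params(duration = 120,
                                                  pges_duration = NA))
cfg <- pipeline_config(K = 2, boost = 2, map_T = 120, seed = 42)
report <- loo_cv(ds, cfg)
print(report)
report$details
```
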