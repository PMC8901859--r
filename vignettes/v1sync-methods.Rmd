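---
title: "Methods: synthetic V1 populations, synchrony, and morphometrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic V1 populations, synchrony, and morphometrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(v1sync)
```

# Scientific setting

Layer-2/3 neurons of mouse primary visual cortex respond sparsely to small
visual stimuli and more broadly to large ones. A hypersensitive circuit
shows three linked signatures: (i) the fraction of neurons recruited by a
*small* stimulus approaches the fraction recruited by a *large* one, (ii)
spontaneous activity contains epochs in which many neurons fire in the same
imaging frame, far beyond what independent firing predicts, and (iii) an
accompanying behavioral startle-like response (the "vidget", measured with
a piezo sensor under the forepaws) is exaggerated. `v1sync` implements the
full measurement chain for these signatures on synthetic two-photon data
with known ground truth, plus dendritic morphometrics of reconstructed
neurons.

All experimental quantities being measurements on live animals, the package
ships a generator whose parameters *are* the study conditions; analyses are
validated by parameter recovery, enumeration oracles, and null-model
calibration rather than by reproducing any particular animal's numbers.

# The generative model

## Population and protocol

`make_population()` places `n` neurons uniformly (optionally in Gaussian
clusters, reflected at the edges) in a square field of view of
517.77 µm — the scale of a typical 2-photon field at low zoom. Each neuron
gets one of four functional types with default fractions
(0.40, 0.10, 0.10, 0.40):

| type | responds to small (S1) | responds to large (S4) | default p(S1), p(S4) |
|------|------------------------|------------------------|----------------------|
| 1    | no                     | yes                    | 0, 0.6               |
| 2    | yes                    | no                     | 0.5, 0               |
| 3    | yes                    | yes                    | 0.5, 0.6             |
| 4    | no                     | no                     | 0, 0                 |

`stim_protocol()` interleaves (by default randomly) 5 repeats each of a
small (S1, 10.2°) and a large (S4, 70.8°) drifting-grating stimulus, 2 s
on, 20 s inter-stimulus interval, 5 s lead-in.

## Activity and traces

`simulate_activity()` draws, per neuron and trial, a Bernoulli response
with the type's probability; a responding trial places one spike uniformly
inside the 2-s stimulus window. Spontaneous activity is Poisson at
`bg_rate` (default 0.02 Hz). Optional population events occur at
`sync_rate` Hz and recruit a `sync_recruit` fraction of neurons in one
frame — the mechanism that generates high-order synchrony.

`render_traces()` convolves the spike train with an exponential calcium
kernel (decay `tau_decay` = 1 s, amplitude `amp` = 0.12 ΔF/F — indicator
kinetics of an OGB-1-like dye at 20.4 Hz), adds i.i.d. Gaussian noise
(`noise_sd` = 0.01 ΔF/F), and scales around a baseline fluorescence
`F0` = 100. The default amplitude-to-noise ratio of 12 is deliberately
comfortable; recovery tests also run at 5–6, where detection becomes
genuinely hard. `render_movie()`/`make_roiset()` optionally rasterize
traces into a pixel movie (and 16-bit TIFF) so the ROI-extraction step can
be tested end to end.

### Realism and limitations

The generator is a *point-process + kernel* model: no drift, no neuropil
contamination, no motion artifacts, no overlapping ROIs (overlap triggers a
warning), and one spike per responding trial. Spikes closer together than
roughly one decay time merge into a single detected transient; at the
study's response rates (≤ 0.35 per 22-s trial cycle, spontaneous
≤ 0.02 Hz) such collisions are rare, but the detector should not be
expected to resolve bursts.

## Behavioral (piezo) channel

`simulate_piezo()` produces a 1000-Hz voltage around a 2-V baseline with an
exponentially decaying deflection of amplitude `evoked_amp` beginning
`latency_s` (default 0.1 s) after each stimulus onset.

## Morphologies

`make_morphology()` grows random dendritic trees (default 4 primary
dendrites, branching probability 0.4 per segment, mean segment length
40 µm, maximum order 5) and returns them as SWC tables.

# The measurement chain

## Transient detection

`compute_dff()` forms ΔF/F₀ with a global-median baseline (or a per-epoch
1-s pre-stimulus mean). `detect_transients()` estimates baseline mean and
SD by iterative 3-SD clipping, thresholds at mean + 2.5 SD, and keeps
strict local maxima at least 0.25 s apart (the larger peak wins). Two shape
checks remove the threshold rule's characteristic false positives on noisy
decay tails, where a dip-then-rise "echo" re-crosses the threshold:

* **rise check** — the peak must exceed the *median* of the preceding
  0.5 s by the full threshold margin, and that median must lie in the
  lower half of the margin (a decay tail keeps the median high, a genuine
  onset does not);
* **sustain check** — every frame within 0.2 s after the peak must stay in
  the upper half of the margin (a one-frame noise spike does not).

Both checks are design choices of this package; thresholds (0.5 s median
window, half-margin level, 0.2 s sustain) were fixed by inspecting
synthetic false positives and are validated by the precision/recall tests.

## Responsiveness and the NAI

A neuron *responds on a trial* if a detected transient peak falls in the
half-open window [onset, onset + 2 s). Frame windows are computed as
`ceiling(t·f) + 1 … ceiling(t·f)` in 1-based indexing, so abutting windows
never share a frame. The percent responsive for a stimulus is the mean
over trials of the per-trial responding percentage (so it estimates the
population-mean response *probability*, not the ever-responded fraction,
which is reported separately). The normalized activity index is

NAI = percent responsive (S1) / percent responsive (S4),

≈ 0.29 under the default probabilities (0.10/0.35 among responsive types)
and → 1 as small-stimulus recruitment approaches large-stimulus
recruitment.

## n-order synchrony and its null

With binary event trains (neurons × frames), `firing_counts()` tallies
Firing(n) = number of frames in which exactly *n* neurons have a transient
peak, and `correlation_prob()` divides by the total frame count
Total(T, f) = ⌈T·f⌉ (73.5 s at 20.4 Hz → 1500 frames). Probabilities are
aggregated into the 1–10 and 11+ bands. The null model preserves each
neuron's spike count exactly: every neuron's train is independently
permuted across frames (or circularly shifted), 10,000 times by default,
in compiled code driven by R's RNG so results are seed-reproducible.
Observed band probabilities are compared with the null's 97.5th
percentile. `sync_analysis()` averages over random 30-neuron subcircuits
to make populations of different sizes comparable.

## Pairwise correlation vs. distance

`preprocess_trace()` low-pass filters ΔF/F₀ (4th-order Butterworth, 2 Hz,
zero-phase), inverts the calcium kernel exactly
(d[t] = x[t] − e^(−1/(f·τ))·x[t−1], τ = 3 s), and zeroes samples below 2 SD,
giving sparse nonnegative activity. The pair coefficient is the cosine
A·B / (‖A‖‖B‖). `distance_binned_correlation()` bins pairs by Euclidean
somatic distance into half-open 50-µm bins.

## Spatial dispersion of functional types

Because the four functional groups have very different sizes, a plain
nearest-neighbor distance is biased. `knn_subgroup_nnd()` instead draws,
for each neuron, random subgroups of k = 5 other neurons (from the whole
population by default) and records the distance to the nearest of them;
the per-neuron value is the running mean, accepted once its relative
change stays below 10⁻³ for 100 consecutive draws (cap 10,000). With a
pool of exactly k candidates the statistic is computed deterministically.

## Vidget scoring

`piezo_preprocess()` block-averages 1000 Hz → 100 Hz, normalizes by the
session mean ((F − F₀)/F₀) and rectifies. The score is the mean rectified
magnitude in [onset, onset + 0.5 s); the delay is the first crossing of
baseline mean + 3 SD sustained for 0.05 s; `cumulative_fit()` fits
independent OLS lines to the cumulative rectified signal before and after
the onset (breakpoint fixed at the onset), giving slopes k_baseline and
k_stimulus in rectified-units/s.

## Morphometrics

`branch_metrics()` restricts an SWC reconstruction to dendrites (types 3
and 4), counts primary dendrites, branch points and terminals, sums
segment lengths, and assigns centrifugal branch orders (primary = 1, +1 at
each branch point). The dendritic complexity is

DC = (Σ terminal branch orders + #terminals) × (total dendritic length /
#primary dendrites),

and `normalize_to_reference()` expresses group metrics relative to a
reference-group mean.

# Numerical choices

* **Frame conventions.** All frame counts use the ceiling convention;
  stimulus windows are half-open; frames are 1-based with frame *i*
  covering time (i−1)/f.
* **Baseline estimation.** Iterative 3-SD clipping (to convergence) rather
  than a fixed quantile, so sparse transients do not inflate the SD.
* **Shuffle null in compiled code.** A partial Fisher–Yates permutation
  with an occupancy-reset trick makes 10,000 shuffles of a 30 × 1500
  matrix run in ~0.2 s; the R-level `shuffle_events()` implements the same
  operation and the two are cross-checked in tests.
* **Convergence rule for the NND statistic.** A running-mean stability
  window (100 consecutive sub-tolerance changes) rather than a fixed
  repetition count, so cheap configurations stop early and hard ones run
  to the cap.
* **Deterministic seeding.** Every pipeline stage consumes a sub-seed
  derived as (seed·1000 + stage) mod (2³¹ − 1), so stages can be re-run
  in isolation.

# Problem sizes

Defaults were chosen so the full pipeline runs in ~1 s and the entire test
suite in ~2 min on one CPU: 50-neuron populations, 10-trial protocols
(~225 s of recording, ~4,600 frames), 30-neuron synchrony subcircuits with
1,000-shuffle nulls in exploratory runs and 10,000 in calibration runs,
and 6 random morphologies. All sizes are arguments, not constants.

# The worked pipeline

```{r, eval = FALSE}
res <- run_pipeline(pipeline_config(seed = 1))
str(res$summary, max.level = 1)
```

The numbered scripts under `analysis/` run this pipeline for a baseline
and a hypersensitive condition (equalized weak/strong response
probabilities plus population events) and write tab-separated tables to
`results/`.
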