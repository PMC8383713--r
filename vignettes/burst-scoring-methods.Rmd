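---
title: "Probabilistic burst scoring for microneurography: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probabilistic burst scoring for microneurography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(msnascore)
```

## Overview

Muscle sympathetic nerve activity (MSNA) is recorded as an integrated
neurogram sampled at 1000 Hz alongside ECG and, when available, continuous
blood pressure. `msnascore` separates burst *detection* from burst
*validation*: a broad geometric detector proposes every remotely burst-like
local prominence, and each candidate is then scored with three independent
probability-like quantities — shape (neural networks), cardiac timing, and
spectral signal quality — combined into one composite validity score.
This document explains each model, its assumptions, the defaults and why
they were chosen, what the synthetic generator does and does not emulate,
and the numerical decisions taken where the design was genuinely open.

## Candidate detection

The detector keeps every interior local maximum of the MSNA channel that
passes, in order:

| filter | default | unit | meaning |
|---|---|---|---|
| amplitude | 0.05–0.8 | V | raw peak height bounds |
| distance | 250 | ms | of two closer peaks the higher survives |
| prominence | ≥ 0.05 | V | height above the higher separating saddle |
| width | ≥ 100 | ms | measured at half prominence |

Open choices resolved here: *width* is measured at half-prominence height
(the common convention; only "100 ms width" is standard phrasing);
*distance ties* keep the earlier of two equally tall peaks; the *amplitude*
filter applies to the raw signal, not a baseline-corrected one. Prominence
is offset-invariant by construction, so only the amplitude bounds react to
a DC shift. Plateaus (exact ties, essentially absent in continuous data)
count once, at their midpoint.

Analysis windows around a peak are zero-padded at the recording edges and
flagged, rather than dropped: discarding edge candidates silently biases
burst counts in short recordings. Even classifier input lengths (1000
samples) are served by the centered odd window with the final sample
trimmed, putting the apex at position 500 + 1.

## Cardiac timing model

The model assumes sinus rhythm (no arrhythmia handling) and a stable
conduction path. A burst triggered by the baroreflex at the diastolic
pressure nadir of one beat appears at the recording electrode after a
body-height-dependent latency; the default line

\[ L(h) = -118.75 + 8.25\,h \quad \text{ms (h in cm)} \]

spans exactly 1160 ms at 155 cm to 1490 ms at 195 cm — the classical
height-latency range. The slope/intercept pair is *not* uniquely
determined by that range; this particular line is declared, configurable,
and used by the simulator and scorer alike. Height defaults to 175 cm when
unrecorded.

The diastolic nadir itself sits a fixed signed offset after the R-wave
(default +180 ms), so timing can be evaluated from the ECG alone when the
pressure channel is damped or absent. The offset is estimated from data by
matching each detected nadir with its closest R-wave and taking the median
of the retained signed differences after two artifact filters:

1. **z-score filter**: offsets with |z| > 0.12 are excluded. The z-score is
   centered on the *median* of the raw offsets (scale: sample standard
   deviation). Mean-centering is unusable here: with a contaminated
   two-cluster distribution, the majority cluster's |z| equals
   √(p/(1−p)) ≈ 0.23 at 5 % contamination, so a mean-centered 0.12
   threshold would discard the good data together with the artifacts.
2. **clip**: surviving offsets below −250 ms are discarded (the long
   negative tail of pressure drop-outs).

The timing likelihood of a candidate at time *t* is the max-normalized
Gaussian `exp(−d²/2σ²)`, σ = 200 ms, where `d` is the distance between the
expected trigger point `t − L(h)` and the diastolic reference of the
*nearest* beat. Max-normalization (rather than per-recording min–max)
keeps scores comparable across recordings. Note a consequence of the
nearest-beat rule: at resting heart rates a candidate displaced by ~600 ms
re-locks onto the neighboring cycle and scores ≈ exp(−2), not ≈ 0; only
against an isolated beat does the likelihood fall monotonically without
bound.

## Spectral quality index

Signal quality of the minute surrounding a peak is summarized by the
median of |DFT| of the raw window (unnormalized forward transform, full
two-sided spectrum, DC included). The reference defaults — valid-signal
center 0.57, noise reference ≈ 1.5+, likelihood width 0.3 — are meaningful
only for one amplifier gain and DFT convention, so they are explicitly
recalibratable: `calibrate_quality_model()` sets the center to the median
of rated valid excerpts and the width to a quarter of the gap between the
valid and noise group medians, which reproduces the 0.3 width from the
0.57/1.82 reference pair. The likelihood is again a max-normalized
Gaussian, deterministic per value.

Two numerical points:

* **Truncated windows.** DFT magnitudes of stationary noise grow like
  √N, so the median of a boundary-truncated window is biased low relative
  to a center calibrated on full windows — a half-length electrode-noise
  window can land exactly on the valid center. Truncated medians are
  therefore rescaled by √(nominal/actual length) and flagged. (The
  alternative — dropping boundary candidates — silently censors short
  recordings.)
* **Windowed quality is epoch-level evidence.** A spurious peaklet inside
  an otherwise clean minute receives quality ≈ 1; discrimination of such
  candidates falls entirely to the shape and timing components. This is by
  design: quality answers "is this minute interpretable?", not "is this
  deflection a burst?".

## Shape classifiers

Three dense feed-forward presets score the raw (unstandardized) voltage
window around the peak:

| preset | input | batch | epochs | positives triplicated |
|---|---|---|---|---|
| `dtct1` | 4001 | 32 | 6 | no |
| `dtct2` | 1000 | 32 | 20 | yes |
| `dtct3` | 1000 | 16 | 35 | no |

All have five ReLU hidden layers (default widths 256-128-64-32-16 — the
exact widths are an open choice, declared and configurable), one dropout
layer (rate 0.5) before the 2-unit softmax, adamax (step 0.002, the
optimizer's original default) on sparse categorical cross-entropy. The
training protocol reshuffles the 80/20 split (training size rounded half
away from zero), optionally triplicates training positives, resets the
network, and retrains from scratch — repeated `n_repetitions` times with
per-repetition held-out accuracy and rank-based ROC AUC (ties averaged)
collected, and learning/loss curves averaged. The model of the final
repetition is retained for application.

No deep-learning framework is used: at these sizes (≤ ~1.3 M parameters,
minibatches of 16–32) plain BLAS-backed matrix algebra trains a preset in
seconds, and owning the implementation makes the seeded determinism exact:
one master seed derives independent sub-seeds for split, triplication
shuffle, initialization, and minibatch order, so identical seeds give
bit-identical models. Saved models store their weights as C99 hexadecimal
float literals inside JSON so persistence round-trips bit-stably.

## Composite score

Each candidate's evidence is laid out on a circle: quality occupies half
(weight 0.5), and the remaining half is split equally between timing and
the individual networks (0.125 each with three networks; the split adapts
when fewer are supplied). Every network block is subdivided into thirds —
positive probability, binary call, positive probability again — so the
continuous evidence flanks the categorical one. The composite is the area
under this profile normalized by the full circle, i.e. exactly the
weighted mean

\[ S = w_q q + w_t t + \sum_i w_i \frac{2 p_i + b_i}{3}, \]

treated as a step function per sector (linear interpolation between
sectors would make the score depend on sector ordering; the step form
keeps it an auditable weighted average). `S` is monotone in every
component and bounded in [0, 1]. Candidates with `S > 0.5` count as
bursts by default; note that when quality saturates at 1 the quality
sector alone contributes 0.5, so in pristine recordings the effective
discrimination at the default threshold is carried by timing and shape.

## The synthetic generator

`simulate_recording()` emulates the statistical structure the analysis
relies on — nothing more. Defaults (the stated world of all seeded tests):

* RR intervals 1000 ± 30 ms (Gaussian jitter); ECG as 10 ms unit
  triangular R spikes — sufficient for a local-maximum detector, no PQRST.
* BP as cosine segments between diastolic nadirs (R + 180 ms, 80 mmHg) and
  systolic peaks 120 ms later (120 mmHg); 120 ms respects the 150 ms
  nadir-artifact filter.
* Bursts on 40 % of beats (Bernoulli), apex at
  R + 180 ms + L(175 cm) + N(0, 50 ms), heights uniform 0.1–0.8 V, shape an
  asymmetric Gaussian (rise σ 100 ms, decay σ 180 ms) approximating
  integrated-burst morphology.
* Baseline noise: *white*, σ 0.02 V. Electrode-search epochs: *integrated*
  (100 ms moving average) broadband noise, σ 0.3 V, with bursts
  suppressed.

The noise split deserves its rationale: white baseline excursions are far
narrower than the 100 ms width filter, so clean epochs produce essentially
no false candidates, while integrated search noise produces bumps with
burst-like widths that *do* become candidates — exactly the two regimes
the scoring stage must separate. One master seed drives every stream
through a documented splitter (`derive_seed()`), so sub-streams are
independently reproducible and identical seeds give bit-identical
recordings.

What the generator does **not** emulate: real burst-shape variability and
baseline wander, arrhythmias and ectopy, respiratory and blood-pressure
modulation of burst probability, amplifier drift, or rater disagreement.
A green end-to-end test therefore establishes that the pipeline's
machinery is correct and self-consistent under its stated assumptions — it
does not certify performance on human recordings, whose published
reference values (classifier accuracies, quality medians, offset medians)
derive from data that is not publicly available.

## Known limitations

* Quality evidence is epoch-level (see above); bursts whose quality window
  overlaps a noise epoch are penalized even when the burst itself is
  clean. This costs a few percent of true bursts near epoch boundaries in
  the end-to-end test and is the price of windowed quality.
* The default composite weighting makes `S > 0.5` a weak criterion in
  recordings where quality saturates; users wanting shape-dominated
  selection should raise the threshold or re-weight the profile.
* The latency regression coefficients and the hidden-layer widths are
  declared defaults, not estimates; both are configuration, not science.
* Resampling uses linear interpolation — adequate for 500→1000 Hz
  upsampling of smooth integrated signals, not a general anti-aliased
  resampler.
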