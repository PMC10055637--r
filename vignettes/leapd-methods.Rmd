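---
title: "An LPC affine-subspace index for resting-state EEG: model, training protocol, and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An LPC affine-subspace index for resting-state EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leapd)
```

## The problem

Cognitive decline in Parkinson's disease and in aging shifts the spectral
content of resting-state EEG across several rhythms at once: the dominant
theta--alpha oscillation moves toward lower frequencies as cognition
deteriorates, and beta-band power falls with it. Traditional band-power
markers capture one slice of this change at a time and correlate only
moderately with screening scores such as the MoCA. The idea implemented
here is to encode the *whole* spectral profile of each band-limited
channel into a handful of linear-predictive-coding (LPC) coefficients and
to measure where that encoding falls between two empirically fitted
prototypes: the cognitively normal class and the cognitively impaired
class.

## The model

Each channel is conditioned (60 Hz notch, zero-phase Butterworth band-pass
to a per-electrode band, unit-power normalization) and fitted with an
order-$p$ autoregressive model by the autocorrelation method,

$$\hat{x}_n = \sum_{i=1}^{p} a_i x_{n-i},$$

solved with the Levinson--Durbin recursion. The coefficient vector
$(a_1,\dots,a_p)$ is a compact description of the channel's spectral
envelope; the residual variance $\sigma^2$ is deliberately excluded from
the feature vector because unit-power normalization makes overall gain
uninformative.

For each electrode, the training vectors of each cognitive class are
summarized by an affine subspace: the class centroid plus the top-$k$
principal directions of the centred scatter. A test vector $v$ with
distances $D_1$ (to the normal-class flat) and $D_2$ (to the
impaired-class flat) receives the bounded index

$$L = \frac{D_2}{D_1 + D_2} \in [0, 1],$$

so $L = 1$ means the vector lies on the normal-class subspace. The
orientation is chosen so that the index correlates *positively* with
cognitive scores. The degenerate case $D_1 = D_2 = 0$ maps to $0.5$ by
symmetry, and exact membership of one flat maps to the corresponding
pole. Per-electrode indices are fused across the selected montage by
geometric mean, with an explicit zero short-circuit rather than a
log-space epsilon, so exact poles are preserved.

## Training protocol

Subjects are split into classes either by a fixed cutoff (MoCA < 26 =
impaired, the clinical convention) or at the cohort median for continuous
scores. For every electrode, a grid over (band, LPC order, subspace
dimensions) is searched; each configuration is scored by the
age-controlled Spearman correlation between the training subjects'
single-electrode indices and their cognitive scores (training AUC is
available as an alternative criterion). Exact criterion ties break toward
the lower LPC order, then the lower band edge, so the search is fully
deterministic. The `n_electrodes` best electrodes (default 8) by training
criterion form the combined index; label ties break lexicographically.

Cross-validation re-runs this *entire* protocol -- class assignment,
configuration search, electrode selection -- inside every training fold;
held-out subjects are scored with the fold's model only. Because the LPC
feature vector of a (recording, channel, band, order) combination does not
depend on any label, features are computed once per dataset and shared
across folds; this caching changes no result, only the cost. A
fixed-montage mode is implicit: fitting once on all data with
`fit_leapd()` and scoring new recordings with `score_subject()` reproduces
the fixed-electrode workflow.

## Tunable parameters

| Parameter | Default | Meaning and rationale |
|---|---|---|
| LPC order $p$ | 10 (grid 6--20) | enough poles for a low-frequency peak, a beta peak, and the 1/f tilt; more risks fitting noise |
| band grid | $f_{lo} \in \{1,2,4,6,8\}$, $f_{hi} \in \{10,13,20,30,50\}$ Hz, $f_{hi} > f_{lo}+4$ | spans narrow low-frequency through broad central-parietal ranges |
| subspace dims $k$ | 3 (grid 1--5) | must stay below each class size in every training fold |
| electrodes fused | 8 | the montage size at which performance saturates |
| threshold | 0.5 | the symmetry point of the bounded index |
| notch | 60 Hz, Q = 35 | ~1.7 Hz wide at 60 Hz: removes the line, leaves neighbours |
| band-pass | Butterworth order 4, forward--backward | standard EEG practice; zero phase; monotone passband |

The `reduced_grid()` (4 bands $\times$ 2 orders, $k = 3$) is used by the
package's own end-to-end validation runs; on the synthetic cohorts the
full grid's extra resolution does not change any conclusion but multiplies
the cost roughly thirty-fold.

## Numerical choices

* **Biased autocorrelation** (divide by $N$, not $N-k$) keeps the
  autocorrelation sequence positive semi-definite, which guarantees the
  Levinson--Durbin recursion is stable; the recursion aborts with an
  explicit error if a reflection coefficient reaches magnitude 1.
* The whole recording is **one analysis frame**: no tapering or
  segmentation, since one index is produced per recording and minutes of
  data make taper bias negligible.
* **Zero-phase filtering** reflect-pads the signal (three
  impulse-response lengths: $3 f_s / f_{lo}$ samples for the band-pass,
  $3 Q f_s / f_{line}$ for the notch) before `signal::filtfilt`, which
  itself does no padding; without this, low-frequency startup transients
  leak into the autocorrelation.
* **Subspace distances** are computed from the explicit residual vector
  $d - BB^{\top} d$ rather than the cancellation-prone
  $\sqrt{\lVert d\rVert^2 - \lVert B^{\top} d\rVert^2}$, so points lying
  on a flat get distance 0 to machine precision -- which matters because
  the index has exact poles there.
* Welch PSD (2 s Hann segments, 50% overlap; 0.5 Hz resolution) is used
  for the spectral baselines and generator checks; it is never part of
  the index pipeline itself.

## The synthetic cohort generator

No recordings ship with the package, so validation runs on a seeded
generator whose informative channels encode exactly the structure the
index is meant to detect: an AR(2) resonator (pole radius 0.97) whose
frequency moves linearly from 6.5 Hz to 10.5 Hz with the latent cognition
level $c \in [0,1]$, a 20 Hz beta resonator whose amplitude grows from
0.5 to 1.5 with $c$, a $1/f$ background, and white noise
(`noise_sd = 0.5`). Non-informative channels carry background and noise
only. The $1/f$ background is realized by frequency-domain shaping of
white noise (FFT amplitudes scaled by $f^{-\alpha/2}$, flat below 1 Hz);
the measured 2--40 Hz log--log slope is $-0.93$ for $\alpha = 1$, within
the intended tolerance, and the method is exactly seed-reproducible.
Latent levels are uniform on $[0,1]$; the MoCA-like score is
`round(10 + 20c)`; ages are uniform on 55--80 and independent of $c$ by
default, so the age-controlled statistics are exercised without being
confounded (an `age_latent_correlation` knob exists for confounding
studies); PD/control labels are assigned 2:1 independently of cognition.
Component amplitudes were fixed once so that the full pipeline operates
in the high-detectability regime (cross-validated AUC above 0.9 on the
120-subject cohort) that the method targets.

What the generator does **not** emulate: volume conduction and
inter-channel correlation, eye-blink and muscle artifacts, non-stationary
arousal drift, and individual alpha-peak variability unrelated to
cognition. Passing the end-to-end checks therefore demonstrates that the
pipeline recovers a spectral-shift signal of plausible size from realistic
noise -- not that it reaches any particular performance on clinical data.

## Validation design and problem sizes

The package's own end-to-end runs use: a 120-subject strong-effect cohort
(60 s recordings, 8 informative channels of 16, seed 7) evaluated by
LOOCV with the reduced grid; a single label-shuffle randomization pass on
the same cohort; ten 40-subject effect-free cohorts (20 s recordings,
`peak_lo = peak_hi`, flat beta gain) whose mean cross-validated AUC must
sit near 0.5; and a truncation sweep over the leading 10%, 40%, and 100%
of each recording. The 40-subject size for the null cohorts is the
smallest at which the default subspace dimension ($k = 3$) stays below
the normal-class size in every leave-one-out fold. The effect-free and
shuffle nulls close the overfitting loop: the per-fold hyperparameter
search is aggressive enough to fit noise, and these controls verify that
it does not manufacture signal.

## Known limitations

* The per-electrode search criterion is a single scalar; electrodes are
  ranked independently, so redundant neighbours can be selected together.
* `median_cut` grouping recomputes the median within each training fold;
  with heavily tied scores the class ratio can shift between folds.
* The EDF and BrainVision readers cover the common continuous layouts
  (16-bit EDF, float32/int16 BrainVision) but not EDF+ annotations or
  variable per-signal rates.
* p-values are reported raw; no multiple-testing correction is applied to
  per-channel baseline tables.
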