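---
title: "Tracking interventional devices from proximal acoustic emission: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking interventional devices from proximal acoustic emission: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aemid)
```

## The problem

When a biopsy needle or a vascular guide wire interacts with tissue, the
friction and puncture dynamics at the distal tip excite elastic waves that
propagate along the device shaft and can be picked up by a microphone
coupled to the proximal end — outside the patient, with an unmodified
clinical device. `aemid` implements the signal-processing chain that turns
such a recording into clinically interpretable events: the instants a
needle enters and leaves a tissue layer, and the decision whether a
guide-wire event is a vessel-wall perforation or a harmless artefact
(wall friction, a small bump of the wire).

The recordings are hard to read directly: the signal-to-noise ratio is
poor, and the interesting dynamics are transient and nonstationary, so
stationary spectral estimates smear exactly the structure that matters.
The package therefore models the audio with a *time-varying autoregressive
(TV-AR)* process and tracks a single scalar summary through time: the
frequency of the *maximal-energy pole* (TV-MEP).

## The TV-AR model and the maximal-energy pole

Within a sliding window centered at time $n$, the signal is modelled as an
all-pole process

$$H(z, n) = \frac{1}{1 + \sum_{k=1}^{p} a_k(n)\, z^{-k}},$$

with window-local coefficients $a_k(n)$ and innovation variance
$\sigma^2(n)$ estimated by the Yule–Walker method (biased autocovariance
estimator, window mean removed). The biased estimator is chosen
deliberately: it guarantees a positive-definite autocovariance sequence and
hence poles strictly inside the unit circle for every window, an invariant
the test suite asserts. The associated parametric spectrum is

$$S_{AR}(f, n) = \frac{\sigma^2(n)}
 {\left|1 + \sum_{k=1}^{p} a_k(n) e^{-i 2\pi f k / f_s}\right|^2}.$$

Factoring the AR polynomial gives $p$ poles $z_k(n)$. Each pole with
strictly positive imaginary part encodes a resonance at
$f_k(n) = \theta_k(n) f_s / 2\pi$, where $\theta_k$ is the pole's phase
angle; real-axis poles model trends rather than resonances and are
excluded. The spectral weight of each resonance comes from the residue of
the factored transfer function,

$$r_k = \prod_{j \ne k} \left(1 - z_j / z_k\right)^{-1}, \qquad
  P_k(n) = 2\sigma^2(n)\,\mathrm{Re}\,r_k(n),$$

and the TV-MEP is the resonant frequency of the pole with maximal $P_k(n)$
per window (ties break toward the lower frequency, for determinism).
Windows with no upper-half-plane pole carry the previous value forward and
are flagged. The residue powers are used *only to rank* poles; their
absolute scale never enters any downstream statistic.

Two presets freeze the published analysis settings:

| preset | window | overlap | order $p$ | band limiting | working rate |
|---|---|---|---|---|---|
| needle | 110 ms | 50% | 30 | Butterworth 3–6 kHz, order 7, zero-phase | 14700 Hz |
| guidewire | 50 ms | 95% | 20 | 10-scale Daubechies (db4) DWT, mid scales kept | 11025 Hz |

Window timestamps sit at window centers and the hop is
`window * (1 - overlap)` rounded to integer samples, so detected event
times are unbiased with respect to the analysis grid.

## Numerical choices

* **Decimation.** The acquisition rate is 44.1 kHz; the decimation factor
  is not dictated by the method, so the package uses the smallest factors
  consistent with each pipeline's analysis band: 3 for the needle chain
  (new Nyquist 7350 Hz, above the 6 kHz band edge) and 4 for the
  guide-wire chain. Anti-aliasing is an order-8 Chebyshev-I low-pass at
  80% of the new Nyquist, applied forward–backward. All filtering in the
  package is zero-phase, because the quantitative claims are *timing*
  claims and group delay would bias them.
* **Wavelet band.** The guide-wire chain band-limits by zeroing DWT
  coefficient sets and reconstructing. The Daubechies order (db4) and the
  retained scales are package choices: detail levels 2–6 of 10 at the
  11025 Hz working rate span roughly 86–2760 Hz, which covers the
  plateau resonances and overshoot excursions of guide-wire events while
  removing high-frequency noise (level 1) and baseline drift (deep levels
  and the approximation). Both are configurable in `filter_spec()`.
* **Root finding.** Per-window AR polynomial roots are eigenvalues of the
  real companion matrix; since the companion is already upper Hessenberg
  the QR iteration is entered directly. Residues use the factored form;
  near-coincident poles (closer than $10^{-8}$) are separated by a
  $10^{-8}$ perturbation before the residue product.
* **Spectrum evaluation.** `n_freq = 128` bins over $[0, f_s/2]$ by
  default; the spectral features are correlations and normalized maxima,
  which stabilize well below that resolution.
* **Degenerate windows.** Constant (zero-variance) windows cannot be fit;
  they are flagged and yield zero coefficients, and the MEP carries the
  last valid value.

## Needle entry/exit: CUSUM on the TV-MEP

A tissue transition moves the dominant resonance abruptly; the detector is
a two-sided tabular CUSUM on the standardized MEP. The baseline mean and
standard deviation come from the initial `baseline_s` seconds (default 2 s,
assumed to precede the insertion). The first alarm is the entry time
$t_{in}$; the statistic is then re-baselined on the post-transition level
(after a short settling interval) and reset, and the next alarm sustained
for at least two consecutive windows is the exit time $t_{out}$.

Two robustness choices matter and were made after observing the detector's
failure modes on stationary synthetic audio:

* the standardized score is winsorized at $\pm 4$ (`clip_z`), so a
  single-window MEP outlier — which the argmax-over-poles rule produces
  occasionally when a noise pole briefly dominates — cannot cross the
  threshold on its own, while a genuine level shift (tens of baseline
  standard deviations) still alarms within about two windows;
* the reference value is `drift_k = 1` baseline standard deviation per
  window rather than the textbook 0.5, because the MEP of stationary
  audio wanders slowly at about the 0.5σ scale and a 0.5σ CUSUM
  eventually converts that wander into false alarms. With the needle
  presets this tuning detects synthetic entries and exits with mean
  absolute errors of roughly 0.1–0.2 s, comfortably inside the
  half-second scale of interest.

Error statistics are reported signed and absolute, in seconds and — after
multiplication by the insertion velocity (3, 5 or 8 mm/s in the study
protocol) — in millimetres.

## Guide-wire events: segmentation, 16 features, SVM

Event bounds $t_{on}/t_{off}$ come from a short-time-energy envelope on
the analysis-window grid, thresholded at the envelope median plus three
MADs, with runs separated by less than 100 ms merged and the
highest-energy run kept. The maximal-energy sub-interval is
$\Delta = 0.2\,(t_{off} - t_{on})$ from onset (the fraction is
configurable; the interval hosts the perforation's energy release).

A perforation's signature in the MEP is (1) a fast, short *overshoot* of
the pole frequency at onset, then (2) a stable *plateau*. The overshoot is
the highest-prominence local maximum of the (5-window median-smoothed) MEP
inside $[t_{on}, t_{on}+\Delta]$, with start/end at half-prominence
crossings; it counts as present only when its prominence exceeds twice the
pre-event MAD of the MEP, so artefacts with wandering frequency rarely
qualify. Plateaus are maximal runs where the per-hop MEP derivative stays
below a threshold (minimum three windows), evaluated at three increasing
thresholds — by default 2%, 5% and 10% of the event's MEP range per hop.
The interval at a larger threshold is chosen as the run *containing* the
smaller-threshold interval, which makes the nesting
$PL_1 \subseteq PL_2 \subseteq PL_3$ structural rather than accidental.

Sixteen features summarize each event: six overshoot features (e.g.
$F_1 = (OS_H/OS_W) \cdot \sum_{OS} P_m / \sum_{event} P_m$, the maxima of
$P_m$ and $P_m \bar S_f$ and their normalizations, where $\bar S_f$ is the
frequency-averaged spectrum), eight plateau features (variance-to-length
ratio, derivative peak counts, plateau lengths and their normalizations)
and two spectral-stability features ($F_{15}, F_{16}$: mean off-diagonal
Pearson correlation between per-window spectra over the event and over
$\Delta$). Absent overshoot yields $F_1 = 0$; a perfectly flat plateau
would zero the denominator of $F_{11}$, which is guarded with
$\varepsilon = 10^{-9}$. $F_6$ equals $F_5 (t_{off}-t_{on})$ by
construction; both are kept as defined.

Classification is a radial-basis SVM in the 16-dimensional feature space.
Standardization (per-feature mean/sd) is estimated on the training set
only; `cost` and `gamma` are selected by deterministic stratified 5-fold
cross-validation on the training set. Balanced training composition
(perforations : artefacts = 1 : 1) follows the study protocol. Reported
metrics are sensitivity $TP/(TP+FN)$ over perforations and specificity
$TN/(TN+FP)$ over artefacts.

## What the synthetic generator emulates — and what it does not

Real recordings from the study are not bundled; the package generates
labelled surrogates so every stage is testable end to end. Events are
modelled as white noise driven through a *time-varying two-pole
resonator*, which makes the dominant pole analytically known — TV-AR
recovery then has an exact oracle:

* **needle**: a resonance that switches 3500 Hz → 5000 Hz → 3500 Hz at the
  annotated entry/exit instants, inside broadband background noise at
  10 dB event-to-background SNR;
* **perforation**: the resonance rises by 1500 Hz over a 0.3 s
  trapezoidal pulse, then settles on a plateau (800 Hz ± 20 Hz slow
  jitter) with a relatively pure resonance;
* **friction**: the resonance is time-dispersed — a slow ±350 Hz sweep
  plus a bounded random walk over 400–2200 Hz, with a broader resonance;
* **bump**: a 50–200 ms broadband burst.

Recordings default to 15 s (event around 7–10.5 s) for the guide-wire
setup and 10 s (entry/exit near 3 and 8 s) for the needle setup; corpus
generation jitters event times and parameters per recording, with
per-recording seeds derived from a master seed so corpora of any size are
reproducible. These lengths and the benchmark composition — the study's
560 : 165 : 150 class ratio and its balanced 100 : 50 : 50 training split,
scaled by 1/5 to 112/33/30 recordings with 20/10/10 training — are the
package's own problem-size choices for routine verification; the
generator accepts any duration and composition.

The generator reproduces the *phenomenology* the method exploits
(dominant-resonance shifts, overshoot-plateau signatures, spectral
dispersion of artefacts), not tissue acoustics: there is no stethoscope
transfer function, no amplitude dependence on insertion depth, no
multi-layer transitions, and artefact variability is far tamer than in
an interventional suite. Passing the synthetic benchmarks therefore
demonstrates that the pipeline recovers what it is designed to recover at
realistic SNR — it does not certify clinical performance on real
recordings.

## Known limitations

* The needle detector assumes one entry and one exit per recording and a
  clean pre-insertion baseline; multi-layer passages need repeated
  application.
* The MEP is an argmax statistic and inherits its brittleness: when two
  poles carry near-equal power the track can switch between them. The
  detectors are built to tolerate isolated switches (winsorized CUSUM,
  median smoothing before overshoot analysis), not sustained ambiguity.
* The event segmenter keeps only the highest-energy event per recording.
* The SVM's operating point is the e1071 default (no probability
  calibration); with strongly imbalanced real-world priors the decision
  threshold would need recalibration.
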