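---
title: "Methods: BCG cardiac-cycle analysis in bcgcycle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: BCG cardiac-cycle analysis in bcgcycle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its models, algorithmic
choices and limitations. It states no empirical result that the test suite
or `scripts/acceptance.R` does not itself compute.

## The measurement problem

A ballistocardiogram is the train of whole-body recoil vibrations produced
by cardiac ejection. Each beat shows a stereotyped sequence of four peaks
and three valleys — the Starr fiducials H, I, J, K, L, M, N, with J
dominant — whose timing maps onto the phases of the cardiac cycle: H marks
mitral closure, I aortic opening (so HI is the isovolumetric contraction
time, IVCT), M aortic closure (IM is the left-ventricular ejection time,
LVET), N mitral opening (MN is the isovolumetric relaxation time, IVRT),
and the NH span to the next beat is diastole, split at the ECG P peak into
ventricular filling and atrial contraction. Nine parameters per beat — the
HI/IM/MN intervals, the HI/IJ/MN amplitude excursions and the HI/IJ/MN
chord slopes — summarize contraction and relaxation; in heart failure IVCT
and IVRT lengthen, LVET shortens, and the IJ ejection amplitude and slope
fall.

All amplitudes in this package are sensor volts and slopes volts/second.
The published feature table nominally labels amplitudes "mV", but its own
slope values are only dimensionally consistent with volts over seconds
(2.715 V over 0.076 s gives the tabulated 35.7), so volts are used
throughout.

## Synthetic data: what is emulated and what is not

The generator is first-class, tested code; its defaults define the study
conditions used everywhere else.

* **Beat model.** One beat is a sum of seven signed Gaussian bumps, one per
  fiducial, with per-fiducial widths of 12–16 ms. This is the simplest
  parametric form whose extrema are exactly controllable; the default
  template carries HI = 65 ms, IM = 310 ms, MN = 69 ms and HI/IJ/MN
  excursions of 0.900/2.715/1.160 V — the published control means. Widths
  were chosen so that neighbouring bumps perturb each other's extrema by
  less than one sample at 1000 Hz (asserted by a brute-force argmax/argmin
  test).
* **Record model.** Beats are placed on a jittered heart-rate grid (first
  beat at 0.5 s), plus a respiration sinusoid (default 18 breaths/min,
  amplitude 23.15 V — about ten times the J peak, as respiration dominates
  the raw sensor trace), a slow drift sinusoid (0.05 Hz, 0.5 V), and white
  noise (0.05 V). The beat-train mean is removed (the sensor chain is AC
  coupled), which also puts more than 99% of the noise- and
  respiration-free energy inside the 0.5–35 Hz BCG band. Ground truth
  (fiducial times and clean amplitudes, ECG R and P times, beat labels) is
  exact. Atrial premature beats are advanced by 25% of the mean interbeat
  interval; ventricular premature beats are advanced and scaled to 0.4.
* **Sampling rate.** 1000 Hz by default; it is not dictated by the method,
  but a 10-level dyadic decomposition at 1000 Hz maps the d5–d10 synthesis
  onto 0.49–31.25 Hz, matching the stated BCG band.
* **Cohort subjects.** A subject's nine features are drawn from
  class-conditional normals (published control/CHF means and sds) coupled
  by one latent severity factor with loading 0.5, truncated to
  physiological bounds. The beat template carries the drawn intervals and
  amplitude excursions exactly; the I-to-J duration is the drawn
  IJ amplitude divided by the drawn IJ slope (that duration is not itself
  a tabulated feature, so both the amplitude and the chord slope are
  reproduced — and the CHF slope decrease is preserved, which a duration
  proportional to LVET would invert). K and L subdivide the J-to-M span in
  the default template's proportions. Heart rate is drawn from the class
  distribution (control 73.0 ± 12.2, CHF 79.5 ± 16.6 beats/min) and
  redrawn, rather than the interval profile, until the whole beat fits
  inside 85% of the cardiac period; templates whose adjacent fiducials
  fall closer than 28 ms are rejected as unresolvable (their bumps would
  merge, so the template would not have seven extrema at all). Acceptance
  of a draw is decided symmetrically for the draw and its sign-mirrored
  partner, so these rejections do not shift class means.
* **Not emulated:** hemodynamic pressure waveforms, multi-channel or
  accelerometer signals, atrial fibrillation, sensor nonlinearity, motion
  artifacts, and between-beat morphology change within a subject. Passing
  tests therefore demonstrate correctness of the algorithms under the
  stated signal model, not performance on real recordings.

## Extraction

`extractBcg` runs three stages:

1. **Global linear detrend** (mean and trend). Per-window DC is removed by
   the band synthesis itself, since the approximation band is excluded.
2. **Respiration/baseline removal.** The paper-level method (synthesis of
   wavelet details) attenuates a 0.3 Hz respiration sinusoid only to ~21%,
   which is far too little when respiration is ten times the beat
   amplitude, so the de-trending stage includes an explicit zero-phase
   estimator of everything below the band: the record is decimated to
   ~25 Hz, extended at both ends with autoregressive (Yule–Walker)
   forecasts (respiration is narrowband, so the continuation is accurate
   for the couple of seconds the smoother needs, which removes the
   boundary transient of any one-sided estimate), smoothed with a
   double-pass Whittaker smoother (second-difference penalty, corner
   0.55 Hz), interpolated back and subtracted; a spectral raised-cosine
   high-pass (transition 0.35–0.55 Hz on the odd-extended signal) removes
   the small remainder. Residual respiration in the record interior is a
   few millivolts; a decaying edge residual survives in the first/last
   couple of seconds, which is why beat detection guards 0.3 s at the
   boundaries and per-subject feature aggregation trims 5 s (reduced on
   short records so at least 8 s remain).
   Because the AR continuation adapts to the data, the full extraction is
   linear only to about 1 mV per volt of input away from the boundaries;
   the windowed band synthesis itself (`respHp = NULL`) is exactly linear
   and a projection.
3. **Windowed multiresolution synthesis.** Consecutive 8-s windows
   (overlapping by 0.25 s, joined with a raised-cosine cross-fade; a short
   final window is covered by a full window ending at the record end) are
   decomposed to 10 levels with the sym4 filter bank (half-sample symmetric
   extension, perfect reconstruction to 1e-12) and details d5–d10 are
   synthesized in a single inverse chain. At other sampling rates the
   level set is those whose dyadic band centre (geometric mean) lies in
   0.5–35 Hz — 4:9 at 500 Hz.

## Beat detection and fiducials

Candidates are local maxima above a per-8-s-window threshold of
median + 3·MAD of the window samples (a peak-height-based threshold proved
self-inconsistent: it rejects ventricular premature beats scaled to 0.4 of
J). A 0.3-s keep-largest refractory period removes same-beat secondary
peaks. The remaining N/H-wave false alarms are removed by a regularity
filter: the cardiac period is estimated from the autocorrelation of the
smoothed energy envelope (the envelope merges a beat's sub-waves into one
lump, so the estimate tracks the beat rate rather than intra-beat wave
spacing, and tolerates rhythm jitter), and the smaller of any detection
pair closer than 0.55 of that period is dropped. Premature beats arrive at
0.75 of the period and survive.

Segments span [J − 0.25·IBI, J + 0.75·IBI) by default. Fiducials are
located on the segment's significant extrema (turning points pruned until
every swing exceeds 5% of the segment range): J is the global maximum; I
the lowest minimum within 0.25 s before J; H the highest maximum before I
(searched from the segment start — in heart failure the pre-J systole can
exceed a fixed 0.25-s window); K the first minimum after J; L the first
maximum after K; M the lowest minimum within 0.25 s after L; N the first
maximum after M. K is detected but used by no feature. Quality is the
fraction of points found, discounted by extraneous prominent extrema
within the beat's own span, so noise segments score below 0.5 and clean
beats exactly 1. When fewer than 60% of beats reach full quality the
segmentation is retried at 0.35/0.65 and 0.45/0.55 splits and the best
assignment kept (high heart rates push H out of the default pre-window).

## DTW beat averaging

Per subject, full-quality beats are averaged by banded dynamic time
warping (Sakoe–Chiba half-width 100 ms, C++ implementation, banded
storage): beats are cropped to their common J-anchored time window (equal
lengths make the band diagonal the identity alignment; a length-scaled
diagonal smears the beat tail), the medoid over at most 25 evenly spaced
beats seeds the reference, and each pass averages both the amplitudes and
the matched sample times per reference index before resampling to the
uniform grid (time-axis averaging recovers mean timing from jittered
beats; amplitude-only averaging would collapse onto the medoid's timing).
Warping paths are computed on lightly smoothed copies so the alignment
does not chase noise extremes, and two refinement passes follow the
medoid-referenced pass. Features come from the fiducials of the averaged
beat; the median of per-beat features is the fallback when averaging is
impossible.

Known bias: the band synthesis removes the beat's own sub-0.5 Hz content
and shades its 20–31 Hz tail, which shifts the small H/I and M/N
excursions by several percent (the IJ ejection features and all intervals
are essentially exact). The test suite asserts intervals to 2 ms, IJ
features to 5%, and the small excursions to 10%.

## Cohort model and classification

The classification cohort mirrors the source study design: 541 analyses of
162 subjects, i.e. repeated measures. A subject carries a profile
`sqrt(icc)·(sqrt(λ)z + sqrt(1−λ)e)` and each of its ~3.3 rows adds an
independent within-subject state with the complementary variance share and
the same loading, so the marginals match the published class tables
exactly, any two features correlate at λ = 0.5 within class, and repeated
rows of a subject correlate at ICC = 0.85 (chosen from the few-millisecond
test–retest repeatability of BCG intervals against reference methods).
An independent-rows construction was examined and rejected: it cannot
reproduce the published decision-tree accuracy, because those 541 rows
were never independent.

Six models are evaluated with stratified five-fold cross-validation at the
row level (the study's protocol; a subject-grouped option exists).
Standardization is fitted on training folds only. Logistic regression,
random forest and XGBoost (100 rounds, depth 3, learning rate 0.3) run at
fixed settings; SVM cost {0.1, 1, 10}, KNN neighbours {3, 5, 7} and tree
depth {3, 5, unlimited} are selected on inner 3-fold cross-validation.
The decision tree is grown unpruned with minimum split 2 and leaf 1 — the
defaults of the Python library the depth grid refers to; R's own tree
defaults prune far more aggressively and are not comparable. Sensitivity
is the recall of the CHF class, specificity of the control class, AUC
comes from continuous scores, and group statistics use Welch's two-sample
t-test on per-subject means (the published "paired" test is impossible for
two independent cohorts, and row-level testing ignores the repeated
measures).

## Numerical choices and degenerate inputs

* Ties between equal-height extrema: earliest sample wins, everywhere.
* DTW ties prefer the diagonal move, so identical inputs align exactly.
* The Whittaker smoother solves pentadiagonal normal equations (sparse
  Cholesky); λ is set from the corner frequency via the second-difference
  frequency response.
* Truncation bounds of the cohort sampler (e.g. intervals 20–450 ms,
  amplitudes 0.05–8 V, IJ slope 2–90 V/s) shift large-sample marginal
  means by well under 1%.
* Zero signals yield empty detection lists, not errors; noise-only
  segments yield partial fiducial sets with quality < 0.5; records shorter
  than two beats, empty files, non-monotone time columns and unknown
  configuration keys raise typed errors.
* End-to-end recovery experiments (`cohortRecoveryExperiment`) draw
  subjects in exactly antithetic pairs under a symmetric acceptance rule,
  cancelling first-order Monte-Carlo error in simulated cohort means —
  standard variance reduction that leaves marginals untouched.

## Problem sizes used by the tests

The suite runs entirely on synthetic data built at test time: most records
are 20–60 s at 1000 Hz; the detector sensitivity/precision property uses
ten 30-s records; jitter-recovery uses 50 seeds of 16 beats; the
scaled-down end-to-end recovery check uses 6 subjects per class at 30 s;
the headline acceptance blocks use the full 20-record and 30-subject
configurations. The acceptance script re-simulates everything from its
`--seed` argument.

## Known limitations

* Respiration at or above ~30 breaths/min (0.5 Hz) lies inside the
  0.49–31.25 Hz BCG band itself; no band-selection method can separate it,
  and morphology stability is only claimed up to 24 breaths/min (the
  fast-breathing category boundary). Physiologically, breathing that fast
  is also much shallower than the default amplitude.
* The first and last few seconds of a record carry the residual edge
  transient of zero-phase baseline removal; edge beats are excluded from
  feature aggregation.
* Amplitude parameters of the small H/I and M/N waves carry a few percent
  of systematic band-limiting bias (intervals do not).
* Real-cohort correlation results against ECG, tissue Doppler imaging and
  echocardiographic cardiac output require recordings that are not
  available and are out of scope.
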