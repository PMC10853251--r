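# bcgcycle

Ballistocardiography (BCG) records the micro-vibrations that every heartbeat
imparts to the body. A high-sensitivity bed sensor picks them up without any
skin contact, but the raw trace is dominated by respiration, baseline drift
and broadband noise, and the cardiac waveform itself is a train of seven
sub-waves per beat. `bcgcycle` implements the full analysis chain that turns
such a single-channel vibration recording into clinically interpretable
cardiac-cycle measurements and a heart-failure classification, together with
a synthetic signal generator that makes every stage verifiable against exact
ground truth — no patient recordings are required or included.

The chain, for scientists working on unobtrusive cardiac monitoring:

1. **Extraction** — per-window linear de-trending, adaptive
   respiration/baseline removal below the BCG band, and multiresolution
   reconstruction with the Symlet-4 discrete wavelet transform: each 8-s
   window is decomposed into 11 subcomponents (details d1–d10 plus the
   approximation) and the BCG waveform is the synthesis of d5–d10, about
   0.49–31.25 Hz at a 1000 Hz sampling rate.
2. **Beats and fiducials** — each beat carries 4 peaks and 3 valleys, the
   Starr points H, I, J, K, L, M, N (J is the dominant peak). Beats are
   detected with an adaptive threshold, a refractory period and an
   interbeat-regularity filter; windowed-extremum rules then locate all
   seven fiducials per beat with a quality score.
3. **Cardiac-cycle phases** — the categorization maps HI to the
   isovolumetric contraction time (IVCT), IM to the left-ventricular
   ejection time (LVET), MN to the isovolumetric relaxation time (IVRT),
   and NH (to the next beat) to diastole, which the synchronized ECG P peak
   splits into ventricular filling and atrial contraction.
4. **Nine features** — HI/IM/MN intervals (ms), HI/IJ/MN amplitude
   excursions (V), and HI/IJ/MN chord slopes (V/s), computed on a
   DTW-averaged beat per subject (banded dynamic time warping,
   medoid-referenced barycenter with time-axis averaging).
5. **Cohorts and classification** — a latent-severity repeated-measures
   simulator reproduces published control/CHF feature distributions, and
   six classifiers (LR, SVM, KNN, decision tree, random forest, XGBoost)
   are evaluated with stratified five-fold cross-validation,
   standardization fitted on training folds only.

## Worked example

```r
library(bcgcycle)

## a simulated 60-s control subject: sinus rhythm, heavy respiration,
## drift and noise, with exact per-beat ground truth attached
pars <- sampleCohortRecordParams("control", seed = 42)
rec  <- synthRecord(pars$rhythm, pars$template, duration = 60, seed = 42)
rec
#> VibrationRecord: 60000 samples @ 1000 Hz (60.0 s)
#>   ground truth: 88 beats (sinus=88)

bcg <- extractBcg(rec)          # de-trend, remove respiration, d5-d10
j   <- detectBeats(bcg)
cmp <- compareIntervals(j, groundTruth(rec)@rTimes)
round(100 * cmp$maxRelativeError, 2)   # vs ECG R-R intervals, percent
#> [1] 1.25

fv <- subjectFeatures(bcg)      # nine parameters from the DTW-averaged beat
round(fv[c("hi_interval_ms", "im_interval_ms", "mn_interval_ms")], 1)
#> hi_interval_ms im_interval_ms mn_interval_ms
#>             70            351             86
round(pars$features[c("hi_interval_ms", "im_interval_ms", "mn_interval_ms")], 1)
#> hi_interval_ms im_interval_ms mn_interval_ms
#>           71.8          350.5           86.0
```

The recovered intervals track this subject's drawn ground truth to within
about a millisecond (H detection is a little coarser for this slow-upstroke
draw): IVCT 70 ms, LVET 351 ms, IVRT 86 ms. A cohort run looks like:

```r
tab <- sampleFeatures(cohortParams(), nControl = 337, nChf = 204, seed = 7)
groupCompare(tab)[1:3, c("feature", "mean_control", "mean_chf", "p_value")]
#>          feature mean_control mean_chf   p_value
#> 1 hi_interval_ms        66.28   103.33 4.1e-15    # IVCT lengthens in CHF
#> 2 im_interval_ms       311.42   257.75 8.3e-16    # LVET shortens
#> 3 mn_interval_ms        68.20    91.75 8.4e-11    # IVRT lengthens
evaluateModels(tab, seed = 7)[, c("model", "accuracy_mean", "auc_mean")]
#>     model accuracy_mean auc_mean
#> 1      LR         0.982    0.998
#> 2     SVM         0.991    0.999
#> 3     KNN         0.980    0.995
#> 4     DTC         0.952    0.951
#> 5      RF         0.972    0.998
#> 6 XGBoost         0.974    0.997
```

A thin command-line front end is installed at
`system.file("cli", "bcg", package = "bcgcycle")` with subcommands
`synth`, `extract`, `annotate`, `features`, `cohort`, `classify` and `e2e`.

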