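#' @import methods
NULL

FIDUCIAL_NAMES <- c("H", "I", "J", "K", "L", "M", "N")
PEAK_FIDUCIALS <- c("H", "J", "L", "N")
VALLEY_FIDUCIALS <- c("I", "K", "M")

FEATURE_NAMES <- c("hi_interval_ms", "im_interval_ms", "mn_interval_ms",
                   "hi_amp_v", "ij_amp_v", "mn_amp_v",
                   "hi_slope_vps", "ij_slope_vps", "mn_slope_vps")

#' Sampling metadata for a uniformly sampled signal
#'
#' @slot fs sampling rate in Hz.
#' @slot nSamples number of samples.
#' @slot t0 time of the first sample in seconds.
#' @export
setClass("SamplingSpec",
         representation(fs = "numeric", nSamples = "integer", t0 = "numeric"),
         prototype(fs = 1000, nSamples = 0L, t0 = 0))

setValidity("SamplingSpec", function(object) {
  if (length(object@fs) != 1 || !is.finite(object@fs) || object@fs <= 0)
    return("fs must be a single positive number")
  if (length(object@nSamples) != 1 || object@nSamples < 0L)
    return("nSamples must be a single non-negative integer")
  if (length(object@t0) != 1 || !is.finite(object@t0))
    return("t0 must be a single finite number")
  TRUE
})

#' Parametric description of one BCG beat
#'
#' A beat is modelled as a sum of seven signed Gaussian bumps, one per Starr
#' fiducial point H, I, J, K, L, M, N (4 peaks H/J/L/N, 3 valleys I/K/M).
#' Times are offsets in seconds from the beat reference (H at 0 by
#' convention); amplitudes are sensor volts; widths are the per-bump Gaussian
#' standard deviations in seconds.
#'
#' @slot times named numeric(7), strictly increasing fiducial time offsets.
#' @slot amps named numeric(7), signed bump amplitudes in volts.
#' @slot widths named numeric(7), positive bump widths in seconds.
#' @export
setClass("BeatTemplate",
         representation(times = "numeric", amps = "numeric",
                        widths = "numeric"))

setValidity("BeatTemplate", function(object) {
  for (s in c("times", "amps", "widths")) {
    v <- slot(object, s)
    if (length(v) != 7 || !identical(names(v), FIDUCIAL_NAMES))
      return(sprintf("%s must be numeric(7) named %s", s,
                     paste(FIDUCIAL_NAMES, collapse = ",")))
    if (any(!is.finite(v))) return(sprintf("%s must be finite", s))
  }
  if (any(diff(object@times) <= 0))
    return("fiducial times must be strictly increasing (H < I < ... < N)")
  if (any(object@widths <= 0)) return("widths must be positive")
  a <- object@amps
  if (all(a == 0)) return(TRUE)  # degenerate all-zero template is allowed
  peak_ok <- a["H"] > a["I"] && a["J"] > a["I"] && a["J"] > a["K"] &&
    a["L"] > a["K"] && a["L"] > a["M"] && a["N"] > a["M"]
  if (!peak_ok)
    return("invalid template: H,J,L,N must be peaks and I,K,M valleys")
  if (a["J"] < max(a))
    return("invalid template: J must be the global maximum")
  if (!(a["I"] < a["H"] && a["I"] < a["J"]))
    return("invalid template: I must lie below both H and J")
  TRUE
})

#' Rhythm and noise specification for the synthetic generator
#'
#' @slot meanHr mean heart rate, beats/min (30-220).
#' @slot hrSd between-beat heart-rate standard deviation, beats/min.
#' @slot respRate respiration rate, breaths/min.
#' @slot respAmp respiration sinusoid amplitude, volts.
#' @slot driftAmp low-frequency baseline drift amplitude, volts.
#' @slot noiseSd additive white-noise standard deviation, volts.
#' @slot apbProb per-beat probability of an atrial premature beat.
#' @slot vpbProb per-beat probability of a ventricular premature beat.
#' @slot vpbAmpScale amplitude scale in (0, 1] applied to VPB beats.
#' @export
setClass("RhythmSpec",
         representation(meanHr = "numeric", hrSd = "numeric",
                        respRate = "numeric", respAmp = "numeric",
                        driftAmp = "numeric", noiseSd = "numeric",
                        apbProb = "numeric", vpbProb = "numeric",
                        vpbAmpScale = "numeric"))

setValidity("RhythmSpec", function(object) {
  one <- function(x) length(x) == 1 && is.finite(x)
  for (s in slotNames(object))
    if (!one(slot(object, s))) return(sprintf("%s must be a single number", s))
  if (object@meanHr < 30 || object@meanHr > 220)
    return("meanHr must be in [30, 220] beats/min")
  if (object@hrSd < 0) return("hrSd must be >= 0")
  for (s in c("respRate", "respAmp", "driftAmp", "noiseSd"))
    if (slot(object, s) < 0) return(sprintf("%s must be >= 0", s))
  for (s in c("apbProb", "vpbProb")) {
    p <- slot(object, s)
    if (p < 0 || p > 1) return(sprintf("%s must be in [0, 1]", s))
  }
  if (object@vpbAmpScale <= 0 || object@vpbAmpScale > 1)
    return("vpbAmpScale must be in (0, 1]")
  if (object@apbProb + object@vpbProb > 1)
    return("apbProb + vpbProb must not exceed 1")
  TRUE
})

#' Per-record ground truth written by the synthetic generator
#'
#' @slot beatTimes absolute J-peak times in seconds, one per beat.
#' @slot fiducials data.frame with one row per beat: columns \code{beat},
#'   \code{t_H..t_N} (absolute seconds) and \code{a_H..a_N} (volts, values of
#'   the clean beat train at the fiducial times).
#' @slot rTimes synchronized ECG R-peak times, seconds.
#' @slot pTimes synchronized ECG P-peak times, seconds.
#' @slot beatLabels one of "sinus", "APB", "VPB" per beat.
#' @export
setClass("GroundTruth",
         representation(beatTimes = "numeric", fiducials = "data.frame",
                        rTimes = "numeric", pTimes = "numeric",
                        beatLabels = "character"))

setValidity("GroundTruth", function(object) {
  n <- length(object@beatTimes)
  if (nrow(object@fiducials) != n || length(object@beatLabels) != n ||
      length(object@rTimes) != n || length(object@pTimes) != n)
    return("beatTimes, fiducials, rTimes, pTimes, beatLabels must agree in length")
  if (!all(object@beatLabels %in% c("sinus", "APB", "VPB")))
    return("beatLabels must be sinus/APB/VPB")
  if (any(object@pTimes >= object@rTimes))
    return("each P time must precede its R time")
  TRUE
})

#' Raw single-channel vibration recording
#'
#' @slot samples sensor voltage samples.
#' @slot sampling a \linkS4class{SamplingSpec}.
#' @slot groundTruth a \linkS4class{GroundTruth}, or NULL for real recordings.
#' @export
setClass("VibrationRecord",
         representation(samples = "numeric", sampling = "SamplingSpec",
                        groundTruth = "ANY"),
         prototype(groundTruth = NULL))

setValidity("VibrationRecord", function(object) {
  if (any(!is.finite(object@samples))) return("samples must be finite")
  if (length(object@samples) != object@sampling@nSamples)
    return("length(samples) must equal sampling@nSamples")
  if (!is.null(object@groundTruth) && !is(object@groundTruth, "GroundTruth"))
    return("groundTruth must be NULL or a GroundTruth")
  TRUE
})

#' Extracted BCG signal (0.5-35 Hz band)
#'
#' @slot samples extracted waveform, volts.
#' @slot sampling a \linkS4class{SamplingSpec}.
#' @slot levelsUsed wavelet detail levels synthesized (default 5:10).
#' @slot sourceWindowLength analysis window length in seconds (default 8).
#' @slot groundTruth ground truth carried over from the source record.
#' @export
setClass("BCGSignal",
         representation(samples = "numeric", sampling = "SamplingSpec",
                        levelsUsed = "integer", sourceWindowLength = "numeric",
                        groundTruth = "ANY"),
         prototype(groundTruth = NULL))

setValidity("BCGSignal", function(object) {
  if (length(object@samples) != object@sampling@nSamples)
    return("length(samples) must equal sampling@nSamples")
  if (!all(object@levelsUsed %in% 1:11))
    return("levelsUsed must be a subset of 1..11")
  TRUE
})

#' One segmented heartbeat
#'
#' Half-open span [start, end) around a detected J peak.
#'
#' @slot start,end segment bounds, absolute seconds.
#' @slot jTime detected J-peak time, seconds, start < jTime < end.
#' @slot samples segment waveform, volts.
#' @slot fs sampling rate, Hz.
#' @export
setClass("BeatSegment",
         representation(start = "numeric", end = "numeric", jTime = "numeric",
                        samples = "numeric", fs = "numeric"))

setValidity("BeatSegment", function(object) {
  if (!(object@start < object@jTime && object@jTime < object@end))
    return("must satisfy start < jTime < end")
  if (object@end - object@start > 1.5 + 1e-9)
    return("segment longer than 1.5 s")
  TRUE
})

#' Detected fiducial points of one beat
#'
#' @slot times named numeric(7) of absolute fiducial times (NA if not found).
#' @slot amps named numeric(7) of fiducial amplitudes in volts.
#' @slot quality detection quality score in [0, 1]; 1 means all seven points
#'   found and the segment contains no extraneous prominent extrema.
#' @export
setClass("FiducialSet",
         representation(times = "numeric", amps = "numeric",
                        quality = "numeric"))

setValidity("FiducialSet", function(object) {
  if (!identical(names(object@times), FIDUCIAL_NAMES) ||
      !identical(names(object@amps), FIDUCIAL_NAMES))
    return("times and amps must be named H..N")
  if (length(object@quality) != 1 || object@quality < 0 || object@quality > 1)
    return("quality must be a single value in [0, 1]")
  tt <- object@times[!is.na(object@times)]
  if (length(tt) > 1 && any(diff(tt) <= 0))
    return("non-missing fiducial times must be strictly increasing")
  if (object@quality == 1) {
    a <- object@amps
    if (any(is.na(object@times))) return("full-quality set cannot have NAs")
    if (a["J"] < max(a)) return("J must be the maximum amplitude")
    if (!(a["I"] < a["H"] && a["I"] < a["J"]))
      return("I must lie below H and J")
  }
  TRUE
})

#' Class-conditional cohort distribution parameters
#'
#' Defaults reproduce the published control/CHF marginals of the nine BCG
#' features plus the group heart rates; a single latent severity factor with
#' loading \code{latentLoading} induces equicorrelation between features.
#'
#' @slot means,sds 2 x 9 matrices (rows control/chf) of feature means and sds.
#' @slot bounds 2 x 9 matrix (rows lower/upper) of truncation bounds.
#' @slot latentLoading fraction of each feature's variance carried by the
#'   shared severity factor, in [0, 0.9].
#' @slot repeatIcc intraclass correlation of repeated samples from the same
#'   subject (fraction of marginal variance that is between-subject), in
#'   [0, 1]; cohorts are repeated-measures samples as in the source study
#'   (541 analyses of 162 subjects).
#' @slot rowsPerSubject average number of repeated samples per subject.
#' @slot hrMean,hrSd named numeric(2) (control, chf) heart-rate moments.
#' @slot hrBounds numeric(2) truncation bounds for heart rate, beats/min.
#' @export
setClass("CohortParams",
         representation(means = "matrix", sds = "matrix", bounds = "matrix",
                        latentLoading = "numeric", repeatIcc = "numeric",
                        rowsPerSubject = "numeric", hrMean = "numeric",
                        hrSd = "numeric", hrBounds = "numeric"))

setValidity("CohortParams", function(object) {
  cls <- c("control", "chf")
  if (!identical(rownames(object@means), cls) ||
      !identical(colnames(object@means), FEATURE_NAMES))
    return("means must be a 2x9 matrix with rows control/chf")
  if (!identical(dim(object@sds), dim(object@means)))
    return("sds must match means in shape")
  if (any(object@sds <= 0)) return("sds must be positive")
  if (!identical(rownames(object@bounds), c("lower", "upper")) ||
      ncol(object@bounds) != 9)
    return("bounds must be a 2x9 matrix with rows lower/upper")
  if (any(object@bounds["lower", ] >= object@bounds["upper", ]))
    return("lower bounds must be below upper bounds")
  l <- object@latentLoading
  if (length(l) != 1 || l < 0 || l > 0.9)
    return("latentLoading must be in [0, 0.9]")
  if (length(object@repeatIcc) != 1 || object@repeatIcc < 0 ||
      object@repeatIcc > 1)
    return("repeatIcc must be in [0, 1]")
  if (length(object@rowsPerSubject) != 1 || object@rowsPerSubject < 1)
    return("rowsPerSubject must be >= 1")
  if (!identical(names(object@hrMean), cls) ||
      !identical(names(object@hrSd), cls))
    return("hrMean and hrSd must be named control/chf")
  TRUE
})

#' Cross-validation metrics for one classification model
#'
#' @slot model model name.
#' @slot folds data.frame with one row per fold: accuracy, auc, sensitivity,
#'   specificity, f1 and the confusion counts tp/fp/tn/fn.
#' @slot summary data.frame with mean and sd per metric.
#' @slot nFolds number of folds.
#' @slot seed RNG seed used.
#' @export
setClass("CVMetrics",
         representation(model = "character", folds = "data.frame",
                        summary = "data.frame", nFolds = "integer",
                        seed = "integer"))

setValidity("CVMetrics", function(object) {
  m <- object@folds[, c("accuracy", "auc", "sensitivity", "specificity", "f1")]
  if (any(m < -1e-9 | m > 1 + 1e-9, na.rm = TRUE))
    return("metrics must lie in [0, 1]")
  if (nrow(object@folds) != object@nFolds)
    return("folds must have nFolds rows")
  TRUE
})
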