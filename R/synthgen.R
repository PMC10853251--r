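## Synthetic BCG/ECG generator: parametric beats, rhythm disturbances,
## respiration, drift and noise, with exact per-beat ground truth.

#' Construct a beat template
#'
#' The default parameters describe a normal-cardiac-function beat: the HI,
#' IM and MN intervals are 65, 310 and 69 ms and the HI/IJ/MN amplitude
#' excursions are 0.900, 2.715 and 1.160 V, matching the published control
#' means of those six parameters.
#'
#' @param times named numeric(7), fiducial time offsets in seconds from H.
#' @param amps named numeric(7), signed Gaussian bump amplitudes in volts.
#' @param widths per-fiducial Gaussian bump widths (s); recycled if scalar.
#' @return a \linkS4class{BeatTemplate}.
#' @export
#' @examples
#' tpl <- beatTemplate()
#' tpl@times[["I"]] - tpl@times[["H"]]  # 0.065 s, the IVCT surrogate
beatTemplate <- function(times = c(H = 0, I = 0.065, J = 0.135, K = 0.185,
                                   L = 0.245, M = 0.375, N = 0.444),
                         amps = c(H = 0.5, I = -0.4, J = 2.315, K = -0.3,
                                  L = 0.8, M = -0.66, N = 0.5),
                         widths = c(H = 0.016, I = 0.015, J = 0.013,
                                    K = 0.012, L = 0.014, M = 0.016,
                                    N = 0.016)) {
  if (length(widths) == 1) widths <- rep(widths, 7)
  names(times) <- names(amps) <- names(widths) <- FIDUCIAL_NAMES
  new("BeatTemplate", times = times, amps = amps, widths = widths)
}

#' Rhythm specification constructor
#'
#' Defaults describe quiet supine recording of a sinus-rhythm subject:
#' 60 beats/min with 3 beats/min variability, respiration at 18 breaths/min
#' (0.3 Hz) with amplitude about ten times the default J peak (respiration
#' dominates the raw sensor trace), slow baseline drift, 0.05 V broadband
#' noise, and no ectopic beats.
#'
#' @param meanHr,hrSd heart rate mean and sd, beats/min.
#' @param respRate respiration rate, breaths/min.
#' @param respAmp respiration amplitude, volts.
#' @param driftAmp baseline drift amplitude, volts.
#' @param noiseSd white-noise sd, volts.
#' @param apbProb,vpbProb per-beat probabilities of atrial/ventricular
#'   premature beats.
#' @param vpbAmpScale amplitude scale of VPB beats (incompletely filled
#'   ventricles produce weaker vibration).
#' @return a \linkS4class{RhythmSpec}.
#' @export
rhythmSpec <- function(meanHr = 60, hrSd = 3, respRate = 18,
                       respAmp = 23.15, driftAmp = 0.5, noiseSd = 0.05,
                       apbProb = 0, vpbProb = 0, vpbAmpScale = 0.4) {
  new("RhythmSpec", meanHr = meanHr, hrSd = hrSd, respRate = respRate,
      respAmp = respAmp, driftAmp = driftAmp, noiseSd = noiseSd,
      apbProb = apbProb, vpbProb = vpbProb, vpbAmpScale = vpbAmpScale)
}

## continuous beat waveform: sum of signed Gaussian bumps
.beat_wave <- function(t, template, scale = 1) {
  y <- numeric(length(t))
  for (i in seq_len(7)) {
    a <- template@amps[[i]] * scale
    if (a == 0) next
    y <- y + a * exp(-(t - template@times[[i]])^2 /
                       (2 * template@widths[[i]]^2))
  }
  y
}

#' Sample one beat template as a waveform
#'
#' Samples the parametric beat on a uniform grid covering
#' [t_H - 6 max(width), t_N + 6 max(width)], outside of which the waveform
#' has decayed to (numerically) zero. The returned record carries a
#' single-beat ground truth.
#'
#' @param template a \linkS4class{BeatTemplate}.
#' @param fs sampling rate in Hz (>= 200; must also resolve the narrowest
#'   bump with at least two samples per width).
#' @return a \linkS4class{VibrationRecord} holding the sampled beat.
#' @export
makeBeatTemplate <- function(template, fs = 1000) {
  stopifnot(is(template, "BeatTemplate"))
  validObject(template)
  if (fs < 200)
    stop("resolution error: fs must be at least 200 Hz")
  if (fs * min(template@widths) < 2)
    stop("resolution error: fs too low to resolve the narrowest bump")
  pad <- 6 * max(template@widths)
  t0 <- template@times[["H"]] - pad
  t1 <- template@times[["N"]] + pad
  n <- as.integer(floor((t1 - t0) * fs)) + 1L
  tt <- t0 + (seq_len(n) - 1) / fs
  y <- .beat_wave(tt, template)
  gt <- new("GroundTruth",
            beatTimes = template@times[["J"]],
            fiducials = .fiducial_row(1L, template@times,
                                      .beat_wave(template@times, template)),
            rTimes = template@times[["H"]] - 0.04,
            pTimes = template@times[["H"]] - 0.2,
            beatLabels = "sinus")
  new("VibrationRecord", samples = y,
      sampling = new("SamplingSpec", fs = fs, nSamples = n, t0 = t0),
      groundTruth = gt)
}

.fiducial_row <- function(beat, times, amps) {
  row <- as.data.frame(c(list(beat = beat),
                         as.list(stats::setNames(times, paste0("t_", FIDUCIAL_NAMES))),
                         as.list(stats::setNames(amps, paste0("a_", FIDUCIAL_NAMES)))))
  row
}

#' Synthesize a vibration recording with ground truth
#'
#' Places jittered copies of the beat template on a heart-rate grid, adds a
#' respiration sinusoid, low-frequency drift and white noise, and removes the
#' beat-train mean (the sensor chain is AC coupled). APB beats are advanced
#' by 25\% of the mean interbeat interval; VPB beats are advanced and
#' amplitude-scaled. ECG R times are placed 40 ms before each H point and P
#' times 160 ms before each R.
#'
#' @param rhythm a \linkS4class{RhythmSpec}.
#' @param template a \linkS4class{BeatTemplate}.
#' @param duration record length in seconds (>= 10).
#' @param fs sampling rate, Hz.
#' @param seed integer RNG seed; identical (seed, parameters) give
#'   bit-identical records.
#' @param rOffset ECG R time relative to H, seconds (R precedes H).
#' @return a \linkS4class{VibrationRecord} with filled ground truth.
#' @export
#' @examples
#' rec <- synthRecord(rhythmSpec(hrSd = 0, respAmp = 0, noiseSd = 0),
#'                    beatTemplate(), duration = 20, fs = 500, seed = 1)
#' length(groundTruth(rec)@beatTimes)  # 20 beats at 60 bpm
synthRecord <- function(rhythm, template, duration, fs = 1000, seed = 1,
                        rOffset = 0.04) {
  stopifnot(is(rhythm, "RhythmSpec"), is(template, "BeatTemplate"))
  validObject(rhythm); validObject(template)
  if (duration < 10)
    stop("too-short error: duration must be at least 10 s")
  mean_ibi <- 60 / rhythm@meanHr
  if (duration < 2 * mean_ibi)
    stop("too-short error: record must span at least two beats")
  set.seed(as.integer(seed))

  span_pre <- template@times[["J"]] - template@times[["H"]]
  span_post <- template@times[["N"]] - template@times[["J"]]
  wpad <- 6 * max(template@widths)

  ## nominal J-time grid from truncated-normal heart rates
  j_nom <- 0.5
  j_grid <- numeric(0)
  while (j_nom <= duration - span_post - wpad) {
    j_grid <- c(j_grid, j_nom)
    hr <- rhythm@meanHr + rhythm@hrSd * stats::rnorm(1)
    hr <- min(220, max(30, hr))
    j_nom <- j_nom + 60 / hr
  }
  nb <- length(j_grid)
  if (nb < 2) stop("too-short error: record must span at least two beats")

  u <- stats::runif(nb)
  labels <- ifelse(u < rhythm@apbProb, "APB",
                   ifelse(u < rhythm@apbProb + rhythm@vpbProb, "VPB", "sinus"))
  j_times <- j_grid - ifelse(labels == "sinus", 0, 0.25 * mean_ibi)
  j_times <- pmax(j_times, span_pre + wpad + 1 / fs)
  scales <- ifelse(labels == "VPB", rhythm@vpbAmpScale, 1)

  n <- as.integer(round(duration * fs))
  tt <- (seq_len(n) - 1) / fs
  train <- numeric(n)
  for (b in seq_len(nb)) {
    lo <- j_times[b] - span_pre - wpad
    hi <- j_times[b] + span_post + wpad
    idx <- max(1L, floor(lo * fs) + 1L):min(n, ceiling(hi * fs) + 1L)
    train[idx] <- train[idx] +
      .beat_wave(tt[idx] - j_times[b] + template@times[["J"]], template,
                 scale = scales[b])
  }
  ac_offset <- mean(train)
  train <- train - ac_offset

  x <- train
  if (rhythm@respAmp > 0)
    x <- x + rhythm@respAmp * sin(2 * pi * rhythm@respRate / 60 * tt +
                                    stats::runif(1, 0, 2 * pi))
  if (rhythm@driftAmp > 0)
    x <- x + rhythm@driftAmp * sin(2 * pi * 0.05 * tt +
                                     stats::runif(1, 0, 2 * pi))
  if (rhythm@noiseSd > 0)
    x <- x + stats::rnorm(n, 0, rhythm@noiseSd)

  ## exact ground truth: continuous-time clean values at the fiducial times
  fid <- do.call(rbind, lapply(seq_len(nb), function(b) {
    ft <- j_times[b] - template@times[["J"]] + template@times
    fa <- .beat_wave(ft - j_times[b] + template@times[["J"]], template,
                     scale = scales[b]) - ac_offset
    .fiducial_row(b, ft, fa)
  }))
  t_h <- fid$t_H
  gt <- new("GroundTruth", beatTimes = j_times, fiducials = fid,
            rTimes = t_h - rOffset, pTimes = t_h - rOffset - 0.16,
            beatLabels = labels)
  new("VibrationRecord", samples = x,
      sampling = new("SamplingSpec", fs = fs, nSamples = n, t0 = 0),
      groundTruth = gt)
}

#' Draw per-subject record parameters for a simulated cohort subject
#'
#' Draws the subject's nine features from the class-conditional
#' latent-factor model of \code{\link{sampleFeatures}} and a heart rate
#' from the class heart-rate distribution (control 73.02 +/- 12.19, CHF
#' 79.52 +/- 16.61 beats/min), then builds a beat template carrying exactly
#' the drawn HI/IM/MN intervals, the HI/IJ/MN amplitude excursions, and the
#' IJ chord slope (via the I-to-J duration, which is not itself a tabulated
#' feature). Draws whose geometry is physiologically impossible (beat span
#' exceeding 85\% of the cardiac period, or an IJ upstroke incompatible
#' with the ejection time) are rejected and redrawn.
#'
#' @param classLabel "control" or "chf".
#' @param cohort a \linkS4class{CohortParams}.
#' @param seed integer RNG seed.
#' @param maxTries rejection-sampling cap for template validity.
#' @param flip draw the antithetic partner (all underlying normal draws
#'   negated); pairing a subject with its partner cancels first-order
#'   sampling error in cohort means.
#' @return list with elements \code{template} (\linkS4class{BeatTemplate}),
#'   \code{rhythm} (\linkS4class{RhythmSpec}), \code{hr} and \code{features}
#'   (the six drawn construction parameters).
#' @export
sampleCohortRecordParams <- function(classLabel = c("control", "chf"),
                                     cohort = cohortParams(), seed = 1,
                                     maxTries = 200, flip = FALSE) {
  classLabel <- match.arg(classLabel)
  validObject(cohort)
  pair <- .sample_subject_pair(cohort, classLabel, seed = seed,
                               maxTries = maxTries)
  pair[[if (flip) 2L else 1L]]
}

## Draw an exactly antithetic subject pair: both members reuse the same
## underlying normal draws with opposite signs, and a candidate is accepted
## only when BOTH orientations yield valid physiology. The acceptance region
## is therefore symmetric, both members consume the same random numbers, and
## pair means cancel first-order Monte-Carlo error.
.sample_subject_pair <- function(cohort, classLabel, seed, maxTries = 200) {
  set.seed(as.integer(seed))
  mu <- cohort@means[classLabel, ]
  sd <- cohort@sds[classLabel, ]
  lam <- cohort@latentLoading
  lo <- cohort@bounds["lower", ]
  hi <- cohort@bounds["upper", ]
  for (try in seq_len(maxTries)) {
    z <- stats::rnorm(1)
    eps <- stats::rnorm(9)
    dev <- sd * (sqrt(lam) * z + sqrt(1 - lam) * eps)
    fA <- mu + dev
    fB <- mu - dev
    if (!all(fA >= lo & fA <= hi & fB >= lo & fB <= hi)) next
    tplA <- try(.template_from_features(fA), silent = TRUE)
    tplB <- try(.template_from_features(fB), silent = TRUE)
    if (inherits(tplA, "try-error") || inherits(tplB, "try-error")) next
    spanA <- tplA@times[["N"]] - tplA@times[["H"]]
    spanB <- tplB@times[["N"]] - tplB@times[["H"]]
    for (hr_try in seq_len(20)) {
      u <- stats::rnorm(1)
      hrA <- cohort@hrMean[[classLabel]] + cohort@hrSd[[classLabel]] * u
      hrB <- cohort@hrMean[[classLabel]] - cohort@hrSd[[classLabel]] * u
      ok <- hrA >= cohort@hrBounds[1] && hrA <= cohort@hrBounds[2] &&
        hrB >= cohort@hrBounds[1] && hrB <= cohort@hrBounds[2] &&
        spanA <= 0.85 * 60 / hrA && spanB <= 0.85 * 60 / hrB
      if (ok)
        return(list(
          list(template = tplA, rhythm = rhythmSpec(meanHr = hrA, hrSd = 2),
               hr = hrA, features = fA, class = classLabel),
          list(template = tplB, rhythm = rhythmSpec(meanHr = hrB, hrSd = 2),
               hr = hrB, features = fB, class = classLabel)))
    }
  }
  stop("degenerate-parameters error: no valid antithetic pair after ",
       maxTries, " rejections")
}

## geometry tying a feature draw to a full template; the I-to-J duration is
## the ratio of the drawn IJ amplitude to the drawn IJ chord slope (that
## duration is not itself a tabulated feature, so both can be carried
## exactly), and the within-systole K/L proportions mirror the default
## control template
.template_from_features <- function(f) {
  hi <- f[["hi_interval_ms"]] / 1000
  im <- f[["im_interval_ms"]] / 1000
  mn <- f[["mn_interval_ms"]] / 1000
  ## clamp instead of rejecting: rejection would select against low-slope
  ## subjects and, through the latent severity factor, bias every
  ## correlated feature of the class upward
  ij_dur <- min(max(f[["ij_amp_v"]] / f[["ij_slope_vps"]], 0.02), 0.5 * im)
  t_H <- 0; t_I <- hi; t_J <- t_I + ij_dur; t_M <- t_I + im; t_N <- t_M + mn
  t_K <- t_J + (0.185 - 0.135) / (0.375 - 0.135) * (t_M - t_J)
  t_L <- t_J + (0.245 - 0.135) / (0.375 - 0.135) * (t_M - t_J)
  a_H <- (0.5 / 0.9) * f[["hi_amp_v"]]
  a_I <- a_H - f[["hi_amp_v"]]
  a_J <- a_I + f[["ij_amp_v"]]
  a_K <- (-0.3 / 2.315) * a_J
  a_L <- (0.8 / 2.315) * a_J
  a_M <- (-0.66 / 1.16) * f[["mn_amp_v"]]
  a_N <- a_M + f[["mn_amp_v"]]
  times <- c(H = t_H, I = t_I, J = t_J, K = t_K, L = t_L, M = t_M, N = t_N)
  ## resolvability: adjacent fiducial bumps closer than ~2 bump widths merge
  ## into a single extremum, breaking the template's extrema contract
  if (any(diff(times) < 0.028))
    stop("degenerate-parameters error: fiducials too close to resolve")
  beatTemplate(times = times,
               amps = c(H = a_H, I = a_I, J = a_J, K = a_K, L = a_L,
                        M = a_M, N = a_N))
}
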