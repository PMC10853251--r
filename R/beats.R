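## Heartbeat detection, beat segmentation, fiducial-point location and
## BCG-vs-ECG interval comparison.

## cardiac period estimate: dominant autocorrelation lag of the smoothed
## energy envelope in the physiological interbeat range [0.3 s, 2 s]. The
## envelope merges the sub-waves of one beat into a single lump, so the
## estimate tracks the beat repetition rate rather than intra-beat wave
## spacings, and tolerates beat-to-beat timing jitter.
.acf_period <- function(x, fs, lo_s = 0.3, hi_s = 2, smooth_s = 0.3) {
  n <- length(x)
  w <- max(3L, as.integer(round(smooth_s * fs)))
  env <- stats::filter(x^2, rep(1 / w, w), method = "convolution", sides = 2)
  env[is.na(env)] <- 0
  env <- as.numeric(env) - mean(env, na.rm = TRUE)
  m <- stats::nextn(2L * n)
  X <- stats::fft(c(env, rep(0, m - n)))
  r <- Re(stats::fft(Mod(X)^2, inverse = TRUE))[seq_len(n)]
  lo <- as.integer(round(lo_s * fs)) + 1L
  hi <- min(n %/% 2L, as.integer(round(hi_s * fs))) + 1L
  if (hi <= lo || r[1] <= 0) return(NA_real_)
  win <- r[lo:hi]
  peak <- which.max(win)
  if (win[peak] <= 0) return(NA_real_)
  (lo + peak - 2L) / fs
}

## strict-left / non-strict-right local maxima (earliest sample wins ties)
.local_max_idx <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
}

#' Detect heartbeats in an extracted BCG signal
#'
#' Candidate beats are local maxima exceeding an adaptive per-window
#' threshold (median + k * MAD of the window samples, computed per 8-s
#' window); a keep-largest refractory period then suppresses secondary peaks
#' of the same beat, and an interbeat-regularity pass drops the
#' smaller-amplitude detection of any pair closer than
#' \code{minGapFrac} times the median interbeat interval (removing residual
#' N/H-wave false alarms). Premature beats are retained: they arrive early
#' but not closer than the regularity floor.
#'
#' @param bcg a \linkS4class{BCGSignal}.
#' @param refractoryS refractory period, seconds.
#' @param k MAD multiplier of the adaptive threshold.
#' @param windowS adaptation window, seconds.
#' @param minGapFrac regularity floor as a fraction of the median IBI.
#' @param edgeGuardS detections closer than this to the record boundaries
#'   are discarded: a beat there is missing part of its waveform, and the
#'   zero-phase extraction leaves its largest residuals at the boundaries.
#' @return numeric vector of J-peak times (seconds), possibly empty; peak
#'   amplitudes are attached as attribute "amplitude".
#' @export
detectBeats <- function(bcg, refractoryS = 0.3, k = 3, windowS = 8,
                        minGapFrac = 0.55, edgeGuardS = 0.3) {
  stopifnot(is(bcg, "BCGSignal"))
  fs <- bcg@sampling@fs
  if (fs < 100) stop("resolution error: fs must be at least 100 Hz")
  x <- bcg@samples
  n <- length(x)
  if (n < 2 * fs) stop("invalid-signal error: signal shorter than 2 s")
  tt <- sampleTimes(bcg)

  cand <- .local_max_idx(x)
  if (length(cand)) {
    w <- as.integer(round(windowS * fs))
    win_of <- (cand - 1L) %/% w
    keep <- logical(length(cand))
    for (wi in unique(win_of)) {
      idx <- (wi * w + 1L):min(n, (wi + 1L) * w)
      thr <- stats::median(x[idx]) + k * stats::mad(x[idx], constant = 1)
      sel <- win_of == wi
      keep[sel] <- x[cand[sel]] > thr
    }
    cand <- cand[keep]
  }
  if (!length(cand)) {
    out <- numeric(0)
    attr(out, "amplitude") <- numeric(0)
    return(out)
  }

  ## keep-largest refractory
  ord <- cand[order(-x[cand], cand)]
  kept <- integer(0)
  ref_n <- refractoryS * fs
  for (i in ord)
    if (!length(kept) || min(abs(kept - i)) > ref_n) kept <- c(kept, i)
  kept <- sort(kept)

  ## interbeat-regularity filter. The interbeat interval is estimated from
  ## the autocorrelation of the signal itself (the beat morphology repeats
  ## at the cardiac period, so secondary-wave false alarms cannot corrupt
  ## the estimate); detections closer than minGapFrac * IBI to a larger
  ## neighbour are then dropped.
  if (length(kept) >= 3) {
    ibi <- .acf_period(x, fs)
    if (!is.finite(ibi)) ibi <- stats::median(diff(kept)) / fs
    repeat {
      gaps <- diff(kept) / fs
      bad <- which(gaps < minGapFrac * ibi)
      if (!length(bad)) break
      b <- bad[1]
      drop <- if (x[kept[b]] < x[kept[b + 1]]) b else b + 1L
      kept <- kept[-drop]
      if (length(kept) < 2) break
    }
  }
  guard <- edgeGuardS * fs
  ok <- kept > guard & kept <= n - guard
  kept <- kept[ok]
  out <- tt[kept]
  attr(out, "amplitude") <- x[kept]
  out
}

#' Segment a BCG signal into per-beat windows
#'
#' Each beat spans [j - 0.25 IBI_prev, j + 0.75 IBI_next), clipped at the
#' record ends (edge beats reuse their single neighbouring interval) and
#' capped at 1.5 s total span; segments are ordered and disjoint.
#'
#' @param bcg a \linkS4class{BCGSignal}.
#' @param jTimes sorted J-peak times from \code{\link{detectBeats}}.
#' @param preFrac,postFrac fractions of the neighbouring interbeat
#'   intervals spanned before and after J (must sum to at most 1 so
#'   segments stay disjoint). A wider \code{preFrac} accommodates the long
#'   pre-J systole of high-rate heart-failure beats.
#' @return list of \linkS4class{BeatSegment}.
#' @export
segmentBeats <- function(bcg, jTimes, preFrac = 0.25, postFrac = 0.75) {
  stopifnot(is(bcg, "BCGSignal"))
  jTimes <- as.numeric(jTimes)
  if (length(jTimes) < 2) stop("segmentation error: need at least 2 beats")
  if (is.unsorted(jTimes, strictly = TRUE))
    stop("segmentation error: jTimes must be strictly increasing")
  if (preFrac <= 0 || postFrac <= 0 || preFrac + postFrac > 1 + 1e-9)
    stop("segmentation error: preFrac/postFrac must be positive and sum <= 1")
  fs <- bcg@sampling@fs
  tt0 <- bcg@sampling@t0
  t_end <- tt0 + (length(bcg@samples) - 1) / fs
  nb <- length(jTimes)
  ibi <- diff(jTimes)
  ibi_prev <- c(ibi[1], ibi)
  ibi_next <- c(ibi, ibi[nb - 1])
  scale <- pmin(1, 1.5 / (preFrac * ibi_prev + postFrac * ibi_next))
  starts <- pmax(tt0, jTimes - preFrac * ibi_prev * scale)
  ends <- pmin(t_end, jTimes + postFrac * ibi_next * scale)
  lapply(seq_len(nb), function(b) {
    i0 <- as.integer(ceiling((starts[b] - tt0) * fs + 1 - 1e-9))
    i1 <- as.integer(floor((ends[b] - tt0) * fs + 1 + 1e-9))
    new("BeatSegment", start = tt0 + (i0 - 1) / fs, end = ends[b],
        jTime = jTimes[b], samples = bcg@samples[i0:i1], fs = fs)
  })
}

## significant alternating extrema of a segment: all strict local extrema,
## iteratively pruned of adjacent pairs whose amplitude difference is below
## promFrac * (segment range)
.significant_extrema <- function(x, promFrac) {
  n <- length(x)
  dx <- diff(x)
  sgn <- sign(dx)
  if (any(sgn == 0)) {
    sgn[sgn == 0] <- NA
    sgn <- .locf(sgn)
  }
  turn <- which(diff(sgn) != 0) + 1L
  idx <- c(1L, turn, n)  # include endpoints as anchors
  thr <- promFrac * (max(x) - min(x))
  repeat {
    if (length(idx) < 3) break
    amp <- abs(diff(x[idx]))
    weak <- which(amp < thr)
    if (!length(weak)) break
    w <- weak[which.min(amp[weak])]
    ## removing one leg of the weakest swing merges its neighbours
    drop <- if (w == 1) 2L else if (w == length(amp)) length(idx) - 1L else
      c(w, w + 1L)
    idx <- idx[-drop]
  }
  interior <- idx[idx != 1L & idx != n]
  is_max <- vapply(interior, function(i) x[i] >= x[i - 1] && x[i] >= x[i + 1],
                   logical(1))
  list(maxima = interior[is_max], minima = interior[!is_max],
       n_sig = length(interior))
}

.locf <- function(v) {
  if (all(is.na(v))) return(rep(1, length(v)))
  filled <- v
  for (i in seq_along(filled))
    if (is.na(filled[i])) filled[i] <- if (i > 1) filled[i - 1] else NA
  if (is.na(filled[1])) filled[is.na(filled)] <- filled[!is.na(filled)][1]
  filled
}

#' Locate the seven fiducial points of one beat
#'
#' Applies windowed-extremum rules on the significant extrema of the
#' segment: J is the global maximum; I the lowest minimum within
#' \code{searchS} before J; H the highest maximum between the start of that
#' window and I; K the first minimum after J; L the first maximum after K;
#' M the lowest minimum within \code{searchS} after L; N the first maximum
#' after M. The quality score is (fraction of fiducials found) *
#' min(1, 7 / number of significant extrema), so beats contaminated by
#' noise or missing waves score below 1.
#'
#' @param segment a \linkS4class{BeatSegment}.
#' @param searchS local search window, seconds.
#' @param promFrac prominence floor as a fraction of the segment range.
#' @return a \linkS4class{FiducialSet} (absolute times).
#' @export
detectFiducials <- function(segment, searchS = 0.25, promFrac = 0.05) {
  stopifnot(is(segment, "BeatSegment"))
  x <- segment@samples
  tt <- sampleTimes(segment)
  fs <- segment@fs
  ext <- .significant_extrema(x, promFrac)
  maxima <- ext$maxima
  minima <- ext$minima

  times <- stats::setNames(rep(NA_real_, 7), FIDUCIAL_NAMES)
  amps <- stats::setNames(rep(NA_real_, 7), FIDUCIAL_NAMES)
  pick <- function(i) {
    if (length(i) && is.finite(i)) c(tt[i], x[i]) else c(NA_real_, NA_real_)
  }
  set_fid <- function(nm, i) {
    v <- pick(i)
    times[nm] <<- v[1]
    amps[nm] <<- v[2]
    i
  }

  jI <- which.max(x)  # global maximum, earliest on ties
  set_fid("J", jI)
  tj <- tt[jI]

  iwin <- minima[tt[minima] > tj - searchS & tt[minima] < tj]
  iI <- if (length(iwin)) iwin[which.min(x[iwin])] else NA_integer_
  set_fid("I", iI)

  if (!is.na(iI)) {
    ## the pre-ejection H wave can sit well before J in heart failure, so
    ## its window runs from the segment start up to I
    hwin <- maxima[maxima < iI]
    set_fid("H", if (length(hwin)) hwin[which.max(x[hwin])] else NA_integer_)
  }

  kwin <- minima[minima > jI]
  kI <- if (length(kwin)) kwin[1] else NA_integer_
  set_fid("K", kI)

  lI <- NA_integer_
  if (!is.na(kI)) {
    lwin <- maxima[maxima > kI]
    lI <- if (length(lwin)) lwin[1] else NA_integer_
    set_fid("L", lI)
  }

  mI <- NA_integer_
  if (!is.na(lI)) {
    mwin <- minima[minima > lI & tt[minima] <= tt[lI] + searchS]
    mI <- if (length(mwin)) mwin[which.min(x[mwin])] else NA_integer_
    set_fid("M", mI)
  }

  if (!is.na(mI)) {
    nwin <- maxima[maxima > mI]
    set_fid("N", if (length(nwin)) nwin[1] else NA_integer_)
  }

  found <- sum(!is.na(times))
  ## extraneous prominent extrema are counted within the beat's own span
  ## (H to N, with a small margin), so structure or noise in the segment
  ## tails does not penalize an otherwise clean beat
  span_lo <- if (!is.na(times[["H"]])) times[["H"]] - 0.05 else tt[1]
  span_hi <- if (!is.na(times[["N"]])) times[["N"]] + 0.05 else tt[length(tt)]
  all_sig <- c(ext$maxima, ext$minima)
  n_sig <- sum(tt[all_sig] >= span_lo & tt[all_sig] <= span_hi)
  q <- (found / 7) * min(1, 7 / max(1, n_sig))
  ## an ordering violation downgrades rather than errors: caller drops beat
  tt_found <- times[!is.na(times)]
  if (length(tt_found) > 1 && any(diff(tt_found) <= 0)) {
    q <- min(q, 0.4)
    times[] <- NA_real_
    amps[] <- NA_real_
    times["J"] <- tt[jI]
    amps["J"] <- x[jI]
  }
  new("FiducialSet", times = times, amps = amps, quality = q)
}

#' Compare BCG interbeat intervals with ECG R-R intervals
#'
#' Pairs detected J times to R times by nearest neighbour within
#' \code{tolS}; unpaired events on either side are excluded and counted.
#' Successive-difference intervals of the paired trains are compared by
#' relative error |bcg - rr| / rr.
#'
#' @param jTimes detected BCG beat times, seconds.
#' @param rTimes ECG R-peak times, seconds.
#' @param tolS pairing tolerance, seconds.
#' @return list with bcgIntervals, rrIntervals, relativeErrors,
#'   maxRelativeError, medianRelativeError, nUnpaired.
#' @export
compareIntervals <- function(jTimes, rTimes, tolS = 0.4) {
  jTimes <- sort(as.numeric(jTimes))
  rTimes <- sort(as.numeric(rTimes))
  ## greedy nearest-neighbour one-to-one pairing
  pairs <- NULL
  used_r <- logical(length(rTimes))
  for (ji in seq_along(jTimes)) {
    d <- abs(rTimes - jTimes[ji])
    d[used_r] <- Inf
    ri <- which.min(d)
    if (length(ri) && d[ri] <= tolS) {
      used_r[ri] <- TRUE
      pairs <- rbind(pairs, c(ji, ri))
    }
  }
  n_pair <- if (is.null(pairs)) 0L else nrow(pairs)
  if (n_pair < 2)
    stop("comparison error: fewer than 2 paired beats")
  jp <- jTimes[pairs[, 1]]
  rp <- rTimes[pairs[, 2]]
  bcg_int <- diff(jp)
  rr_int <- diff(rp)
  rel <- abs(bcg_int - rr_int) / rr_int
  list(bcgIntervals = bcg_int, rrIntervals = rr_int, relativeErrors = rel,
       maxRelativeError = max(rel), medianRelativeError = stats::median(rel),
       nUnpaired = (length(jTimes) - n_pair) + (length(rTimes) - n_pair))
}

#' Subdivide diastole at the ECG P peak
#'
#' The diastolic NH interval runs from mitral opening (N) to the next mitral
#' closure (H); the synchronized ECG P peak splits it into the ventricular
#' filling phase (N to P) and the atrial contraction phase (P to next H).
#'
#' @param fiducials \linkS4class{FiducialSet} of the current beat.
#' @param nextFiducials \linkS4class{FiducialSet} of the next beat.
#' @param pTime ECG P-peak time between them, seconds.
#' @return named numeric: filling and atrial interval, seconds.
#' @export
subdivideDiastole <- function(fiducials, nextFiducials, pTime) {
  t_n <- fiducials@times[["N"]]
  t_h2 <- nextFiducials@times[["H"]]
  if (is.na(t_n) || is.na(t_h2))
    stop("phase error: N or next H fiducial missing")
  if (!(pTime > t_n && pTime < t_h2))
    stop("ordering error: P time must lie strictly inside (t_N, next t_H)")
  c(filling = pTime - t_n, atrial = t_h2 - pTime)
}
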