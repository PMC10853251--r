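## Cardiac-cycle phase categorization and the nine-parameter feature vector
## (three intervals, three amplitudes, three chord slopes), with DTW-based
## beat averaging for per-subject robustness.

.need_fiducials <- function(f, pts) {
  missing <- pts[is.na(f@times[pts])]
  if (length(missing))
    stop("phase error: missing fiducial point(s) ",
         paste(missing, collapse = ", "))
}

#' Cardiac-cycle phase intervals of one beat
#'
#' Maps fiducial intervals onto the phases of the cardiac cycle: HI is the
#' isovolumetric contraction time (IVCT), IM the left ventricular ejection
#' time (LVET), MN the isovolumetric relaxation time (IVRT) and NH (to the
#' next beat's H) the diastolic filling plus atrial contraction span.
#'
#' @param fiducials \linkS4class{FiducialSet} of the beat.
#' @param nextFiducials \linkS4class{FiducialSet} of the following beat.
#' @return named numeric (ms): ivct_ms, lvet_ms, ivrt_ms, nh_ms.
#' @export
phaseIntervals <- function(fiducials, nextFiducials) {
  .need_fiducials(fiducials, c("H", "I", "M", "N"))
  .need_fiducials(nextFiducials, "H")
  t <- fiducials@times
  ivct <- t[["I"]] - t[["H"]]
  if (ivct <= 0) stop("phase error: zero or negative IVCT (t_I <= t_H)")
  out <- c(ivct_ms = ivct,
           lvet_ms = t[["M"]] - t[["I"]],
           ivrt_ms = t[["N"]] - t[["M"]],
           nh_ms = nextFiducials@times[["H"]] - t[["N"]]) * 1000
  if (any(out <= 0)) stop("phase error: non-positive phase interval")
  out
}

#' Nine-parameter feature vector of one beat
#'
#' Computes the three cardiac time intervals (HI, IM, MN in ms), the three
#' amplitude excursions (|a_I - a_H|, |a_J - a_I|, |a_N - a_M| in V) and the
#' three signed chord slopes ((a_Y - a_X) / (t_Y - t_X) in V/s) from a
#' full-quality fiducial set.
#'
#' @param fiducials a full-quality \linkS4class{FiducialSet}.
#' @return named numeric(9) in the canonical feature order.
#' @export
beatFeatures <- function(fiducials) {
  .need_fiducials(fiducials, FIDUCIAL_NAMES)
  t <- fiducials@times
  a <- fiducials@amps
  seg <- function(p, q) {
    dt <- t[[q]] - t[[p]]
    if (dt == 0) stop("slope error: coincident fiducial times ", p, "-", q)
    c(1000 * dt, abs(a[[q]] - a[[p]]), (a[[q]] - a[[p]]) / dt)
  }
  hi <- seg("H", "I"); ij <- seg("I", "J")
  im <- seg("I", "M"); mn <- seg("M", "N")
  stats::setNames(c(hi[1], im[1], mn[1], hi[2], ij[2], mn[2],
                    hi[3], ij[3], mn[3]), FEATURE_NAMES)
}

## internal: beats as (relative time, amplitude) pairs anchored at J, plus
## a lightly smoothed copy used for alignment only (aligning on smoothed
## amplitudes stops the warping from chasing noise extremes, which would
## otherwise systematically deepen slow valleys in the average)
.beat_curve <- function(segment, smooth_n = 11L) {
  y <- segment@samples
  k <- rep(1 / smooth_n, smooth_n)
  ys <- stats::filter(y, k, method = "convolution", sides = 2)
  ys[is.na(ys)] <- y[is.na(ys)]
  list(t = sampleTimes(segment) - segment@jTime, y = y,
       ys = as.numeric(ys))
}

#' Average beats by banded dynamic time warping
#'
#' The medoid beat (smallest total DTW distance over a subset of at most
#' \code{maxMedoid} evenly spaced beats) serves as the initial reference;
#' every beat is aligned to the reference with a Sakoe-Chiba band of
#' \code{bandS} seconds, and both amplitudes and matched sample times are
#' averaged per reference index, so beat-to-beat timing jitter averages out
#' instead of collapsing onto the medoid's timing. The averaged (time,
#' amplitude) curve is resampled on the uniform grid and the procedure is
#' refined for \code{iterations} further passes. Deterministic given the
#' input order.
#'
#' @param segments list of at least three \linkS4class{BeatSegment}.
#' @param bandS Sakoe-Chiba band half-width, seconds.
#' @param maxMedoid cap on the number of beats entering the medoid search.
#' @param iterations refinement passes after the medoid-referenced pass.
#' @return a \linkS4class{BeatSegment} holding the averaged beat, with time
#'   axis relative to the J peak (jTime = 0).
#' @export
dtwAverageBeat <- function(segments, bandS = 0.1, maxMedoid = 25,
                           iterations = 2) {
  if (length(segments) < 3)
    stop("averaging error: need at least 3 beats")
  fs <- segments[[1]]@fs
  band <- as.integer(round(bandS * fs))
  beats <- lapply(segments, .beat_curve)
  nb <- length(beats)
  ## crop to the common J-anchored time window so all beats have equal
  ## length and the band diagonal is the identity alignment; segment spans
  ## differ with the local interbeat interval, and a length-scaled diagonal
  ## would smear the beat tail
  lo <- max(vapply(beats, function(b) b$t[1], numeric(1)))
  hi <- min(vapply(beats, function(b) b$t[length(b$t)], numeric(1)))
  if (hi - lo < 0.3)
    stop("averaging error: beats share too little common support")
  beats <- lapply(beats, function(b) {
    k <- which(b$t >= lo - 1e-9 & b$t <= hi + 1e-9)
    list(t = b$t[k], y = b$y[k], ys = b$ys[k])
  })

  sub <- unique(as.integer(round(seq(1, nb, length.out = min(maxMedoid, nb)))))
  dmat <- matrix(0, length(sub), length(sub))
  for (i in seq_along(sub))
    for (j in seq_along(sub))
      if (j > i) {
        d <- .dtw_align(beats[[sub[i]]]$ys, beats[[sub[j]]]$ys, band,
                        FALSE, 0)$dist
        dmat[i, j] <- dmat[j, i] <- d
      }
  ref <- beats[[sub[which.min(rowSums(dmat))]]]

  for (pass in seq_len(1 + iterations)) {
    nr <- length(ref$y)
    sum_y <- numeric(nr)
    sum_t <- numeric(nr)
    cnt <- numeric(nr)
    for (b in beats) {
      al <- .dtw_align(ref$ys, b$ys, band, TRUE, 0)
      ir <- al$index_ref
      iq <- al$index_query
      ok <- ir > 0 & iq > 0
      ir <- ir[ok]; iq <- iq[ok]
      sum_y <- sum_y + tabulate_sum(ir, b$y[iq], nr)
      sum_t <- sum_t + tabulate_sum(ir, b$t[iq], nr)
      cnt <- cnt + tabulate(ir, nbins = nr)
    }
    tau <- sum_t / cnt
    avg <- sum_y / cnt
    tau <- cummax(tau)  # guard monotonicity against float ties
    grid <- seq(ceiling(tau[1] * fs) / fs, floor(tau[nr] * fs) / fs,
                by = 1 / fs)
    y_grid <- stats::approx(tau, avg, xout = grid, ties = mean,
                            rule = 2)$y
    sm <- stats::filter(y_grid, rep(1 / 11, 11), method = "convolution",
                        sides = 2)
    sm[is.na(sm)] <- y_grid[is.na(sm)]
    ref <- list(t = grid, y = y_grid, ys = as.numeric(sm))
  }
  new("BeatSegment", start = ref$t[1], end = ref$t[length(ref$t)] + 1 / fs,
      jTime = 0, samples = ref$y, fs = fs)
}

## grouped sum: sum values v by integer group g into n bins
tabulate_sum <- function(g, v, n) {
  out <- numeric(n)
  agg <- rowsum(v, g)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

#' Per-subject feature vector from an extracted BCG signal
#'
#' Detects beats, segments them, locates fiducials, keeps full-quality
#' beats, and computes the nine features on the DTW-averaged beat; when
#' averaging is impossible (fewer than three usable beats) or the averaged
#' beat fails fiducial detection, the median of per-beat features is used
#' instead. The aggregation path is reported in attribute "path".
#'
#' @param bcg a \linkS4class{BCGSignal} of at least 8 s.
#' @param annotations optional precomputed list with elements
#'   \code{segments} and \code{fiducials} (as produced internally); when
#'   NULL the beat pipeline is run.
#' @param useDtw average beats with DTW (default) or go straight to the
#'   per-beat median.
#' @param minQuality minimum fiducial quality for a beat to be used.
#' @param edgeTrimS seconds excluded at both record ends (where zero-phase
#'   baseline removal leaves a decaying transient); automatically reduced on
#'   short records so at least 8 s remain.
#' @return named numeric(9) with attribute "path" and "nBeatsUsed".
#' @export
subjectFeatures <- function(bcg, annotations = NULL, useDtw = TRUE,
                            minQuality = 1, edgeTrimS = 5) {
  stopifnot(is(bcg, "BCGSignal"))
  dur <- duration(bcg)
  if (dur < 8)
    stop("subject-feature error: need at least 8 s of signal")
  if (is.null(annotations)) {
    j <- detectBeats(bcg)
    if (length(j) < 2) stop("subject-feature error: no beats detected")
    segs <- segmentBeats(bcg, j)
    fids <- lapply(segs, detectFiducials)
    ## a long pre-J systole (high-rate heart-failure beats) can push the H
    ## wave out of the default segment window, or leave next-beat structure
    ## in the tail; when few beats reach full quality, retry with a wider
    ## pre-window and keep the better segmentation
    q1frac <- function(ff)
      mean(vapply(ff, function(f) f@quality >= 1 - 1e-9, logical(1)))
    best <- q1frac(fids)
    for (pf in c(0.35, 0.45)) {
      if (best >= 0.6) break
      segs2 <- segmentBeats(bcg, j, preFrac = pf, postFrac = 1 - pf)
      fids2 <- lapply(segs2, detectFiducials)
      q2 <- q1frac(fids2)
      if (q2 > best) {
        segs <- segs2
        fids <- fids2
        best <- q2
      }
    }
    annotations <- list(segments = segs, fiducials = fids)
  }
  trim <- min(edgeTrimS, max(0, (dur - 8) / 2))
  t0 <- bcg@sampling@t0
  inside <- vapply(annotations$segments, function(s)
    s@start >= t0 + trim && s@end <= t0 + dur - trim, logical(1))
  q <- vapply(annotations$fiducials, quality, numeric(1))
  full <- inside & q >= minQuality - 1e-9
  if (!any(full)) stop("subject-feature error: no full-quality beats")
  segs <- annotations$segments[full]
  fids <- annotations$fiducials[full]

  path <- "per_beat_median"
  feats <- NULL
  if (useDtw && length(segs) >= 3) {
    avg <- dtwAverageBeat(segs)
    af <- detectFiducials(avg)
    if (quality(af) >= 1 - 1e-9) {
      feats <- try(beatFeatures(af), silent = TRUE)
      if (!inherits(feats, "try-error")) path <- "dtw_average"
      else feats <- NULL
    }
  }
  if (is.null(feats)) {
    per_beat <- lapply(fids, function(f) try(beatFeatures(f), silent = TRUE))
    per_beat <- per_beat[!vapply(per_beat, inherits, logical(1), "try-error")]
    if (!length(per_beat))
      stop("subject-feature error: no beat yielded features")
    feats <- apply(do.call(rbind, per_beat), 2, stats::median)
  }
  structure(feats, path = path, nBeatsUsed = length(segs))
}

#' Agreement statistics between two measurement series
#'
#' Spearman's rank correlation, the coefficient of determination of the
#' least-squares fit, and the median absolute error.
#'
#' @param x,y equal-length numeric vectors (n >= 3).
#' @return named numeric: spearman_r, r_squared, median_abs_error.
#' @export
agreementStats <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop("agreement error: need equal lengths >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined-correlation error: constant input")
  c(spearman_r = stats::cor(x, y, method = "spearman"),
    r_squared = stats::cor(x, y)^2,
    median_abs_error = stats::median(abs(x - y)))
}
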