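## BCG extraction: de-trending, respiration/baseline high-pass, and windowed
## wavelet multiresolution synthesis of the 0.5-35 Hz band.

#' Remove per-window mean and linear trend
#'
#' Splits the record into consecutive 8-s windows (the final partial window
#' is handled as-is) and subtracts the least-squares linear fit from each,
#' leaving every window with zero mean and negligible residual slope.
#'
#' @param record a \linkS4class{VibrationRecord}.
#' @param windowS detrending window length in seconds.
#' @return the detrended \linkS4class{VibrationRecord}.
#' @export
detrendRecord <- function(record, windowS = 8) {
  stopifnot(is(record, "VibrationRecord"))
  x <- record@samples
  if (any(!is.finite(x))) stop("invalid-signal error: non-finite samples")
  fs <- record@sampling@fs
  n <- length(x)
  if (n < fs) stop("invalid-signal error: record shorter than 1 s")
  w <- as.integer(round(windowS * fs))
  starts <- seq(1L, n, by = w)
  for (s in starts) {
    e <- min(n, s + w - 1L)
    idx <- s:e
    tt <- seq_along(idx)
    fit <- stats::lm.fit(cbind(1, tt), x[idx])
    x[idx] <- fit$residuals
  }
  methods::initialize(record, samples = x)
}

## autoregressive continuation of a series (Yule-Walker fit); rev = TRUE
## returns the backward extension in natural time order
.ar_forecast <- function(v, steps, rev = FALSE) {
  if (steps < 1) return(numeric(0))
  fit <- try(stats::ar(v, order.max = min(30L, length(v) %/% 3),
                       method = "yule-walker"), silent = TRUE)
  out <- if (inherits(fit, "try-error") || fit$order == 0)
    rep(v[length(v)], steps)
  else as.numeric(stats::predict(fit, n.ahead = steps, se.fit = FALSE))
  if (rev) rev(out) else out
}

## penalized-least-squares (Whittaker) smoother, second-difference penalty,
## solved on the pentadiagonal normal equations
.whittaker <- function(y, lambda) {
  n <- length(y)
  if (n < 5) return(y)
  D <- Matrix::bandSparse(n - 2, n,
                          k = 0:2,
                          diagonals = list(rep(1, n - 2), rep(-2, n - 2),
                                           rep(1, n - 2)))
  A <- Matrix::Diagonal(n) + lambda * Matrix::crossprod(D)
  as.numeric(Matrix::solve(A, y))
}

## zero-phase respiration/baseline removal below the BCG band. The baseline
## is estimated on a ~25 Hz decimated series with a double-pass Whittaker
## smoother (corner frequency f_pass), interpolated back and subtracted;
## a spectral raised-cosine high-pass (transition f_stop..f_pass on the
## odd-extended signal) then removes the small mid-record remainder. Edge
## transients decay within a few seconds of the record ends.
.hp_baseline <- function(x, fs, f_stop = 0.35, f_pass = 0.55, pad_s = 8) {
  n <- length(x)
  ## baseline estimate on the decimated series; the series is extended at
  ## both ends with autoregressive forecasts (the respiratory component is
  ## narrowband, so the continuation is accurate for the couple of seconds
  ## the smoother kernel needs), which removes the one-sided edge bias
  dec <- max(1L, as.integer(floor(fs / 25)))
  nb <- as.integer(floor(n / dec))
  if (nb >= 10) {
    xb <- colMeans(matrix(x[1:(nb * dec)], nrow = dec))
    fsb <- fs / dec
    tb <- (seq_len(nb) - 0.5) * dec / fs
    pb <- min(nb - 1L, as.integer(round(10 * fsb)))
    ext <- c(.ar_forecast(rev(xb), pb, rev = TRUE), xb,
             .ar_forecast(xb, pb))
    wc <- 2 * pi * f_pass / fsb
    lam <- 1 / (2 - 2 * cos(wc))^2
    b1 <- .whittaker(ext, lam)
    b2 <- (b1 + .whittaker(ext - b1, lam))[(pb + 1):(pb + nb)]
    base <- stats::spline(tb, b2, xout = (seq_len(n) - 1) / fs)$y
    x <- x - base
  }
  ## spectral high-pass of the remainder (odd extension at the boundaries)
  p <- min(n - 1L, as.integer(round(pad_s * fs)))
  ext <- c(2 * x[1] - rev(x[2:(p + 1)]), x,
           2 * x[n] - rev(x[(n - p):(n - 1)]))
  m <- length(ext)
  f <- (seq_len(m) - 1) / m * fs
  f <- pmin(f, fs - f)  # two-sided frequency axis
  mask <- rep(1, m)
  mask[f <= f_stop] <- 0
  tr <- f > f_stop & f < f_pass
  mask[tr] <- 0.5 * (1 - cos(pi * (f[tr] - f_stop) / (f_pass - f_stop)))
  y <- Re(stats::fft(stats::fft(ext) * mask, inverse = TRUE)) / m
  y[(p + 1):(p + n)]
}

## default level set: detail levels whose dyadic band [fs/2^(j+1), fs/2^j]
## has its geometric centre inside the 0.5-35 Hz BCG band, so levels that
## merely graze the band edge are excluded; at fs = 1000 this is 5:10
.bcg_levels <- function(fs, band = c(0.5, 35)) {
  j <- 1:15
  centre <- sqrt(fs / 2^(j + 1) * fs / 2^j)
  j[centre > band[1] & centre < band[2]]
}

#' Extract the BCG waveform from a raw vibration record
#'
#' The record is de-trended per 8-s window, the respiratory/baseline
#' component below the BCG band is removed with a zero-phase spectral
#' high-pass (raised-cosine transition 0.35-0.55 Hz), and each 8-s analysis
#' window is decomposed with the sym4 DWT; the BCG waveform is the synthesis
#' of detail subcomponents d5-d10 (at 1000 Hz: about 0.49-31.25 Hz).
#' Adjacent windows overlap by \code{crossfadeS} seconds and are joined with
#' a raised-cosine cross-fade; a record shorter than one window is
#' symmetrically extended.
#'
#' @param record a \linkS4class{VibrationRecord}.
#' @param levels integer detail levels to synthesize. Default \code{NULL}
#'   selects the levels whose dyadic bands intersect 0.5-35 Hz (5:10 at
#'   fs = 1000).
#' @param wavelet wavelet name (sym4).
#' @param windowS analysis window length, seconds.
#' @param crossfadeS cross-fade length between adjacent windows, seconds.
#' @param respHp two-element numeric: stop and pass edges (Hz) of the
#'   baseline high-pass; NULL disables it.
#' @return a \linkS4class{BCGSignal}.
#' @export
extractBcg <- function(record, levels = NULL, wavelet = "sym4", windowS = 8,
                       crossfadeS = 0.25, respHp = c(0.35, 0.55)) {
  stopifnot(is(record, "VibrationRecord"))
  if (length(record@samples) == 0) stop("invalid-signal error: empty record")
  fs <- record@sampling@fs
  if (is.null(levels)) levels <- .bcg_levels(fs)
  levels <- sort(as.integer(levels))
  max_level <- max(levels)

  ## one global linear detrend (mean + trend); per-window DC is removed by
  ## the band synthesis itself since the approximation band is excluded
  record <- detrendRecord(record, windowS = duration(record) + 1)
  x <- record@samples
  if (!is.null(respHp) && length(x) > 2 * fs)
    x <- .hp_baseline(x, fs, f_stop = respHp[1], f_pass = respHp[2])

  n <- length(x)
  w <- as.integer(round(windowS * fs))
  ov <- as.integer(round(crossfadeS * fs))
  hop <- w - ov
  flt <- .wt_filters(wavelet)
  synth <- function(seg) {
    if (any(!is.finite(seg))) stop("invalid-signal error: non-finite samples")
    .band_sum_reconstruct(.wavedec(seg, max_level, flt), levels, flt)
  }
  if (n <= w) {
    out <- synth(.sym_extend(x, w))[seq_len(n)]
  } else {
    starts <- unique(c(seq(1L, n - w + 1L, by = hop), n - w + 1L))
    out <- numeric(n)
    wsum <- numeric(n)
    ramp_up <- 0.5 * (1 - cos(pi * seq_len(ov) / (ov + 1)))
    for (s in starts) {
      e <- s + w - 1L
      y <- synth(x[s:e])
      wt <- rep(1, w)
      if (s > 1L) wt[seq_len(ov)] <- ramp_up
      if (e < n) wt[(w - ov + 1L):w] <- rev(ramp_up)
      out[s:e] <- out[s:e] + wt * y
      wsum[s:e] <- wsum[s:e] + wt
    }
    out <- out / wsum
  }
  new("BCGSignal", samples = out, sampling = record@sampling,
      levelsUsed = levels, sourceWindowLength = windowS,
      groundTruth = record@groundTruth)
}

## symmetric (half-sample) extension of a short window up to length w
.sym_extend <- function(x, w) {
  while (length(x) < w) {
    need <- w - length(x)
    x <- c(x, rev(x)[seq_len(min(need, length(x)))])
  }
  x
}
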