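## Signal and ground-truth file I/O. Primary interchange format is a
## two-column CSV (time_s, volts); a minimal WFDB format-16 subset
## (.hea header + 16-bit little-endian .dat) is supported for
## interoperability with physiological-waveform tools.

#' Write a vibration record or BCG signal
#'
#' @param record a \linkS4class{VibrationRecord} or \linkS4class{BCGSignal}.
#' @param path output path; for WFDB the path without extension (a .hea and
#'   a .dat file are written).
#' @param format "csv" or "wfdb".
#' @param gain WFDB ADC gain (units per volt); quantization step is 1/gain.
#' @return the path, invisibly.
#' @export
writeSignal <- function(record, path, format = c("csv", "wfdb"),
                        gain = 1000) {
  format <- match.arg(format)
  x <- samples(record)
  fs <- samplingRate(record)
  if (format == "csv") {
    tt <- sampleTimes(record)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("time_s,volts", con)
    writeLines(sprintf("%.12f,%.17g", tt, x), con)
  } else {
    base <- sub("\\.(hea|dat)$", "", path)
    rec_name <- basename(base)
    adc <- as.integer(pmin(32767, pmax(-32768, round(x * gain))))
    writeLines(c(sprintf("%s 1 %g %d", rec_name, fs, length(x)),
                 sprintf("%s.dat 16 %g(0)/V 16 0 %d 0 0 bcg", rec_name,
                         gain, adc[1])),
               paste0(base, ".hea"))
    writeBin(adc, paste0(base, ".dat"), size = 2, endian = "little")
  }
  invisible(path)
}

#' Read a vibration record
#'
#' CSV dialect: header \code{time_s,volts}, UTF-8, '.' decimal, strictly
#' increasing time with uniform sampling (interval jitter beyond 1 ppm is a
#' format error). WFDB: the format-16 subset written by
#' \code{\link{writeSignal}}.
#'
#' @param path file path (for WFDB, with or without the .hea extension).
#' @param format "csv" or "wfdb".
#' @return a \linkS4class{VibrationRecord} (without ground truth).
#' @export
readSignal <- function(path, format = c("csv", "wfdb")) {
  format <- match.arg(format)
  if (format == "csv") {
    if (!file.exists(path)) stop("format error: file not found: ", path)
    head_line <- readLines(path, n = 1)
    if (!length(head_line) || !identical(head_line, "time_s,volts"))
      stop("format error: expected header 'time_s,volts'")
    df <- utils::read.csv(path, colClasses = "numeric")
    if (!nrow(df)) stop("format error: no samples")
    dt <- diff(df$time_s)
    if (nrow(df) < 2 || any(dt <= 0))
      stop("format error: time column must be strictly increasing")
    med <- stats::median(dt)
    if (max(abs(dt - med)) > 1e-6 * med + 1e-12)
      stop("format error: inconsistent sampling interval")
    fs <- 1 / med
    new("VibrationRecord", samples = df$volts,
        sampling = new("SamplingSpec", fs = fs, nSamples = nrow(df),
                       t0 = df$time_s[1]))
  } else {
    base <- sub("\\.(hea|dat)$", "", path)
    hea <- paste0(base, ".hea")
    if (!file.exists(hea)) stop("format error: header not found: ", hea)
    lines <- readLines(hea)
    rec_fields <- strsplit(trimws(lines[1]), "\\s+")[[1]]
    sig_fields <- strsplit(trimws(lines[2]), "\\s+")[[1]]
    fs <- as.numeric(rec_fields[3])
    n <- as.integer(rec_fields[4])
    gain <- as.numeric(sub("\\(.*$", "", sig_fields[3]))
    if (!is.finite(fs) || !is.finite(gain) || is.na(n))
      stop("format error: malformed WFDB header")
    adc <- readBin(paste0(base, ".dat"), "integer", n = n, size = 2,
                   endian = "little")
    if (length(adc) != n) stop("format error: truncated .dat file")
    new("VibrationRecord", samples = adc / gain,
        sampling = new("SamplingSpec", fs = fs, nSamples = n, t0 = 0))
  }
}

#' Write / read the ground-truth sidecar as JSON
#'
#' @param gt a \linkS4class{GroundTruth}.
#' @param path JSON file path.
#' @return \code{writeGroundTruth}: the path invisibly;
#'   \code{readGroundTruth}: a \linkS4class{GroundTruth}.
#' @export
writeGroundTruth <- function(gt, path) {
  stopifnot(is(gt, "GroundTruth"))
  obj <- list(beat_times = gt@beatTimes,
              fiducials = gt@fiducials,
              r_times = gt@rTimes,
              p_times = gt@pTimes,
              beat_labels = gt@beatLabels)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname writeGroundTruth
#' @export
readGroundTruth <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("GroundTruth", beatTimes = as.numeric(obj$beat_times),
      fiducials = as.data.frame(obj$fiducials),
      rTimes = as.numeric(obj$r_times),
      pTimes = as.numeric(obj$p_times),
      beatLabels = as.character(obj$beat_labels))
}

#' Write per-beat annotations as CSV
#'
#' One row per beat: index, quality and the fiducial times/amplitudes.
#'
#' @param fiducials list of \linkS4class{FiducialSet}.
#' @param path CSV path.
#' @return the annotation data.frame, invisibly.
#' @export
writeAnnotations <- function(fiducials, path) {
  df <- annotationTable(fiducials)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' @rdname writeAnnotations
#' @export
annotationTable <- function(fiducials) {
  rows <- lapply(seq_along(fiducials), function(i) {
    f <- fiducials[[i]]
    cbind(.fiducial_row(i, f@times, f@amps), quality = f@quality)
  })
  do.call(rbind, rows)
}
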