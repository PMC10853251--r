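#' Accessors for signal containers
#'
#' \code{samples} returns the raw numeric samples, \code{samplingRate} the
#' sampling rate in Hz, \code{sampleTimes} the absolute time of every sample,
#' \code{groundTruth} the generator sidecar (or NULL), \code{quality} the
#' fiducial detection quality, and \code{fiducialTimes}/\code{fiducialAmps}
#' the named per-beat fiducial vectors.
#'
#' @param x an object.
#' @return the accessed component.
#' @name accessors
#' @rdname accessors
#' @export
setGeneric("samples", function(x) standardGeneric("samples"))

#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname accessors
#' @export
setGeneric("sampleTimes", function(x) standardGeneric("sampleTimes"))

#' @rdname accessors
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

#' @rdname accessors
#' @export
setGeneric("quality", function(x) standardGeneric("quality"))

#' @rdname accessors
#' @export
setGeneric("fiducialTimes", function(x) standardGeneric("fiducialTimes"))

#' @rdname accessors
#' @export
setGeneric("fiducialAmps", function(x) standardGeneric("fiducialAmps"))

#' @rdname accessors
#' @export
setGeneric("duration", function(x) standardGeneric("duration"))

#' @rdname accessors
setMethod("samples", "VibrationRecord", function(x) x@samples)
#' @rdname accessors
setMethod("samples", "BCGSignal", function(x) x@samples)
#' @rdname accessors
setMethod("samples", "BeatSegment", function(x) x@samples)

#' @rdname accessors
setMethod("samplingRate", "SamplingSpec", function(x) x@fs)
#' @rdname accessors
setMethod("samplingRate", "VibrationRecord", function(x) x@sampling@fs)
#' @rdname accessors
setMethod("samplingRate", "BCGSignal", function(x) x@sampling@fs)
#' @rdname accessors
setMethod("samplingRate", "BeatSegment", function(x) x@fs)

#' @rdname accessors
setMethod("sampleTimes", "SamplingSpec", function(x)
  x@t0 + (seq_len(x@nSamples) - 1) / x@fs)
#' @rdname accessors
setMethod("sampleTimes", "VibrationRecord", function(x) sampleTimes(x@sampling))
#' @rdname accessors
setMethod("sampleTimes", "BCGSignal", function(x) sampleTimes(x@sampling))
#' @rdname accessors
setMethod("sampleTimes", "BeatSegment", function(x)
  x@start + (seq_along(x@samples) - 1) / x@fs)

#' @rdname accessors
setMethod("groundTruth", "VibrationRecord", function(x) x@groundTruth)
#' @rdname accessors
setMethod("groundTruth", "BCGSignal", function(x) x@groundTruth)

#' @rdname accessors
setMethod("quality", "FiducialSet", function(x) x@quality)
#' @rdname accessors
setMethod("fiducialTimes", "FiducialSet", function(x) x@times)
#' @rdname accessors
setMethod("fiducialAmps", "FiducialSet", function(x) x@amps)

#' @rdname accessors
setMethod("duration", "SamplingSpec", function(x) x@nSamples / x@fs)
#' @rdname accessors
setMethod("duration", "VibrationRecord", function(x) duration(x@sampling))
#' @rdname accessors
setMethod("duration", "BCGSignal", function(x) duration(x@sampling))
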