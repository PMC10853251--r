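#' @describeIn accessors compact display of a VibrationRecord
setMethod("show", "VibrationRecord", function(object) {
  cat(sprintf("VibrationRecord: %d samples @ %g Hz (%.1f s)\n",
              length(object@samples), object@sampling@fs, duration(object)))
  if (!is.null(object@groundTruth))
    cat(sprintf("  ground truth: %d beats (%s)\n",
                length(object@groundTruth@beatTimes),
                paste(names(table(object@groundTruth@beatLabels)),
                      table(object@groundTruth@beatLabels),
                      sep = "=", collapse = ", ")))
  invisible(NULL)
})

#' @describeIn accessors compact display of a BCGSignal
setMethod("show", "BCGSignal", function(object) {
  cat(sprintf("BCGSignal: %d samples @ %g Hz, levels d%s\n",
              length(object@samples), object@sampling@fs,
              paste(object@levelsUsed, collapse = ",d")))
  invisible(NULL)
})

#' @describeIn accessors compact display of a BeatSegment
setMethod("show", "BeatSegment", function(object) {
  cat(sprintf("BeatSegment: [%.3f, %.3f) s, J at %.3f s, %d samples\n",
              object@start, object@end, object@jTime,
              length(object@samples)))
  invisible(NULL)
})

#' @describeIn accessors compact display of a FiducialSet
setMethod("show", "FiducialSet", function(object) {
  cat(sprintf("FiducialSet (quality %.2f)\n", object@quality))
  print(round(rbind(time_s = object@times, amp_v = object@amps), 4))
  invisible(NULL)
})

#' @describeIn accessors compact display of a BeatTemplate
setMethod("show", "BeatTemplate", function(object) {
  cat("BeatTemplate\n")
  print(round(rbind(t_s = object@times, a_v = object@amps,
                    width_s = object@widths), 4))
  invisible(NULL)
})

#' @describeIn accessors compact display of CVMetrics
setMethod("show", "CVMetrics", function(object) {
  cat(sprintf("CVMetrics: %s, %d-fold (seed %d)\n", object@model,
              object@nFolds, object@seed))
  s <- object@summary
  cat(paste(sprintf("  %s %.3f +/- %.3f", s$metric, s$mean, s$sd),
            collapse = "\n"), "\n")
  invisible(NULL)
})
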