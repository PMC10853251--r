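## shared fixture builders; everything is generated in code at test time

quietRhythm <- function(...) {
  rhythmSpec(respAmp = 0, driftAmp = 0, noiseSd = 0, ...)
}

## wrap a bare numeric vector as a VibrationRecord
asRecord <- function(x, fs = 1000, t0 = 0) {
  new("VibrationRecord", samples = as.numeric(x),
      sampling = new("SamplingSpec", fs = fs, nSamples = length(x), t0 = t0))
}

## wrap a bare numeric vector as a BCGSignal (already-extracted waveform)
asBcg <- function(x, fs = 1000, t0 = 0) {
  new("BCGSignal", samples = as.numeric(x),
      sampling = new("SamplingSpec", fs = fs, nSamples = length(x), t0 = t0),
      levelsUsed = 5:10, sourceWindowLength = 8)
}

## one clean sampled beat as a BeatSegment
templateSegment <- function(template = beatTemplate(), fs = 1000) {
  beat <- makeBeatTemplate(template, fs = fs)
  new("BeatSegment", start = beat@sampling@t0,
      end = beat@sampling@t0 + duration(beat),
      jTime = template@times[["J"]], samples = samples(beat), fs = fs)
}

## manual FiducialSet builder
fidSet <- function(times, amps, quality = 1) {
  names(times) <- names(amps) <- c("H", "I", "J", "K", "L", "M", "N")
  new("FiducialSet", times = times, amps = amps, quality = quality)
}

## default control fiducial geometry as absolute times/amps
controlFid <- function(t0 = 0) {
  tpl <- beatTemplate()
  fidSet(t0 + tpl@times, tpl@amps)
}
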