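test_that("clean 60-bpm record yields one detection per beat within 10 ms", {
  rec <- synthRecord(rhythmSpec(hrSd = 0, respAmp = 0, driftAmp = 0),
                     beatTemplate(), 20, seed = 1)
  bcg <- extractBcg(rec)
  j <- detectBeats(bcg)
  gt <- groundTruth(rec)
  expect_true(abs(length(j) - 20) <= 1)
  for (t in gt@beatTimes)
    expect_lt(min(abs(j - t)), 0.010)
})

test_that("zero signal gives an empty detection list", {
  expect_length(detectBeats(asBcg(numeric(15000))), 0)
})

test_that("a VPB is detected early despite its reduced amplitude", {
  rec <- synthRecord(rhythmSpec(vpbProb = 0.05), beatTemplate(), 60, seed = 3)
  gt <- groundTruth(rec)
  expect_gte(sum(gt@beatLabels == "VPB"), 1)
  j <- detectBeats(extractBcg(rec))
  vpb <- which(gt@beatLabels == "VPB")
  for (b in vpb) {
    expect_lt(min(abs(j - gt@beatTimes[b])), 0.02)
    ## advanced relative to the sinus grid: earlier than the midpoint of
    ## its neighbours
    if (b > 1 && b < length(gt@beatTimes))
      expect_lt(gt@beatTimes[b] - gt@beatTimes[b - 1],
                gt@beatTimes[b + 1] - gt@beatTimes[b])
  }
  expect_true(abs(length(j) - length(gt@beatTimes)) <= 1)
})

test_that("detection degrades monotonically with noise", {
  sens <- vapply(c(0.05, 0.3, 1, 2.5, 5), function(nsd) {
    hits <- 0; total <- 0
    for (s in 1:3) {
      rec <- synthRecord(rhythmSpec(noiseSd = nsd), beatTemplate(), 20,
                         seed = 100 + s)
      gt <- groundTruth(rec)
      j <- detectBeats(extractBcg(rec))
      total <- total + length(gt@beatTimes)
      if (length(j))
        hits <- hits + sum(vapply(gt@beatTimes, function(t)
          min(abs(j - t)) < 0.05, logical(1)))
    }
    hits / total
  }, numeric(1))
  expect_true(all(diff(sens) <= 1e-9))
})

test_that("detection sensitivity and precision exceed 0.99 on clean records", {
  hits <- 0; total_truth <- 0; total_det <- 0
  for (s in 1:10) {
    rec <- synthRecord(rhythmSpec(), beatTemplate(), 30, seed = 200 + s)
    gt <- groundTruth(rec)
    j <- detectBeats(extractBcg(rec))
    total_truth <- total_truth + length(gt@beatTimes)
    total_det <- total_det + length(j)
    hits <- hits + sum(vapply(gt@beatTimes, function(t)
      min(abs(j - t)) < 0.05, logical(1)))
  }
  expect_gte(hits / total_truth, 0.99)   # sensitivity
  expect_gte(hits / total_det, 0.99)     # precision
})

test_that("beat segments follow the quarter/three-quarter split", {
  bcg <- asBcg(numeric(4000), fs = 1000)
  segs <- segmentBeats(bcg, c(1, 2, 3))
  expect_equal(segs[[2]]@start, 2 - 0.25)
  expect_equal(segs[[2]]@end, 2 + 0.75, tolerance = 1e-3)
  ## edge beats are clipped at the record bounds
  expect_gte(segs[[1]]@start, 0)
  expect_lte(segs[[3]]@end, 4)
  expect_error(segmentBeats(bcg, 1.5), "segmentation")
})

test_that("segments stay ordered and disjoint under rhythm jitter", {
  bcg <- asBcg(numeric(30000), fs = 1000)
  for (s in 1:25) {
    set.seed(s)
    j <- cumsum(runif(20, 0.6, 1.4)) + 0.5
    j <- j[j < 29]
    segs <- segmentBeats(bcg, j)
    starts <- vapply(segs, function(x) x@start, numeric(1))
    ends <- vapply(segs, function(x) x@end, numeric(1))
    expect_true(all(diff(starts) > 0))
    expect_true(all(starts[-1] >= ends[-length(ends)] - 1e-6))
    expect_true(all(ends - starts <= 1.5 + 1e-9))
  }
})

test_that("fiducials of a clean beat match the template within 5 ms and 5%", {
  tpl <- beatTemplate()
  f <- detectFiducials(templateSegment(tpl))
  expect_equal(quality(f), 1)
  for (nm in c("H", "I", "J", "K", "L", "M", "N")) {
    expect_lt(abs(f@times[[nm]] - tpl@times[[nm]]), 0.005, label = nm)
    expect_lt(abs(f@amps[[nm]] - tpl@amps[[nm]]) / abs(tpl@amps[[nm]]),
              0.05, label = nm)
  }
  ## exactly 4 peak-type and 3 valley-type fiducials
  expect_equal(sum(!is.na(f@times[c("H", "J", "L", "N")])), 4)
  expect_equal(sum(!is.na(f@times[c("I", "K", "M")])), 3)
})

test_that("pipeline fiducials track the generator ground truth", {
  rec <- synthRecord(rhythmSpec(), beatTemplate(), 30, seed = 1)
  bcg <- extractBcg(rec)
  j <- detectBeats(bcg)
  segs <- segmentBeats(bcg, j)
  fids <- lapply(segs, detectFiducials)
  gt <- groundTruth(rec)
  n_checked <- 0
  for (b in seq_along(fids)) {
    if (quality(fids[[b]]) < 1 - 1e-9) next
    tb <- which.min(abs(gt@beatTimes - segs[[b]]@jTime))
    if (gt@beatTimes[tb] < 6 || gt@beatTimes[tb] > 24) next
    n_checked <- n_checked + 1
    for (nm in c("H", "I", "J", "M", "N")) {
      expect_lt(abs(fids[[b]]@times[[nm]] -
                      gt@fiducials[[paste0("t_", nm)]][tb]), 0.008)
    }
    tt <- fids[[b]]@times
    expect_true(all(diff(tt) > 0))  # ordering invariant
  }
  expect_gte(n_checked, 12)
})

test_that("noise-only segments score quality below 0.5", {
  set.seed(4)
  bn <- extractBcg(asRecord(rnorm(20000, 0, 0.05)))
  for (s0 in seq(3, 15, by = 1.3)) {
    i0 <- round(s0 * 1000)
    seg <- new("BeatSegment", start = s0, end = s0 + 1, jTime = s0 + 0.4,
               samples = samples(bn)[(i0 + 1):(i0 + 1000)], fs = 1000)
    expect_lt(quality(detectFiducials(seg)), 0.5)
  }
})

test_that("interval comparison pairs, excludes and scores correctly", {
  tt <- c(1, 2.01, 3.02, 4.05)
  cmp <- compareIntervals(tt, tt)
  expect_true(all(cmp$relativeErrors == 0))
  expect_equal(cmp$nUnpaired, 0)
  ## one spurious extra detection is dropped and counted
  cmp2 <- compareIntervals(c(tt, 2.5), tt + 0.01)
  expect_equal(cmp2$nUnpaired, 1)
  expect_lt(cmp2$maxRelativeError, 0.03)
  expect_error(compareIntervals(1, c(1, 2)), "comparison")
})

test_that("interbeat intervals match ECG R-R intervals within 2%", {
  rec <- synthRecord(rhythmSpec(), beatTemplate(), 60, seed = 2)
  j <- detectBeats(extractBcg(rec))
  cmp <- compareIntervals(j, groundTruth(rec)@rTimes)
  expect_lt(cmp$maxRelativeError, 0.02)
})

test_that("diastole subdivides at the P peak and conserves the NH span", {
  f1 <- fidSet(c(0, 0.065, 0.135, 0.185, 0.245, 0.375, 0.45),
               beatTemplate()@amps)
  f2 <- fidSet(c(0, 0.065, 0.135, 0.185, 0.245, 0.375, 0.45) + 1,
               beatTemplate()@amps)
  parts <- subdivideDiastole(f1, f2, 0.85)
  expect_equal(unname(parts), c(0.40, 0.15))
  expect_equal(sum(parts), 1 - 0.45)  # NH interval exactly
  expect_error(subdivideDiastole(f1, f2, 0.45), "ordering")
})

test_that("phase intervals sum to the beat period on detected beats", {
  rec <- synthRecord(rhythmSpec(), beatTemplate(), 30, seed = 6)
  bcg <- extractBcg(rec)
  segs <- segmentBeats(bcg, detectBeats(bcg))
  fids <- lapply(segs, detectFiducials)
  q <- vapply(fids, quality, numeric(1))
  checked <- 0
  for (b in seq_len(length(fids) - 1)) {
    if (q[b] < 1 || q[b + 1] < 1) next
    ph <- phaseIntervals(fids[[b]], fids[[b + 1]])
    period <- fids[[b + 1]]@times[["H"]] - fids[[b]]@times[["H"]]
    expect_lt(abs(sum(ph) / 1000 - period), 2 / 1000)
    checked <- checked + 1
  }
  expect_gte(checked, 10)
})
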