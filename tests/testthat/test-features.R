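test_that("phase categorization maps the control template onto IVCT/LVET/IVRT", {
  f1 <- controlFid(0)
  f2 <- controlFid(1)
  ph <- phaseIntervals(f1, f2)
  expect_equal(unname(ph[c("ivct_ms", "lvet_ms", "ivrt_ms")]),
               c(65, 310, 69))
  expect_equal(unname(sum(ph)), 1000)
  ## a zero IVCT (t_I == t_H) violates the fiducial ordering contract
  expect_error(fidSet(c(0, 0, 0.135, 0.185, 0.245, 0.375, 0.444),
                      beatTemplate()@amps, quality = 0.9), "increasing")
})

test_that("beat features follow the chord arithmetic", {
  f <- fidSet(times = c(0, 0.05, 0.126, 0.176, 0.236, 0.366, 0.435),
              amps = c(0.5, -0.4, 1.715, -0.3, 0.8, -0.66, 0.5))
  v <- beatFeatures(f)
  expect_equal(unname(v["hi_amp_v"]), 0.9)
  expect_equal(unname(v["hi_slope_vps"]), -18.0)
  f2 <- fidSet(times = c(0, 0.05, 0.126, 0.176, 0.236, 0.366, 0.435),
               amps = c(0.5, -1.0, 1.715, -0.3, 0.8, -0.66, 0.5))
  v2 <- beatFeatures(f2)
  expect_equal(unname(v2["ij_amp_v"]), 2.715)
  expect_equal(unname(v2["ij_slope_vps"]), 2.715 / 0.076, tolerance = 1e-9)
  expect_error(fidSet(times = c(0, 0, 0.126, 0.176, 0.236, 0.366, 0.435),
                      amps = f@amps, quality = 0.9), "increasing")
})

test_that("sign flip of a beat keeps amplitudes and negates slopes", {
  tpl <- beatTemplate()
  f <- fidSet(tpl@times, tpl@amps)
  flipped <- new("FiducialSet", times = tpl@times, amps = -tpl@amps,
                 quality = 0.9)  # not a valid full-quality set; bypass check
  v <- beatFeatures(f)
  v2 <- beatFeatures(flipped)
  expect_equal(v2[4:6], v[4:6])
  expect_equal(v2[7:9], -v[7:9])
})

test_that("averaging identical beats reproduces any input beat", {
  seg <- templateSegment()
  avg <- dtwAverageBeat(list(seg, seg, seg, seg))
  ref_t <- sampleTimes(seg) - seg@jTime
  common <- sampleTimes(avg) >= ref_t[1] - 1e-9 &
    sampleTimes(avg) <= ref_t[length(ref_t)] + 1e-9
  expected <- stats::approx(ref_t, samples(seg), xout = sampleTimes(avg)[common])$y
  expect_lt(max(abs(samples(avg)[common] - expected)), 1e-9)
})

test_that("averaging recovers template timing from jittered beats", {
  tpl <- beatTemplate()
  err <- c()
  for (s in 1:50) {
    set.seed(s)
    segs <- lapply(1:16, function(i) {
      jt <- tpl@times + runif(7, -0.02, 0.02)
      jt <- sort(jt)
      jtpl <- try(beatTemplate(times = jt, amps = tpl@amps), silent = TRUE)
      if (inherits(jtpl, "try-error")) jtpl <- tpl
      templateSegment(jtpl)
    })
    avg <- dtwAverageBeat(segs)
    af <- detectFiducials(avg)
    if (quality(af) < 1) next
    err <- c(err, abs(af@times + tpl@times[["J"]] - tpl@times))
  }
  expect_gte(length(err), 40 * 7)
  expect_lt(mean(err), 0.005)
  expect_lt(stats::quantile(err, 0.9, names = FALSE), 0.012)
})

test_that("pre-filtered averaging ignores a VPB cluster", {
  tpl <- beatTemplate()
  vpb <- beatTemplate(amps = tpl@amps * 0.4)
  segs <- c(lapply(1:8, function(i) templateSegment(tpl)),
            lapply(1:4, function(i) templateSegment(vpb)))
  amp <- vapply(segs, function(s) max(samples(s)), numeric(1))
  keep <- segs[amp > 0.7 * max(amp)]  # VPBs pre-filtered on amplitude
  avg <- dtwAverageBeat(keep)
  expect_lt(abs(max(samples(avg)) - tpl@amps[["J"]]) / tpl@amps[["J"]], 0.02)
  expect_error(dtwAverageBeat(segs[1:2]), "averaging")
})

test_that("subject features recover the control template", {
  rec <- synthRecord(rhythmSpec(), beatTemplate(), 60, seed = 1)
  fv <- subjectFeatures(extractBcg(rec))
  expect_identical(attr(fv, "path"), "dtw_average")
  truth <- c(hi_interval_ms = 65, im_interval_ms = 310, mn_interval_ms = 69,
             hi_amp_v = 0.9, ij_amp_v = 2.715, mn_amp_v = 1.16,
             hi_slope_vps = -0.9 / 0.065, ij_slope_vps = 2.715 / 0.07,
             mn_slope_vps = 1.16 / 0.069)
  ## intervals and the ejection (IJ) features are tight; the small H/I and
  ## M/N excursions carry a few percent of band-limiting baseline shading
  for (nm in c("hi_interval_ms", "im_interval_ms", "mn_interval_ms"))
    expect_lt(abs(fv[[nm]] - truth[[nm]]), 2, label = nm)
  for (nm in c("ij_amp_v", "ij_slope_vps"))
    expect_lt(abs(fv[[nm]] - truth[[nm]]) / abs(truth[[nm]]), 0.05,
              label = nm)
  for (nm in c("hi_amp_v", "mn_amp_v", "hi_slope_vps", "mn_slope_vps"))
    expect_lt(abs(fv[[nm]] - truth[[nm]]) / abs(truth[[nm]]), 0.10,
              label = nm)
})

test_that("CHF subjects show longer IVCT and weaker ejection than controls", {
  ## the class distributions overlap, so the direction is asserted on the
  ## mean over a few seed-paired subjects (30-s records)
  one <- function(cl, s) {
    p <- sampleCohortRecordParams(cl, seed = s)
    subjectFeatures(extractBcg(synthRecord(p$rhythm, p$template, 30,
                                           seed = s)))
  }
  fc <- rowMeans(sapply(21:24, function(s) one("control", s)))
  fh <- rowMeans(sapply(21:24, function(s) one("chf", s)))
  expect_gt(fh[["hi_interval_ms"]], fc[["hi_interval_ms"]])
  expect_lt(fh[["ij_slope_vps"]], fc[["ij_slope_vps"]])
})

test_that("an 8-s minimal record still yields a feature vector", {
  rec <- synthRecord(rhythmSpec(respAmp = 2), beatTemplate(), 10, seed = 9)
  fv <- subjectFeatures(extractBcg(rec))
  expect_length(fv, 9)
  expect_true(all(is.finite(fv)))
})

test_that("features scale with gain and ignore the time origin", {
  rec <- synthRecord(rhythmSpec(), beatTemplate(), 30, seed = 8)
  bcg <- extractBcg(rec)
  fv <- subjectFeatures(bcg)
  g <- 2.5
  fv_g <- subjectFeatures(methods::initialize(bcg,
                                              samples = g * samples(bcg)))
  expect_equal(fv_g[1:3], fv[1:3], tolerance = 1e-6)
  expect_equal(unname(fv_g[4:9]), unname(g * fv[4:9]), tolerance = 1e-6)
  shifted <- methods::initialize(bcg, sampling = methods::initialize(
    bcg@sampling, t0 = 100))
  fv_s <- subjectFeatures(shifted)
  expect_equal(fv_s, fv, tolerance = 1e-6)
})

test_that("end-to-end recovery is faithful per subject and per class", {
  ## scaled-down recovery check: 6 subjects per class, 30-s records; the
  ## pipeline must track each subject's drawn parameters, and the drawn
  ## class means must sit near the published targets within sampling error
  tab_c <- c(65, 310, 69, 0.900, 2.715, 1.160)
  tab_h <- c(102, 260, 93, 1.286, 2.163, 1.405)
  for (cl in c("control", "chf")) {
    rec <- cohortRecoveryExperiment(cl, nSubjects = 6, duration = 30,
                                    seed = 77)
    drawn <- attr(rec, "drawn")
    ok <- !is.na(rec[, 1])
    expect_gte(sum(ok), 5)
    ## per-subject pipeline fidelity
    int_err <- abs(rec[ok, 1:3] - drawn[ok, 1:3])
    expect_lt(max(int_err), 6)  # ms
    amp_rel <- abs(rec[ok, 4:6] - drawn[ok, 4:6]) / abs(drawn[ok, 4:6])
    expect_lt(mean(amp_rel), 0.10)
    ## drawn class means near the published values (3 SE + truncation bias)
    tab <- if (cl == "control") tab_c else tab_h
    for (k in 1:6) {
      se <- sd(drawn[, k]) / sqrt(nrow(drawn))
      expect_lt(abs(mean(drawn[, k]) - tab[k]), 3 * se + 0.05 * tab[k])
    }
  }
})

test_that("agreement statistics match brute-force computation", {
  x <- c(3, 1, 4, 1.5, 5)
  y <- c(2.8, 1.2, 4.4, 1.4, 5.3)
  st <- agreementStats(x, y)
  expect_equal(unname(st["spearman_r"]),
               stats::cor(rank(x), rank(y)))  # rank oracle
  fit <- stats::lm(y ~ x)
  expect_equal(unname(st["r_squared"]), summary(fit)$r.squared)
  expect_equal(unname(st["median_abs_error"]), stats::median(abs(x - y)))
  expect_equal(unname(agreementStats(x, x)), c(1, 1, 0))
  expect_equal(unname(agreementStats(x, -x)["spearman_r"]), -1)
  expect_error(agreementStats(rep(1, 5), x), "constant")
})
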