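test_that("tachogram generation is deterministic and matches closed forms", {
  spec <- subjectSpec(nBeats = 500, seed = 42)
  a <- genTachogram(spec)
  b <- genTachogram(spec)
  expect_identical(a$rr_ms, b$rr_ms)
  # zero amplitudes, zero jitter: constant tachogram
  flat <- genTachogram(subjectSpec(lfAmpMs = 0, hfAmpMs = 0, jitterSdMs = 0,
                                   nBeats = 100, seed = 1))
  expect_equal(stats::sd(flat$rr_ms), 0)
  # successive-difference RMS of a pure HF modulation:
  # 2*A*|sin(pi*f*RR0/1000)|/sqrt(2)
  hf <- genTachogram(subjectSpec(lfAmpMs = 0, hfAmpMs = 40, hfHz = 0.25,
                                 jitterSdMs = 0, rr0Ms = 850,
                                 nBeats = 2000, seed = 2))
  pred <- 2 * 40 * sin(pi * 0.25 * 0.85) / sqrt(2)
  expect_equal(rmssd(hf$rr_ms), pred, tolerance = 0.02)
  # spectral peak at the modulation frequency within one grid step
  sp <- lombPsd(tachogramIntervals(hf))
  expect_lt(abs(sp$freq[which.max(sp$psd)] - 0.25), 0.0011)
})

test_that("PVC injection follows the coupling/compensatory formulas", {
  tach <- pvcTachogram(3, jitter = 0, rr0 = 800, coupling = 0.6, seed = 1)
  expect_equal(sum(beatLabels(tach$beats) == "V"), 3)
  for (ev in tach$hrtTruth) {
    expect_equal(ev$couplI_ms, 0.6 * 800)
    expect_equal(ev$compI_ms, 2 * 800 - 0.6 * 800)
  }
  # slope truth is recovered exactly by the turbulence slope on zero jitter
  tach2 <- pvcTachogram(1, jitter = 0, slope = 7, seed = 2, nBeats = 200)
  ev <- Filter(function(e) e$eligible, hrtEvents(tach2$beats))
  expect_length(ev, 1)
  expect_equal(hrtSlope(ev[[1]]), 7, tolerance = 1e-9)
})

test_that("coupled sBP truth gains are recoverable and G = 0 decouples", {
  spec <- subjectSpec(brsGain = 0, jitterSdMs = 5, nBeats = 800,
                      sbpProcess = "walk", seed = 3)
  tach <- genCoupledSbp(genTachogram(spec), spec)
  expect_lt(abs(cor(tach$rr_ms, tach$sbp_mmHg)), 0.1)
  # triangular ramp process: PRSA recovers G (unit rising runs; anchors
  # within two beats of a turning point contribute slight distortion)
  spec2 <- subjectSpec(brsGain = 10, jitterSdMs = 0, nBeats = 600,
                       sbpProcess = "ramp", seed = 4)
  tach2 <- genCoupledSbp(genTachogram(spec2), spec2)
  expect_equal(prsaBrs(tachogramIntervals(tach2))$brs, 10, tolerance = 0.05)
})

test_that("rendered waveforms preserve beat truth and PVC template
           properties", {
  wf <- renderedFixture(nBeats = 90, pvcCount = 2, seed = 5, fs = 250,
                        nLeads = 1)
  lead <- channelSignal(wf$record, 1)
  det <- detectRPeaks(lead, 250)
  truth <- beatTimes(wf$truth)
  offs <- vapply(truth, function(t) min(abs(beatTimes(det) - t)), numeric(1))
  expect_lt(max(offs), 0.010)
  # V beats are wide by construction: half-height width above 120 ms
  tt <- seq(-0.3, 0.3, by = 1 / 1000)
  v <- autonomiq:::ecgBeatTemplate(tt, isPvc = TRUE)
  hw <- 1000 * diff(range(tt[abs(v) >= 0.5 * max(abs(v))]))
  expect_gt(hw, 120)
  n <- autonomiq:::ecgBeatTemplate(tt, isPvc = FALSE)
  hwN <- 1000 * diff(range(tt[n >= 0.5 * max(n)]))
  expect_lt(hwN, 120)
})

test_that("corruption is a no-op at zero noise and honest about its mask", {
  wf <- renderedFixture(nBeats = 30, seed = 6, nLeads = 1)
  out <- corruptRecord(wf$record, list(), seed = 1)
  expect_identical(out$record@signals, wf$record@signals)
  expect_false(any(out$mask))
  noisy <- corruptRecord(wf$record, list(ECG1 = list(whiteSd = 0.5)),
                         seed = 2)
  expect_true(all(noisy$mask[, 1]))
  expect_false(any(noisy$mask[, 2]))
})

test_that("heavy corruption fails the ECG image classifier and flatline
           invalidates the spanning ABP pulse", {
  libs <- qualityLibs()
  wf <- renderedFixture(nBeats = 70, seed = 7, nLeads = 1)
  bad <- corruptRecord(wf$record,
                       list(ECG1 = list(whiteSd = 1.0)), seed = 3)$record
  img <- renderEcgImage(channelSignal(bad, 1), 125)
  expect_equal(classifyEcgQuality(img, libs$ecg)$quality, "poor")
  # flatline region: the pulse spanning it scores invalid
  flat <- corruptRecord(wf$record,
                        list(ABP = list(flatlineS = list(c(10, 25)))),
                        seed = 4)$record
  abp <- channelSignal(flat, "ABP")
  pk <- detectSystolicPeaks(abp, 125)
  on <- detectPulseOnsets(abp, 125, pk)
  pulses <- splitPulses(abp, 125, on)
  spans <- vapply(seq_along(pulses), function(i)
    on[i] < 25 && on[i + 1] > 10 && (on[i + 1] - on[i]) > 3, logical(1))
  expect_true(any(spans))
  for (i in which(spans))
    expect_false(scoreAbpPulse(pulses[[i]], libs$abp)$valid)
})

test_that("cohorts are deterministic with binomial truth prevalence", {
  a <- makeCohort(200, prevalence = 0.3, seed = 9)
  b <- makeCohort(200, prevalence = 0.3, seed = 9)
  expect_identical(a, b)
  expect_true(abs(sum(a$truth_ead) - 60) < 3 * sqrt(200 * 0.3 * 0.7))
  none <- makeCohort(50, prevalence = 0, seed = 10)
  expect_false(any(none$truth_ead))
  # spec-level cohorts carry per-subject generator specs
  sc <- makeCohort(5, prevalence = 0.5, seed = 11, level = "spec")
  expect_true(all(vapply(sc$spec, inherits, logical(1), "subjectSpec")))
})
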