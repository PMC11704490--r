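test_that("enhancement mask sums to zero and reproduces itself on an
           impulse", {
  m <- enhancementMask(k = 5)
  expect_equal(sum(m), 0)
  expect_length(m, 11)
  expect_equal(m[6], 10)
  # convolution with a centered unit impulse returns the (symmetric) mask
  x <- numeric(21); x[11] <- 1
  out <- autonomiq:::applyMask(x, m)
  expect_equal(out[6:16], rev(m))
  expect_equal(out[11], 10)
  # zero response to constant input away from the zero-padded edges
  resp <- autonomiq:::applyMask(rep(3, 30), m)
  expect_equal(resp[6:25], rep(0, 20), tolerance = 1e-12)
})

test_that("R-peak detection recovers generator truth within 10 ms", {
  # 5 min at 60 bpm: 300 +/- 1 beats
  spec <- subjectSpec(rr0Ms = 1000, lfAmpMs = 0, hfAmpMs = 0, jitterSdMs = 0,
                      nBeats = 300, seed = 1)
  wf <- renderWaveforms(genTachogram(spec), fsEcg = 250, nLeads = 1)
  det <- detectRPeaks(channelSignal(wf$record, 1), 250)
  truth <- beatTimes(wf$truth)
  expect_lte(abs(length(beatTimes(det)) - length(truth)), 1)
  offs <- vapply(truth, function(t) min(abs(beatTimes(det) - t)), numeric(1))
  expect_lt(max(offs), 0.010)
  expect_true(all(diff(beatTimes(det)) > 0.2))
  # flat signal: no beats
  expect_length(beatTimes(detectRPeaks(rep(0.1, 1000), 250)), 0)
  expect_error(detectRPeaks(rnorm(100), 50), "sampling rate")
})

test_that("R-peak sensitivity stays at least 0.99 across seeds at the default
           noise level", {
  sens <- vapply(0:9, function(s) {
    wf <- renderedFixture(nBeats = 90, seed = s, fs = 250, nLeads = 1)
    det <- detectRPeaks(channelSignal(wf$record, 1), 250)
    truth <- beatTimes(wf$truth)
    matched <- sum(vapply(truth, function(t)
      any(abs(beatTimes(det) - t) <= 0.05), logical(1)))
    matched / length(truth)
  }, numeric(1))
  expect_true(all(sens >= 0.99))
})

test_that("systolic peak detection counts pulses and tolerates mains noise", {
  # 60 s at 72 bpm
  spec <- subjectSpec(rr0Ms = 60000 / 72, lfAmpMs = 0, hfAmpMs = 0,
                      jitterSdMs = 0, nBeats = 73, seed = 2)
  wf <- renderWaveforms(genTachogram(spec), fsEcg = 125, nLeads = 1)
  abp <- channelSignal(wf$record, "ABP")[1:(60 * 125)]
  pk <- detectSystolicPeaks(abp, 125)
  expect_lte(abs(length(beatTimes(pk)) - 72), 1)
  # 50-Hz noise of 1 mmHg leaves the count unchanged
  tt <- seq_along(abp) / 125
  pk2 <- detectSystolicPeaks(abp + sin(2 * pi * 50 * tt), 125)
  expect_equal(length(beatTimes(pk2)), length(beatTimes(pk)))
  # constant pressure is non-pulsatile
  expect_length(beatTimes(detectSystolicPeaks(rep(90, 1000), 125)), 0)
})

test_that("pulse onsets pair one-to-one with peaks and precede them", {
  wf <- renderedFixture(nBeats = 40, seed = 3, nLeads = 1)
  abp <- channelSignal(wf$record, "ABP")
  pk <- detectSystolicPeaks(abp, 125)
  on <- detectPulseOnsets(abp, 125, pk)
  expect_length(on, length(beatTimes(pk)))
  expect_true(all(on <= beatTimes(pk)))
  # triangular pulses: the onset is the generator-truth foot within 2 samples
  fs <- 125
  feet <- seq(0.5, 29.5, by = 0.8)
  tt <- seq(0, 30, by = 1 / fs)
  tri <- 80 + vapply(tt, function(x) {
    d <- x - feet[feet <= x]
    if (!length(d)) 0 else {
      u <- min(d)
      40 * max(0, ifelse(u < 0.25, u / 0.25, 1 - (u - 0.25) / 0.55))
    }
  }, numeric(1))
  pkT <- detectSystolicPeaks(tri, fs)
  onT <- detectPulseOnsets(tri, fs, pkT)
  offs <- vapply(onT[-1], function(o) min(abs(feet - o)), numeric(1))
  expect_lte(max(offs), 2 / fs + 1e-9)
})

test_that("rendered systolic amplitude equals the requested sBP", {
  wf <- renderedFixture(nBeats = 40, seed = 8, nLeads = 1)
  abp <- channelSignal(wf$record, "ABP")
  t <- beatTimes(wf$tach$beats)
  sbp <- wf$sbp
  for (b in seq(5, 30, by = 5)) {
    idx <- which(seq_along(abp) / 125 >= t[b] &
                 seq_along(abp) / 125 < t[b + 1])
    expect_lt(abs(max(abp[idx]) - sbp[b]), 0.5)
  }
})

test_that("PVC detection labels exactly the injected ectopics", {
  for (s in c(0, 4, 9)) {
    wf <- renderedFixture(nBeats = 240, pvcCount = 5, seed = s, fs = 250,
                          nLeads = 1)
    lead <- channelSignal(wf$record, 1)
    det <- detectPvc(lead, 250, detectRPeaks(lead, 250))
    m <- detectionMetrics(det, wf$truth)
    expect_equal(m$TP, 5)
    expect_equal(m$FP, 0)
    expect_equal(m$FN, 0)
  }
})

test_that("PVC F1 stays at least 0.9 across seeds 0-9", {
  f1 <- vapply(0:9, function(s) {
    wf <- renderedFixture(nBeats = 150, pvcCount = 3, seed = s, fs = 250,
                          nLeads = 1)
    lead <- channelSignal(wf$record, 1)
    det <- detectPvc(lead, 250, detectRPeaks(lead, 250))
    detectionMetrics(det, wf$truth)$F1
  }, numeric(1))
  expect_true(all(f1 >= 0.9))
})

test_that("solitary normal-shaped candidates are demoted and labeling never
           creates beats", {
  wf <- renderedFixture(nBeats = 120, pvcCount = 0, seed = 5, fs = 250,
                        nLeads = 1)
  lead <- channelSignal(wf$record, 1)
  beats <- detectRPeaks(lead, 250)
  det <- detectPvc(lead, 250, beats)
  expect_equal(sum(beatLabels(det) == "V"), 0)
  expect_equal(beatTimes(det), beatTimes(beats))
  # too few beats for a template: all labels X
  few <- beatSeries(beatTimes(beats)[1:5], rep("X", 5))
  expect_true(all(beatLabels(detectPvc(lead, 250, few)) == "X"))
})

test_that("detection metrics match the confusion-matrix arithmetic", {
  pred <- rep(c("V", "N"), c(9, 91))
  truth <- c(rep("V", 8), "N", rep("V", 2), rep("N", 89))
  m <- detectionMetrics(pred, truth)
  expect_equal(m$TP, 8); expect_equal(m$FN, 2)
  expect_equal(m$FP, 1); expect_equal(m$TN, 89)
  expect_equal(m$Sen, 0.8)
  expect_equal(m$F1, 16 / 19)
  # perfect prediction
  p <- detectionMetrics(truth, truth)
  expect_equal(c(p$Sen, p$Spec, p$Acc, p$F1), rep(1, 4))
  # all-negative prediction on mixed truth
  expect_equal(detectionMetrics(rep("N", length(truth)), truth)$Sen, 0)
})
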