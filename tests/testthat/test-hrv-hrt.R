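test_that("RMSSD matches closed forms and is shift-invariant", {
  expect_equal(rmssd(c(800, 800, 800)), 0)
  expect_equal(rmssd(c(800, 850, 800)), 50)       # sqrt((50^2 + 50^2)/2)
  set.seed(1)
  v <- 800 + rnorm(100, sd = 20)
  expect_equal(rmssd(v), rmssd(v + 123))
  expect_true(is.na(rmssd(c(800, 810))))          # missing, not 0
})

test_that("RMSSD skips differences across ectopy gaps", {
  # beats N N N V N N N: RR gap where the PVC pair was dropped
  b <- beatSeries(c(0, 0.8, 1.6, 2.2, 3.2, 4.0, 4.8),
                  labels = c("N", "N", "N", "V", "N", "N", "N"))
  rr <- deriveIntervals(b)
  expect_equal(intervalValues(rr), c(800, 800, 800, 800))
  # the 800-800 difference across the gap (beats 3 -> 5) must not be formed:
  # differences only within the two contiguous runs
  expect_equal(rmssd(rr), 0)
  # contrast: a jump across the gap would register without adjacency logic
  b2 <- beatSeries(c(0, 0.8, 1.6, 2.2, 3.2, 4.1, 5.0),
                   labels = c("N", "N", "N", "V", "N", "N", "N"))
  rr2 <- deriveIntervals(b2)
  expect_equal(intervalValues(rr2), c(800, 800, 900, 900))
  expect_equal(rmssd(rr2), 0)                     # 800->900 spans the gap
})

test_that("Lomb PSD localizes pure modulations and separates LF/HF regimes", {
  mkSeries <- function(f, n = 400, rr0 = 850, amp = 40) {
    t <- numeric(n + 1)
    rr <- numeric(n)
    for (k in seq_len(n)) {
      rr[k] <- rr0 + amp * sin(2 * pi * f * t[k])
      t[k + 1] <- t[k] + rr[k] / 1000
    }
    intervalSeries(t[-1], rr)
  }
  hf <- lombPsd(mkSeries(0.25))
  expect_lt(abs(hf$freq[which.max(hf$psd)] - 0.25), 0.0011)
  expect_gt(hf$hf_power, 10 * hf$lf_power)
  expect_lt(hf$lf_hf, 0.2)
  lf <- lombPsd(mkSeries(0.10))
  expect_lt(abs(lf$freq[which.max(lf$psd)] - 0.10), 0.0011)
  expect_gt(lf$lf_hf, 5)
  # constant series: negligible band power
  const <- lombPsd(intervalSeries(seq(0.85, by = 0.85, length.out = 100),
                                  rep(850, 100)))
  expect_lt(const$lf_power + const$hf_power, 1e-6)
  expect_true(is.na(const$lf_hf))                 # HF below the floor
})

test_that("total Lomb band power approximates the variance of a broadband
           near-uniform series", {
  set.seed(2)
  n <- 600
  rr <- 850 + rnorm(n, sd = 30)
  t <- cumsum(rr) / 1000
  # integrate to the Nyquist rate of the mean beat period so the flat
  # spectrum's full support is covered
  sp <- lombPsd(intervalSeries(t, rr), fmax = 1 / (2 * mean(rr) / 1000))
  expect_lt(abs(sp$total_power - var(rr)) / var(rr), 0.15)
})

test_that("Lomb preconditions produce missing results with reasons", {
  short <- intervalSeries(seq(0.85, by = 0.85, length.out = 20),
                          rep(850, 20))
  expect_true(is.na(lombPsd(short)$lf_power))
})

test_that("turbulence onset follows the quarter-interval formula", {
  ev <- function(rr1, rr2, pre = c(800, 800))
    list(eligible = TRUE, pre_ms = pre, post_ms = c(rr1, rr2, rep(800, 13)))
  expect_equal(hrtOnset(ev(800, 800)), 0)
  expect_equal(hrtOnset(ev(760, 760)), -5)        # (1520-1600)/1600 * 100
  expect_equal(hrtOnset(ev(840, 840)), 5)
  expect_true(is.na(hrtOnset(list(eligible = FALSE))))
})

test_that("turbulence slope is the maximum 5-beat regression slope", {
  mk <- function(post) list(eligible = TRUE, pre_ms = c(800, 800),
                            post_ms = post)
  expect_equal(hrtSlope(mk(800 + 10 * (1:15))), 10)
  expect_equal(hrtSlope(mk(rep(800, 15))), 0)
  expect_equal(hrtSlope(mk(800 - 5 * (1:15))), -5)  # all windows negative
  expect_true(is.na(hrtSlope(list(eligible = FALSE))))
})

test_that("TO is scale-invariant and TS scales linearly with the RR scale", {
  tach <- pvcTachogram(12, jitter = 2, seed = 3)
  ev <- Filter(function(e) e$eligible, hrtEvents(tach$beats))
  scale <- function(e, c) {
    e$pre_ms <- c * e$pre_ms; e$post_ms <- c * e$post_ms
    e$couplI_ms <- c * e$couplI_ms; e$compI_ms <- c * e$compI_ms
    e
  }
  for (e in ev[1:3]) {
    expect_equal(hrtOnset(scale(e, 2)), hrtOnset(e))
    expect_equal(hrtSlope(scale(e, 2)), 2 * hrtSlope(e))
  }
})

test_that("HRT event eligibility enforces the pre/post context rules", {
  # exactly 15 post intervals: eligible; fewer: not
  expect_true(hrtEvents(singlePvcBeats(15))[[1]]$eligible)
  expect_false(hrtEvents(singlePvcBeats(14))[[1]]$eligible)
  ok <- hrtEvents(singlePvcBeats(15))[[1]]
  expect_lt(ok$couplI_ms, 800)
  expect_gt(ok$compI_ms, 800)
  # a non-premature "coupling" interval disqualifies the event
  b <- singlePvcBeats(15, coupling = 0.6)
  t <- beatTimes(b)
  t[5] <- t[4] + 0.9                     # longer than the preceding RR
  bad <- beatSeries(t, beatLabels(b))
  expect_false(hrtEvents(bad)[[1]]$eligible)
})

test_that("segment HRT applies the >10 PVC gate and the eligibility filter", {
  # 10 PVCs: skipped; 11: computed
  expect_true(segmentHrt(pvcTachogram(10, seed = 4)$beats)$skipped)
  h11 <- segmentHrt(pvcTachogram(11, seed = 4)$beats)
  expect_false(h11$skipped)
  expect_equal(h11$n_events, 11)
  # identical responses: mean equals the per-event value
  expect_equal(h11$ts_ms_per_beat, 8, tolerance = 1e-6)
  # events lacking 15 post intervals are excluded from the means
  tach <- pvcTachogram(12, seed = 5)
  lab <- beatLabels(tach$beats)
  t <- beatTimes(tach$beats)
  sites <- which(lab == "V")
  for (p in sites[1:4]) lab[p + 8] <- "X"      # break the post context
  h <- segmentHrt(beatSeries(t, lab))
  expect_equal(h$n_pvc, 12)
  expect_equal(h$n_events, 8)
})

test_that("PRV equals HRV on identical interval input", {
  tach <- genTachogram(subjectSpec(nBeats = 300, seed = 6))
  rr <- tachogramIntervals(tach)
  ppi <- intervalSeries(intervalTimes(rr), intervalValues(rr), kind = "PPI")
  expect_equal(rmssd(ppi), rmssd(rr))
  expect_equal(lombPsd(ppi)$lf_hf, lombPsd(rr)$lf_hf)
})
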