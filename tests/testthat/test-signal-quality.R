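test_that("SSIM satisfies identity, symmetry, bounds and the constant-image
           closed form", {
  set.seed(1)
  x <- matrix(runif(400), 20)
  y <- matrix(runif(400), 20)
  expect_equal(ssimIndex(x, x), 1)
  expect_equal(ssimIndex(x, y), ssimIndex(y, x))
  expect_true(abs(ssimIndex(x, y)) <= 1)
  # constant images: variance terms vanish, luminance term remains
  C1 <- (0.01 * 1)^2
  expect_equal(ssimIndex(matrix(2, 5, 5), matrix(4, 5, 5)),
               (2 * 2 * 4 + C1) / (4 + 16 + C1))
  expect_error(ssimIndex(matrix(0, 2, 2), matrix(0, 3, 3)), "dimensions")
})

test_that("ECG image rendering is deterministic and geometry scales with
           amplitude", {
  set.seed(2)
  fs <- 125
  x <- 0.8 * sin(2 * pi * seq(0, 10, by = 1 / fs))
  a <- renderEcgImage(x, fs)
  b <- renderEcgImage(x, fs)
  expect_identical(a@pixels, b@pixels)
  # zero signal draws grid plus a flat center trace only
  flat <- renderEcgImage(numeric(10 * fs), fs)
  traceRows <- unique(which(flat@pixels == 1, arr.ind = TRUE)[, 1])
  expect_length(traceRows, 1)
  # doubling amplitude doubles the trace's vertical extent (within clipping)
  extent <- function(im) {
    r <- which(im@pixels == 1, arr.ind = TRUE)[, 1]
    diff(range(r))
  }
  half <- renderEcgImage(0.4 * sin(2 * pi * seq(0, 10, by = 1 / fs)), fs)
  expect_equal(extent(a) / extent(half), 2, tolerance = 0.05)
  expect_error(renderEcgImage(matrix(numeric(0), 0, 1), fs), "empty")
})

test_that("cluster representative maximizes mean within-cluster SSIM", {
  # cluster {A, A, B} with S(A,B) = 0.5: A wins (0.833 vs 0.667)
  sim <- rbind(c(1, 1, 0.5), c(1, 1, 0.5), c(0.5, 0.5, 1))
  expect_equal(clusterRepresentative(sim), 1)
  # identical members tie; lowest index wins
  expect_equal(clusterRepresentative(matrix(1, 2, 2)), 1)
})

test_that("template classifier separates clean from corrupted images", {
  libs <- qualityLibs()
  # held-out images, not used in training
  correct <- 0; n <- 0
  for (s in 201:206) {
    spec <- subjectSpec(rr0Ms = 760 + 30 * (s - 200), jitterSdMs = 4,
                        nBeats = 18, seed = s)
    wf <- renderWaveforms(genTachogram(spec), fsEcg = 125, nLeads = 1)
    lead <- channelSignal(wf$record, 1)
    cls <- classifyEcgQuality(renderEcgImage(lead, 125), libs$ecg)
    correct <- correct + (cls$quality == "good"); n <- n + 1
    set.seed(s)
    noisy <- lead * 0.1 + rnorm(length(lead), sd = 0.6)
    cls2 <- classifyEcgQuality(renderEcgImage(noisy, 125), libs$ecg)
    correct <- correct + (cls2$quality == "poor"); n <- n + 1
  }
  expect_gte(correct / n, 0.95)
  # a training template classifies into its own group
  tpl <- libs$ecg@templates[[1]]
  expect_equal(classifyEcgQuality(tpl, libs$ecg)$quality,
               libs$ecg@groups[1])
})

test_that("unsupervised 2-means split recovers the good/poor partition", {
  imgs <- list(); truth <- character()
  for (s in 1:3) {
    spec <- subjectSpec(rr0Ms = 800 + 40 * s, jitterSdMs = 4, nBeats = 18,
                        seed = 300 + s)
    lead <- channelSignal(renderWaveforms(genTachogram(spec), fsEcg = 125,
                                          nLeads = 1)$record, 1)
    imgs <- c(imgs, list(renderEcgImage(lead, 125)))
    truth <- c(truth, "good")
    set.seed(300 + s)
    imgs <- c(imgs, list(renderEcgImage(rnorm(length(lead)), 125)))
    truth <- c(truth, "poor")
  }
  lib <- buildTemplates(imgs, groups = NULL, nClusters = 2, seed = 5)
  preds <- vapply(imgs, function(im)
    classifyEcgQuality(im, lib)$quality, character(1))
  expect_equal(preds, truth)
})

test_that("SQIs behave as designed on clean signal and noise", {
  fs <- 250
  spec <- subjectSpec(nBeats = 30, jitterSdMs = 4, seed = 4)
  lead <- channelSignal(renderWaveforms(genTachogram(spec), fsEcg = fs,
                                        nLeads = 1)$record, 1)
  clean <- computeSqis(lead, fs)
  expect_gte(clean$bSQI, 0.95)
  set.seed(5)
  noise <- computeSqis(rnorm(length(lead)), fs)
  expect_lt(noise$sSQI, clean$sSQI)
  # Gaussian noise has near-zero excess kurtosis; QRS signal is leptokurtic
  expect_lt(abs(noise$kSQI), 0.5)
  expect_gt(clean$kSQI, 3)
  # all-constant signal: bSQI defined as 0
  expect_equal(computeSqis(rep(1, fs * 12), fs)$bSQI, 0)
  expect_true(clean$bSQI >= 0 && clean$bSQI <= 1)
  expect_true(noise$sSQI >= 0 && noise$sSQI <= 1)
})

test_that("composite SQI selects the clean lead with deterministic
           tie-breaks", {
  fs <- 250
  spec <- subjectSpec(nBeats = 30, jitterSdMs = 4, seed = 6)
  lead <- channelSignal(renderWaveforms(genTachogram(spec), fsEcg = fs,
                                        nLeads = 1)$record, 1)
  set.seed(7)
  sqis <- list(computeSqis(rnorm(length(lead)), fs),
               computeSqis(lead, fs),
               computeSqis(lead * 0.2 + rnorm(length(lead), sd = 0.4), fs))
  expect_equal(selectBestLead(sqis), 2)
  # identical leads tie; lowest index wins
  s1 <- computeSqis(lead, fs)
  expect_equal(selectBestLead(list(s1, s1)), 1)
  expect_equal(selectBestLead(list(s1)), 1)
})

test_that("ABP subspace model is orthonormal, energy-splitting and tau is the
           library minimum", {
  lib <- syntheticAbpLibrary(n = 60, seed = 9)
  model <- fitAbpSubspace(lib)
  # orthonormal basis
  G <- crossprod(model@basis)
  expect_equal(G, diag(model@k), tolerance = 1e-10, ignore_attr = TRUE)
  # projection energies sum to total energy
  x <- normalizePulse(lib[[3]])
  proj <- model@basis %*% crossprod(model@basis, x)
  expect_equal(sum(proj^2) + sum((x - proj)^2), sum(x^2))
  # every reference pulse valid (tau is their minimum)
  ratios <- vapply(lib, function(p) scoreAbpPulse(p, model)$ratio, numeric(1))
  expect_true(all(ratios >= model@tau))
  expect_equal(min(ratios), model@tau)
})

test_that("rank-1 pulse libraries give a rank-1 signal subspace and exact
           subspace membership caps the ratio", {
  base <- sin(seq(0, pi, length.out = 80))^2
  lib <- lapply(seq(0.5, 2, length.out = 12), function(a) a * base)
  model <- fitAbpSubspace(lib)
  expect_equal(model@k, 1)
  sc <- scoreAbpPulse(1.7 * base, model)
  expect_true(sc$valid)
  expect_gte(sc$ratio, 1e12)
})

test_that("noise monotonically degrades the subspace ratio in expectation", {
  lib <- syntheticAbpLibrary(n = 60, seed = 10)
  model <- fitAbpSubspace(lib)
  pulse <- lib[[1]]
  meanRatio <- function(sd) {
    mean(vapply(1:20, function(i) {
      set.seed(i)
      scoreAbpPulse(pulse + rnorm(length(pulse), sd = sd), model)$ratio
    }, numeric(1)))
  }
  r <- c(meanRatio(0.5), meanRatio(2), meanRatio(8))
  expect_true(all(diff(r) < 0))
  # white-noise pulses are invalid
  set.seed(11)
  expect_false(scoreAbpPulse(rnorm(100), model)$valid)
})

test_that("quality gate passes only the clean/clean cell of the 2x2 design", {
  libs <- qualityLibs()
  cfg <- defaultConfig()
  wf <- renderedFixture(nBeats = 70, seed = 21)
  corruptEcg <- function(rec) corruptRecord(rec, list(
    ECG1 = list(whiteSd = 0.9), ECG2 = list(whiteSd = 0.9)), seed = 1)$record
  corruptAbp <- function(rec) corruptRecord(rec, list(
    ABP = list(whiteSd = 18)), seed = 2)$record
  expect_true(gateSegment(wf$record, libs, cfg)$pass)
  expect_false(gateSegment(corruptEcg(wf$record), libs, cfg)$pass)
  expect_false(gateSegment(corruptAbp(wf$record), libs, cfg)$pass)
  expect_false(gateSegment(corruptAbp(corruptEcg(wf$record)), libs, cfg)$pass)
  # ABP-only mode skips the ECG criterion
  cfgA <- defaultConfig(mode = "abp-only")
  expect_true(gateSegment(corruptEcg(wf$record), libs, cfgA)$pass)
})

test_that("template library archives round-trip through JSON", {
  libs <- qualityLibs()
  path <- file.path(tempdir(), "lib.json")
  saveTemplateLibrary(libs$ecg, path)
  back <- loadTemplateLibrary(path)
  spec <- subjectSpec(nBeats = 16, seed = 77)
  lead <- channelSignal(renderWaveforms(genTachogram(spec), fsEcg = 125,
                                        nLeads = 1)$record, 1)
  img <- renderEcgImage(lead, 125)
  expect_equal(classifyEcgQuality(img, back)$quality,
               classifyEcgQuality(img, libs$ecg)$quality)
})
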