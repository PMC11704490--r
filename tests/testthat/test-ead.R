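test_that("z-standardization and the abnormality flag follow the 2.5-SD
           exclusive boundary", {
  expect_equal(standardizeIndex(47, list(mean = 47, sd = 14)), 0)
  expect_equal(standardizeIndex(47 + 28, list(mean = 47, sd = 14)), 2)
  expect_equal(standardizeIndex(10, list(mean = 47, sd = 14)), -37 / 14)
  expect_true(flagAbnormal(2.6))
  expect_true(flagAbnormal(-2.6))
  expect_false(flagAbnormal(2.5))          # strict boundary
  expect_false(flagAbnormal(-2.5))
  expect_false(flagAbnormal(NA))
})

test_that("the packaged reference table is complete and well-formed", {
  rr <- defaultReferenceRanges()
  expect_s3_class(rr, "referenceRanges")
  expect_true(all(rr$sd > 0))
  st <- lookupStratum(rr, 34, "F", "rmssd")
  expect_equal(st$mean, 47)
  expect_equal(st$sd, 14)
  # out-of-table age falls back to the nearest bin
  expect_equal(lookupStratum(rr, 95, "M", "brs"),
               lookupStratum(rr, 85, "M", "brs"))
})

test_that("subject aggregation takes the median across passing segments and
           reports missing indices", {
  seg <- data.frame(start_s = c(0, 3600, 7200), quality_pass = TRUE,
                    rmssd = c(20, 30, 40), hrt_ts = NA_real_,
                    brs = c(8, 9, 10), lf_power = c(500, 600, 700),
                    lf_hf = c(1, 2, 3), to_pct = c(-1, 0, 1))
  agg <- aggregateSubject(seg)
  expect_equal(agg$values[["rmssd"]], 30)
  expect_true(is.na(agg$values[["hrt_ts"]]))
  expect_equal(agg$n_segments, 3)
  # single segment: its values
  one <- aggregateSubject(seg[1, ])
  expect_equal(one$values[["rmssd"]], 20)
  # zero passing segments: unclassifiable
  seg$quality_pass <- FALSE
  expect_null(aggregateSubject(seg)$values)
})

test_that("a missing index counts as non-abnormal in the composite rule", {
  vals <- c(rmssd = 47, hrt_ts = NA_real_, brs = 19.47, lf_power = 1170,
            lf_hf = 2.8)
  prof <- indexProfile(vals, 40, "F")
  expect_false(prof$abnormal[prof$index == "hrt_ts"])
  expect_equal(characterizeEad(prof)$abnormal_count, 0)
  # all missing: count 0, not classified
  allNa <- indexProfile(stats::setNames(rep(NA_real_, 5), eadIndices()),
                        40, "F")
  res <- characterizeEad(allNa)
  expect_equal(res$abnormal_count, 0)
  expect_false(res$classified)
})

test_that("classification switches exactly once at 3 displaced indices", {
  rr <- defaultReferenceRanges()
  classifiedAt <- vapply(0:5, function(k) {
    vals <- vapply(eadIndices(), function(ix) {
      st <- lookupStratum(rr, 50, "F", ix)
      st$mean
    }, numeric(1))
    for (ix in eadIndices()[seq_len(k)]) {
      st <- lookupStratum(rr, 50, "F", ix)
      vals[ix] <- st$mean - 4 * st$sd
    }
    characterizeEad(indexProfile(vals, 50, "F", rr))$classified
  }, logical(1))
  expect_equal(classifiedAt, c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))
  expect_equal(sum(diff(classifiedAt) != 0), 1)
})

test_that("classification depends only on z-scores (monotone relabeling
           invariance)", {
  rr <- defaultReferenceRanges()
  vals <- c(rmssd = 5, hrt_ts = 0.1, brs = 1, lf_power = 1170, lf_hf = 2.8)
  prof <- indexProfile(vals, 50, "F", rr)
  res <- characterizeEad(prof)
  # rebuilding from a transformed table with identical z-scores is identical
  res2 <- characterizeEad(prof[sample(nrow(prof)), ])
  expect_equal(res2$abnormal_count, res$abnormal_count)
  expect_equal(res2$classified, res$classified)
})

test_that("planted-cohort recovery reaches 0.9 sensitivity and specificity", {
  co <- makeCohort(200, prevalence = 0.3, effectSd = 4, nDisplaced = 4,
                   seed = 1)
  out <- runCohort(co)
  pred <- out$subjects$classified
  truth <- co$truth_ead
  sens <- sum(pred & truth) / sum(truth)
  spec <- sum(!pred & !truth) / sum(!truth)
  expect_gte(sens, 0.9)
  expect_gte(spec, 0.9)
  # incidence table reconciles with per-subject rows
  expect_equal(out$incidence$incidence[out$incidence$index == "ead"],
               mean(pred))
})

test_that("daily trajectories bin segments into 24-h days and mark empty
           days missing", {
  seg <- data.frame(start_s = c(0, 3600, 86400 * 2, 86400 * 2 + 3600),
                    quality_pass = TRUE,
                    rmssd = c(30, 34, 20, 22), hrt_ts = c(5, 6, 2, 2.4),
                    brs = c(10, 11, 5, 6), lf_power = c(600, 620, 300, 320),
                    lf_hf = c(2, 2.1, 1, 1.2))
  days <- dailyTrajectory(seg, days = 5)
  expect_length(days, 5)
  expect_equal(days[[1]]$values[["rmssd"]], 32)
  expect_null(days[[2]]$values)               # no segments on day 2
  expect_equal(days[[3]]$values[["rmssd"]], 21)
})

test_that("a synthetic day-3 deterioration raises day-3 abnormal counts over
           day 1", {
  rr <- defaultReferenceRanges()
  worse <- 0
  for (s in 1:10) {
    set.seed(s)
    mk <- function(shiftSd) {
      vals <- vapply(eadIndices(), function(ix) {
        st <- lookupStratum(rr, 50, "F", ix)
        stats::rnorm(1, st$mean - shiftSd * st$sd, 0.2 * st$sd)
      }, numeric(1))
      characterizeEad(indexProfile(vals, 50, "F", rr))$abnormal_count
    }
    worse <- worse + (mk(4) > mk(0))          # day 3 displaced vs day 1
  }
  expect_gte(worse, 9)
})
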