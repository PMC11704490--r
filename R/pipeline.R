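#' Default pipeline configuration
#'
#' All tunables of the analysis pipeline in one nested list, with defaults
#' matching the printed method parameters (0.5-17 Hz QRS band-pass, 0.3 s
#' search range, 0.24 s R-peak interval, 2-s windows, LF 0.04-0.15 Hz,
#' HF 0.15-0.4 Hz, PRSA L = 15, HRT gate of more than 10 PVCs, 2.5 SD
#' abnormality threshold, 3-of-5 composite rule). Override any entry via
#' `...` or a YAML file through [readConfig()].
#'
#' @param ... named overrides, e.g. `segment_length_s = 600`.
#' @return Nested configuration list.
#' @export
defaultConfig <- function(...) {
  cfg <- list(
    segment_length_s = 3600,
    allow_partial = FALSE,
    mode = "ecg+abp",                 # or "abp-only"
    quality = list(enabled = TRUE, abp_valid_fraction = 0.8,
                   pulse_resample = 100, energy_fraction = 0.95,
                   n_clusters = 3, image_seconds = 10),
    detector = list(mask_k = NULL, search_s = 0.3, peak_s = 0.24,
                    threshold = 0.5, refractory_s = 0.2),
    pvc = list(width_ms = 120, amp_factor = 1.5, corr_min = 0.9),
    hrt = list(min_pvc = 10, n_post = 15, strict = FALSE),
    bands = list(lf = c(0.04, 0.15), hf = c(0.15, 0.4)),
    prsa = list(L = 15, align_tol_s = 0.5),
    arx = list(order = 8, alpha_sqrt = TRUE),
    ead = list(threshold = 2.5, min_count = 3, aggregate = "median",
               reference_path = NULL),
    seed = 1)
  modifyList(cfg, list(...))
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys raise an error; known keys override [defaultConfig()].
#'
#' @param path YAML file path.
#' @return Configuration list.
#' @export
readConfig <- function(path) {
  user <- yaml::read_yaml(path)
  base <- defaultConfig()
  unknown <- setdiff(names(user), names(base))
  if (length(unknown))
    stopWith("autonomiq_config_error",
             sprintf("unknown configuration keys: %s",
                     paste(unknown, collapse = ", ")))
  modifyList(base, user)
}

#' Build default quality-gate models
#'
#' Constructs the packaged synthetic ECG template library (clean renders vs
#' noise-corrupted renders) and the synthetic-reference ABP subspace model.
#' Both are synthetic stand-ins; study-specific libraries plug in through
#' [buildTemplates()] and [fitAbpSubspace()].
#'
#' @param seed RNG seed.
#' @param config pipeline configuration (quality section used).
#' @return List with `ecg` (a [TemplateLibrary-class]) and `abp` (an
#'   [AbpSubspaceModel-class]).
#' @export
defaultQualityLibraries <- function(seed = 1, config = defaultConfig()) {
  imgs <- list(); groups <- character()
  fs <- 125
  for (i in 1:6) {
    spec <- subjectSpec(rr0Ms = 700 + 60 * i, jitterSdMs = 4, nBeats = 20,
                        seed = seed * 100 + i)
    wf <- renderWaveforms(genTachogram(spec), fsEcg = fs, nLeads = 1)
    lead <- channelSignal(wf$record, 1)
    cfgImg <- ecgImageConfig(seconds = config$quality$image_seconds)
    imgs <- c(imgs, list(renderEcgImage(lead, fs, cfgImg)))
    groups <- c(groups, "good")
    set.seed(seed * 100 + i)
    noisy <- if (i %% 2 == 0) stats::rnorm(length(lead), sd = 0.8)
             else lead * 0.05 + stats::rnorm(length(lead), sd = 0.5)
    imgs <- c(imgs, list(renderEcgImage(noisy, fs, cfgImg)))
    groups <- c(groups, "poor")
  }
  ecgLib <- buildTemplates(imgs, groups, nClusters = config$quality$n_clusters,
                           seed = seed)
  abpModel <- fitAbpSubspace(syntheticAbpLibrary(seed = seed + 7),
                             P = config$quality$pulse_resample,
                             energyFraction = config$quality$energy_fraction)
  list(ecg = ecgLib, abp = abpModel)
}

#' Quality-gate one segment
#'
#' A segment passes when its rendered multi-lead ECG image is classified
#' `good` and the fraction of subspace-valid ABP pulses reaches the
#' configured minimum (default 0.8). In ABP-only mode the ECG criterion is
#' skipped.
#'
#' @param segRecord a [WaveformRecord-class] covering one segment.
#' @param libraries from [defaultQualityLibraries()].
#' @param config pipeline configuration.
#' @return List (QualityReport) with `pass`, `ecg_quality`, `ecg_score`,
#'   `abp_valid_fraction`, `n_pulses`, `mode`.
#' @export
gateSegment <- function(segRecord, libraries, config = defaultConfig()) {
  mode <- config$mode
  fs <- sampleRate(segRecord)
  ecgCols <- which(channelRoles(segRecord) == "ecg")
  abpCols <- which(channelRoles(segRecord) == "abp")
  ecgQ <- NA_character_; ecgScore <- NA_real_
  if (mode != "abp-only" && length(ecgCols)) {
    img <- renderEcgImage(segRecord@signals[, ecgCols, drop = FALSE], fs,
                          ecgImageConfig(seconds = config$quality$image_seconds))
    cls <- classifyEcgQuality(img, libraries$ecg)
    ecgQ <- cls$quality; ecgScore <- cls$score
  }
  abpFrac <- NA_real_; nPulses <- 0L
  if (length(abpCols)) {
    abp <- segRecord@signals[, abpCols[1]]
    peaks <- detectSystolicPeaks(abp, fs)
    if (length(beatTimes(peaks)) >= 3) {
      onsets <- detectPulseOnsets(abp, fs, peaks)
      pulses <- splitPulses(abp, fs, onsets)
      pulses <- Filter(function(p) length(p) >= 3, pulses)
      if (length(pulses)) {
        valid <- vapply(pulses, function(p)
          scoreAbpPulse(p, libraries$abp)$valid, logical(1))
        abpFrac <- mean(valid); nPulses <- length(pulses)
      } else abpFrac <- 0
    } else abpFrac <- 0
  }
  pass <- (mode == "abp-only" || identical(ecgQ, "good")) &&
    (!length(abpCols) || (is.finite(abpFrac) &&
                          abpFrac >= config$quality$abp_valid_fraction))
  list(pass = pass, ecg_quality = ecgQ, ecg_score = ecgScore,
       abp_valid_fraction = abpFrac, n_pulses = nPulses, mode = mode)
}

# analyse one quality-passing segment; returns a one-row data.frame
analyseSegment <- function(segRecord, startS, libraries, config) {
  fs <- sampleRate(segRecord)
  mode <- config$mode
  row <- data.frame(start_s = startS, quality_pass = TRUE,
                    rmssd = NA_real_, lf_power = NA_real_, hf_power = NA_real_,
                    lf_hf = NA_real_, hrt_ts = NA_real_, to_pct = NA_real_,
                    brs = NA_real_, alpha_lf = NA_real_, n_pvc = NA_integer_,
                    n_beats = NA_integer_, flags = "")
  flags <- character()
  abpCols <- which(channelRoles(segRecord) == "abp")
  abpBeats <- NULL
  if (length(abpCols)) {
    abp <- segRecord@signals[, abpCols[1]]
    abpBeats <- detectSystolicPeaks(abp, fs)
    abpBeats <- beatSeries(beatTimes(abpBeats) + startS,
                           beatLabels(abpBeats), "abp", beatSbp(abpBeats))
  }
  if (mode == "abp-only") {
    if (is.null(abpBeats) || length(beatTimes(abpBeats)) < 3)
      return(transform(row, flags = "no ABP beats"))
    ppi <- deriveIntervals(abpBeats, kind = "PPI")
    row$n_beats <- length(beatTimes(abpBeats))
    row$n_pvc <- NA_integer_            # HRT structurally missing without ECG
    flags <- c(flags, "HRT unavailable in ABP-only mode")
    row$rmssd <- rmssd(ppi)
    sp <- lombPsd(ppi, lfBand = config$bands$lf, hfBand = config$bands$hf)
    row$lf_power <- sp$lf_power; row$hf_power <- sp$hf_power
    row$lf_hf <- sp$lf_hf
    paired <- intervalSeries(intervalTimes(ppi), intervalValues(ppi),
                             kind = "PPI", sbp = pairedSbp(ppi))
    pr <- prsaBrs(paired, L = config$prsa$L)
    row$brs <- pr$brs
    if (sum(is.finite(pairedSbp(ppi))) >= 10 * config$arx$order) {
      ax <- tryCatch(arxBrs(intervalValues(ppi), pairedSbp(ppi),
                            order = config$arx$order,
                            lfBand = config$bands$lf),
                     error = function(e) NULL)
      if (!is.null(ax)) row$alpha_lf <- ax$alpha_lf
    }
  } else {
    ecgCols <- which(channelRoles(segRecord) == "ecg")
    sqis <- lapply(ecgCols, function(j)
      computeSqis(segRecord@signals[, j], fs))
    best <- ecgCols[selectBestLead(sqis)]
    lead <- segRecord@signals[, best]
    beats <- detectRPeaks(lead, fs,
                          maskK = config$detector$mask_k,
                          searchS = config$detector$search_s,
                          peakS = config$detector$peak_s,
                          threshold = config$detector$threshold,
                          refractoryS = config$detector$refractory_s)
    if (length(beatTimes(beats)) < 3)
      return(transform(row, flags = "no ECG beats"))
    beats <- detectPvc(lead, fs, beats,
                       widthMs = config$pvc$width_ms,
                       ampFactor = config$pvc$amp_factor,
                       corrMin = config$pvc$corr_min)
    beats <- beatSeries(beatTimes(beats) + startS, beatLabels(beats), "ecg")
    row$n_beats <- length(beatTimes(beats))
    row$n_pvc <- sum(beatLabels(beats) == "V")
    rr <- deriveIntervals(beats, kind = "RR")
    row$rmssd <- rmssd(rr)
    sp <- lombPsd(rr, lfBand = config$bands$lf, hfBand = config$bands$hf)
    row$lf_power <- sp$lf_power; row$hf_power <- sp$hf_power
    row$lf_hf <- sp$lf_hf
    if (!is.na(sp$reason)) flags <- c(flags, paste("spectrum:", sp$reason))
    ht <- segmentHrt(beats, minPvc = config$hrt$min_pvc,
                     nPost = config$hrt$n_post, strict = config$hrt$strict)
    row$hrt_ts <- ht$ts_ms_per_beat; row$to_pct <- ht$to_pct
    if (!is.na(ht$reason)) flags <- c(flags, paste("hrt:", ht$reason))
    if (!is.null(abpBeats) && length(beatTimes(abpBeats)) >= 3) {
      paired <- alignRrSbp(rr, abpBeats, tolS = config$prsa$align_tol_s)
      pr <- prsaBrs(paired, L = config$prsa$L)
      row$brs <- pr$brs
      if (!is.na(pr$reason)) flags <- c(flags, paste("prsa:", pr$reason))
      if (length(intervalValues(paired)) >= 10 * config$arx$order) {
        ax <- tryCatch(arxBrs(paired, order = config$arx$order,
                              lfBand = config$bands$lf),
                       error = function(e) NULL)
        if (!is.null(ax)) row$alpha_lf <- ax$alpha_lf
      }
    } else flags <- c(flags, "no ABP channel for BRS")
  }
  row$flags <- paste(flags, collapse = "; ")
  row
}

#' Run the full pipeline on one record
#'
#' Slices the record into segments, quality-gates each, analyses the passing
#' segments (ECG path: lead selection, R peaks, PVC labeling, HRV, HRT, BRS;
#' ABP-only path: systolic peaks, PPI-based variability and BRS with HRT
#' structurally missing), aggregates the first-24-h indices to the subject
#' level, standardizes them and applies the composite classification. Every
#' per-segment decision (pass/fail/skip and its reason) is logged exactly
#' once.
#'
#' @param record a [WaveformRecord-class] or a path readable by
#'   [readRecord()].
#' @param config pipeline configuration from [defaultConfig()].
#' @param age,sex subject demographics for standardization.
#' @param libraries quality-gate models; built once per call when `NULL`.
#' @return List with `segments` (per-segment index table), `subject`
#'   (aggregated values), `profile`, `ead`, `log` (data.frame of decisions)
#'   and `status` (`"ok"`, `"unclassifiable"`).
#' @export
runRecord <- function(record, config = defaultConfig(), age = 50, sex = "F",
                      libraries = NULL) {
  if (is.character(record)) {
    fmt <- if (file.exists(paste0(record, ".hea"))) "wfdb" else "csv"
    record <- readRecord(record, format = fmt)
  }
  if (is.null(libraries) && isTRUE(config$quality$enabled))
    libraries <- defaultQualityLibraries(seed = config$seed, config = config)
  wins <- sliceSegments(record, config$segment_length_s)
  log <- data.frame(start_s = numeric(), decision = character(),
                    reason = character())
  segRows <- list()
  for (i in seq_len(nrow(wins))) {
    w <- wins[i, ]
    if (w$partial && !isTRUE(config$allow_partial)) {
      log <- rbind(log, data.frame(start_s = w$start_s, decision = "skip",
                                   reason = "partial trailing segment"))
      next
    }
    seg <- cropRecord(record, w$start_s, w$end_s)
    if (isTRUE(config$quality$enabled)) {
      q <- gateSegment(seg, libraries, config)
      if (!q$pass) {
        log <- rbind(log, data.frame(
          start_s = w$start_s, decision = "fail",
          reason = sprintf("quality gate (ecg=%s, abp_valid=%.2f)",
                           q$ecg_quality, q$abp_valid_fraction)))
        segRows <- c(segRows, list(data.frame(start_s = w$start_s,
                                              quality_pass = FALSE)))
        next
      }
    }
    log <- rbind(log, data.frame(start_s = w$start_s, decision = "pass",
                                 reason = "analysed"))
    segRows <- c(segRows, list(analyseSegment(seg, w$start_s, libraries,
                                              config)))
  }
  segments <- if (length(segRows))
    do.call(rbind, lapply(segRows, function(r) {
      need <- c("start_s", "quality_pass", "rmssd", "lf_power", "hf_power",
                "lf_hf", "hrt_ts", "to_pct", "brs", "alpha_lf", "n_pvc",
                "n_beats", "flags")
      for (cn in setdiff(need, names(r))) r[[cn]] <- NA
      r[need]
    }))
  else data.frame()
  ranges <- if (is.null(config$ead$reference_path)) defaultReferenceRanges()
            else readReferenceRanges(config$ead$reference_path)
  names(segments)[names(segments) == "brs"] <- "brs"
  agg <- aggregateSubject(segments, statistic = config$ead$aggregate)
  if (is.null(agg$values))
    return(list(segments = segments, subject = NULL, profile = NULL,
                ead = NULL, log = log, status = "unclassifiable"))
  vals <- agg$values
  names(vals)[names(vals) == "brs"] <- "brs"
  profile <- indexProfile(vals, age, sex, ranges,
                          threshold = config$ead$threshold)
  ead <- characterizeEad(profile, minCount = config$ead$min_count)
  list(segments = segments, subject = agg, profile = profile, ead = ead,
       log = log, status = "ok")
}

#' Run the pipeline over a cohort manifest
#'
#' @param manifest data.frame with columns `id`, `age`, `sex` and either
#'   `path` (record paths) or the five index columns (pre-computed subject
#'   indices, e.g. from [makeCohort()]).
#' @param config pipeline configuration.
#' @return List with `subjects` (per-subject data.frame including
#'   `ead_classified` and `abnormal_count`) and `incidence` (per-index
#'   abnormality incidence plus overall eAD incidence). Empty manifests yield
#'   empty outputs with a warning.
#' @export
runCohort <- function(manifest, config = defaultConfig()) {
  if (!nrow(manifest)) {
    warning("empty cohort manifest")
    return(list(subjects = data.frame(), incidence = data.frame()))
  }
  ranges <- if (is.null(config$ead$reference_path)) defaultReferenceRanges()
            else readReferenceRanges(config$ead$reference_path)
  res <- lapply(seq_len(nrow(manifest)), function(i) {
    m <- manifest[i, ]
    if (!is.null(manifest$path) && !is.na(m$path)) {
      r <- runRecord(m$path, config, age = m$age, sex = m$sex)
      if (r$status != "ok") return(data.frame(id = m$id, classified = NA,
                                              count = NA_integer_))
      prof <- r$profile
    } else {
      vals <- stats::setNames(as.numeric(m[eadIndices()]), eadIndices())
      prof <- indexProfile(vals, m$age, m$sex, ranges,
                           threshold = config$ead$threshold)
    }
    e <- characterizeEad(prof, minCount = config$ead$min_count)
    out <- data.frame(id = m$id, classified = e$classified,
                      count = e$abnormal_count)
    for (ix in eadIndices())
      out[[paste0("abn_", ix)]] <- ix %in% e$contributions
    out
  })
  subjects <- do.call(rbind, lapply(res, function(r) {
    for (cn in c(paste0("abn_", eadIndices())))
      if (!cn %in% names(r)) r[[cn]] <- NA
    r
  }))
  incidence <- data.frame(
    index = c(eadIndices(), "ead"),
    incidence = c(vapply(eadIndices(), function(ix)
      mean(subjects[[paste0("abn_", ix)]], na.rm = TRUE), numeric(1)),
      mean(subjects$classified, na.rm = TRUE)))
  list(subjects = subjects, incidence = incidence)
}
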