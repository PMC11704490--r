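#' Subject specification for the synthetic generator
#'
#' Collects every tunable of the synthetic subject in one list: baseline RR,
#' LF/HF sinusoidal modulation of the tachogram, white RR jitter, the PVC
#' injection plan (count, coupling fraction, post-ectopic response), the
#' baroreflex coupling (gain and sBP process) and per-channel waveform noise.
#' Every stochastic draw is governed by `seed`.
#'
#' @param rr0Ms baseline RR (ms), default 850.
#' @param lfAmpMs,lfHz LF modulation amplitude (ms) and frequency (Hz).
#' @param hfAmpMs,hfHz HF modulation amplitude (ms) and frequency (Hz).
#' @param jitterSdMs white RR jitter SD (ms).
#' @param nBeats number of beats to generate.
#' @param pvcCount PVCs to inject (0 = none).
#' @param couplingFraction coupling interval as a fraction of the preceding
#'   RR, in (0, 1), default 0.6.
#' @param earlyDepthMs early post-ectopic acceleration depth (ms), default 20.
#' @param slopeMsPerBeat per-beat deceleration increment during recovery
#'   (ms/beat); the turbulence-slope truth.
#' @param recoveryBeats recovery length (beats), default 10.
#' @param brsGain baroreflex gain G (ms/mmHg) for closed-loop sBP coupling.
#' @param sbpProcess `"ramp"`, `"sinusoid"` or `"walk"` (+/-1 mmHg random
#'   walk).
#' @param sbp0 reference systolic pressure (mmHg), default 120.
#' @param noise list of waveform noise settings for [corruptRecord()].
#' @param seed RNG seed (mandatory for reproducibility).
#' @return A `subjectSpec` list.
#' @export
subjectSpec <- function(rr0Ms = 850, lfAmpMs = 30, lfHz = 0.10,
                        hfAmpMs = 40, hfHz = 0.25, jitterSdMs = 5,
                        nBeats = 4200, pvcCount = 0, couplingFraction = 0.6,
                        earlyDepthMs = 20, slopeMsPerBeat = 8,
                        recoveryBeats = 10, brsGain = 15,
                        sbpProcess = "walk", sbp0 = 120, noise = list(),
                        seed = 1) {
  stopifnot(couplingFraction > 0, couplingFraction < 1,
            lfAmpMs >= 0, hfAmpMs >= 0, jitterSdMs >= 0)
  structure(as.list(environment()), class = "subjectSpec")
}

#' Generate a sinus tachogram
#'
#' RR-domain additive model:
#' \deqn{RR_k = RR_0 + A_{LF}\sin(2\pi f_{LF} t_k) + A_{HF}\sin(2\pi f_{HF}
#'   t_k) + \epsilon_k}
#' with cumulative beat times (each beat placed one RR after the previous).
#' The additive RR-domain form gives closed-form oracles for RMSSD and the
#' spectral peak locations.
#'
#' @param spec a [subjectSpec()].
#' @return List (class `tachogram`) with `beats` (a [BeatSeries-class]),
#'   `rr_ms`, and a `truth` list carrying every generator parameter.
#' @export
genTachogram <- function(spec) {
  set.seed(spec$seed)
  n <- spec$nBeats
  t <- numeric(n + 1)
  rr <- numeric(n)
  eps <- stats::rnorm(n, sd = spec$jitterSdMs)
  for (k in seq_len(n)) {
    rr[k] <- spec$rr0Ms +
      spec$lfAmpMs * sin(2 * pi * spec$lfHz * t[k]) +
      spec$hfAmpMs * sin(2 * pi * spec$hfHz * t[k]) + eps[k]
    t[k + 1] <- t[k] + rr[k] / 1000
  }
  beats <- beatSeries(t, labels = rep("N", n + 1), source = "ecg")
  structure(list(beats = beats, rr_ms = rr,
                 truth = list(spec = spec, jitter = eps)),
            class = "tachogram")
}

#' Inject PVCs with a turbulence response into a tachogram
#'
#' At each injection site the sinus beat is replaced by an ectopic beat placed
#' one coupling interval (`couplingFraction` x preceding RR) after the
#' previous sinus beat, followed by a full compensatory pause
#' (`compI = 2 RR - couplI`). The subsequent `recoveryBeats` sinus intervals
#' are offset by the post-ectopic response profile: an early acceleration of
#' `earlyDepthMs` then per-beat lengthening by `slopeMsPerBeat` (so the
#' turbulence-slope truth equals `slopeMsPerBeat` when jitter is zero). Sites
#' are spaced at least 20 sinus beats apart and keep full pre/post context.
#'
#' @param tach a `tachogram` from [genTachogram()].
#' @param spec the [subjectSpec()] (PVC fields are used); per-event slopes may
#'   be supplied via `slopes`.
#' @param slopes optional numeric vector of per-event slope increments
#'   (ms/beat), recycled over events.
#' @return The modified `tachogram` with `"V"` labels and an `hrtTruth` list
#'   (per event: site, couplI, compI, slope).
#' @export
injectPvc <- function(tach, spec, slopes = NULL) {
  k <- spec$pvcCount
  if (k < 1) return(tach)
  rr <- tach$rr_ms                 # rr[m] = t[m+1] - t[m]
  n <- length(rr)
  margin <- max(20, spec$recoveryBeats + 5)
  lo <- 25
  hi <- n - max(16, spec$recoveryBeats + 1)
  if (hi <= lo) stopWith("autonomiq_input_error",
                         "tachogram too short for requested PVC count")
  sites <- round(seq(lo, hi, length.out = k))     # PVC beat indices
  if (k > 1 && min(diff(sites)) < margin)
    stopWith("autonomiq_input_error",
             "tachogram too short to space PVCs 20 sinus beats apart")
  if (is.null(slopes)) slopes <- spec$slopeMsPerBeat
  slopes <- rep_len(slopes, k)
  lab <- beatLabels(tach$beats)
  truth <- list()
  for (e in seq_len(k)) {
    p <- sites[e]                  # the PVC beat; rr[p-1] ends at it
    rrPrev <- rr[p - 1]
    couplI <- spec$couplingFraction * rrPrev
    compI <- 2 * rrPrev - couplI   # full compensatory pause
    rr[p - 1] <- couplI
    rr[p] <- compI
    offs <- -spec$earlyDepthMs + slopes[e] * (seq_len(spec$recoveryBeats) - 1)
    post <- p + seq_len(spec$recoveryBeats)
    rr[post] <- rr[post] + offs
    lab[p] <- "V"
    truth[[e]] <- list(site = p, couplI_ms = couplI, compI_ms = compI,
                       slope_ms_per_beat = slopes[e])
  }
  t <- beatTimes(tach$beats)[1] + c(0, cumsum(rr) / 1000)
  tach$beats <- beatSeries(t, labels = lab, source = "ecg")
  tach$rr_ms <- rr
  tach$hrtTruth <- truth
  tach
}

#' Couple a systolic-pressure series to the tachogram
#'
#' Generates a per-beat sBP series by the chosen process, then (closed loop)
#' regenerates the RR series as
#' \deqn{RR_k = RR_0 + G (sBP_k - sBP_0) + \epsilon_k}
#' so the baroreflex-gain truth `G` is recoverable by the BRS estimators.
#'
#' @param tach a `tachogram`.
#' @param spec a [subjectSpec()]; uses `brsGain`, `sbpProcess`, `sbp0`,
#'   `jitterSdMs`, `seed`.
#' @return The `tachogram` with per-beat `sbp` attached (both on the beats and
#'   as `sbp_mmHg`), RR regenerated, and `truth$brsGain` recorded.
#' @export
genCoupledSbp <- function(tach, spec) {
  set.seed(spec$seed + 1L)
  n <- length(tach$rr_ms)
  sbp <- switch(spec$sbpProcess,
    # 1 mmHg/beat triangular ramp bounded at +/-15 mmHg (keeps RR positive
    # at physiological gains while every rising run is an exact unit ramp)
    ramp = {
      half <- 15
      phase <- (seq_len(n) - 1) %% (4 * half)
      spec$sbp0 + ifelse(phase < 2 * half, phase - half,
                         3 * half - phase)
    },
    sinusoid = spec$sbp0 + 10 * sin(2 * pi * 0.1 *
                                    cumsum(tach$rr_ms) / 1000),
    walk = {
      # +/-1 mmHg per-beat random walk, reflected at +/-15 mmHg so the
      # excursion stays physiological and RR stays positive at high gain
      steps <- sample(c(-1, 1), n, replace = TRUE)
      w <- numeric(n)
      cur <- 0
      for (i in seq_len(n)) {
        if (abs(cur + steps[i]) > 15) steps[i] <- -steps[i]
        cur <- cur + steps[i]
        w[i] <- cur
      }
      spec$sbp0 + w
    },
    stopWith("autonomiq_input_error", "unknown sBP process"))
  eps <- stats::rnorm(n, sd = spec$jitterSdMs)
  rr <- spec$rr0Ms + spec$brsGain * (sbp - spec$sbp0) + eps
  t <- c(0, cumsum(rr) / 1000)
  lab <- beatLabels(tach$beats)[seq_len(n + 1)]
  tach$beats <- beatSeries(t, labels = lab, source = "ecg",
                           sbp = c(NA, sbp))
  tach$rr_ms <- rr
  tach$sbp_mmHg <- sbp
  tach$truth$brsGain <- spec$brsGain
  tach
}

#' Paired RR/sBP interval series of a coupled tachogram
#'
#' @param tach a `tachogram` processed by [genCoupledSbp()].
#' @return An [IntervalSeries-class] with `sbp` pairing (RR_k paired with
#'   sBP_k).
#' @export
tachogramIntervals <- function(tach) {
  t <- beatTimes(tach$beats)
  intervalSeries(t[-1], tach$rr_ms, kind = "RR",
                 sbp = if (is.null(tach$sbp_mmHg)) NULL else tach$sbp_mmHg)
}

# single-beat ECG template: Gaussian-bump P-QRS-T, wide/large for PVCs
ecgBeatTemplate <- function(tt, isPvc = FALSE) {
  if (!isPvc) {
    0.12 * exp(-((tt + 0.16) / 0.025)^2) -     # P
      0.15 * exp(-((tt + 0.025) / 0.010)^2) +  # Q
      1.00 * exp(-(tt / 0.012)^2) -            # R
      0.20 * exp(-((tt - 0.030) / 0.012)^2) +  # S
      0.30 * exp(-((tt - 0.25) / 0.05)^2)      # T
  } else {
    # wide (half-height > 120 ms), large, discordant morphology, no P wave
    1.80 * exp(-(tt / 0.082)^2) -
      0.80 * exp(-((tt - 0.16) / 0.06)^2) -
      0.40 * exp(-((tt - 0.32) / 0.07)^2)
  }
}

# single ABP pulse from onset over `dur` seconds, scaled to [dbp, sbp].
# The same parametric family underlies the synthetic reference library.
abpPulseTemplate <- function(tt, dur, sbp, dbp, peakT = 0.18, peakW = 0.10,
                             notchAmp = 0.25, notchT = 0.45, notchW = 0.07,
                             decay = 0.8) {
  x <- tt / dur
  shape <- exp(-((x - peakT) / peakW)^2) +
    notchAmp * exp(-((x - notchT) / notchW)^2)
  shape <- shape * exp(-x / decay)
  dbp + (sbp - dbp) * shape / max(shape)
}

#' Render ECG and ABP waveforms from a tachogram
#'
#' ECG beats are synthesized from Gaussian-bump P-QRS-T templates (PVC beats
#' rendered wide, large and discordant so the rule-based detector's ground
#' truth is meaningful); the ABP channel places one pulse per beat with its
#' onset at the beat time and its systolic amplitude equal to the requested
#' sBP. Ground-truth beat times and labels are returned alongside.
#'
#' @param tach a `tachogram` (optionally with sBP attached).
#' @param fsEcg,fsAbp sampling rates (Hz), defaults 250 and 125.
#' @param nLeads number of ECG leads to render (default 2; leads get
#'   amplitude factors 1 and 0.7).
#' @return List with `record` (a [WaveformRecord-class]), `truth` (a
#'   [BeatSeries-class] of true beats) and `sbp` (per-beat systolic truth).
#' @export
renderWaveforms <- function(tach, fsEcg = 250, fsAbp = 125, nLeads = 2) {
  t <- beatTimes(tach$beats)
  lab <- beatLabels(tach$beats)
  dur <- max(t) + 1
  nE <- ceiling(dur * fsEcg)
  ecg <- numeric(nE)
  tE <- (seq_len(nE) - 1) / fsEcg
  for (b in seq_along(t)) {
    lo <- max(1, floor((t[b] - 0.45) * fsEcg) + 1)
    hi <- min(nE, ceiling((t[b] + 0.55) * fsEcg) + 1)
    ecg[lo:hi] <- ecg[lo:hi] + ecgBeatTemplate(tE[lo:hi] - t[b],
                                               isPvc = lab[b] == "V")
  }
  sbp <- if (is.null(tach$sbp_mmHg)) rep(120, length(t) - 1) else tach$sbp_mmHg
  nA <- ceiling(dur * fsAbp)
  abp <- numeric(nA) + (min(sbp) - 40)
  tA <- (seq_len(nA) - 1) / fsAbp
  for (b in seq_len(length(t) - 1)) {
    lo <- floor(t[b] * fsAbp) + 1
    hi <- min(nA, floor(t[b + 1] * fsAbp))
    if (hi < lo) next
    abp[lo:hi] <- abpPulseTemplate(tA[lo:hi] - t[b], t[b + 1] - t[b],
                                   sbp = sbp[b], dbp = sbp[b] - 40)
  }
  leads <- vapply(seq_len(nLeads), function(m)
    ecg * c(1, 0.7, 0.5, 0.4)[m], numeric(nE))
  # common fs record: resample ABP onto the ECG clock for a single container
  abpE <- stats::approx(tA, abp, xout = tE, rule = 2)$y
  record <- waveformRecord(cbind(leads, ABP = abpE),
                           names = c(paste0("ECG", seq_len(nLeads)), "ABP"),
                           roles = c(rep("ecg", nLeads), "abp"),
                           fs = fsEcg)
  list(record = record,
       truth = beatSeries(t, lab, source = "ecg"),
       sbp = sbp)
}

#' Corrupt a record with waveform-level noise
#'
#' Additive white noise, slow baseline wander (below 0.5 Hz), flatline
#' intervals and burst motion artifacts, each applied per channel with a
#' retained truth mask. A zero noise specification returns the record
#' unchanged.
#'
#' @param record a [WaveformRecord-class].
#' @param noise list with optional elements `whiteSd`, `wanderAmp`
#'   (and `wanderHz`, default 0.3), `flatlineS` (list of `c(start, end)`
#'   second pairs), `burstS` (list of `c(start, end)`), `burstSd`; each may be
#'   a single spec applied to all channels or a list per channel name.
#' @param seed RNG seed.
#' @return List with `record` (corrupted) and `mask` (per-channel logical
#'   vectors marking corrupted samples).
#' @export
corruptRecord <- function(record, noise = list(), seed = 1) {
  set.seed(seed)
  sig <- record@signals
  fs <- sampleRate(record)
  n <- nrow(sig)
  tt <- (seq_len(n) - 1) / fs
  mask <- matrix(FALSE, n, ncol(sig))
  for (j in seq_len(ncol(sig))) {
    nm <- channelNames(record)[j]
    sp <- if (!is.null(noise[[nm]])) noise[[nm]] else noise
    if (!is.null(sp$whiteSd) && sp$whiteSd > 0) {
      sig[, j] <- sig[, j] + stats::rnorm(n, sd = sp$whiteSd)
      mask[, j] <- TRUE
    }
    if (!is.null(sp$wanderAmp) && sp$wanderAmp > 0) {
      hz <- if (is.null(sp$wanderHz)) 0.3 else min(sp$wanderHz, 0.5)
      sig[, j] <- sig[, j] + sp$wanderAmp * sin(2 * pi * hz * tt +
                                                stats::runif(1, 0, 2 * pi))
      mask[, j] <- TRUE
    }
    for (fl in sp$flatlineS %||% list()) {
      idx <- which(tt >= fl[1] & tt < fl[2])
      if (length(idx)) { sig[idx, j] <- sig[max(1, idx[1] - 1), j]
                         mask[idx, j] <- TRUE }
    }
    for (bu in sp$burstS %||% list()) {
      idx <- which(tt >= bu[1] & tt < bu[2])
      sdv <- if (is.null(sp$burstSd)) 1 else sp$burstSd
      if (length(idx)) { sig[idx, j] <- sig[idx, j] + stats::rnorm(length(idx),
                                                                   sd = sdv)
                         mask[idx, j] <- TRUE }
    }
  }
  out <- record
  out@signals <- sig
  list(record = out, mask = mask)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a synthetic cohort with planted dysfunction prevalence
#'
#' Draws per-subject truth labels from a Bernoulli(`prevalence`) and builds,
#' for each subject, either (default, `level = "indices"`) the five index
#' values drawn from the subject's reference stratum - healthy subjects at
#' the stratum mean/SD, affected subjects with `nDisplaced` randomly chosen
#' indices displaced downward by `effectSd` stratum SDs - or
#' (`level = "spec"`) a full [subjectSpec()] with parameters shifted for
#' affected subjects (reduced jitter, flat turbulence response, low gain).
#'
#' @param n cohort size.
#' @param prevalence planted dysfunction prevalence in \[0, 1\].
#' @param effectSd displacement effect size in SD units (default 4).
#' @param nDisplaced number of displaced indices (default 4).
#' @param seed RNG seed.
#' @param level `"indices"` or `"spec"`.
#' @param ranges reference table for `"indices"` level.
#' @return data.frame (one row per subject) with `id`, `age`, `sex`,
#'   `truth_ead` and, for the indices level, the five index columns; for the
#'   spec level a `spec` list-column.
#' @export
makeCohort <- function(n, prevalence, effectSd = 4, nDisplaced = 4, seed = 1,
                       level = c("indices", "spec"),
                       ranges = defaultReferenceRanges()) {
  level <- match.arg(level)
  set.seed(seed)
  age <- sample(20:89, n, replace = TRUE)
  sex <- sample(c("F", "M"), n, replace = TRUE)
  truth <- stats::runif(n) < prevalence
  out <- data.frame(id = sprintf("S%03d", seq_len(n)), age = age, sex = sex,
                    truth_ead = truth, stringsAsFactors = FALSE)
  if (level == "indices") {
    vals <- matrix(NA_real_, n, 5, dimnames = list(NULL, eadIndices()))
    for (i in seq_len(n)) {
      displaced <- if (truth[i]) sample(eadIndices(), nDisplaced) else character()
      for (ix in eadIndices()) {
        st <- lookupStratum(ranges, age[i], sex[i], ix)
        shift <- if (ix %in% displaced) -effectSd * st$sd else 0
        vals[i, ix] <- stats::rnorm(1, st$mean + shift, st$sd)
      }
    }
    out <- cbind(out, as.data.frame(vals))
  } else {
    out$spec <- lapply(seq_len(n), function(i) {
      if (truth[i])
        subjectSpec(jitterSdMs = 1, hfAmpMs = 5, lfAmpMs = 3,
                    slopeMsPerBeat = 0.5, brsGain = 1, pvcCount = 15,
                    seed = seed * 1000 + i)
      else subjectSpec(pvcCount = 15, seed = seed * 1000 + i)
    })
  }
  out
}
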