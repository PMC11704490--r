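#' QRS enhancement mask
#'
#' Length `2k + 1` mask with value `2k` at the center and `-1` on both flanks.
#' Its coefficients sum to zero, so it has no response to a constant signal
#' and amplifies sharp deflections spanning about `k` samples.
#'
#' @param k half-width in samples; default `round(0.05 * fs)` (50 ms spans a
#'   QRS upstroke).
#' @param fs sampling rate, used only for the default `k`.
#' @return Numeric coefficient vector of length `2k + 1`.
#' @export
enhancementMask <- function(k = NULL, fs = NULL) {
  if (is.null(k)) k <- round(0.05 * fs)
  stopifnot(k >= 1)
  m <- rep(-1, 2 * k + 1)
  m[k + 1] <- 2 * k
  m
}

# S_n = sum_j M_{k+j} E_{n+j}, zero-padded at the edges
applyMask <- function(x, mask) {
  k <- (length(mask) - 1) / 2
  xp <- c(rep(0, k), x, rep(0, k))
  out <- stats::filter(xp, rev(mask), method = "convolution", sides = 2)
  as.numeric(out[(k + 1):(k + length(x))])
}

# zero-phase Butterworth band-pass
bandpass <- function(x, fs, low, high, order = 3) {
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

#' Detect R peaks on an ECG lead
#'
#' Band-pass (0.5-17 Hz) filtering, QRS enhancement by the zero-sum mask
#' ([enhancementMask()]), per-window min-max normalization to \[0, 1\] over
#' 2-s sliding windows (1-s advance), fiducial search over consecutive 0.3-s
#' ranges with a normalized amplitude threshold of 0.5, and R-peak
#' localization as the absolute extremum of the filtered signal within 0.24 s
#' centered at each fiducial. Candidates from overlapping windows are
#' deduplicated with a 0.2-s refractory period (largest amplitude wins), so
#' the returned times are strictly increasing.
#'
#' @param ecg numeric ECG samples.
#' @param fs sampling rate in Hz (>= 100).
#' @param maskK enhancement-mask half-width (samples); default 50 ms.
#' @param searchS fiducial search range (s), default 0.3.
#' @param peakS R-peak recognition interval (s), default 0.24.
#' @param threshold normalized amplitude threshold, default 0.5.
#' @param refractoryS minimum beat spacing (s), default 0.2.
#' @return A [BeatSeries-class] with all labels `"X"` pending classification
#'   (use [detectPvc()] to assign N/V labels).
#' @export
detectRPeaks <- function(ecg, fs, maskK = NULL, searchS = 0.3, peakS = 0.24,
                         threshold = 0.5, refractoryS = 0.2) {
  if (fs < 100)
    stopWith("autonomiq_input_error", "sampling rate below 100 Hz")
  if (length(ecg) < 2 * fs)
    stopWith("autonomiq_input_error", "need at least 2 s of signal")
  if (stats::sd(ecg) == 0)
    return(beatSeries(numeric(), character(), source = "ecg"))
  filt <- bandpass(ecg, fs, 0.5, min(17, 0.45 * fs))
  enh <- applyMask(filt, enhancementMask(maskK, fs))
  n <- length(ecg)
  win <- round(2 * fs); step <- round(fs)
  half <- round(peakS * fs / 2)
  starts <- seq(1, max(1, n - win + 1), by = step)
  cand <- integer()
  for (s0 in starts) {
    idx <- s0:min(n, s0 + win - 1)
    e <- enh[idx]
    rng <- range(e)
    if (diff(rng) < 1e-8) next                    # constant window skipped
    en <- (e - rng[1]) / diff(rng)
    # consecutive search ranges of searchS within the window
    rstep <- round(searchS * fs)
    for (r0 in seq(1, length(idx), by = rstep)) {
      ridx <- r0:min(length(idx), r0 + rstep - 1)
      mx <- which.max(en[ridx])
      if (en[ridx][mx] < threshold) next
      fid <- idx[ridx[mx]]
      lo <- max(1, fid - half); hi <- min(n, fid + half)
      cand <- c(cand, lo - 1 + which.max(abs(filt[lo:hi])))
    }
  }
  if (!length(cand)) return(beatSeries(numeric(), character(), source = "ecg"))
  cand <- unique(cand)
  keep <- integer()
  for (i in cand[order(-abs(filt[cand]))])
    if (!length(keep) || all(abs(i - keep) > refractoryS * fs))
      keep <- c(keep, i)
  keep <- sort(keep)
  beatSeries((keep - 1) / fs, labels = rep("X", length(keep)), source = "ecg")
}

#' Detect systolic peaks on an ABP waveform
#'
#' Savitzky-Golay smoothing followed by sliding-window maximum detection with
#' a refractory period. The systolic pressure at each peak is the smoothed
#' amplitude, in the input units.
#'
#' @param abp numeric ABP samples (mmHg).
#' @param fs sampling rate in Hz (>= 50).
#' @param smoothS smoothing window length (s), default 0.2.
#' @param order Savitzky-Golay polynomial order, default 3.
#' @param refractoryS minimum peak spacing (s), default 0.3.
#' @param minRange minimum pulsatile range (units) below which the signal is
#'   treated as non-pulsatile and no peaks are returned.
#' @return A [BeatSeries-class] (source `"abp"`) carrying `sbp` values.
#' @export
detectSystolicPeaks <- function(abp, fs, smoothS = 0.2, order = 3,
                                refractoryS = 0.3, minRange = 5) {
  if (fs < 50) stopWith("autonomiq_input_error", "sampling rate below 50 Hz")
  w <- round(smoothS * fs)
  if (w %% 2 == 0) w <- w + 1
  w <- max(w, order + 2 + (order %% 2 == 0))
  sm <- as.numeric(signal::sgolayfilt(abp, p = order, n = w))
  if (diff(range(sm)) < minRange)
    return(beatSeries(numeric(), character(), source = "abp"))
  thr <- stats::quantile(sm, 0.02) + 0.5 * (stats::quantile(sm, 0.98) -
                                            stats::quantile(sm, 0.02))
  n <- length(sm)
  isMax <- c(FALSE, sm[2:(n - 1)] > sm[1:(n - 2)] & sm[2:(n - 1)] >= sm[3:n],
             FALSE)
  cand <- which(isMax & sm > thr)
  keep <- integer()
  for (i in cand[order(-sm[cand])])
    if (!length(keep) || all(abs(i - keep) > refractoryS * fs))
      keep <- c(keep, i)
  keep <- sort(keep)
  beatSeries((keep - 1) / fs, labels = rep("N", length(keep)), source = "abp",
             sbp = sm[keep])
}

#' Detect pulse onsets preceding systolic peaks
#'
#' The onset (foot) of each pulse is the minimum of the waveform in the 0.5 s
#' preceding its systolic peak. Onsets delimit the pulses scored by the
#' subspace quality model.
#'
#' @param abp numeric ABP samples.
#' @param fs sampling rate in Hz.
#' @param peaks optional [BeatSeries-class] of systolic peaks (detected if
#'   missing).
#' @param lookbackS search window before each peak (s), default 0.5.
#' @return Numeric vector of onset times (s), one per systolic peak.
#' @export
detectPulseOnsets <- function(abp, fs, peaks = NULL, lookbackS = 0.5) {
  if (is.null(peaks)) peaks <- detectSystolicPeaks(abp, fs)
  pk <- round(beatTimes(peaks) * fs) + 1
  vapply(pk, function(i) {
    lo <- max(1, i - round(lookbackS * fs))
    (lo - 1 + which.min(abp[lo:i]) - 1) / fs
  }, numeric(1))
}

#' Split an ABP waveform into onset-delimited pulses
#'
#' @param abp numeric ABP samples.
#' @param fs sampling rate.
#' @param onsets onset times in seconds (from [detectPulseOnsets()]).
#' @return List of numeric pulse vectors (onset to next onset).
#' @export
splitPulses <- function(abp, fs, onsets) {
  idx <- round(onsets * fs) + 1
  if (length(idx) < 2) return(list())
  lapply(seq_len(length(idx) - 1), function(i) abp[idx[i]:(idx[i + 1] - 1)])
}
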