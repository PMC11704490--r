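#' Signal quality indices for one ECG lead
#'
#' Three per-lead indices:
#' * `bSQI` — consensus beat detection: beats found by the band-pass /
#'   enhancement-mask detector ([detectRPeaks()]) are matched within 150 ms to
#'   beats from an independent amplitude-threshold peak picker; bSQI is the
#'   matched fraction `n_match / (n1 + n2 - n_match)`, in \[0, 1\].
#' * `sSQI` — spectral concentration: periodogram power in the QRS band
#'   5-14 Hz as a fraction of power in 1-40 Hz, in \[0, 1\].
#' * `kSQI` — excess kurtosis of the segment (0 for Gaussian noise; large and
#'   positive for spiky QRS-dominated signal).
#'
#' @param lead numeric ECG samples (>= 10 s recommended).
#' @param fs sampling rate in Hz.
#' @param agreementTolS beat-matching tolerance in seconds.
#' @return List with `bSQI`, `sSQI`, `kSQI`.
#' @export
computeSqis <- function(lead, fs, agreementTolS = 0.15) {
  if (stats::sd(lead) == 0)
    return(list(bSQI = 0, sSQI = 0, kSQI = NA_real_))
  b1 <- tryCatch(beatTimes(detectRPeaks(lead, fs)), error = function(e) numeric())
  b2 <- amplitudeThresholdBeats(lead, fs)
  nm <- nrow(matchEvents(b1, b2, agreementTolS))
  denom <- length(b1) + length(b2) - nm
  bSQI <- if (denom > 0) nm / denom else 0
  # spectral fraction via raw periodogram
  sp <- stats::spec.pgram(stats::ts(lead, frequency = fs), taper = 0,
                          detrend = TRUE, plot = FALSE)
  inBand <- function(lo, hi) sum(sp$spec[sp$freq >= lo & sp$freq <= hi])
  tot <- inBand(1, 40)
  sSQI <- if (tot > 0) inBand(5, 14) / tot else 0
  list(bSQI = bSQI, sSQI = sSQI, kSQI = excessKurtosis(lead))
}

# Independent second detector for the consensus SQI: simple amplitude
# thresholding on the baseline-removed signal with a 0.3-s refractory.
amplitudeThresholdBeats <- function(lead, fs, thresholdFrac = 0.6,
                                    refractoryS = 0.3) {
  k <- max(3, round(fs * 0.6))
  if (k %% 2 == 0) k <- k + 1
  x <- lead - stats::runmed(lead, k)
  thr <- thresholdFrac * max(abs(x))
  if (thr <= 0) return(numeric())
  cand <- which(abs(x) >= thr)
  if (!length(cand)) return(numeric())
  # greedy refractory: keep the largest |x| in each cluster
  ord <- cand[order(-abs(x[cand]))]
  keep <- numeric()
  for (i in ord)
    if (!length(keep) || all(abs(i - keep) > refractoryS * fs))
      keep <- c(keep, i)
  sort(keep - 1) / fs
}

#' Composite signal quality and optimal-lead selection
#'
#' Each SQI is min-max scaled across leads (a degenerate spread maps to 0.5)
#' and the composite is the weighted mean of the scaled values. The optimal
#' lead is the argmax of the composite, ties broken by the lowest lead index.
#'
#' @param sqis list of per-lead SQI lists from [computeSqis()].
#' @param weights weights for (bSQI, sSQI, kSQI), default equal.
#' @return `compositeSqi`: numeric composite per lead. `selectBestLead`: the
#'   chosen lead index.
#' @export
compositeSqi <- function(sqis, weights = c(1, 1, 1) / 3) {
  m <- vapply(sqis, function(s) c(s$bSQI, s$sSQI, s$kSQI), numeric(3))
  m <- matrix(m, nrow = 3)
  scaled <- apply(m, 1, function(r) {
    if (all(!is.finite(r))) return(rep(NA_real_, length(r)))
    rng <- range(r, na.rm = TRUE)
    if (diff(rng) == 0) return(rep(0.5, length(r)))
    (r - rng[1]) / diff(rng)
  })
  scaled <- matrix(scaled, ncol = 3)
  as.numeric(scaled %*% (weights / sum(weights)))
}

#' @rdname compositeSqi
#' @export
selectBestLead <- function(sqis, weights = c(1, 1, 1) / 3) {
  comp <- compositeSqi(sqis, weights)
  if (all(!is.finite(comp)))
    stopWith("autonomiq_input_error", "no lead has a finite composite SQI")
  which.max(comp)
}
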