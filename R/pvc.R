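# Beat morphology features used by the rule-based PVC detector.
# Windows are baseline-removed, sign-rectified relative to the beat peak.
beatMorphology <- function(ecg, fs, beatIdx, winS = 0.3) {
  k <- max(3, round(fs * 0.6))
  if (k %% 2 == 0) k <- k + 1
  x <- ecg - stats::runmed(ecg, k)
  half <- round(winS * fs / 2)
  n <- length(x)
  win <- t(vapply(beatIdx, function(i) {
    lo <- i - half; hi <- i + half
    out <- numeric(2 * half + 1)
    src <- max(1, lo):min(n, hi)
    out[src - lo + 1] <- x[src]
    out
  }, numeric(2 * half + 1)))
  list(windows = win, amp = abs(x[beatIdx]), x = x, half = half)
}

# width (ms) of the deflection around the window center at absolute level
widthAtLevel <- function(window, center, level, fs) {
  p <- window * sign(window[center])
  if (p[center] < level) return(0)
  l <- center
  while (l > 1 && p[l - 1] >= level) l <- l - 1
  r <- center
  while (r < length(p) && p[r + 1] >= level) r <- r + 1
  (r - l + 1) * 1000 / fs
}

#' Two-stage rule-based PVC detection
#'
#' Stage 1 flags a beat as a PVC candidate when at least two of three
#' morphological rules fire: QRS width above `widthMs` (measured at half the
#' beat's peak amplitude), absolute amplitude above `ampFactor` times the
#' median beat amplitude, and correlation with the median beat template below
#' `corrMin`.
#'
#' Stage 2 rejects false positives. A solitary candidate whose morphology
#' closely aligns with the median beat (correlation at or above `corrMin`) is
#' reclassified as non-PVC. With multiple candidates, each candidate's width
#' `cW` is measured at three-fourths the height of the smallest candidate; a
#' candidate is kept as an ectopic PVC only if its morphology deviation
#' (1 - correlation with the median beat) exceeds the median deviation of all
#' beats and its `cW` exceeds that of the median-beat template at the same
#' level, i.e. it is both considerably deviant and wider than a normal beat.
#'
#' @param ecg numeric ECG samples.
#' @param fs sampling rate in Hz.
#' @param beats a [BeatSeries-class] of detected beats.
#' @param widthMs stage-1 QRS width threshold (ms), default 120.
#' @param ampFactor stage-1 amplitude factor, default 1.5.
#' @param corrMin stage-1/2 correlation threshold, default 0.9.
#' @param minBeats minimum beats for a stable median template, default 10;
#'   below this all labels are `"X"`.
#' @return The [BeatSeries-class] with labels `"N"`/`"V"` assigned (or all
#'   `"X"` when too few beats).
#' @export
detectPvc <- function(ecg, fs, beats, widthMs = 120, ampFactor = 1.5,
                      corrMin = 0.9, minBeats = 10) {
  tms <- beatTimes(beats)
  nb <- length(tms)
  if (nb < minBeats)
    return(beatSeries(tms, rep("X", nb), source = "ecg"))
  idx <- pmin(length(ecg), pmax(1, round(tms * fs) + 1))
  mo <- beatMorphology(ecg, fs, idx)
  center <- mo$half + 1
  template <- apply(mo$windows, 2, stats::median)
  corr <- vapply(seq_len(nb), function(i) {
    w <- mo$windows[i, ]
    if (stats::sd(w) == 0 || stats::sd(template) == 0) return(0)
    stats::cor(w, template)
  }, numeric(1))
  width <- vapply(seq_len(nb), function(i)
    widthAtLevel(mo$windows[i, ], center, 0.5 * mo$amp[i], fs), numeric(1))
  medAmp <- stats::median(mo$amp)
  score <- (width > widthMs) + (mo$amp > ampFactor * medAmp) + (corr < corrMin)
  # beats whose morphology window is truncated at the record edge have
  # unreliable features and are never candidates
  edge <- idx - mo$half < 1 | idx + mo$half > length(ecg)
  score[edge] <- 0
  cand <- which(score >= 2)
  labels <- rep("N", nb)
  if (length(cand) == 1) {
    if (corr[cand] < corrMin) labels[cand] <- "V"
  } else if (length(cand) > 1) {
    level <- 0.75 * min(mo$amp[cand])
    cW <- vapply(cand, function(i)
      widthAtLevel(mo$windows[i, ], center, level, fs), numeric(1))
    cwTemplate <- widthAtLevel(template, center, level, fs)
    deviation <- 1 - corr
    devMed <- stats::median(deviation)
    keep <- deviation[cand] > devMed & cW > cwTemplate
    labels[cand[keep]] <- "V"
  }
  beatSeries(tms, labels, source = "ecg")
}

#' Beat-level detection performance metrics
#'
#' Predicted and reference beats are matched within `tolS` seconds; the
#' positive class is the PVC label `"V"`. Sensitivity, specificity, accuracy
#' and F1 follow the standard confusion-matrix definitions, with unmatched
#' reference positives counted as false negatives and unmatched predicted
#' positives as false positives.
#'
#' @param pred predicted [BeatSeries-class] (or character label vector).
#' @param truth reference [BeatSeries-class] (or character label vector of the
#'   same length as `pred`).
#' @param tolS matching tolerance in seconds, default 0.15.
#' @return List with `Sen`, `Spec`, `Acc`, `F1` and the confusion counts.
#' @examples
#' detectionMetrics(rep(c("V", "N"), c(9, 90)),
#'                  rep(c("V", "N", "V"), c(8, 90, 1)))
#' @export
detectionMetrics <- function(pred, truth, tolS = 0.15) {
  if (is.character(pred) && is.character(truth)) {
    stopifnot(length(pred) == length(truth))
    tp <- sum(pred == "V" & truth == "V")
    fp <- sum(pred == "V" & truth != "V")
    fn <- sum(pred != "V" & truth == "V")
    tn <- sum(pred != "V" & truth != "V")
  } else {
    pt <- beatTimes(pred); pl <- beatLabels(pred)
    tt <- beatTimes(truth); tl <- beatLabels(truth)
    pairs <- matchEvents(tt, pt, tolS)
    tp <- fp <- fn <- tn <- 0
    matchedP <- rep(FALSE, length(pt))
    for (r in seq_len(nrow(pairs))) {
      iT <- pairs[r, 1]; iP <- pairs[r, 2]
      matchedP[iP] <- TRUE
      if (tl[iT] == "V" && pl[iP] == "V") tp <- tp + 1
      else if (tl[iT] == "V") fn <- fn + 1
      else if (pl[iP] == "V") fp <- fp + 1
      else tn <- tn + 1
    }
    fn <- fn + sum(tl == "V") - sum(tl[pairs[, 1]] == "V")
    fp <- fp + sum(pl == "V" & !matchedP)
  }
  list(Sen = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       Spec = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       Acc = (tp + tn) / max(1, tp + tn + fp + fn),
       F1 = if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NA_real_,
       TP = tp, FP = fp, FN = fn, TN = tn)
}
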