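# Welch-averaged spectra of two equal-length uniform series.
welchCross <- function(x, y, fs, segLengthS = 120, overlap = 0.5) {
  n <- length(x)
  L <- round(segLengthS * fs)
  step <- max(1, round(L * (1 - overlap)))
  starts <- seq(1, n - L + 1, by = step)
  if (n < L) stopWith("autonomiq_input_error", "record too short for one segment")
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, L - 1) / (L - 1))   # Hann
  nf <- floor(L / 2)
  Sxx <- Syy <- numeric(nf)
  Sxy <- complex(nf)
  for (s0 in starts) {
    xi <- x[s0:(s0 + L - 1)]; yi <- y[s0:(s0 + L - 1)]
    xi <- (xi - mean(xi)) * w; yi <- (yi - mean(yi)) * w
    X <- stats::fft(xi)[2:(nf + 1)]
    Y <- stats::fft(yi)[2:(nf + 1)]
    Sxx <- Sxx + Mod(X)^2
    Syy <- Syy + Mod(Y)^2
    Sxy <- Sxy + X * Conj(Y)
  }
  list(freq = (1:nf) * fs / L, Sxx = Sxx, Syy = Syy, Sxy = Sxy,
       nSegments = length(starts))
}

#' Magnitude-squared coherence between two uniform series (Welch)
#'
#' @param x,y equal-length numeric series.
#' @param fs sampling rate in Hz.
#' @param segLengthS Welch segment length in seconds (default 120).
#' @param overlap fractional segment overlap (default 0.5, Hann window).
#' @return List with `freq`, `coherence` (pointwise in \[0, 1\]) and
#'   `nSegments`.
#' @export
msCoherence <- function(x, y, fs, segLengthS = 120, overlap = 0.5) {
  s <- welchCross(x, y, fs, segLengthS, overlap)
  coh <- Mod(s$Sxy)^2 / (s$Sxx * s$Syy)
  coh[!is.finite(coh)] <- 0
  list(freq = s$freq, coherence = pmin(1, coh), nSegments = s$nSegments)
}

#' Coherence between pulse rate variability and blood pressure variability
#'
#' The pulse-to-pulse interval series and the systolic pressure series from
#' the ABP fiducials are each cubic-interpolated onto a uniform grid
#' (default 4 Hz), smoothed by a Gaussian kernel whose -3 dB point lies at
#' `gaussCutHz` on the continuous representation (at the default 10 Hz the
#' kernel is far narrower than the 4-Hz sample spacing and acts as identity on
#' the beat-derived variability content), and compared by Welch
#' magnitude-squared coherence (120-s segments, 50% overlap, Hann). Band
#' means are reported over the LF and HF bands.
#'
#' @param abpBeats an ABP [BeatSeries-class] carrying `sbp` values.
#' @param gridHz uniform resampling rate, default 4 Hz.
#' @param gaussCutHz Gaussian -3 dB frequency, default 10 Hz.
#' @param segLengthS,overlap Welch parameters.
#' @param lfBand,hfBand band edges in Hz.
#' @param minSpanS minimum beat span (default 300 s, i.e. 5 min).
#' @return List with `freq`, `coherence`, `lf_mean`, `hf_mean`, `nSegments`.
#' @export
prvBpvCoherence <- function(abpBeats, gridHz = 4, gaussCutHz = 10,
                            segLengthS = 120, overlap = 0.5,
                            lfBand = c(0.04, 0.15), hfBand = c(0.15, 0.4),
                            minSpanS = 300) {
  ppi <- deriveIntervals(abpBeats, kind = "PPI")
  t <- intervalTimes(ppi)
  if (length(t) < 2 || diff(range(t)) < minSpanS)
    stopWith("autonomiq_input_error", "record too short for coherence analysis")
  grid <- seq(min(t), max(t), by = 1 / gridHz)
  xi <- stats::spline(t, intervalValues(ppi), xout = grid)$y
  yi <- stats::spline(t, pairedSbp(ppi), xout = grid)$y
  xi <- gaussSmooth(xi, gridHz, gaussCutHz)
  yi <- gaussSmooth(yi, gridHz, gaussCutHz)
  coh <- msCoherence(xi, yi, gridHz, segLengthS, overlap)
  bandMean <- function(lo, hi) {
    inb <- coh$freq >= lo & coh$freq <= hi
    if (!any(inb)) NA_real_ else mean(coh$coherence[inb])
  }
  c(coh, list(lf_mean = bandMean(lfBand[1], lfBand[2]),
              hf_mean = bandMean(hfBand[1], hfBand[2])))
}

# Gaussian low-pass with -3 dB point at cutHz on the continuous representation.
# sigma solves exp(-2 pi^2 sigma^2 f^2) = 1/sqrt(2) at f = cutHz; when sigma is
# far below the sample spacing the discretized kernel is a unit impulse.
gaussSmooth <- function(x, fs, cutHz) {
  sigma <- sqrt(log(sqrt(2)) / (2 * pi^2 * cutHz^2))
  half <- max(1L, ceiling(4 * sigma * fs))
  k <- exp(-0.5 * ((-half:half) / (sigma * fs))^2)
  k <- k / sum(k)
  if (length(k) == 3 && k[2] > 0.999) return(x)    # effectively identity
  pad <- c(rep(x[1], half), x, rep(x[length(x)], half))
  as.numeric(stats::filter(pad, k, sides = 2))[(half + 1):(half + length(x))]
}
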