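#' Root mean square of successive differences (RMSSD)
#'
#' Successive differences are taken only across temporally adjacent interval
#' pairs: when ectopy-adjacent intervals have been excluded from an RR series,
#' the gap breaks adjacency and no difference is formed across it (interval
#' `j+1` is adjacent to `j` only when it starts where `j` ended).
#'
#' @param intervals an [IntervalSeries-class] (or numeric vector of interval
#'   values in ms, treated as fully adjacent).
#' @param minIntervals minimum usable intervals, default 3; below this the
#'   result is `NA` (missing, not 0).
#' @return RMSSD in ms.
#' @examples
#' rmssd(c(800, 850, 800))   # 50
#' @export
rmssd <- function(intervals, minIntervals = 3) {
  if (methods::is(intervals, "IntervalSeries")) {
    v <- intervalValues(intervals)
    t <- intervalTimes(intervals)
    if (length(v) < minIntervals) return(NA_real_)
    adj <- abs(diff(t) * 1000 - v[-1]) < 1    # within 1 ms: contiguous
    d <- diff(v)[adj]
  } else {
    v <- as.numeric(intervals)
    if (length(v) < minIntervals) return(NA_real_)
    d <- diff(v)
  }
  if (!length(d)) return(NA_real_)
  sqrt(mean(d^2))
}

#' Lomb-Scargle power spectral density of a beat-interval series
#'
#' Classical Lomb periodogram (with the tau phase shift) of the mean-subtracted
#' interval values at their irregular beat times, chosen precisely because
#' beat-interval samples are non-uniformly spaced in time and need no
#' interpolation. The periodogram is scaled to a one-sided density
#' (ms^2/Hz) such that the integral over frequency approximates the series
#' variance. Band powers are obtained by trapezoidal integration over the LF
#' band \[0.04, 0.15) Hz and HF band \[0.15, 0.4\] Hz (half-open at the
#' shared edge).
#'
#' @param intervals an [IntervalSeries-class].
#' @param fmin,fmax,df frequency grid (Hz), default 0.003-0.5 step 0.001.
#' @param lfBand,hfBand band edges in Hz.
#' @param minIntervals minimum intervals required (default 30).
#' @param minSpanS minimum time span (default two LF periods, 50 s).
#' @param hfFloor HF power (ms^2) below which LF/HF is reported missing.
#' @return List with `freq`, `psd`, `lf_power`, `hf_power`, `total_power`,
#'   `lf_hf` and `reason` (`NA` unless the result is missing).
#' @export
lombPsd <- function(intervals, fmin = 0.003, fmax = 0.5, df = 0.001,
                    lfBand = c(0.04, 0.15), hfBand = c(0.15, 0.4),
                    minIntervals = 30, minSpanS = 2 / 0.04, hfFloor = 1e-6) {
  t <- intervalTimes(intervals)
  x <- intervalValues(intervals)
  miss <- function(reason)
    list(freq = numeric(), psd = numeric(), lf_power = NA_real_,
         hf_power = NA_real_, total_power = NA_real_, lf_hf = NA_real_,
         reason = reason)
  if (length(x) < minIntervals) miss("too few intervals")
  else if (diff(range(t)) < minSpanS) miss("span too short")
  else {
    x <- x - mean(x)
    freq <- seq(fmin, fmax, by = df)
    w <- 2 * pi * freq
    P <- vapply(w, function(wi) {
      tau <- atan2(sum(sin(2 * wi * t)), sum(cos(2 * wi * t))) / (2 * wi)
      ct <- cos(wi * (t - tau)); st <- sin(wi * (t - tau))
      0.5 * (sum(x * ct)^2 / sum(ct^2) + sum(x * st)^2 / sum(st^2))
    }, numeric(1))
    dtbar <- diff(range(t)) / (length(t) - 1)
    psd <- 2 * dtbar * P      # one-sided density, ms^2/Hz
    band <- function(lo, hi, closed = FALSE) {
      inb <- freq >= lo & (if (closed) freq <= hi else freq < hi)
      trapz(freq[inb], psd[inb])
    }
    lf <- band(lfBand[1], lfBand[2])
    hf <- band(hfBand[1], hfBand[2], closed = TRUE)
    list(freq = freq, psd = psd, lf_power = lf, hf_power = hf,
         total_power = trapz(freq, psd),
         lf_hf = if (is.finite(hf) && hf > hfFloor) lf / hf else NA_real_,
         reason = NA_character_)
  }
}
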