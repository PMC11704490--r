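#' Construct a BeatSeries
#'
#' @param times strictly increasing beat times in seconds.
#' @param labels per-beat labels `"N"`, `"V"` or `"X"` (recycled if scalar).
#' @param source `"ecg"` or `"abp"`.
#' @param sbp optional systolic pressure (mmHg) per beat.
#' @return A [BeatSeries-class].
#' @export
beatSeries <- function(times, labels = "N", source = "ecg", sbp = NULL) {
  n <- length(times)
  if (length(labels) == 1) labels <- rep(labels, n)
  if (is.null(sbp)) sbp <- rep(NA_real_, n)
  methods::new("BeatSeries", times = as.numeric(times),
               labels = as.character(labels), source = source,
               sbp = as.numeric(sbp))
}

#' @rdname beatTimes
#' @export
setMethod("beatTimes", "BeatSeries", function(x) x@times)

#' @rdname beatTimes
#' @export
setMethod("beatLabels", "BeatSeries", function(x) x@labels)

#' @rdname beatTimes
#' @export
setMethod("beatSbp", "BeatSeries", function(x) x@sbp)

setMethod("show", "BeatSeries", function(object) {
  tab <- table(factor(object@labels, levels = c("N", "V", "X")))
  cat(sprintf("BeatSeries (%s): %d beats [N=%d V=%d X=%d]",
              object@source, length(object@times), tab["N"], tab["V"],
              tab["X"]))
  if (length(object@times))
    cat(sprintf(", %.1f-%.1f s", object@times[1],
                object@times[length(object@times)]))
  cat("\n")
})

#' Construct an IntervalSeries
#'
#' @param t times (s) of each interval's terminating beat.
#' @param value interval lengths in ms.
#' @param kind `"RR"` or `"PPI"`.
#' @param sbp optional aligned systolic pressures.
#' @return An [IntervalSeries-class].
#' @export
intervalSeries <- function(t, value, kind = "RR", sbp = NULL) {
  if (is.null(sbp)) sbp <- rep(NA_real_, length(t))
  methods::new("IntervalSeries", t = as.numeric(t), value = as.numeric(value),
               kind = kind, sbp = as.numeric(sbp))
}

#' @rdname intervalTimes
#' @export
setMethod("intervalTimes", "IntervalSeries", function(x) x@t)

#' @rdname intervalTimes
#' @export
setMethod("intervalValues", "IntervalSeries", function(x) x@value)

#' @rdname intervalTimes
#' @export
setMethod("pairedSbp", "IntervalSeries", function(x) x@sbp)

#' @rdname intervalTimes
#' @export
setMethod("intervalKind", "IntervalSeries", function(x) x@kind)

setMethod("show", "IntervalSeries", function(object) {
  cat(sprintf("IntervalSeries (%s): %d intervals", object@kind,
              length(object@t)))
  if (length(object@t))
    cat(sprintf(", mean %.0f ms, %d paired sBP", mean(object@value),
                sum(is.finite(object@sbp))))
  cat("\n")
})

#' Derive inter-beat intervals from a beat series
#'
#' For `kind = "RR"` (the default for ECG sources) an interval is formed only
#' between consecutive beats that are both sinus (`"N"`); any pair touching a
#' `"V"` or `"X"` beat is omitted, so ectopy-adjacent intervals never enter
#' HRV/BRS statistics. For `kind = "PPI"` (ABP sources) all consecutive
#' fiducial pairs are used and the terminating beat's systolic pressure is
#' carried along. Each interval is timestamped at its terminating beat.
#'
#' @param beats a [BeatSeries-class].
#' @param kind `"RR"` or `"PPI"`; defaults by source.
#' @return An [IntervalSeries-class] (empty when fewer than 2 usable beats).
#' @examples
#' b <- beatSeries(c(0, 0.8, 1.6), labels = c("N", "N", "N"))
#' intervalValues(deriveIntervals(b))   # 800 800
#' @export
deriveIntervals <- function(beats, kind = NULL) {
  if (is.null(kind)) kind <- if (beats@source == "abp") "PPI" else "RR"
  t <- beatTimes(beats)
  lab <- beatLabels(beats)
  if (length(t) < 2) return(intervalSeries(numeric(), numeric(), kind = kind))
  keep <- if (kind == "RR") lab[-length(lab)] == "N" & lab[-1] == "N"
          else rep(TRUE, length(t) - 1)
  dt <- diff(t) * 1000
  sbp <- beatSbp(beats)[-1]
  intervalSeries(t[-1][keep], dt[keep], kind = kind, sbp = sbp[keep])
}

#' Pair RR intervals with systolic blood pressures
#'
#' Each RR interval is paired with the systolic pressure of the ABP pulse
#' whose fiducial is nearest the interval's terminating beat, within
#' `tolS` seconds. Unpaired intervals are dropped (they cannot contribute to
#' baroreflex analysis).
#'
#' @param rr an RR [IntervalSeries-class].
#' @param abpBeats an ABP [BeatSeries-class] carrying `sbp` values.
#' @param tolS pairing tolerance in seconds (default 0.5).
#' @return An [IntervalSeries-class] containing only paired intervals.
#' @export
alignRrSbp <- function(rr, abpBeats, tolS = 0.5) {
  tA <- beatTimes(abpBeats)
  sA <- beatSbp(abpBeats)
  tR <- intervalTimes(rr)
  if (!length(tR) || !length(tA))
    return(intervalSeries(numeric(), numeric(), kind = intervalKind(rr)))
  idx <- vapply(tR, function(x) which.min(abs(tA - x)), integer(1))
  ok <- abs(tA[idx] - tR) <= tolS & is.finite(sA[idx])
  intervalSeries(tR[ok], intervalValues(rr)[ok], kind = intervalKind(rr),
                 sbp = sA[idx][ok])
}

#' Restrict a beat or interval series to a time window
#'
#' @param x a [BeatSeries-class] or [IntervalSeries-class].
#' @param startS,endS window bounds in seconds (half-open, `[startS, endS)`).
#' @return Object of the same class restricted to the window.
#' @export
windowSeries <- function(x, startS, endS) {
  if (methods::is(x, "BeatSeries")) {
    keep <- x@times >= startS & x@times < endS
    beatSeries(x@times[keep], x@labels[keep], x@source, x@sbp[keep])
  } else {
    keep <- x@t >= startS & x@t < endS
    intervalSeries(x@t[keep], x@value[keep], x@kind, x@sbp[keep])
  }
}
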