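#' Baroreflex sensitivity by phase-rectified signal averaging (PRSA)
#'
#' Anchor points are the beats at which the systolic pressure strictly
#' increases over the preceding beat (equal values are not anchors); anchors
#' within `L` beats of either edge are excluded so every segment has full
#' margins. RR segments of length `2L + 1` are aligned at the anchors and
#' averaged into the PRSA signal
#' \deqn{X(l) = \frac{1}{P}\sum_{p=1}^{P} RR_{n_p + l}, \quad l = -L..L,}
#' and the sensitivity is the quarter-sum
#' \deqn{BRS = \tfrac{1}{4}(X_0 + X_1 - X_{-1} - X_{-2}).}
#'
#' @param rr an [IntervalSeries-class] with paired systolic pressures (from
#'   [alignRrSbp()] or the generator), or a numeric RR vector if `sbp` given.
#' @param L segment half-length in beats (default 15).
#' @param sbp numeric systolic pressures, required when `rr` is a vector.
#' @return List with `brs` (ms per anchor step), `profile` (X(l)), `offsets`
#'   (l), `nAnchors`, `reason` (`NA` unless missing).
#' @examples
#' sbp <- 100 + seq_len(200)            # rising ramp, every beat an anchor
#' prsaBrs(10 * sbp + 100, sbp = sbp)$brs   # 10
#' @export
prsaBrs <- function(rr, L = 15, sbp = NULL) {
  if (methods::is(rr, "IntervalSeries")) {
    sbp <- pairedSbp(rr)
    rr <- intervalValues(rr)
  }
  stopifnot(length(rr) == length(sbp))
  keep <- is.finite(rr) & is.finite(sbp)
  rr <- rr[keep]; sbp <- sbp[keep]
  n <- length(rr)
  miss <- function(reason)
    list(brs = NA_real_, profile = rep(NA_real_, 2 * L + 1),
         offsets = -L:L, nAnchors = 0L, reason = reason)
  if (n < 2 * L + 1) return(miss("series shorter than one PRSA window"))
  anchors <- which(c(FALSE, diff(sbp) > 0))
  anchors <- anchors[anchors > L & anchors <= n - L]
  if (!length(anchors)) return(miss("no anchor points"))
  profile <- vapply(-L:L, function(l) mean(rr[anchors + l]), numeric(1))
  names(profile) <- -L:L
  x <- function(l) profile[as.character(l)]
  list(brs = unname((x(0) + x(1) - x(-1) - x(-2)) / 4),
       profile = profile, offsets = -L:L, nAnchors = length(anchors),
       reason = NA_character_)
}
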