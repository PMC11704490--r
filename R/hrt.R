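#' Extract heart-rate-turbulence events around PVCs
#'
#' For each isolated `"V"` beat the surrounding context is assembled: the
#' coupling interval (preceding sinus beat to the PVC), the compensatory
#' interval (PVC to the next sinus beat), the two sinus RR intervals
#' immediately preceding the coupling interval, and the first `nPost` sinus RR
#' intervals after the compensatory interval. An event is eligible when all
#' context beats are sinus, at least 2 pre and `nPost` post intervals exist,
#' the coupling interval is shorter than the preceding sinus RR and the
#' compensatory interval is longer than it.
#'
#' @param beats a labeled [BeatSeries-class].
#' @param nPost required post-compensatory sinus RR intervals (default 15).
#' @param strict when `TRUE`, additionally apply the classical +/-20%
#'   reference-interval filters (coupling interval < 80% and compensatory
#'   interval > 120% of the reference RR).
#' @return List of events, each with `index`, `couplI_ms`, `compI_ms`,
#'   `pre_ms` (RR-2, RR-1), `post_ms` (RR1..), `eligible`, `reason`.
#' @seealso [hrtOnset()], [hrtSlope()], [segmentHrt()]
#' @export
hrtEvents <- function(beats, nPost = 15, strict = FALSE) {
  t <- beatTimes(beats)
  lab <- beatLabels(beats)
  out <- list()
  for (i in which(lab == "V")) {
    ev <- list(index = i, couplI_ms = NA_real_, compI_ms = NA_real_,
               pre_ms = c(NA_real_, NA_real_), post_ms = numeric(),
               eligible = FALSE, reason = NA_character_)
    if (i < 4 || i + nPost + 1 > length(t)) {
      ev$reason <- "insufficient context"
      out <- c(out, list(ev)); next
    }
    preIdx <- (i - 3):(i - 1)
    postIdx <- (i + 1):(i + nPost + 1)
    if (any(lab[preIdx] != "N")) { ev$reason <- "non-sinus pre context" }
    else if (any(lab[postIdx] != "N")) { ev$reason <- "non-sinus post context" }
    ev$couplI_ms <- (t[i] - t[i - 1]) * 1000
    ev$compI_ms <- (t[i + 1] - t[i]) * 1000
    ev$pre_ms <- c((t[i - 2] - t[i - 3]) * 1000,   # RR-2
                   (t[i - 1] - t[i - 2]) * 1000)   # RR-1
    ev$post_ms <- diff(t[(i + 1):(i + nPost + 1)]) * 1000
    if (is.na(ev$reason)) {
      refRR <- ev$pre_ms[2]
      if (!(ev$couplI_ms < refRR)) ev$reason <- "coupling interval not premature"
      else if (!(ev$compI_ms > refRR)) ev$reason <- "no compensatory pause"
      else if (strict && !(ev$couplI_ms < 0.8 * refRR &&
                           ev$compI_ms > 1.2 * refRR))
        ev$reason <- "fails strict reference-interval filter"
      else ev$eligible <- TRUE
    }
    out <- c(out, list(ev))
  }
  out
}

#' Turbulence onset (TO) of an HRT event
#'
#' \deqn{TO = 100 \cdot \frac{(RR_1 + RR_2) - (RR_{-2} + RR_{-1})}
#'   {RR_{-2} + RR_{-1}}}
#' where \eqn{RR_1, RR_2} are the two sinus RR intervals immediately after the
#' compensatory interval and \eqn{RR_{-2}, RR_{-1}} the two immediately before
#' the coupling interval. Negative TO indicates post-ectopic early
#' acceleration (the normal response).
#'
#' @param event one event from [hrtEvents()].
#' @return TO in percent, or `NA` for an ineligible event.
#' @export
hrtOnset <- function(event) {
  if (!isTRUE(event$eligible)) return(NA_real_)
  pre <- sum(event$pre_ms)
  100 * (sum(event$post_ms[1:2]) - pre) / pre
}

#' Turbulence slope (TS) of an HRT event
#'
#' The maximum least-squares regression slope over any 5 consecutive sinus RR
#' intervals within the first 15 intervals after the compensatory interval
#' (11 candidate windows). The maximum may be negative when every window
#' slopes downward.
#'
#' @param event one event from [hrtEvents()].
#' @param windowLen regression window length (default 5).
#' @param nPost intervals considered after the compensatory interval (15).
#' @return TS in ms per RR interval, or `NA` for an ineligible event.
#' @export
hrtSlope <- function(event, windowLen = 5, nPost = 15) {
  if (!isTRUE(event$eligible)) return(NA_real_)
  post <- event$post_ms[seq_len(min(nPost, length(event$post_ms)))]
  if (length(post) < windowLen) return(NA_real_)
  starts <- seq_len(length(post) - windowLen + 1)
  max(vapply(starts, function(s) lsSlope(post[s:(s + windowLen - 1)]),
             numeric(1)))
}

#' Segment-level heart rate turbulence
#'
#' HRT is computed only when the number of detected PVCs in the segment
#' exceeds `minPvc` (default 10, i.e. analysis requires more than 10 PVC
#' beats). Events failing context eligibility are excluded from the means;
#' when no eligible event remains the result is missing with a reason.
#'
#' @param beats a labeled [BeatSeries-class] for one segment.
#' @param minPvc PVC-count gate: analysis runs only when `n_pvc > minPvc`.
#' @param nPost required post-compensatory intervals per event.
#' @param strict passed to [hrtEvents()].
#' @return List with `skipped`, `reason`, `n_pvc`, `n_events`, `to_pct`
#'   (mean TO), `ts_ms_per_beat` (mean TS).
#' @export
segmentHrt <- function(beats, minPvc = 10, nPost = 15, strict = FALSE) {
  nPvc <- sum(beatLabels(beats) == "V")
  base <- list(skipped = TRUE, reason = NA_character_, n_pvc = nPvc,
               n_events = 0L, to_pct = NA_real_, ts_ms_per_beat = NA_real_)
  if (nPvc <= minPvc) {
    base$reason <- sprintf("PVC count %d not above gate %d", nPvc, minPvc)
    return(base)
  }
  events <- hrtEvents(beats, nPost = nPost, strict = strict)
  eligible <- Filter(function(e) isTRUE(e$eligible), events)
  if (!length(eligible)) {
    base$skipped <- FALSE
    base$reason <- "no eligible HRT events"
    return(base)
  }
  list(skipped = FALSE, reason = NA_character_, n_pvc = nPvc,
       n_events = length(eligible),
       to_pct = mean(vapply(eligible, hrtOnset, numeric(1))),
       ts_ms_per_beat = mean(vapply(eligible, hrtSlope, numeric(1))))
}
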