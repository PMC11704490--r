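#' Aggregate per-segment indices to the subject level
#'
#' Aggregates the five autonomic indices across quality-passing segments in a
#' time window. The default statistic is the median (robust to residual
#' artifacts); the mean is available. The HRT index is the turbulence slope,
#' with turbulence onset carried as an auxiliary value. An index missing in
#' every contributing segment stays missing.
#'
#' @param segTable data.frame of per-segment indices with columns
#'   `rmssd`, `hrt_ts`, `brs`, `lf_power`, `lf_hf` (optionally `to_pct`) and
#'   logical `quality_pass`; rows are segments.
#' @param statistic `"median"` or `"mean"`.
#' @return List with per-index values, `to_pct`, and `n_segments`; `NULL`
#'   values signal an unclassifiable subject (zero passing segments).
#' @export
aggregateSubject <- function(segTable, statistic = c("median", "mean")) {
  statistic <- match.arg(statistic)
  fun <- if (statistic == "median") stats::median else mean
  pass <- if ("quality_pass" %in% names(segTable)) segTable$quality_pass
          else rep(TRUE, nrow(segTable))
  sub <- segTable[isTRUE0(pass), , drop = FALSE]
  if (!nrow(sub))
    return(list(values = NULL, to_pct = NA_real_, n_segments = 0L))
  agg <- function(col) {
    if (!col %in% names(sub)) return(NA_real_)
    v <- sub[[col]][is.finite(sub[[col]])]
    if (!length(v)) NA_real_ else fun(v)
  }
  values <- stats::setNames(vapply(eadIndices(), agg, numeric(1)),
                            eadIndices())
  list(values = values, to_pct = agg("to_pct"), n_segments = nrow(sub))
}

isTRUE0 <- function(x) !is.na(x) & x

#' Standardize an index value against a reference stratum
#'
#' @param value index value.
#' @param stratum list with `mean` and `sd` (from [lookupStratum()]).
#' @return z-score `(value - mean) / sd`.
#' @examples
#' standardizeIndex(10, list(mean = 47, sd = 14))   # about -2.64
#' @export
standardizeIndex <- function(value, stratum) (value - stratum$mean) / stratum$sd

#' Flag an abnormal z-score
#'
#' Two-sided, strictly exclusive boundary: a value is abnormal only when it
#' exceeds or falls below `threshold` standard deviations, i.e.
#' `|z| > threshold`. Missing z-scores are non-abnormal (conservative).
#'
#' @param z z-score.
#' @param threshold abnormality threshold in SD units (default 2.5).
#' @return Logical.
#' @export
flagAbnormal <- function(z, threshold = 2.5) {
  !is.na(z) & abs(z) > threshold
}

#' Build a standardized subject index profile
#'
#' @param values named per-index values (names [eadIndices()]).
#' @param age,sex subject age (years) and sex (`"F"`/`"M"`).
#' @param ranges a `referenceRanges` table.
#' @param threshold abnormality threshold (SD), default 2.5.
#' @return data.frame with columns `index`, `value`, `z`, `abnormal`,
#'   `direction` (`low`/`high`/`NA`, reported but not used by the
#'   classification rule).
#' @export
indexProfile <- function(values, age, sex, ranges = defaultReferenceRanges(),
                         threshold = 2.5) {
  rows <- lapply(eadIndices(), function(ix) {
    v <- if (ix %in% names(values)) values[[ix]] else NA_real_
    z <- if (is.na(v)) NA_real_
         else standardizeIndex(v, lookupStratum(ranges, age, sex, ix))
    data.frame(index = ix, value = v, z = z,
               abnormal = flagAbnormal(z, threshold),
               direction = if (is.na(z)) NA_character_
                           else if (z < 0) "low" else "high")
  })
  do.call(rbind, rows)
}

#' Composite classification of early autonomic dysfunction
#'
#' Counts abnormal indices among the five and classifies the subject when at
#' least `minCount` (default 3 of 5) are abnormal. Continuous z-scores are
#' retained in the profile for use as continuous measures.
#'
#' @param profile data.frame from [indexProfile()].
#' @param minCount abnormal-index count required for classification.
#' @return List with `abnormal_count`, `classified`, `contributions`
#'   (abnormal index names) and the `profile`.
#' @export
characterizeEad <- function(profile, minCount = 3) {
  cnt <- sum(profile$abnormal, na.rm = TRUE)
  list(abnormal_count = cnt, classified = cnt >= minCount,
       contributions = profile$index[isTRUE0(profile$abnormal)],
       profile = profile)
}

#' Daily trajectory of autonomic indices
#'
#' Applies [aggregateSubject()] per 24-h day bin over the first `days` days;
#' days without passing segments yield missing profiles.
#'
#' @param segTable per-segment index table with a `start_s` column (seconds
#'   from admission) plus the columns required by [aggregateSubject()].
#' @param days number of day bins (default 5).
#' @param statistic aggregation statistic.
#' @return List of per-day aggregation results (as from [aggregateSubject()]),
#'   each with a `day` element.
#' @export
dailyTrajectory <- function(segTable, days = 5,
                            statistic = c("median", "mean")) {
  statistic <- match.arg(statistic)
  lapply(seq_len(days), function(d) {
    lo <- (d - 1) * 86400; hi <- d * 86400
    sub <- segTable[segTable$start_s >= lo & segTable$start_s < hi, ,
                    drop = FALSE]
    out <- aggregateSubject(sub, statistic)
    out$day <- d
    out
  })
}
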