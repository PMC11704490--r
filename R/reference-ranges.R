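#' Index names of the composite autonomic profile
#'
#' The five subject-level indices entering the composite classification:
#' RMSSD (ms), heart rate turbulence operationalized as the turbulence slope
#' (ms/beat, with turbulence onset kept as an auxiliary column), PRSA
#' baroreflex sensitivity, LF power (ms^2) and the LF/HF ratio.
#'
#' @return Character vector of index names.
#' @export
eadIndices <- function() c("rmssd", "hrt_ts", "brs", "lf_power", "lf_hf")

#' Read an age/sex-stratified reference-range table
#'
#' CSV with columns `age_lo,age_hi,sex,index,mean,sd,source`; each (age bin,
#' sex) stratum must cover all five indices with positive SDs.
#'
#' @param path CSV path; the packaged synthetic default is used when omitted.
#' @return data.frame of class `referenceRanges`.
#' @seealso [defaultReferenceRanges()], [standardizeIndex()]
#' @export
readReferenceRanges <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "reference_ranges_synthetic.csv",
                        package = "autonomiq", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("age_lo", "age_hi", "sex", "index", "mean", "sd", "source")
  if (!all(need %in% names(tab)))
    stopWith("autonomiq_format_error", "reference table missing columns")
  if (any(tab$sd <= 0))
    stopWith("autonomiq_format_error", "reference SDs must be positive")
  strata <- unique(tab[c("age_lo", "age_hi", "sex")])
  for (r in seq_len(nrow(strata))) {
    idx <- tab$index[tab$age_lo == strata$age_lo[r] &
                     tab$sex == strata$sex[r]]
    if (!all(eadIndices() %in% idx))
      stopWith("autonomiq_format_error",
               "every stratum must cover all five indices")
  }
  class(tab) <- c("referenceRanges", "data.frame")
  tab
}

#' Packaged synthetic reference ranges
#'
#' A synthetic stand-in normative table (decade age bins 20-89, both sexes).
#' RMSSD, turbulence-slope and BRS entries are derived from published normal
#' ranges (RMSSD 19-75 ms; TS above 2.5 ms/beat; BRS 4.87-34.07) read as
#' mean +/- 2 SD; LF power and LF/HF entries are plausible placeholders. The
#' table is explicitly not a clinically validated normative source - replace
#' it with study-appropriate norms via [readReferenceRanges()].
#'
#' @return data.frame of class `referenceRanges`.
#' @export
defaultReferenceRanges <- function() readReferenceRanges()

#' Look up one stratum entry of a reference table
#'
#' @param ranges a `referenceRanges` table.
#' @param age subject age in years.
#' @param sex `"F"` or `"M"`.
#' @param index one of [eadIndices()].
#' @return List with `mean` and `sd`.
#' @export
lookupStratum <- function(ranges, age, sex, index) {
  hit <- ranges$age_lo <= age & age < ranges$age_hi &
    ranges$sex == sex & ranges$index == index
  if (!any(hit)) {
    # fall back to the nearest age bin for out-of-table ages
    sub <- ranges[ranges$sex == sex & ranges$index == index, ]
    if (!nrow(sub))
      stopWith("autonomiq_input_error",
               sprintf("no reference entry for sex=%s index=%s", sex, index))
    d <- pmax(sub$age_lo - age, age - sub$age_hi, 0)
    sub <- sub[which.min(d), ]
    return(list(mean = sub$mean, sd = sub$sd))
  }
  row <- ranges[which(hit)[1], ]
  list(mean = row$mean, sd = row$sd)
}
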