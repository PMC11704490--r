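#' WaveformRecord: multi-channel sampled physiological signals
#'
#' Container for synchronously sampled ECG and arterial blood pressure (ABP)
#' channels sharing one sampling rate. Channels carry a role (`"ecg"` or
#' `"abp"`) used by the pipeline to route them to the ECG or ABP analysis path.
#'
#' @slot signals numeric matrix, samples in rows, one column per channel.
#' @slot channels data.frame with columns `name`, `role`, `units`, one row per
#'   column of `signals`.
#' @slot fs sampling rate in Hz (scalar, > 0), shared by all channels.
#' @slot t0 record start time in seconds (offset applied to all sample times).
#'
#' @seealso [waveformRecord()], [readRecord()], [sliceSegments()]
#' @export
setClass("WaveformRecord",
  slots = c(signals = "matrix", channels = "data.frame", fs = "numeric",
            t0 = "numeric"))

setValidity("WaveformRecord", function(object) {
  msg <- character()
  if (length(object@fs) != 1 || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive number")
  if (nrow(object@signals) < 1)
    msg <- c(msg, "record must contain at least one sample")
  if (ncol(object@signals) != nrow(object@channels))
    msg <- c(msg, "channel table must have one row per signal column")
  if (!all(c("name", "role", "units") %in% names(object@channels)))
    msg <- c(msg, "channel table needs columns name, role, units")
  else if (!all(object@channels$role %in% c("ecg", "abp")))
    msg <- c(msg, "channel roles must be 'ecg' or 'abp'")
  if (length(object@t0) != 1 || !is.finite(object@t0))
    msg <- c(msg, "t0 must be a single finite number")
  if (length(msg)) msg else TRUE
})

#' BeatSeries: beat fiducial times with labels
#'
#' Ordered beat fiducial times (R peaks for ECG, systolic peaks for ABP) with
#' per-beat labels: `"N"` normal sinus, `"V"` premature ventricular
#' contraction, `"X"` unclassified. ABP-derived series additionally carry the
#' systolic pressure at each fiducial.
#'
#' @slot times numeric, strictly increasing beat times in seconds.
#' @slot labels character, one of `"N"`, `"V"`, `"X"` per beat.
#' @slot source `"ecg"` or `"abp"`.
#' @slot sbp numeric, systolic pressure (mmHg) per beat; `NA` for ECG series.
#'
#' @seealso [beatSeries()], [detectRPeaks()], [detectSystolicPeaks()],
#'   [deriveIntervals()]
#' @export
setClass("BeatSeries",
  slots = c(times = "numeric", labels = "character", source = "character",
            sbp = "numeric"))

setValidity("BeatSeries", function(object) {
  msg <- character()
  n <- length(object@times)
  if (length(object@labels) != n)
    msg <- c(msg, "labels must have the same length as times")
  if (n > 1 && any(diff(object@times) <= 0))
    msg <- c(msg, "beat times must be strictly increasing")
  if (!all(object@labels %in% c("N", "V", "X")))
    msg <- c(msg, "labels must be 'N', 'V' or 'X'")
  if (!object@source %in% c("ecg", "abp"))
    msg <- c(msg, "source must be 'ecg' or 'abp'")
  if (length(object@sbp) != n)
    msg <- c(msg, "sbp must have the same length as times")
  if (length(msg)) msg else TRUE
})

#' IntervalSeries: inter-beat intervals in milliseconds
#'
#' Interval series derived from a [BeatSeries-class]: RR intervals between
#' consecutive sinus beats (pairs touching an ectopic beat are omitted) or
#' pulse-to-pulse intervals (PPI) between consecutive ABP fiducials. Each
#' interval is timestamped at its terminating beat and may carry an aligned
#' systolic blood pressure for baroreflex analysis.
#'
#' @slot t numeric, strictly increasing times (s) of each terminating beat.
#' @slot value numeric, interval lengths in ms, all positive.
#' @slot kind `"RR"` or `"PPI"`.
#' @slot sbp numeric, aligned systolic pressures (mmHg), `NA` where unpaired.
#'
#' @seealso [intervalSeries()], [deriveIntervals()], [alignRrSbp()], [rmssd()],
#'   [lombPsd()]
#' @export
setClass("IntervalSeries",
  slots = c(t = "numeric", value = "numeric", kind = "character",
            sbp = "numeric"))

setValidity("IntervalSeries", function(object) {
  msg <- character()
  n <- length(object@t)
  if (length(object@value) != n || length(object@sbp) != n)
    msg <- c(msg, "t, value and sbp must have equal length")
  if (n > 1 && any(diff(object@t) <= 0))
    msg <- c(msg, "interval times must be strictly increasing")
  if (n > 0 && any(!is.finite(object@value) | object@value <= 0))
    msg <- c(msg, "interval values must be positive and finite")
  if (!object@kind %in% c("RR", "PPI"))
    msg <- c(msg, "kind must be 'RR' or 'PPI'")
  if (length(msg)) msg else TRUE
})

#' EcgImage: rasterized paper-format ECG
#'
#' Deterministic raster of a multi-lead ECG segment in standard paper layout
#' (25 mm/s, 10 mm/mV by default) with grid marks, one horizontal strip per
#' lead. Pixel values are in \[0, 1\] (0 background, 0.5 grid, 1 trace). Used
#' by the structural-similarity quality classifier.
#'
#' @slot pixels numeric matrix of the full stacked image.
#' @slot leadRows list of integer row ranges, one per lead strip.
#' @slot config list of render parameters (mm/s, mm/mV, px/mm, seconds, range).
#'
#' @seealso [renderEcgImage()], [ecgImageSimilarity()]
#' @export
setClass("EcgImage",
  slots = c(pixels = "matrix", leadRows = "list", config = "list"))

setValidity("EcgImage", function(object) {
  if (length(object@leadRows) < 1) return("image must contain at least one lead strip")
  TRUE
})

#' TemplateLibrary: ECG quality templates plus discriminant classifier
#'
#' Representative ECG images per quality group (`good`/`poor`), obtained by
#' agglomerative clustering on structural-similarity distance, together with a
#' linear-discriminant classifier fitted on SSIM-to-template feature vectors.
#'
#' @slot templates list of [EcgImage-class] objects.
#' @slot groups character, quality group of each template.
#' @slot lda fitted `MASS::lda` object (or `NULL` before fitting).
#' @slot featureCols integer indices of the SSIM feature columns retained for
#'   the discriminant (columns constant within groups are dropped).
#' @slot nClusters integer, clusters requested per group.
#'
#' @seealso [buildTemplates()], [classifyEcgQuality()]
#' @export
setClass("TemplateLibrary",
  slots = c(templates = "list", groups = "character", lda = "ANY",
            featureCols = "numeric", nClusters = "numeric"))

setValidity("TemplateLibrary", function(object) {
  msg <- character()
  if (length(object@templates) != length(object@groups))
    msg <- c(msg, "one group label per template required")
  if (!all(c("good", "poor") %in% object@groups))
    msg <- c(msg, "library needs at least one template per quality group")
  if (length(msg)) msg else TRUE
})

#' AbpSubspaceModel: SVD signal-subspace model for ABP pulse validation
#'
#' Signal subspace learned from a reference library of valid ABP pulses, each
#' spline-resampled to `P` points and standardized to zero mean, unit SD. The
#' acceptance threshold `tau` is the minimum signal-to-noise energy ratio over
#' the reference pulses, so every reference pulse is itself valid.
#'
#' @slot basis orthonormal P x k matrix spanning the signal subspace.
#' @slot P pulse length after resampling.
#' @slot k signal-subspace rank (smallest rank capturing `energyFraction`).
#' @slot tau acceptance threshold (minimum reference energy ratio).
#' @slot energyFraction energy fraction used to pick `k`.
#'
#' @seealso [fitAbpSubspace()], [scoreAbpPulse()]
#' @export
setClass("AbpSubspaceModel",
  slots = c(basis = "matrix", P = "numeric", k = "numeric", tau = "numeric",
            energyFraction = "numeric"))

setValidity("AbpSubspaceModel", function(object) {
  msg <- character()
  if (object@k >= object@P) msg <- c(msg, "subspace rank must be below pulse length")
  g <- crossprod(object@basis)
  if (max(abs(g - diag(ncol(object@basis)))) > 1e-8)
    msg <- c(msg, "basis must be orthonormal")
  if (!is.finite(object@tau) || object@tau <= 0)
    msg <- c(msg, "tau must be positive")
  if (length(msg)) msg else TRUE
})
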