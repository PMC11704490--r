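#' @import methods
NULL

#' Sampling rate of a waveform object
#'
#' @param x an object with a sampling rate, typically a [WaveformRecord-class].
#' @return Sampling rate in Hz.
#' @export
setGeneric("sampleRate", function(x) standardGeneric("sampleRate"))

#' Number of samples per channel
#'
#' @param x a [WaveformRecord-class].
#' @return Integer sample count.
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' Channel metadata accessors
#'
#' `channelNames`, `channelRoles` and `channelUnits` return the per-channel
#' metadata of a [WaveformRecord-class]; `channelSignal` extracts one channel's
#' sample vector by name or index.
#'
#' @param x a [WaveformRecord-class].
#' @param which channel name or index (for `channelSignal`).
#' @return Character vector (names, roles, units) or numeric sample vector.
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' @rdname channelNames
#' @export
setGeneric("channelRoles", function(x) standardGeneric("channelRoles"))

#' @rdname channelNames
#' @export
setGeneric("channelUnits", function(x) standardGeneric("channelUnits"))

#' @rdname channelNames
#' @export
setGeneric("channelSignal", function(x, which) standardGeneric("channelSignal"))

#' Beat-series accessors
#'
#' @param x a [BeatSeries-class].
#' @return `beatTimes`: numeric seconds; `beatLabels`: character vector of
#'   beat labels (`"N"` sinus, `"V"` ventricular ectopic, `"X"` unclassified);
#'   `beatSbp`: systolic pressures (mmHg) attached to ABP fiducials, `NA` when
#'   absent.
#' @export
setGeneric("beatTimes", function(x) standardGeneric("beatTimes"))

#' @rdname beatTimes
#' @export
setGeneric("beatLabels", function(x) standardGeneric("beatLabels"))

#' @rdname beatTimes
#' @export
setGeneric("beatSbp", function(x) standardGeneric("beatSbp"))

#' Interval-series accessors
#'
#' @param x an [IntervalSeries-class].
#' @return `intervalTimes`: seconds of each interval's terminating beat;
#'   `intervalValues`: interval lengths in ms; `pairedSbp`: aligned systolic
#'   pressures (mmHg, `NA` where unpaired); `intervalKind`: `"RR"` or `"PPI"`.
#' @export
setGeneric("intervalTimes", function(x) standardGeneric("intervalTimes"))

#' @rdname intervalTimes
#' @export
setGeneric("intervalValues", function(x) standardGeneric("intervalValues"))

#' @rdname intervalTimes
#' @export
setGeneric("pairedSbp", function(x) standardGeneric("pairedSbp"))

#' @rdname intervalTimes
#' @export
setGeneric("intervalKind", function(x) standardGeneric("intervalKind"))
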