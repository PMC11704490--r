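#' Construct a WaveformRecord
#'
#' @param signals numeric matrix (samples x channels) or a list of equal-length
#'   numeric vectors.
#' @param names character vector of channel names.
#' @param roles channel roles, `"ecg"` or `"abp"`; inferred from `names` via
#'   [inferChannelRoles()] when `NULL`.
#' @param units physical units per channel (default `"mV"` for ECG channels,
#'   `"mmHg"` for ABP).
#' @param fs sampling rate in Hz.
#' @param t0 record start time in seconds.
#' @return A [WaveformRecord-class].
#' @examples
#' rec <- waveformRecord(cbind(II = sin(seq(0, 10, by = 0.004))), fs = 250)
#' sampleRate(rec)
#' @export
waveformRecord <- function(signals, names = NULL, roles = NULL, units = NULL,
                           fs, t0 = 0) {
  if (is.list(signals) && !is.data.frame(signals)) {
    len <- vapply(signals, length, integer(1))
    if (length(unique(len)) != 1) {
      bad <- base::names(signals)[which(len != len[1])[1]]
      stopWith("autonomiq_channel_length_error",
               sprintf("channel '%s' has a mismatched length", bad))
    }
    if (is.null(names)) names <- base::names(signals)
    signals <- do.call(cbind, signals)
  }
  signals <- as.matrix(signals)
  if (is.null(names)) names <- colnames(signals)
  if (is.null(names)) names <- paste0("ch", seq_len(ncol(signals)))
  if (is.null(roles)) roles <- inferChannelRoles(names)
  if (is.null(units)) units <- ifelse(roles == "abp", "mmHg", "mV")
  colnames(signals) <- names
  methods::new("WaveformRecord", signals = signals,
               channels = data.frame(name = names, role = roles, units = units,
                                     stringsAsFactors = FALSE),
               fs = as.numeric(fs), t0 = as.numeric(t0))
}

#' Infer channel roles from channel names
#'
#' Names matching the ABP patterns (case-insensitive `abp`, `art`, `press`,
#' `bp`) are assigned role `"abp"`; everything else is treated as an ECG lead.
#' The pattern set is configurable.
#'
#' @param names character channel names.
#' @param abpPatterns regular expressions identifying pressure channels.
#' @return Character vector of roles.
#' @export
inferChannelRoles <- function(names,
                              abpPatterns = c("abp", "art", "press", "^bp$")) {
  isAbp <- Reduce(`|`, lapply(abpPatterns, function(p)
    grepl(p, names, ignore.case = TRUE)))
  ifelse(isAbp, "abp", "ecg")
}

#' @rdname sampleRate
#' @export
setMethod("sampleRate", "WaveformRecord", function(x) x@fs)

#' @rdname nSamples
#' @export
setMethod("nSamples", "WaveformRecord", function(x) nrow(x@signals))

#' @rdname channelNames
#' @export
setMethod("channelNames", "WaveformRecord", function(x) x@channels$name)

#' @rdname channelNames
#' @export
setMethod("channelRoles", "WaveformRecord", function(x) x@channels$role)

#' @rdname channelNames
#' @export
setMethod("channelUnits", "WaveformRecord", function(x) x@channels$units)

#' @rdname channelNames
#' @export
setMethod("channelSignal", "WaveformRecord", function(x, which) {
  if (is.character(which)) which <- match(which, x@channels$name)
  x@signals[, which]
})

#' Record duration in seconds
#' @param record a [WaveformRecord-class].
#' @return Duration (n samples / fs) in seconds.
#' @export
recordDuration <- function(record) nSamples(record) / sampleRate(record)

setMethod("show", "WaveformRecord", function(object) {
  cat(sprintf("WaveformRecord: %d channel(s), %d samples @ %g Hz (%.1f s)\n",
              ncol(object@signals), nrow(object@signals), object@fs,
              recordDuration(object)))
  for (i in seq_len(nrow(object@channels)))
    cat(sprintf("  [%d] %s (%s, %s)\n", i, object@channels$name[i],
                object@channels$role[i], object@channels$units[i]))
})

#' Read a waveform record from disk
#'
#' Two dialects are supported. `format = "csv"`: a CSV with header
#' `time_s,<chan1>,<chan2>,...` accompanied by a YAML sidecar `<path>.yaml`
#' holding `fs` and optionally per-channel `roles`/`units`. `format = "wfdb"`:
#' a WFDB header/signal pair (see [readWfdb()]).
#'
#' @param path file path (CSV file, or WFDB record name without extension).
#' @param format `"csv"` or `"wfdb"`.
#' @return A [WaveformRecord-class].
#' @seealso [writeRecord()]
#' @export
readRecord <- function(path, format = c("csv", "wfdb")) {
  format <- match.arg(format)
  if (format == "wfdb") return(readWfdb(path))
  if (!file.exists(path)) stopWith("autonomiq_io_error",
                                   sprintf("file not found: %s", path))
  tab <- utils::read.csv(path, check.names = FALSE)
  if (!"time_s" %in% names(tab))
    stopWith("autonomiq_format_error", "CSV must contain a time_s column")
  side <- paste0(path, ".yaml")
  meta <- if (file.exists(side)) yaml::read_yaml(side) else list()
  if (is.null(meta$fs))
    stopWith("autonomiq_format_error", "sampling rate unspecified")
  chans <- setdiff(names(tab), "time_s")
  roles <- if (!is.null(meta$roles)) unlist(meta$roles)[chans] else NULL
  units <- if (!is.null(meta$units)) unlist(meta$units)[chans] else NULL
  waveformRecord(as.matrix(tab[chans]), names = chans, roles = roles,
                 units = units, fs = meta$fs,
                 t0 = if (is.null(meta$t0)) tab$time_s[1] else meta$t0)
}

#' Write a waveform record to disk
#'
#' @param record a [WaveformRecord-class].
#' @param path output path (CSV file, or WFDB record name without extension).
#' @param format `"csv"` or `"wfdb"`.
#' @return `path`, invisibly.
#' @export
writeRecord <- function(record, path, format = c("csv", "wfdb")) {
  format <- match.arg(format)
  if (format == "wfdb") return(writeWfdb(record, path))
  t <- record@t0 + (seq_len(nSamples(record)) - 1) / sampleRate(record)
  tab <- data.frame(time_s = t, record@signals, check.names = FALSE)
  utils::write.csv(tab, path, row.names = FALSE)
  meta <- list(fs = sampleRate(record), t0 = record@t0,
               roles = as.list(stats::setNames(channelRoles(record),
                                               channelNames(record))),
               units = as.list(stats::setNames(channelUnits(record),
                                               channelNames(record))))
  yaml::write_yaml(meta, paste0(path, ".yaml"))
  invisible(path)
}

#' Tile a record into fixed-length analysis segments
#'
#' Consecutive, non-overlapping windows of `lengthS` seconds starting at the
#' record start. A trailing remainder shorter than `lengthS` is flagged
#' `partial` and excluded from index computation unless `allowPartial = TRUE`
#' downstream.
#'
#' @param record a [WaveformRecord-class].
#' @param lengthS segment length in seconds (default 3600, i.e. 1 h).
#' @return data.frame with columns `start_s`, `end_s`, `partial`.
#' @examples
#' rec <- waveformRecord(cbind(II = numeric(250 * 90)), fs = 250)
#' sliceSegments(rec, lengthS = 30)
#' @export
sliceSegments <- function(record, lengthS = 3600) {
  stopifnot(isScalarNumber(lengthS), lengthS > 0)
  dur <- recordDuration(record)
  nFull <- floor(dur / lengthS + 1e-9)
  starts <- seq_len(nFull) - 1
  out <- data.frame(start_s = starts * lengthS,
                    end_s = (starts + 1) * lengthS,
                    partial = rep(FALSE, nFull))
  rem <- dur - nFull * lengthS
  if (rem > 1 / sampleRate(record) / 2)
    out <- rbind(out, data.frame(start_s = nFull * lengthS, end_s = dur,
                                 partial = TRUE))
  out
}

#' Extract the samples of one segment window
#'
#' @param record a [WaveformRecord-class].
#' @param startS,endS window bounds in seconds from record start.
#' @return A [WaveformRecord-class] restricted to the window (t0 shifted).
#' @export
cropRecord <- function(record, startS, endS) {
  fs <- sampleRate(record)
  i0 <- max(1L, floor(startS * fs) + 1L)
  i1 <- min(nSamples(record), ceiling(endS * fs))
  waveformRecord(record@signals[i0:i1, , drop = FALSE],
                 names = channelNames(record), roles = channelRoles(record),
                 units = channelUnits(record), fs = fs,
                 t0 = record@t0 + (i0 - 1) / fs)
}
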