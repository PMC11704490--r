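# Minimal WFDB dialect: text .hea header plus a single format-16 .dat file
# (16-bit little-endian, channels interleaved), and a plain-text beat
# annotation file. Covers the subset needed to exchange records and beat
# labels; amplitude round-trip precision is 1/gain per channel.

#' Read a WFDB record (format-16 subset)
#'
#' @param recordName path to the record without extension (`.hea`/`.dat`
#'   appended).
#' @return A [WaveformRecord-class].
#' @seealso [writeWfdb()], [readRecord()]
#' @export
readWfdb <- function(recordName) {
  hea <- paste0(recordName, ".hea")
  if (!file.exists(hea))
    stopWith("autonomiq_io_error", sprintf("file not found: %s", hea))
  lines <- readLines(hea)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  top <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  nsig <- as.integer(top[2])
  fs <- as.numeric(top[3])
  nsamp <- as.integer(top[4])
  if (!is.finite(fs) || fs <= 0)
    stopWith("autonomiq_format_error", "sampling rate unspecified")
  sig <- lines[1 + seq_len(nsig)]
  parse1 <- function(ln) {
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    gainUnits <- strsplit(f[3], "/")[[1]]
    gain <- as.numeric(sub("\\(.*\\)", "", gainUnits[1]))
    base <- if (grepl("\\(", gainUnits[1]))
      as.numeric(sub(".*\\((-?[0-9.]+)\\).*", "\\1", gainUnits[1])) else 0
    list(file = f[1], fmt = f[2], gain = gain, baseline = base,
         units = if (length(gainUnits) > 1) gainUnits[2] else "mV",
         name = f[length(f)])
  }
  info <- lapply(sig, parse1)
  datFile <- file.path(dirname(recordName), info[[1]]$file)
  con <- file(datFile, "rb")
  on.exit(close(con))
  raw <- readBin(con, "integer", n = nsig * nsamp, size = 2, endian = "little",
                 signed = TRUE)
  m <- matrix(as.numeric(raw), ncol = nsig, byrow = TRUE)
  for (j in seq_len(nsig))
    m[, j] <- (m[, j] - info[[j]]$baseline) / info[[j]]$gain
  nm <- vapply(info, `[[`, "", "name")
  waveformRecord(m, names = nm,
                 units = vapply(info, `[[`, "", "units"), fs = fs)
}

#' Write a WFDB record (format-16 subset)
#'
#' Each channel is scaled by an integer gain chosen so the signal spans most of
#' the 16-bit range; the gain is recorded in the header, so values round-trip
#' to within 1/gain of the original.
#'
#' @param record a [WaveformRecord-class].
#' @param recordName output path without extension.
#' @return `recordName`, invisibly.
#' @export
writeWfdb <- function(record, recordName) {
  sig <- record@signals
  nsig <- ncol(sig)
  gains <- vapply(seq_len(nsig), function(j) {
    amp <- max(abs(sig[, j]), na.rm = TRUE)
    if (amp == 0) 200 else max(1, floor(30000 / amp))
  }, numeric(1))
  dig <- vapply(seq_len(nsig), function(j) as.integer(round(sig[, j] * gains[j])),
                integer(nrow(sig)))
  dig <- matrix(dig, ncol = nsig)
  base <- basename(recordName)
  hea <- c(sprintf("%s %d %g %d", base, nsig, sampleRate(record), nrow(sig)),
           vapply(seq_len(nsig), function(j)
             sprintf("%s.dat 16 %d(0)/%s 16 0 %d 0 0 %s", base, gains[j],
                     channelUnits(record)[j], dig[1, j],
                     channelNames(record)[j]), character(1)))
  writeLines(hea, paste0(recordName, ".hea"))
  con <- file(paste0(recordName, ".dat"), "wb")
  on.exit(close(con))
  writeBin(as.integer(t(dig)), con, size = 2, endian = "little")
  invisible(recordName)
}

#' Read / write beat annotations
#'
#' Beat labels are exchanged as plain text with columns `time_s,label`
#' (WFDB-style `N`/`V` symbols), either comma-separated with a header or
#' whitespace-separated.
#'
#' @param beats a [BeatSeries-class].
#' @param path annotation file path.
#' @param source `"ecg"` or `"abp"` for the series read back.
#' @return `readBeatAnnotations`: a [BeatSeries-class]; `writeBeatAnnotations`:
#'   `path`, invisibly.
#' @export
writeBeatAnnotations <- function(beats, path) {
  utils::write.csv(data.frame(time_s = beatTimes(beats),
                              label = beatLabels(beats)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeBeatAnnotations
#' @export
readBeatAnnotations <- function(path, source = "ecg") {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  beatSeries(tab$time_s, labels = tab$label, source = source)
}
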