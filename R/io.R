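# Readers and writers: EDF (European Data Format, 16-bit), the
# concatenated-text format (all samples of channel 1, then channel 2, ...),
# and delimited cohort manifests.

padField <- function(x, width) {
  s <- substr(as.character(x), 1, width)
  formatC(s, width = width, flag = "-")
}

numField <- function(x, width) {
  for (d in 7:1) {
    s <- formatC(x, width = 1, format = "g", digits = d)
    if (nchar(s) <= width) return(formatC(s, width = width, flag = "-"))
  }
  stop(sprintf("EDF header field overflow: %s", x), call. = FALSE)
}

#' Write a recording to an EDF file
#'
#' Standard 16-bit EDF with one data record holding the whole signal.
#' Physical range is taken per channel from the data (so quantization error
#' is at most (max - min) / 65535 per channel).
#'
#' @param rec an \linkS4class{EEGRecording}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @seealso \code{\link{readEDF}}
#' @export
writeEDF <- function(rec, path) {
  stopifnot(is(rec, "EEGRecording"))
  data <- signalData(rec)
  ns <- nrow(data)
  n <- ncol(data)
  stopIf(n < 1, "cannot write an empty recording")
  recDur <- n / samplingRate(rec)
  # integer physical bounds: exactly representable in the 8-char decimal
  # header fields, so the calibration read back matches the one used here
  physMin <- floor(apply(data, 1, min)) - 1
  physMax <- ceiling(apply(data, 1, max)) + 1
  stopIf(any(abs(c(physMin, physMax)) >= 1e7),
         "signal amplitude too large for the EDF header fields")
  digMin <- -32768; digMax <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    padField("0", 8),
    padField(subjectId(rec), 80),
    padField(ifelse(is.na(classLabel(rec)), "", classLabel(rec)), 80),
    "01.01.00", "00.00.00",
    numField(256 + ns * 256, 8),
    padField("", 44),
    numField(1, 8),
    numField(recDur, 8),
    numField(ns, 4))
  writeChar(hdr, con, eos = NULL)
  sig <- paste0(
    paste(vapply(channelNames(rec), padField, "", width = 16), collapse = ""),
    paste(rep(padField("", 80), ns), collapse = ""),
    paste(rep(padField("uV", 8), ns), collapse = ""),
    paste(vapply(physMin, numField, "", width = 8), collapse = ""),
    paste(vapply(physMax, numField, "", width = 8), collapse = ""),
    paste(rep(numField(digMin, 8), ns), collapse = ""),
    paste(rep(numField(digMax, 8), ns), collapse = ""),
    paste(rep(padField("", 80), ns), collapse = ""),
    paste(rep(numField(n, 8), ns), collapse = ""),
    paste(rep(padField("", 32), ns), collapse = ""))
  writeChar(sig, con, eos = NULL)
  for (ch in seq_len(ns)) {
    dig <- round((data[ch, ] - physMin[ch]) / (physMax[ch] - physMin[ch]) *
                   (digMax - digMin) + digMin)
    writeBin(as.integer(dig), con, size = 2, endian = "little")
  }
  invisible(path)
}

readField <- function(con, width) trimws(readChar(con, width, useBytes = TRUE))

#' Read an EDF file into an EEGRecording
#'
#' Amplitudes are converted to physical units using the per-channel
#' calibration in the header; the subject id is taken from the filename stem.
#' All channels must share one sampling rate.
#'
#' @param path path to an EDF file.
#' @return An \linkS4class{EEGRecording} (label \code{NA}; labels come from
#'   the cohort manifest, not from signal headers).
#' @export
readEDF <- function(path) {
  stopIf(!file.exists(path), "file not found: %s", path)
  stopIf(file.size(path) < 256, "malformed EDF (truncated header): %s", path)
  con <- file(path, "rb")
  on.exit(close(con))
  version <- readField(con, 8)
  stopIf(version != "0", "malformed EDF (bad version field): %s", path)
  readChar(con, 80 + 80 + 8 + 8, useBytes = TRUE)       # ids, date, time
  headerBytes <- as.integer(readField(con, 8))
  readChar(con, 44, useBytes = TRUE)
  nRecords <- as.integer(readField(con, 8))
  recDur <- as.numeric(readField(con, 8))
  ns <- as.integer(readField(con, 4))
  stopIf(is.na(ns) || ns < 1, "malformed EDF (no signals): %s", path)
  stopIf(is.na(headerBytes) || headerBytes != 256 + ns * 256,
         "malformed EDF (inconsistent header size): %s", path)
  rd <- function(width) vapply(seq_len(ns), function(i) readField(con, width), "")
  labels <- rd(16); rd(80)
  rd(8)                                                  # physical dimension
  physMin <- as.numeric(rd(8)); physMax <- as.numeric(rd(8))
  digMin <- as.numeric(rd(8)); digMax <- as.numeric(rd(8))
  rd(80)
  sampPerRec <- as.integer(rd(8)); rd(32)
  stopIf(anyNA(c(physMin, physMax, digMin, digMax, sampPerRec)),
         "malformed EDF (bad signal header): %s", path)
  stopIf(length(unique(sampPerRec)) != 1L,
         "unsupported EDF: heterogeneous per-channel sampling rates in %s", path)
  stopIf(is.na(nRecords) || nRecords < 1 || is.na(recDur) || recDur <= 0,
         "malformed EDF (bad record count/duration): %s", path)
  fs <- sampPerRec[1] / recDur
  data <- matrix(0, ns, sampPerRec[1] * nRecords)
  for (r in seq_len(nRecords)) {
    for (ch in seq_len(ns)) {
      dig <- readBin(con, "integer", n = sampPerRec[ch], size = 2,
                     signed = TRUE, endian = "little")
      stopIf(length(dig) != sampPerRec[ch],
             "malformed EDF (truncated data): %s", path)
      phys <- (dig - digMin[ch]) * (physMax[ch] - physMin[ch]) /
        (digMax[ch] - digMin[ch]) + physMin[ch]
      data[ch, (r - 1) * sampPerRec[ch] + seq_len(sampPerRec[ch])] <- phys
    }
  }
  EEGRecording(data, fs, labels,
               subjectId = sub("\\.[^.]*$", "", basename(path)))
}

#' Read a concatenated-text recording
#'
#' One numeric value per line; all samples of channel 1 first, then channel
#' 2, and so on.
#'
#' @param path text file path.
#' @param nChannels number of channels.
#' @param fs sampling rate, Hz.
#' @param channelNames optional channel labels.
#' @param subjectId subject id (defaults to the filename stem).
#' @return An \linkS4class{EEGRecording}.
#' @export
readConcatText <- function(path, nChannels, fs, channelNames = NULL,
                           subjectId = sub("\\.[^.]*$", "", basename(path))) {
  stopIf(!file.exists(path), "file not found: %s", path)
  raw <- scan(path, what = character(), quiet = TRUE)
  vals <- suppressWarnings(as.numeric(raw))
  stopIf(anyNA(vals), "parse error: non-numeric token in %s", path)
  stopIf(length(vals) %% nChannels != 0,
         "format error: %d values not divisible by %d channels",
         length(vals), nChannels)
  data <- matrix(vals, nrow = nChannels, byrow = TRUE)
  if (is.null(channelNames)) channelNames <- paste0("ch", seq_len(nChannels))
  EEGRecording(data, fs, channelNames, subjectId = subjectId)
}

#' Write a recording in concatenated-text format
#'
#' @param rec an \linkS4class{EEGRecording}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeConcatText <- function(rec, path) {
  stopifnot(is(rec, "EEGRecording"))
  vals <- as.vector(t(signalData(rec)))   # channel 1 block, channel 2, ...
  writeLines(format(vals, scientific = FALSE, trim = TRUE, digits = 15), path)
  invisible(path)
}

#' Read / write a cohort manifest
#'
#' A manifest is a comma-delimited table with header
#' \code{subject_id,label,path}; labels are \code{control}/\code{patient}.
#'
#' @param path manifest file path.
#' @return \code{readManifest}: a data.frame with columns subject_id, label,
#'   path (relative paths resolved against the manifest's directory).
#' @export
readManifest <- function(path) {
  stopIf(!file.exists(path), "manifest not found: %s", path)
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopIf(!all(c("subject_id", "label", "path") %in% names(m)),
         "manifest must have columns subject_id, label, path")
  stopIf(nrow(m) == 0, "manifest is empty: %s", path)
  stopIf(!all(m$label %in% CLASS_LEVELS),
         "manifest labels must be 'control' or 'patient'")
  abs <- file.path(dirname(path), m$path)
  m$path <- ifelse(file.exists(m$path) | grepl("^/", m$path), m$path, abs)
  m
}

#' @rdname readManifest
#' @param manifest data.frame with subject_id, label, path.
#' @export
writeManifest <- function(manifest, path) {
  utils::write.csv(manifest[, c("subject_id", "label", "path")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a cohort to disk with a manifest
#'
#' @param cohort list of \linkS4class{EEGRecording}.
#' @param dir output directory (created if missing).
#' @param format \code{"edf"} or \code{"text"}.
#' @return Path of the written manifest, invisibly.
#' @export
writeCohort <- function(cohort, dir, format = c("edf", "text")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (format == "edf") "edf" else "txt"
  rows <- lapply(cohort, function(rec) {
    fn <- paste0(subjectId(rec), ".", ext)
    fp <- file.path(dir, fn)
    if (format == "edf") writeEDF(rec, fp) else writeConcatText(rec, fp)
    data.frame(subject_id = subjectId(rec), label = classLabel(rec),
               path = fn, stringsAsFactors = FALSE)
  })
  mp <- file.path(dir, "manifest.csv")
  writeManifest(do.call(rbind, rows), mp)
  invisible(mp)
}

#' Load a cohort listed in a manifest
#'
#' @param manifestPath path to a manifest written by \code{\link{writeCohort}}.
#' @param format \code{"edf"} or \code{"text"} (guessed from file extensions
#'   when missing).
#' @param nChannels,fs,channelNames required for the text format.
#' @return A list of labelled \linkS4class{EEGRecording} objects.
#' @export
loadCohort <- function(manifestPath, format = NULL, nChannels = NULL,
                       fs = NULL, channelNames = NULL) {
  m <- readManifest(manifestPath)
  if (is.null(format))
    format <- if (grepl("\\.edf$", m$path[1], ignore.case = TRUE)) "edf" else "text"
  lapply(seq_len(nrow(m)), function(i) {
    rec <- if (format == "edf") readEDF(m$path[i]) else {
      stopIf(is.null(nChannels) || is.null(fs),
             "nChannels and fs are required to read text recordings")
      readConcatText(m$path[i], nChannels, fs, channelNames)
    }
    EEGRecording(signalData(rec), samplingRate(rec), channelNames(rec),
                 subjectId = m$subject_id[i], label = m$label[i])
  })
}
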