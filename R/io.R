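# fixed-width ASCII field helpers for EDF headers
edfField <- function(x, width) {
  s <- as.character(x)
  if (nchar(s) > width) s <- substr(s, 1L, width)
  sprintf(paste0("%-", width, "s"), s)
}
edfNum <- function(x, width) edfField(format(x, trim = TRUE, digits = 8), width)

#' Write a session to European Data Format (EDF)
#'
#' Minimal continuous EDF: 16-bit samples, one-second data records, EEG
#' channels followed by the EMG trace as the last signal. The physical range
#' of each signal is its observed min/max, so amplitude resolution is
#' (max - min)/65535. The final record is zero-padded when the session
#' length is not a whole number of seconds; events are not stored in the EDF
#' (see \code{\link{writeEvents}}).
#'
#' @param session an \code{\linkS4class{EEGSession}}
#' @param path output file path
#' @return \code{path}, invisibly
#' @export
writeSessionEDF <- function(session, path) {
  fs <- samplingRate(session)
  if (abs(fs - round(fs)) > 1e-9)
    stop("EDF export requires an integer sampling rate")
  fs <- as.integer(round(fs))
  signals <- rbind(eegData(session), EMG = emgData(session))
  ns <- nrow(signals)
  nSamples <- ncol(signals)
  nRecords <- as.integer(ceiling(nSamples / fs))
  labels <- c(paste("EEG", channelNames(session)), "EMG")

  physMin <- apply(signals, 1L, min)
  physMax <- apply(signals, 1L, max)
  same <- physMax - physMin < 1e-12
  physMax[same] <- physMin[same] + 1
  digMin <- -32768L; digMax <- 32767L

  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  hdr <- paste0(
    edfField("0", 8), edfField("synthetic subject", 80),
    edfField("mrcpbench session", 80),
    edfField("01.01.26", 8), edfField("00.00.00", 8),
    edfField(256L * (1L + ns), 8), edfField("", 44),
    edfField(nRecords, 8), edfField(1L, 8), edfField(ns, 4))
  writeChar(hdr, con, eos = NULL)
  writeChar(paste0(vapply(labels, edfField, "", width = 16), collapse = ""),
            con, eos = NULL)
  writeChar(strrep(edfField("", 80), ns), con, eos = NULL)
  writeChar(strrep(edfField("uV", 8), ns), con, eos = NULL)
  writeChar(paste0(vapply(physMin, edfNum, "", width = 8), collapse = ""),
            con, eos = NULL)
  writeChar(paste0(vapply(physMax, edfNum, "", width = 8), collapse = ""),
            con, eos = NULL)
  writeChar(strrep(edfField(digMin, 8), ns), con, eos = NULL)
  writeChar(strrep(edfField(digMax, 8), ns), con, eos = NULL)
  writeChar(strrep(edfField("", 80), ns), con, eos = NULL)
  writeChar(strrep(edfField(fs, 8), ns), con, eos = NULL)
  writeChar(strrep(edfField("", 32), ns), con, eos = NULL)

  padded <- matrix(0, ns, nRecords * fs)
  padded[, seq_len(nSamples)] <- signals
  scale <- (digMax - digMin) / (physMax - physMin)
  for (r in seq_len(nRecords)) {
    cols <- ((r - 1L) * fs + 1L):(r * fs)
    for (s in seq_len(ns)) {
      dig <- round((padded[s, cols] - physMin[s]) * scale[s]) + digMin
      writeBin(as.integer(pmin(pmax(dig, digMin), digMax)), con,
               size = 2L, endian = "little")
    }
  }
  invisible(path)
}

#' Read a session written by \code{\link{writeSessionEDF}}
#'
#' Supports continuous 16-bit EDF with equal sampling rates across signals.
#' A signal labelled "EMG" becomes the session's EMG trace; events start
#' empty (attach them with \code{\link{readEvents}}).
#'
#' @param path EDF file path
#' @return an \code{\linkS4class{EEGSession}}
#' @export
readSessionEDF <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8) # header bytes
  rd(44)
  nRecords <- as.integer(rd(8))
  recDur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80) # transducer
  for (i in seq_len(ns)) rd(8) # phys dim
  physMin <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  physMax <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  digMin <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  digMax <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  for (i in seq_len(ns)) rd(80) # prefiltering
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), 0L)
  for (i in seq_len(ns)) rd(32)
  if (length(unique(spr)) != 1L)
    stop("mixed per-signal sampling rates are not supported")
  fs <- spr[1L] / recDur
  signals <- matrix(0, ns, nRecords * spr[1L])
  scale <- (physMax - physMin) / (digMax - digMin)
  for (r in seq_len(nRecords)) {
    cols <- ((r - 1L) * spr[1L] + 1L):(r * spr[1L])
    for (s in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[s], size = 2L, signed = TRUE,
                     endian = "little")
      signals[s, cols] <- physMin[s] + (dig - digMin[s]) * scale[s]
    }
  }
  isEmg <- toupper(labels) == "EMG"
  eegRows <- which(!isEmg)
  chn <- sub("^EEG ", "", labels[eegRows])
  emg <- if (any(isEmg)) signals[which(isEmg)[1L], ] else
    numeric(ncol(signals))
  ev <- matrix(integer(0), 0L, 2L,
               dimnames = list(NULL, c("onset", "offset")))
  new("EEGSession", eeg = signals[eegRows, , drop = FALSE], emg = emg,
      fs = fs, channelNames = chn, events = ev, groundTruth = ev,
      meta = list(source = path))
}

#' Write movement events as a tab-separated annotation file
#'
#' Two columns, \code{onset} and \code{offset}, 1-based inclusive sample
#' indices.
#'
#' @param events integer matrix with onset/offset columns (e.g.
#'   \code{sessionEvents(session)})
#' @param path output path
#' @return \code{path}, invisibly
#' @export
writeEvents <- function(events, path) {
  utils::write.table(as.data.frame(events), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a tab-separated annotation file written by \code{\link{writeEvents}}
#' @param path annotation file path
#' @return integer matrix with columns onset, offset
#' @export
readEvents <- function(path) {
  tab <- utils::read.delim(path)
  out <- cbind(onset = as.integer(tab$onset), offset = as.integer(tab$offset))
  out
}

#' Write a session as a plain columnar container
#'
#' A directory holding \code{signals.tsv} (one column per EEG channel plus
#' \code{EMG}, one row per sample), \code{events.tsv}, and a
#' \code{manifest.json} sidecar with the sampling rate and channel order.
#'
#' @param session an \code{\linkS4class{EEGSession}}
#' @param dir output directory (created if needed)
#' @return \code{dir}, invisibly
#' @export
writeSessionColumnar <- function(session, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sig <- as.data.frame(t(eegData(session)))
  names(sig) <- channelNames(session)
  sig$EMG <- emgData(session)
  utils::write.table(sig, file.path(dir, "signals.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  writeEvents(sessionEvents(session), file.path(dir, "events.tsv"))
  manifest <- list(fs = samplingRate(session),
                   channels = channelNames(session),
                   nSamples = ncol(eegData(session)),
                   nEvents = nrow(sessionEvents(session)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a session from a columnar container directory
#' @param dir directory written by \code{\link{writeSessionColumnar}}
#' @return an \code{\linkS4class{EEGSession}}
#' @export
readSessionColumnar <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  sig <- utils::read.delim(file.path(dir, "signals.tsv"),
                           check.names = FALSE)
  ev <- readEvents(file.path(dir, "events.tsv"))
  eeg <- t(as.matrix(sig[, manifest$channels, drop = FALSE]))
  new("EEGSession", eeg = eeg, emg = sig$EMG, fs = manifest$fs,
      channelNames = manifest$channels, events = ev, groundTruth = ev,
      meta = list(source = dir))
}

#' Write an epoch set as a columnar file with a JSON manifest
#'
#' \code{<path>.tsv} holds one row per (epoch, channel) with the sample
#' values in columns; \code{<path>.json} records the label counts, band,
#' sampling rate, and channel names.
#'
#' @param epochs an \code{\linkS4class{EpochSet}}
#' @param path output path stem (without extension)
#' @param subject optional subject id stored in the manifest
#' @return \code{path}, invisibly
#' @export
writeEpochs <- function(epochs, path, subject = NA_character_) {
  arr <- epochData(epochs)
  d <- dim(arr)
  rows <- expand.grid(channel = seq_len(d[1L]), epoch = seq_len(d[3L]))
  flat <- t(vapply(seq_len(nrow(rows)), function(i)
    arr[rows$channel[i], , rows$epoch[i]], numeric(d[2L])))
  tab <- data.frame(epoch = rows$epoch,
                    channel = channelNames(epochs)[rows$channel],
                    label = as.character(epochLabels(epochs))[rows$epoch])
  utils::write.table(cbind(tab, as.data.frame(flat)),
                     paste0(path, ".tsv"), sep = "\t", row.names = FALSE,
                     quote = FALSE)
  counts <- table(epochLabels(epochs))
  jsonlite::write_json(
    list(subject = subject, band = epochs@band, fs = epochs@fs,
         channels = channelNames(epochs), samplesPerEpoch = d[2L],
         counts = as.list(counts)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write factorial result tables as tidy TSV plus a JSON run manifest
#'
#' @param result a \code{\linkS4class{FactorialResult}}
#' @param dir output directory (created if needed)
#' @return \code{dir}, invisibly
#' @export
writeResultTSV <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(gridTable(result), file.path(dir, "grid.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(bestTable(result), file.path(dir, "best.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  cfg <- result@meta$config
  manifest <- list(
    seed = cfg$seed,
    bands = names(cfg$bands), spatials = cfg$spatials,
    classifiers = cfg$classifiers, decimateTo = cfg$decimateTo,
    thresholdOn = cfg$thresholdOn,
    subjects = result@meta$subjects,
    gridRows = nrow(gridTable(result)), bestCells = nrow(bestTable(result)),
    rVersion = as.character(getRversion()),
    package = as.character(utils::packageVersion("mrcpbench")))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
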