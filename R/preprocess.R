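#' Frequency band specification
#'
#' Analysis bands use a causal second-order Butterworth band-pass; the order
#' is fixed at 2 because higher-order IIR band-passes with sub-Hz edges are
#' numerically unstable.
#'
#' @param lo,hi band edges in Hz, 0 < lo < hi
#' @param kind "bandpass" or "notch" (band-stop, used for mains removal)
#' @return a list of class \code{BandSpec}; its \code{name} field is the
#'   human-readable "lo-hi" label used in result tables
#' @export
bandSpec <- function(lo, hi, kind = c("bandpass", "notch")) {
  kind <- match.arg(kind)
  stopifnot(lo > 0, hi > lo)
  structure(list(lo = lo, hi = hi, order = 2L, kind = kind, causal = TRUE,
                 name = paste0(format(lo, trim = TRUE), "-",
                               format(hi, trim = TRUE))),
            class = "BandSpec")
}

#' The five standard analysis bands: 0.01-1, 1-2, 2-3, 3-4, 4-5 Hz
#' @return named list of \code{\link{bandSpec}} objects
#' @export
analysisBands <- function() {
  bands <- list(bandSpec(0.01, 1), bandSpec(1, 2), bandSpec(2, 3),
                bandSpec(3, 4), bandSpec(4, 5))
  names(bands) <- vapply(bands, `[[`, "", "name")
  bands
}

butterCoefs <- function(band, fs) {
  if (band$hi >= fs / 2)
    stop("band upper edge must be below the Nyquist frequency")
  w <- c(band$lo, band$hi) * 2 / fs
  type <- if (band$kind == "notch") "stop" else "pass"
  ba <- signal::butter(band$order, w, type)
  poles <- Mod(polyroot(rev(ba$a)))
  if (any(!is.finite(poles)) || max(poles) >= 1)
    stop("unstable filter coefficients for band ", band$name, " at fs = ", fs,
         "; use a cascade of a ", band$order, "-order high-pass at ", band$lo,
         " Hz and low-pass at ", band$hi, " Hz instead")
  ba
}

#' Apply a causal Butterworth band filter to every EEG channel
#'
#' Forward-only (causal) filtering; the output has the same length as the
#' input and the EMG trace and events are left untouched.
#'
#' @param session an \code{\linkS4class{EEGSession}}
#' @param band a \code{\link{bandSpec}}
#' @return the filtered session
#' @export
bandpassSession <- function(session, band) {
  ba <- butterCoefs(band, samplingRate(session))
  x <- eegData(session)
  y <- t(apply(x, 1L, function(ch) as.numeric(signal::filter(ba, ch))))
  dimnames(y) <- dimnames(x)
  initialize(session, eeg = y,
             meta = c(session@meta, list(band = band$name)))
}

#' Remove 49-51 Hz mains interference
#'
#' Applied at session load for raw recordings only; synthetic sessions inject
#' no mains artifact, so this is opt-in.
#'
#' @param session an \code{\linkS4class{EEGSession}}
#' @return the notch-filtered session
#' @export
notchMains <- function(session) {
  bandpassSession(session, bandSpec(49, 51, kind = "notch"))
}

#' Downsample a session with anti-aliased decimation
#'
#' Integer-factor decimation of all EEG channels and the EMG trace
#' (\code{signal::decimate}), with events remapped to the new rate. Intended
#' for detector tractability after band filtering (all analysis bands live
#' below 5 Hz, far under any decimated Nyquist used here).
#'
#' @param session an \code{\linkS4class{EEGSession}}
#' @param to target sampling rate in Hz; must divide the current rate
#' @return the decimated session
#' @export
decimateSession <- function(session, to = 64) {
  fs <- samplingRate(session)
  if (to >= fs) return(session)
  q <- fs / to
  if (abs(q - round(q)) > 1e-9)
    stop("target rate must divide the session sampling rate")
  q <- as.integer(round(q))
  x <- eegData(session)
  y <- t(apply(x, 1L, function(ch) signal::decimate(ch, q)))
  dimnames(y) <- list(rownames(x), NULL)
  emg <- signal::decimate(emgData(session), q)
  remap <- function(ev) {
    if (!nrow(ev)) return(ev)
    out <- cbind(onset = pmax(1L, as.integer(ceiling(ev[, 1L] / q))),
                 offset = pmax(1L, as.integer(ceiling(ev[, 2L] / q))))
    out
  }
  initialize(session, eeg = y, emg = as.numeric(emg), fs = to,
             events = remap(session@events),
             groundTruth = remap(session@groundTruth))
}

#' Extract labelled 2-s epochs around movement events
#'
#' For every retained trial: one MRCP epoch covering the \code{windowS}
#' seconds immediately before the movement onset and one NON_MRCP epoch
#' covering the \code{windowS} seconds immediately after the offset. Trials
#' whose onset falls less than \code{minSepS} seconds after the previous
#' trial's offset are dropped entirely; epochs that would extend outside the
#' recording are dropped individually. Drops are recorded in the
#' \code{"dropLog"} attribute of the result.
#'
#' @param session an \code{\linkS4class{EEGSession}}
#' @param windowS epoch duration in seconds (default 2)
#' @param minSepS minimum onset-to-previous-offset separation (default 4)
#' @return an \code{\linkS4class{EpochSet}} (possibly with zero epochs)
#' @export
segmentSession <- function(session, windowS = 2, minSepS = 4) {
  fs <- samplingRate(session)
  L <- round(windowS * fs)
  ev <- sessionEvents(session)
  x <- eegData(session)
  n <- ncol(x)
  mats <- list(); labels <- character(); src <- integer()
  dropLog <- character()
  prevOffset <- -Inf
  for (i in seq_len(nrow(ev))) {
    onset <- ev[i, 1L]; offset <- ev[i, 2L]
    if (is.finite(prevOffset) && (onset - prevOffset) < minSepS * fs) {
      dropLog <- c(dropLog, sprintf(
        "trial %d dropped: onset %.2f s after previous offset (< %g s)",
        i, (onset - prevOffset) / fs, minSepS))
      prevOffset <- offset
      next
    }
    prevOffset <- offset
    if (onset - L >= 1L) {
      mats <- c(mats, list(x[, (onset - L):(onset - 1L), drop = FALSE]))
      labels <- c(labels, "MRCP"); src <- c(src, i)
    } else {
      dropLog <- c(dropLog, sprintf(
        "trial %d: MRCP epoch dropped (extends before recording start)", i))
    }
    if (offset + L <= n) {
      mats <- c(mats, list(x[, (offset + 1L):(offset + L), drop = FALSE]))
      labels <- c(labels, "NON_MRCP"); src <- c(src, i)
    } else {
      dropLog <- c(dropLog, sprintf(
        "trial %d: NON_MRCP epoch dropped (extends past recording end)", i))
    }
  }
  out <- makeEpochSet(mats, labels, fs, channelNames(session),
                      band = if (is.null(session@meta$band)) NA_character_
                             else session@meta$band,
                      sourceEvent = src)
  attr(out, "dropLog") <- dropLog
  out
}

#' z-normalize a single epoch matrix
#'
#' Per-channel centering and scaling using the population (1/N) standard
#' deviation. Errors on a constant channel.
#'
#' @param x channels x samples numeric matrix (or a numeric vector)
#' @return matrix (or vector) with per-channel mean 0 and population SD 1
#' @export
zNormalize <- function(x) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, nrow = 1L)
  mu <- rowMeans(x)
  cx <- x - mu
  sdp <- sqrt(rowMeans(cx^2))
  if (any(sdp < 1e-12))
    stop("degenerate epoch: constant channel cannot be z-normalized")
  out <- cx / sdp
  if (vec) drop(out) else out
}

#' z-normalize every epoch in a set, dropping degenerate ones
#'
#' Epochs with a constant channel are dropped and logged in the
#' \code{"dropLog"} attribute.
#'
#' @param epochs an \code{\linkS4class{EpochSet}}
#' @return the normalized \code{\linkS4class{EpochSet}}
#' @export
zNormalizeEpochs <- function(epochs) {
  n <- length(epochs)
  keep <- logical(n); dropLog <- character()
  arr <- epochs@data
  for (i in seq_len(n)) {
    m <- arr[, , i, drop = FALSE]
    dim(m) <- dim(arr)[1:2]
    z <- try(zNormalize(m), silent = TRUE)
    if (inherits(z, "try-error")) {
      dropLog <- c(dropLog, sprintf("epoch %d dropped: constant channel", i))
    } else {
      arr[, , i] <- z
      keep[i] <- TRUE
    }
  }
  out <- epochs
  out@data <- arr[, , keep, drop = FALSE]
  out@labels <- factor(as.character(epochs@labels[keep]),
                       levels = c("MRCP", "NON_MRCP"))
  out@sourceEvent <- epochs@sourceEvent[keep]
  attr(out, "dropLog") <- c(attr(epochs, "dropLog"), dropLog)
  out
}

#' Stratified train/test split of an epoch set
#'
#' Per class, epochs are shuffled with the given seed and the first
#' \code{floor(ratio * n)} go to the training set, the remainder to the test
#' set, so class proportions match the pooled proportions within one epoch.
#'
#' @param epochs an \code{\linkS4class{EpochSet}} with both classes present
#' @param ratio training fraction (default 2/3)
#' @param seed integer seed controlling the shuffle
#' @return an \code{\linkS4class{EpochSplit}}
#' @export
stratifiedSplit <- function(epochs, ratio = 2 / 3, seed = 1L) {
  y <- epochLabels(epochs)
  if (any(table(y) < 2L))
    stop("need at least 2 epochs per class to split")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  trainIdx <- integer(0)
  for (cl in levels(y)) {
    idx <- which(y == cl)
    idx <- idx[sample.int(length(idx))]
    nTrain <- floor(ratio * length(idx))
    trainIdx <- c(trainIdx, idx[seq_len(nTrain)])
  }
  trainIdx <- sort(trainIdx)
  testIdx <- setdiff(seq_along(y), trainIdx)
  new("EpochSplit", train = epochs[trainIdx], test = epochs[testIdx],
      ratio = ratio, seed = as.integer(seed))
}
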