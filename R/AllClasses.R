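#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib mrcpbench, .registration = TRUE
NULL

#' EEGSession: one multichannel recording run
#'
#' Container for a single self-paced movement session: a channels x samples
#' EEG matrix, a single surface EMG trace used for event labelling, the
#' sampling rate, ordered channel names, and movement events as 1-based
#' inclusive (onset, offset) sample pairs. For synthetic sessions
#' \code{groundTruth} holds the true generating events (identical to
#' \code{events} at creation; \code{events} may later be replaced by
#' EMG-derived detections).
#'
#' @slot eeg numeric matrix, channels x samples
#' @slot emg numeric vector, same length as \code{ncol(eeg)}
#' @slot fs sampling rate in Hz
#' @slot channelNames character, one per EEG row
#' @slot events integer matrix with columns \code{onset}, \code{offset}
#' @slot groundTruth integer matrix, same layout as \code{events}
#' @slot meta list of free-form provenance (generator config, filters applied)
#' @exportClass EEGSession
setClass("EEGSession",
  representation(
    eeg = "matrix", emg = "numeric", fs = "numeric",
    channelNames = "character", events = "matrix",
    groundTruth = "matrix", meta = "list"
  )
)

setValidity("EEGSession", function(object) {
  msg <- character()
  if (length(object@fs) != 1L || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive number")
  if (nrow(object@eeg) != length(object@channelNames))
    msg <- c(msg, "eeg row count must equal length(channelNames)")
  if (length(object@emg) != ncol(object@eeg))
    msg <- c(msg, "emg length must equal ncol(eeg)")
  for (nm in c("events", "groundTruth")) {
    ev <- slot(object, nm)
    if (nrow(ev)) {
      if (ncol(ev) != 2L)
        msg <- c(msg, sprintf("%s must have columns onset, offset", nm))
      else {
        if (any(ev[, 2L] < ev[, 1L]))
          msg <- c(msg, sprintf("%s: every onset must precede its offset", nm))
        if (nrow(ev) > 1L &&
            any(ev[-1L, 1L] <= ev[-nrow(ev), 2L]))
          msg <- c(msg, sprintf("%s must be sorted and non-overlapping", nm))
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' EpochSet: fixed-length labelled segments
#'
#' Epochs share dimensions and live in a channels x samples x epochs array.
#' Labels are the two detection classes \code{"MRCP"} and \code{"NON_MRCP"}.
#'
#' @slot data numeric array, channels x samples x epochs
#' @slot labels factor with levels MRCP, NON_MRCP
#' @slot fs sampling rate in Hz
#' @slot channelNames character, one per array row
#' @slot band character scalar naming the frequency band (e.g. "0.01-1"),
#'   or NA when unfiltered
#' @slot sourceEvent integer index of the generating event per epoch
#' @exportClass EpochSet
setClass("EpochSet",
  representation(
    data = "array", labels = "factor", fs = "numeric",
    channelNames = "character", band = "character", sourceEvent = "integer"
  )
)

setValidity("EpochSet", function(object) {
  msg <- character()
  d <- dim(object@data)
  if (length(d) != 3L)
    msg <- c(msg, "data must be a 3-d array (channels x samples x epochs)")
  else {
    if (d[1L] != length(object@channelNames))
      msg <- c(msg, "array row count must equal length(channelNames)")
    if (d[3L] != length(object@labels))
      msg <- c(msg, "number of epochs must equal length(labels)")
    if (d[3L] != length(object@sourceEvent))
      msg <- c(msg, "sourceEvent must have one entry per epoch")
  }
  if (!identical(levels(object@labels), c("MRCP", "NON_MRCP")))
    msg <- c(msg, 'labels must be a factor with levels c("MRCP","NON_MRCP")')
  if (length(msg)) msg else TRUE
})

#' EpochSplit: stratified train/test partition
#'
#' @slot train,test EpochSet partitions
#' @slot ratio training fraction per class
#' @slot seed integer seed that produced the shuffle
#' @exportClass EpochSplit
setClass("EpochSplit",
  representation(train = "EpochSet", test = "EpochSet",
                 ratio = "numeric", seed = "integer")
)

#' SpatialModel: fitted spatial representation
#'
#' All five spatial methods are exposed as a linear map: output component
#' time courses are \code{weights \%*\% (epoch - center)}. NoF is the
#' identity, SL a fixed neighbor-difference stencil, ICA the unmixing matrix
#' estimated on concatenated training data, CSP the single best-ratio filter,
#' PCA the eigenvector rows of the pooled covariance.
#'
#' @slot method one of "NoF", "SL", "ICA", "CSP", "PCA"
#' @slot weights numeric matrix, nOutputs x nChannels
#' @slot center per-channel training mean removed before projection
#' @slot outputNames character, one per output component
#' @slot channelNames expected input channel order
#' @slot fitMeta list (seed, iterations, converged, eigenvalues, ...)
#' @exportClass SpatialModel
setClass("SpatialModel",
  representation(
    method = "character", weights = "matrix", center = "numeric",
    outputNames = "character", channelNames = "character", fitMeta = "list"
  )
)

setValidity("SpatialModel", function(object) {
  msg <- character()
  if (!object@method %in% c("NoF", "SL", "ICA", "CSP", "PCA"))
    msg <- c(msg, "unknown spatial method")
  if (nrow(object@weights) != length(object@outputNames))
    msg <- c(msg, "weights row count must equal length(outputNames)")
  if (ncol(object@weights) != length(object@channelNames))
    msg <- c(msg, "weights column count must equal length(channelNames)")
  expected <- c(NoF = NA, SL = NA, ICA = NA, CSP = 1L, PCA = NA)
  if (identical(object@method, "CSP") && nrow(object@weights) != 1L)
    msg <- c(msg, "CSP keeps exactly one filter")
  if (length(msg)) msg else TRUE
})

#' DetectorModel: fitted single-channel MRCP detector
#'
#' @slot kind one of "LDA", "SVM", "NN_ED", "NN_DTW", "MF", "TM"
#' @slot fit list holding the fitted parameters (hyperplane, svm object,
#'   stored training epochs, or template)
#' @slot threshold decision threshold (MF and TM only, NA otherwise);
#'   statistic >= threshold predicts MRCP
#' @slot dtwBandR Sakoe-Chiba band fraction used by NN_DTW and TM
#' @slot epochLength expected input length in samples
#' @slot fitMeta list (seed, grid-search results, calibration mode, ...)
#' @exportClass DetectorModel
setClass("DetectorModel",
  representation(
    kind = "character", fit = "list", threshold = "numeric",
    dtwBandR = "numeric", epochLength = "integer", fitMeta = "list"
  )
)

setValidity("DetectorModel", function(object) {
  msg <- character()
  if (!object@kind %in% c("LDA", "SVM", "NN_ED", "NN_DTW", "MF", "TM"))
    msg <- c(msg, "unknown detector kind")
  if (object@kind %in% c("NN_DTW", "TM") &&
      !isTRUE(all.equal(object@dtwBandR, 0.10)))
    msg <- c(msg, "dtwBandR is fixed at 0.10 for NN_DTW and TM")
  if (length(msg)) msg else TRUE
})

#' FactorialResult: output of the full factorial grid
#'
#' @slot grid data.frame, one row per subject x band x spatial x
#'   channel/component x detector combination
#' @slot best data.frame, one row per subject x band x spatial x detector
#'   cell after best-channel selection
#' @slot meta list (config, seeds, session counts, drop log)
#' @exportClass FactorialResult
setClass("FactorialResult",
  representation(grid = "data.frame", best = "data.frame", meta = "list")
)

setMethod("show", "EEGSession", function(object) {
  cat(sprintf(
    "EEGSession: %d channels x %d samples at %g Hz (%.1f s), %d events\n",
    nrow(object@eeg), ncol(object@eeg), object@fs,
    ncol(object@eeg) / object@fs, nrow(object@events)))
})

setMethod("show", "EpochSet", function(object) {
  tab <- table(object@labels)
  cat(sprintf(
    "EpochSet: %d epochs (%d MRCP / %d NON_MRCP), %d channel(s) x %d samples at %g Hz, band %s\n",
    length(object@labels), tab[["MRCP"]], tab[["NON_MRCP"]],
    dim(object@data)[1L], dim(object@data)[2L], object@fs, object@band))
})

setMethod("show", "SpatialModel", function(object) {
  cat(sprintf("SpatialModel <%s>: %d channels -> %d output(s)\n",
              object@method, ncol(object@weights), nrow(object@weights)))
})

setMethod("show", "DetectorModel", function(object) {
  thr <- if (is.na(object@threshold)) "" else
    sprintf(", threshold %.4g", object@threshold)
  cat(sprintf("DetectorModel <%s>: epoch length %d%s\n",
              object@kind, object@epochLength, thr))
})

setMethod("show", "FactorialResult", function(object) {
  cat(sprintf(
    "FactorialResult: %d grid rows, %d best-channel cells, %d subject(s)\n",
    nrow(object@grid), nrow(object@best),
    length(unique(object@grid$subject))))
})

# ---- accessors ----

#' @rdname EEGSession-class
#' @param object an object
#' @export
setGeneric("eegData", function(object) standardGeneric("eegData"))
#' @rdname EEGSession-class
#' @export
setMethod("eegData", "EEGSession", function(object) object@eeg)

#' @rdname EEGSession-class
#' @export
setGeneric("emgData", function(object) standardGeneric("emgData"))
#' @rdname EEGSession-class
#' @export
setMethod("emgData", "EEGSession", function(object) object@emg)

#' @rdname EEGSession-class
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))
#' @rdname EEGSession-class
#' @export
setMethod("samplingRate", "EEGSession", function(object) object@fs)
#' @rdname EpochSet-class
#' @export
setMethod("samplingRate", "EpochSet", function(object) object@fs)

#' @rdname EEGSession-class
#' @export
setGeneric("channelNames", function(object) standardGeneric("channelNames"))
#' @rdname EEGSession-class
#' @export
setMethod("channelNames", "EEGSession", function(object) object@channelNames)
#' @rdname EpochSet-class
#' @export
setMethod("channelNames", "EpochSet", function(object) object@channelNames)

#' @rdname EEGSession-class
#' @export
setGeneric("sessionEvents", function(object) standardGeneric("sessionEvents"))
#' @rdname EEGSession-class
#' @export
setMethod("sessionEvents", "EEGSession", function(object) object@events)

#' @rdname EpochSet-class
#' @param object an object
#' @export
setGeneric("epochData", function(object) standardGeneric("epochData"))
#' @rdname EpochSet-class
#' @export
setMethod("epochData", "EpochSet", function(object) object@data)

#' @rdname EpochSet-class
#' @export
setGeneric("epochLabels", function(object) standardGeneric("epochLabels"))
#' @rdname EpochSet-class
#' @export
setMethod("epochLabels", "EpochSet", function(object) object@labels)

#' Number of epochs in an EpochSet
#' @param x an EpochSet
#' @export
setMethod("length", "EpochSet", function(x) length(x@labels))

#' Subset an EpochSet by epoch index
#' @param x an EpochSet
#' @param i epoch indices
#' @param j,...,drop ignored
#' @export
setMethod("[", "EpochSet", function(x, i, j, ..., drop = FALSE) {
  new("EpochSet",
      data = x@data[, , i, drop = FALSE],
      labels = factor(as.character(x@labels[i]),
                      levels = c("MRCP", "NON_MRCP")),
      fs = x@fs, channelNames = x@channelNames, band = x@band,
      sourceEvent = x@sourceEvent[i])
})

#' @rdname FactorialResult-class
#' @param object an object
#' @export
setGeneric("gridTable", function(object) standardGeneric("gridTable"))
#' @rdname FactorialResult-class
#' @export
setMethod("gridTable", "FactorialResult", function(object) object@grid)

#' @rdname FactorialResult-class
#' @export
setGeneric("bestTable", function(object) standardGeneric("bestTable"))
#' @rdname FactorialResult-class
#' @export
setMethod("bestTable", "FactorialResult", function(object) object@best)

# internal constructor used throughout: build an EpochSet from a list of
# equally sized channels x samples matrices
makeEpochSet <- function(mats, labels, fs, channelNames, band = NA_character_,
                         sourceEvent = seq_along(mats)) {
  stopifnot(length(mats) == length(labels))
  if (!length(mats)) {
    arr <- array(numeric(0), dim = c(length(channelNames), 0L, 0L))
  } else {
    arr <- array(unlist(mats, use.names = FALSE),
                 dim = c(nrow(mats[[1L]]), ncol(mats[[1L]]), length(mats)))
  }
  new("EpochSet", data = arr,
      labels = factor(as.character(labels), levels = c("MRCP", "NON_MRCP")),
      fs = fs, channelNames = channelNames, band = band,
      sourceEvent = as.integer(sourceEvent))
}
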