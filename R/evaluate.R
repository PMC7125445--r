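#' F1 score from confusion counts
#'
#' Precision is TP/(TP+FP), recall TP/(TP+FN), and the F1 score their
#' harmonic mean \eqn{2 (recall^{-1} + precision^{-1})^{-1}}; all three are 0
#' when TP = 0 (zero-division convention).
#'
#' @param tp,fp,fn confusion counts (tp + fp + fn >= 1)
#' @return list with \code{precision}, \code{recall}, \code{f1}
#' @export
f1Score <- function(tp, fp, fn) {
  stopifnot(tp + fp + fn >= 1)
  if (tp == 0) return(list(precision = 0, recall = 0, f1 = 0))
  precision <- tp / (tp + fp)
  recall <- tp / (tp + fn)
  list(precision = precision, recall = recall,
       f1 = 2 / (1 / recall + 1 / precision))
}

#' Select the best channel/component row of a per-channel result table
#'
#' Argmax of F1; ties are broken by the lowest channel index (table order).
#'
#' @param rows data.frame with at least an \code{f1} column, one row per
#'   channel/component of one (subject, band, spatial, classifier) cell
#' @return the selected row
#' @export
selectBestChannel <- function(rows) {
  stopifnot(nrow(rows) >= 1L)
  rows[which.max(rows$f1), , drop = FALSE]
}

#' Configuration of a factorial benchmark run
#'
#' @param bands list of \code{\link{bandSpec}}s (default the five standard
#'   analysis bands)
#' @param spatials spatial methods to include
#' @param classifiers detectors to include
#' @param seed master integer seed; all per-subject seeds derive from it
#' @param decimateTo sampling rate (Hz) sessions are decimated to after band
#'   filtering, or NULL to stay at the native rate (default 64)
#' @param splitRatio training fraction (default 2/3)
#' @param thresholdOn "train" (default) calibrates MF/TM thresholds on the
#'   training set; "test" reproduces the optimistic test-calibrated variant
#' @param montage a \code{\link{standardMontage}}
#' @return list of class \code{GridConfig}
#' @export
gridConfig <- function(bands = analysisBands(),
                       spatials = c("NoF", "SL", "ICA", "CSP", "PCA"),
                       classifiers = c("LDA", "SVM", "NN_ED", "NN_DTW",
                                       "MF", "TM"),
                       seed = 1L, decimateTo = 64, splitRatio = 2 / 3,
                       thresholdOn = c("train", "test"),
                       montage = standardMontage()) {
  thresholdOn <- match.arg(thresholdOn)
  stopifnot(all(spatials %in% c("NoF", "SL", "ICA", "CSP", "PCA")),
            all(classifiers %in% c("LDA", "SVM", "NN_ED", "NN_DTW",
                                   "MF", "TM")))
  structure(list(bands = bands, spatials = spatials,
                 classifiers = classifiers, seed = as.integer(seed),
                 decimateTo = decimateTo, splitRatio = splitRatio,
                 thresholdOn = thresholdOn, montage = montage),
            class = "GridConfig")
}

# deterministic per-(subject, purpose) seed below 2^31
derivedSeed <- function(seed, subject, salt = 0L) {
  as.integer((as.numeric(seed) + 104729 * subject + 31 * salt) %%
               .Machine$integer.max)
}

#' Run the full band x spatial x channel x detector factorial grid
#'
#' For every subject and band: causal band filtering, optional decimation,
#' epoch segmentation (2-s windows, 4-s separation rule), z-normalization,
#' seeded stratified 2/3-1/3 split, spatial-model fitting on the training
#' partition only, then every detector fitted per output channel/component
#' and scored by F1 on the test partition. With the five standard bands, all
#' five spatial methods (19 + 9 + 19 + 19 + 1 = 67 outputs) and all six
#' detectors this yields 5 x 67 x 6 = 2010 grid rows and, after best-channel
#' selection, 5 x 5 x 6 = 150 cells per subject.
#'
#' Degenerate cells (e.g. a class lost to epoch drops) are recorded with an
#' NA F1 and a reason, never silently removed. Identical seeds give
#' identical tables.
#'
#' @param sessions named list of \code{\linkS4class{EEGSession}}s, one per
#'   subject
#' @param config a \code{\link{gridConfig}}
#' @param verbose print per-subject progress
#' @return a \code{\linkS4class{FactorialResult}}
#' @export
runGrid <- function(sessions, config = gridConfig(), verbose = FALSE) {
  stopifnot(inherits(config, "GridConfig"))
  subjects <- names(sessions)
  if (is.null(subjects)) subjects <- sprintf("S%02d", seq_along(sessions))
  rows <- list(); dropLogs <- list()
  for (s in seq_along(sessions)) {
    if (verbose) message("subject ", subjects[s])
    rows[[s]] <- runSubjectGrid(sessions[[s]], subjects[s], s, config)
  }
  grid <- do.call(rbind, rows)
  rownames(grid) <- NULL
  best <- bestChannelTable(grid)
  new("FactorialResult", grid = grid, best = best,
      meta = list(config = config, subjects = subjects))
}

runSubjectGrid <- function(session, subjectId, subjectIdx, config) {
  out <- list()
  for (b in seq_along(config$bands)) {
    band <- config$bands[[b]]
    filtered <- bandpassSession(session, band)
    if (!is.null(config$decimateTo))
      filtered <- decimateSession(filtered, config$decimateTo)
    epochs <- zNormalizeEpochs(segmentSession(filtered))
    enough <- length(epochs) >= 4L &&
      all(table(epochLabels(epochs)) >= 3L)
    split <- if (enough)
      stratifiedSplit(epochs, ratio = config$splitRatio,
                      seed = derivedSeed(config$seed, subjectIdx, b))
    else NULL
    for (sp in config$spatials) {
      rows <- gridCellRows(split, sp, band, subjectId, subjectIdx, b, config)
      out <- c(out, list(rows))
    }
  }
  do.call(rbind, out)
}

spatialOutputNames <- function(method, config) {
  switch(method,
    NoF = CHANNELS_1020,
    SL = config$montage$workingChannels,
    ICA = sprintf("IC%02d", seq_len(19L)),
    PCA = sprintf("PC%02d", seq_len(19L)),
    CSP = "CSP1")
}

emptyCellRows <- function(subjectId, band, method, config, reason) {
  outs <- spatialOutputNames(method, config)
  expand.grid(subject = subjectId, band = band$name, spatial = method,
              channel = outs, classifier = config$classifiers,
              stringsAsFactors = FALSE) |>
    transform(channelIndex = match(channel, outs),
              tp = NA_integer_, fp = NA_integer_, fn = NA_integer_,
              tn = NA_integer_, precision = NA_real_, recall = NA_real_,
              f1 = NA_real_, note = reason)
}

gridCellRows <- function(split, method, band, subjectId, subjectIdx,
                         bandIdx, config) {
  if (is.null(split))
    return(emptyCellRows(subjectId, band, method, config,
                         "too few epochs after segmentation"))
  model <- try(fitSpatial(method, split@train, montage = config$montage,
                          seed = derivedSeed(config$seed, subjectIdx,
                                             100L + bandIdx)),
               silent = TRUE)
  if (inherits(model, "try-error"))
    return(emptyCellRows(subjectId, band, method, config,
                         paste("spatial fit failed:",
                               conditionMessage(attr(model, "condition")))))
  trainP <- applySpatial(model, split@train)
  testP <- applySpatial(model, split@test)
  yTest <- epochLabels(testP)
  outs <- model@outputNames
  res <- list()
  for (ci in seq_along(outs)) {
    trainC <- singleChannel(trainP, ci)
    testC <- singleChannel(testP, ci)
    for (k in config$classifiers) {
      row <- data.frame(subject = subjectId, band = band$name,
                        spatial = method, channel = outs[ci],
                        channelIndex = ci, classifier = k,
                        tp = NA_integer_, fp = NA_integer_, fn = NA_integer_,
                        tn = NA_integer_, precision = NA_real_,
                        recall = NA_real_, f1 = NA_real_, note = "",
                        stringsAsFactors = FALSE)
      fit <- try({
        thrEp <- if (config$thresholdOn == "test" && k %in% c("MF", "TM"))
          testC else NULL
        m <- fitDetector(k, trainC,
                         seed = derivedSeed(config$seed, subjectIdx,
                                            1000L * bandIdx + ci),
                         thresholdEpochs = thrEp)
        pred <- predictDetector(m, testC)
        tp <- sum(pred == "MRCP" & yTest == "MRCP")
        fp <- sum(pred == "MRCP" & yTest == "NON_MRCP")
        fn <- sum(pred == "NON_MRCP" & yTest == "MRCP")
        tn <- sum(pred == "NON_MRCP" & yTest == "NON_MRCP")
        sc <- f1Score(tp, fp, fn)
        row[c("tp", "fp", "fn", "tn")] <- c(tp, fp, fn, tn)
        row[c("precision", "recall", "f1")] <-
          c(sc$precision, sc$recall, sc$f1)
        NULL
      }, silent = TRUE)
      if (inherits(fit, "try-error"))
        row$note <- paste("detector failed:",
                          conditionMessage(attr(fit, "condition")))
      res <- c(res, list(row))
    }
  }
  do.call(rbind, res)
}

singleChannel <- function(epochs, ci) {
  new("EpochSet",
      data = epochs@data[ci, , , drop = FALSE],
      labels = epochs@labels, fs = epochs@fs,
      channelNames = epochs@channelNames[ci], band = epochs@band,
      sourceEvent = epochs@sourceEvent)
}

# per (subject, band, spatial, classifier): keep the argmax-F1 channel,
# ties to the lowest channel index; all-NA cells stay NA with the reason
bestChannelTable <- function(grid) {
  key <- interaction(grid$subject, grid$band, grid$spatial, grid$classifier,
                     drop = TRUE)
  parts <- split(grid, key)
  best <- lapply(parts, function(rows) {
    rows <- rows[order(rows$channelIndex), , drop = FALSE]
    ok <- !is.na(rows$f1)
    if (!any(ok)) return(rows[1L, , drop = FALSE])
    selectBestChannel(rows[ok, , drop = FALSE])
  })
  out <- do.call(rbind, best)
  rownames(out) <- NULL
  out[order(out$subject, out$band, out$spatial, out$classifier), ,
      drop = FALSE]
}

#' Per-channel F1 map for the surface-Laplacian representation
#'
#' Extracts, for one subject, the test F1 of every SL surrogate channel at a
#' given band and classifier — the tabular equivalent of a topographic map
#' of detection performance.
#'
#' @param result a \code{\linkS4class{FactorialResult}}
#' @param subject subject id as used in the result tables
#' @param band band name (default "0.01-1")
#' @param classifier detector name (default "SVM")
#' @return data.frame with columns \code{channel}, \code{f1}
#' @export
channelF1Map <- function(result, subject, band = "0.01-1",
                         classifier = "SVM") {
  g <- gridTable(result)
  rows <- g[g$subject == subject & g$band == band & g$spatial == "SL" &
              g$classifier == classifier, , drop = FALSE]
  if (!nrow(rows))
    stop("no SL rows for this subject/band/classifier in the result")
  data.frame(channel = rows$channel, f1 = rows$f1,
             stringsAsFactors = FALSE)
}

#' Assemble the subject x cell response matrix for the ANOVA stage
#'
#' Builds the n-subject x 150-cell matrix of best-channel F1 scores in the
#' factor order (band fastest, then spatial, then classifier as configured).
#' Missing cells are imputed by the subject's own cell mean — for the ANOVA
#' stage only; raw tables are never imputed.
#'
#' @param result a \code{\linkS4class{FactorialResult}}
#' @return list with \code{response} (matrix, subjects x cells) and
#'   \code{factors} (named list of factor levels, fastest-varying first)
#' @export
factorialResponse <- function(result) {
  best <- bestTable(result)
  subjects <- unique(best$subject)
  cfg <- result@meta$config
  bands <- names(cfg$bands)
  cells <- expand.grid(band = bands, spatial = cfg$spatials,
                       classifier = cfg$classifiers,
                       stringsAsFactors = FALSE)
  Y <- matrix(NA_real_, length(subjects), nrow(cells),
              dimnames = list(subjects, NULL))
  cellKey <- paste(cells$band, cells$spatial, cells$classifier, sep = "|")
  rowIdx <- match(best$subject, subjects)
  colIdx <- match(paste(best$band, best$spatial, best$classifier, sep = "|"),
                  cellKey)
  Y[cbind(rowIdx, colIdx)] <- best$f1
  for (s in seq_len(nrow(Y))) {
    nas <- is.na(Y[s, ])
    if (any(nas)) Y[s, nas] <- mean(Y[s, ], na.rm = TRUE)
  }
  list(response = Y,
       factors = list(Freq = bands, SF = cfg$spatials,
                      Classifier = cfg$classifiers))
}
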