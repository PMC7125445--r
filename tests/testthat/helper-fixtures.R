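# shared fixtures and independent oracles, built in code at test time

# tiny session with hand-placed events on a flat recording
flatSession <- function(nChannels = 3, nSamples = 4000, fs = 100,
                        events = cbind(onset = integer(0),
                                       offset = integer(0))) {
  new("EEGSession",
      eeg = matrix(0, nChannels, nSamples,
                   dimnames = list(CHANNELS_1020[seq_len(nChannels)], NULL)),
      emg = numeric(nSamples), fs = fs,
      channelNames = CHANNELS_1020[seq_len(nChannels)],
      events = events, groundTruth = events, meta = list())
}

# EpochSet from a list of channels x samples matrices
epochsFromMats <- function(mats, labels, fs = 64,
                           channels = paste0("ch", seq_len(nrow(mats[[1]])))) {
  mrcpbench:::makeEpochSet(mats, labels, fs, channels)
}

# single-channel EpochSet from a matrix of series (one epoch per row)
seriesEpochs <- function(X, labels, fs = 64) {
  epochsFromMats(lapply(seq_len(nrow(X)), function(i)
    matrix(X[i, ], 1L)), labels, fs = fs, channels = "ch1")
}

# ---- independent oracles ----

# exhaustive DTW by enumerating all monotone warping paths inside the band;
# exponential, for series of length <= 12 only
bruteDtw <- function(a, b, r) {
  n <- length(a)
  w <- max(1L, ceiling(r * n))
  best <- Inf
  recurse <- function(i, j, acc) {
    if (abs(i - j) > w) return()
    acc <- acc + (a[i] - b[j])^2
    if (acc >= best) return()
    if (i == n && j == n) { best <<- min(best, acc); return() }
    if (i < n && j < n) recurse(i + 1, j + 1, acc)
    if (i < n) recurse(i + 1, j, acc)
    if (j < n) recurse(i, j + 1, acc)
  }
  recurse(1L, 1L, 0)
  sqrt(best)
}

# exhaustive search over unit-vector angles for the best 2-channel variance
# ratio (CSP oracle)
bruteCspAngle <- function(C1, C2, nAngles = 360) {
  angles <- seq(0, pi, length.out = nAngles + 1L)[-(nAngles + 1L)]
  ratios <- vapply(angles, function(th) {
    v <- c(cos(th), sin(th))
    drop(v %*% C1 %*% v) / drop(v %*% C2 %*% v)
  }, 0)
  list(angle = angles[which.max(ratios)], ratio = max(ratios))
}

# confusion-matrix F1 computed the long way
bruteF1 <- function(pred, truth) {
  tp <- sum(pred == "MRCP" & truth == "MRCP")
  fp <- sum(pred == "MRCP" & truth == "NON_MRCP")
  fn <- sum(pred == "NON_MRCP" & truth == "MRCP")
  if (tp == 0) return(0)
  pr <- tp / (tp + fp); rc <- tp / (tp + fn)
  2 * pr * rc / (pr + rc)
}

# permutation null for chance-level F1: quantiles of F1 under random
# relabelling of the truth
permutationF1Band <- function(pred, truth, nPerm = 500, seed = 1,
                              probs = c(0.005, 0.995)) {
  set.seed(seed)
  sims <- replicate(nPerm, bruteF1(pred, sample(truth)))
  stats::quantile(sims, probs = probs, names = FALSE)
}

# run one band of the standard pipeline on a session and return the
# projected train/test sets for a spatial method
pipelineOneBand <- function(session, band = "0.01-1", spatial = "SL",
                            seed = 7, decimateTo = 64) {
  filt <- bandpassSession(session, analysisBands()[[band]])
  if (!is.null(decimateTo)) filt <- decimateSession(filt, decimateTo)
  ep <- zNormalizeEpochs(segmentSession(filt))
  sp <- stratifiedSplit(ep, seed = seed)
  model <- fitSpatial(spatial, sp@train, seed = seed)
  list(train = applySpatial(model, sp@train),
       test = applySpatial(model, sp@test),
       model = model, split = sp)
}

channelEpochs <- function(epochs, i) mrcpbench:::singleChannel(epochs, i)

testF1 <- function(model, testEpochs) {
  pred <- predictDetector(model, testEpochs)
  bruteF1(pred, epochLabels(testEpochs))
}
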