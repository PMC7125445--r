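#' Names of the 19 monopolar 10-20 channels used throughout
#' @export
CHANNELS_1020 <- c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "T3", "C3",
                   "Cz", "C4", "T4", "T5", "P3", "Pz", "P4", "T6", "O1", "O2")

defaultSpatialSpread <- function(channels = CHANNELS_1020,
                                 focusChannel = "Cz") {
  # focal slow negativity: full weight at the focus, 0.6 on the ring of
  # fronto-central/parietal neighbors, 0.3 on the periphery
  w <- stats::setNames(rep(0.3, length(channels)), channels)
  ring <- c("Fz", "Pz", "C3", "C4")
  w[intersect(ring, channels)] <- 0.6
  w[focusChannel] <- 1.0
  w
}

#' Sharply focal spatial spread around one channel
#'
#' Attenuation weights for a compact cortical source: 1 at the focus, 0.35
#' at its montage neighbors, 0.1 elsewhere. Used by the localization
#' (channel-map) recovery experiments, where the source must actually be
#' focal for a topographic peak to be recoverable; the default
#' 1 / 0.6-ring / 0.3 spread describes a more diffuse source.
#'
#' @param focus focus channel name
#' @param montage a \code{\link{standardMontage}}
#' @param channels channel names
#' @return named weight vector
#' @export
focalSpatialSpread <- function(focus, montage = standardMontage(),
                               channels = CHANNELS_1020) {
  w <- stats::setNames(rep(0.1, length(channels)), channels)
  w[intersect(montage$neighbors[[focus]], channels)] <- 0.35
  w[focus] <- 1
  w
}

#' Configuration for the synthetic self-paced movement session generator
#'
#' The generator emulates a self-paced ballistic dorsiflexion protocol:
#' 19 channels of 10-20 EEG sampled at 1024 Hz, trials separated by idle
#' gaps drawn uniformly from \code{idleRange} seconds, a slow negative
#' pre-movement deflection (MRCP-like) spatially focused at
#' \code{focusChannel}, additive background noise, and an EMG channel whose
#' bursts mark movement onsets and offsets.
#'
#' @param nChannels number of EEG channels (default 19)
#' @param channels channel names (default the 19-channel 10-20 list)
#' @param fs sampling rate in Hz (default 1024)
#' @param nTrials number of movement trials
#' @param idleRange numeric length-2, min/max idle gap between an offset and
#'   the next onset, in seconds (default c(3, 7))
#' @param mrcpAmplitude depth of the pre-movement negative ramp, in units of
#'   the background-noise standard deviation (default 1)
#' @param mrcpDuration ramp duration in seconds (default 2)
#' @param mrcpShape "ramp" (linear descent) or "cosine" (half-cosine descent)
#' @param reboundDuration seconds to return to baseline after onset
#' @param focusChannel channel carrying the full-amplitude deflection
#' @param spatialSpread named per-channel attenuation weights in [0, 1] with
#'   weight 1 at \code{focusChannel}; default 1 at the focus, 0.6 at
#'   Fz/Pz/C3/C4, 0.3 elsewhere
#' @param noiseModel "pink" (1/f amplitude spectrum, default) or "white"
#' @param noiseSd noise standard deviation (default 1)
#' @param emgBurstDuration movement (EMG burst) duration in seconds
#' @param emgBurstGain burst amplitude as a multiple of the EMG baseline
#'   standard deviation (default 10)
#' @param seed integer RNG seed
#' @return a list of class \code{SynthConfig}
#' @export
synthConfig <- function(nChannels = 19L, channels = CHANNELS_1020[seq_len(nChannels)],
                        fs = 1024, nTrials = 30L, idleRange = c(3, 7),
                        mrcpAmplitude = 1, mrcpDuration = 2,
                        mrcpShape = c("ramp", "cosine"),
                        reboundDuration = 0.5,
                        focusChannel = "Cz",
                        spatialSpread = defaultSpatialSpread(channels, focusChannel),
                        noiseModel = c("pink", "white"), noiseSd = 1,
                        emgBurstDuration = 0.5, emgBurstGain = 10,
                        seed = 1L) {
  mrcpShape <- match.arg(mrcpShape)
  noiseModel <- match.arg(noiseModel)
  stopifnot(fs > 0, nTrials >= 1, mrcpDuration > 0,
            length(idleRange) == 2L, idleRange[1L] <= idleRange[2L],
            noiseSd >= 0, mrcpAmplitude >= 0, emgBurstDuration > 0)
  if (length(channels) != nChannels)
    stop("channels must have length nChannels")
  if (!focusChannel %in% channels)
    stop("focusChannel must be one of the configured channels")
  spatialSpread <- spatialSpread[channels]
  if (anyNA(spatialSpread) || any(spatialSpread < 0) || any(spatialSpread > 1))
    stop("spatialSpread must assign a weight in [0,1] to every channel")
  if (!isTRUE(all.equal(unname(spatialSpread[focusChannel]), 1)))
    stop("spatialSpread must be 1 at the focus channel")
  if (idleRange[1L] < mrcpDuration + reboundDuration)
    stop("idleRange minimum must be at least mrcpDuration + reboundDuration ",
         "so consecutive deflections cannot overlap")
  structure(list(
    nChannels = as.integer(nChannels), channels = channels, fs = fs,
    nTrials = as.integer(nTrials), idleRange = idleRange,
    mrcpAmplitude = mrcpAmplitude, mrcpDuration = mrcpDuration,
    mrcpShape = mrcpShape, reboundDuration = reboundDuration,
    focusChannel = focusChannel, spatialSpread = spatialSpread,
    noiseModel = noiseModel, noiseSd = noiseSd,
    emgBurstDuration = emgBurstDuration, emgBurstGain = emgBurstGain,
    seed = as.integer(seed)), class = "SynthConfig")
}

# unit-variance pink noise: white noise reshaped in the frequency domain
# with a 1/f amplitude profile (DC component zeroed)
pinkNoise <- function(n) {
  # FFT at a highly composite length (then truncate) to keep the transform
  # O(n log n) for arbitrary n
  m <- stats::nextn(n, c(2, 3, 5))
  white <- stats::rnorm(m)
  spec <- stats::fft(white)
  f <- c(0, seq_len(m - 1))
  f <- pmin(f, m - f) # two-sided frequency index
  amp <- ifelse(f == 0, 0, 1 / sqrt(f))
  shaped <- Re(stats::fft(spec * amp, inverse = TRUE))[seq_len(n)] / m
  s <- stats::sd(shaped)
  if (s > 0) shaped / s else shaped
}

# the single-trial deflection waveform sampled at fs: descent to -amplitude
# over mrcpDuration ending at the movement onset, rebound to 0 afterwards
mrcpWaveform <- function(cfg) {
  nRamp <- round(cfg$mrcpDuration * cfg$fs)
  nReb <- round(cfg$reboundDuration * cfg$fs)
  ph <- seq_len(nRamp) / nRamp
  ramp <- if (cfg$mrcpShape == "ramp") -cfg$mrcpAmplitude * ph
          else -cfg$mrcpAmplitude * (1 - cos(pi * ph)) / 2
  reb <- if (nReb > 0) -cfg$mrcpAmplitude * (1 - seq_len(nReb) / nReb)
         else numeric(0)
  list(ramp = ramp, rebound = reb)
}

#' Generate a synthetic self-paced movement session
#'
#' Deterministic for a fixed \code{cfg$seed}. Each trial contributes a slow
#' negative deflection of duration \code{mrcpDuration} ending at the movement
#' onset (scaled per channel by \code{spatialSpread}), and an EMG burst
#' (rectified white noise under a raised-cosine envelope, positive at every
#' sample) spanning onset to offset. Idle gaps between an offset and the next
#' onset are drawn uniformly from \code{idleRange}.
#'
#' @param cfg a \code{\link{synthConfig}}
#' @return an \code{\linkS4class{EEGSession}}; \code{sessionEvents} and the
#'   ground-truth slot both hold the true (onset, offset) sample pairs
#' @export
generateSession <- function(cfg) {
  stopifnot(inherits(cfg, "SynthConfig"))
  withr_seed <- cfg$seed
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(withr_seed)

  fs <- cfg$fs
  burstLen <- round(cfg$emgBurstDuration * fs)
  # layout: lead-in idle, then nTrials bursts separated by idle gaps,
  # then a tail long enough for the last post-offset epoch
  gaps <- stats::runif(cfg$nTrials, cfg$idleRange[1L], cfg$idleRange[2L])
  lead <- max(gaps[1L], cfg$mrcpDuration + cfg$reboundDuration + 0.5)
  onsets <- integer(cfg$nTrials)
  pos <- round(lead * fs) + 1L
  offsets <- integer(cfg$nTrials)
  for (i in seq_len(cfg$nTrials)) {
    if (i > 1L) pos <- offsets[i - 1L] + round(gaps[i] * fs) + 1L
    onsets[i] <- pos
    offsets[i] <- pos + burstLen - 1L
  }
  nSamples <- offsets[cfg$nTrials] + round((2.5) * fs)

  wf <- mrcpWaveform(cfg)
  trialShape <- c(wf$ramp, wf$rebound)
  nRamp <- length(wf$ramp)

  # focus-channel deflection train
  defl <- numeric(nSamples)
  for (i in seq_len(cfg$nTrials)) {
    idx <- (onsets[i] - nRamp):(onsets[i] - nRamp + length(trialShape) - 1L)
    keep <- idx >= 1L & idx <= nSamples
    defl[idx[keep]] <- defl[idx[keep]] + trialShape[keep]
  }

  eeg <- matrix(0, nrow = cfg$nChannels, ncol = nSamples,
                dimnames = list(cfg$channels, NULL))
  for (ch in seq_len(cfg$nChannels)) {
    noise <- if (cfg$noiseSd > 0) {
      base <- if (cfg$noiseModel == "pink") pinkNoise(nSamples)
              else stats::rnorm(nSamples)
      cfg$noiseSd * base
    } else numeric(nSamples)
    eeg[ch, ] <- cfg$spatialSpread[ch] * defl + noise
  }

  # EMG: baseline noise plus bursts of rectified white noise under a
  # raised-cosine envelope that is strictly positive on every burst sample,
  # so noise-free bursts span exactly [onset, offset]
  baselineSd <- 0.1 * cfg$noiseSd
  emg <- if (baselineSd > 0) stats::rnorm(nSamples, sd = baselineSd)
         else numeric(nSamples)
  env <- sin(pi * (seq_len(burstLen) - 0.5) / burstLen)^2
  burstAmp <- cfg$emgBurstGain * max(baselineSd, 0.1)
  for (i in seq_len(cfg$nTrials)) {
    idx <- onsets[i]:offsets[i]
    emg[idx] <- emg[idx] + burstAmp * env * abs(stats::rnorm(burstLen))
  }

  ev <- cbind(onset = as.integer(onsets), offset = as.integer(offsets))
  new("EEGSession", eeg = eeg, emg = emg, fs = fs,
      channelNames = cfg$channels, events = ev, groundTruth = ev,
      meta = list(config = cfg))
}

#' Generate a cohort of synthetic subjects
#'
#' Per-subject sessions share the configuration but use distinct seeds
#' derived deterministically from \code{cfg$seed}.
#'
#' @param nSubjects number of subjects
#' @param cfg a \code{\link{synthConfig}} template
#' @return named list of \code{\linkS4class{EEGSession}} objects
#' @export
generateCohort <- function(nSubjects, cfg) {
  stopifnot(nSubjects >= 1)
  sessions <- vector("list", nSubjects)
  for (s in seq_len(nSubjects)) {
    cfgS <- cfg
    cfgS$seed <- (cfg$seed + 7919L * s) %% .Machine$integer.max
    sessions[[s]] <- generateSession(cfgS)
  }
  names(sessions) <- sprintf("S%02d", seq_len(nSubjects))
  sessions
}

#' Detect movement events from a surface EMG trace
#'
#' The trace is rectified and smoothed with a centered moving average;
#' maximal runs where the smoothed envelope exceeds \code{threshold} are
#' taken as movements, runs separated by less than \code{minGapS} seconds are
#' merged, and run edges are refined on the rectified raw trace against a
#' robust baseline level (3 x MAD; exact recovery when the baseline is
#' silent). Replaces the visual EMG inspection used for labelling real
#' recordings.
#'
#' @param emg numeric EMG trace
#' @param fs sampling rate in Hz
#' @param threshold envelope amplitude threshold (> 0)
#' @param minGapS runs closer than this many seconds are merged (default 0.5)
#' @param smoothS moving-average window in seconds (default 0.05)
#' @return integer matrix with columns \code{onset}, \code{offset}
#'   (1-based inclusive); zero rows when nothing exceeds the threshold
#' @export
detectEmgEvents <- function(emg, fs, threshold, minGapS = 0.5,
                            smoothS = 0.05) {
  stopifnot(threshold > 0, fs > 0)
  n <- length(emg)
  empty <- matrix(integer(0), 0L, 2L,
                  dimnames = list(NULL, c("onset", "offset")))
  if (!n) return(empty)
  rect <- abs(emg)
  w <- max(1L, round(smoothS * fs))
  kernel <- rep(1 / w, w)
  env <- as.numeric(stats::filter(rect, kernel, sides = 2))
  env[is.na(env)] <- 0
  above <- env > threshold
  if (!any(above)) return(empty)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- cbind(starts[r$values], ends[r$values])
  # merge runs separated by less than minGapS
  minGap <- round(minGapS * fs)
  merged <- runs[1L, , drop = FALSE]
  if (nrow(runs) > 1L) {
    for (i in 2L:nrow(runs)) {
      if (runs[i, 1L] - merged[nrow(merged), 2L] < minGap)
        merged[nrow(merged), 2L] <- runs[i, 2L]
      else merged <- rbind(merged, runs[i, , drop = FALSE])
    }
  }
  # refine edges on the raw rectified trace: extend each run outward to the
  # full extent of activity above a robust baseline level
  sigma <- stats::mad(emg)
  lo <- max(3 * sigma, .Machine$double.eps)
  out <- merged
  for (i in seq_len(nrow(merged))) {
    a <- merged[i, 1L]; b <- merged[i, 2L]
    while (a > 1L && rect[a - 1L] > lo) a <- a - 1L
    while (a <= b && rect[a] <= lo) a <- a + 1L
    while (b < n && rect[b + 1L] > lo) b <- b + 1L
    while (b >= a && rect[b] <= lo) b <- b - 1L
    out[i, ] <- c(a, b)
  }
  colnames(out) <- c("onset", "offset")
  storage.mode(out) <- "integer"
  out
}

#' Relabel a session's events from its EMG trace
#'
#' @param session an \code{\linkS4class{EEGSession}}
#' @param threshold envelope threshold passed to \code{\link{detectEmgEvents}}
#' @param ... further arguments to \code{\link{detectEmgEvents}}
#' @return the session with \code{events} replaced by the detections
#' @export
labelEventsFromEmg <- function(session, threshold, ...) {
  ev <- detectEmgEvents(emgData(session), samplingRate(session),
                        threshold, ...)
  initialize(session, events = ev)
}

# save/restore the global RNG state so generators are pure functions
.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
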