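# gain of the digital band-pass at frequency f (Hz), from its own transfer
# function; independent oracle for the filtering tests
butterGain <- function(band, fs, f) {
  ba <- signal::butter(2, c(band$lo, band$hi) * 2 / fs, "pass")
  z <- exp(1i * 2 * pi * f / fs)
  Mod(sum(ba$b * z^-(seq_along(ba$b) - 1)) /
        sum(ba$a * z^-(seq_along(ba$a) - 1)))
}

test_that("band filtering matches its transfer-function oracle", {
  fs <- 256
  sess <- flatSession(nChannels = 2, nSamples = 10 * fs, fs = fs)
  band <- bandSpec(1, 2)
  # zero in, zero out
  expect_equal(max(abs(eegData(bandpassSession(sess, band)))), 0)
  t <- seq_len(10 * fs) / fs
  # out-of-band 10 Hz tone: strongly attenuated after settling
  sess@eeg[1, ] <- sin(2 * pi * 10 * t)
  # in-band 1.5 Hz tone: steady-state gain from the transfer function
  sess@eeg[2, ] <- sin(2 * pi * 1.5 * t)
  out <- eegData(bandpassSession(sess, band))
  settle <- (2 * fs):(10 * fs)
  rmsOut10 <- sqrt(mean(out[1, settle]^2))
  expect_lt(rmsOut10 / sqrt(0.5), 0.05)
  rms15 <- sqrt(mean(out[2, (4 * fs):(10 * fs)]^2))
  gain <- butterGain(band, fs, 1.5)
  expect_equal(rms15 / sqrt(0.5), gain, tolerance = 0.02)
})

test_that("analysis filters are causal: impulse response is zero before the impulse", {
  fs <- 256
  sess <- flatSession(nChannels = 1, nSamples = 4 * fs, fs = fs)
  sess@eeg[1, 2 * fs] <- 1
  out <- eegData(bandpassSession(sess, bandSpec(1, 2)))
  expect_equal(max(abs(out[1, seq_len(2 * fs - 1)])), 0)
  expect_gt(max(abs(out[1, (2 * fs):(4 * fs)])), 0)
})

test_that("the 0.01-1 Hz band is numerically stable at fs = 1024", {
  fs <- 1024
  sess <- flatSession(nChannels = 1, nSamples = 60 * fs, fs = fs)
  set.seed(1)
  sess@eeg[1, ] <- rnorm(ncol(sess@eeg))
  out <- eegData(bandpassSession(sess, bandSpec(0.01, 1)))
  expect_true(all(is.finite(out)))
  expect_lt(max(abs(out)), 10)
})

test_that("invalid band configurations are rejected", {
  sess <- flatSession(fs = 100)
  expect_error(bandpassSession(sess, bandSpec(1, 60)), "Nyquist")
  expect_error(bandSpec(2, 1))
  expect_error(bandSpec(0, 1))
})

test_that("segmentation applies the 4-s separation and boundary drop rules", {
  fs <- 100
  # trials at gaps 5 s / 3 s / 6 s: trial 2 dropped entirely
  ev <- matrix(0L, 3, 2)
  ev[1, ] <- c(501L, 550L)                       # 5 s lead-in
  ev[2, ] <- c(550L + 300L + 1L, 550L + 350L)    # 3 s after offset 1
  ev[3, ] <- c(900L + 600L + 1L, 900L + 650L)    # 6 s after offset 2
  sess <- flatSession(nChannels = 2, nSamples = 4000, fs = fs,
                      events = ev)
  ep <- segmentSession(sess, windowS = 2, minSepS = 4)
  expect_identical(length(ep), 4L)
  expect_identical(as.character(epochLabels(ep)),
                   c("MRCP", "NON_MRCP", "MRCP", "NON_MRCP"))
  expect_identical(unique(ep@sourceEvent), c(1L, 3L))
  expect_match(attr(ep, "dropLog"), "trial 2", all = FALSE)
  # epoch windows: 2 s immediately before the onset / after the offset
  expect_identical(dim(epochData(ep))[2], 200L)
})

test_that("epochs that extend outside the recording are dropped individually", {
  fs <- 100
  ev <- matrix(c(100L, 150L), 1)
  sess <- flatSession(nChannels = 1, nSamples = 1000, fs = fs, events = ev)
  ep <- segmentSession(sess)
  expect_identical(length(ep), 1L)
  expect_identical(as.character(epochLabels(ep)), "NON_MRCP")
  expect_match(attr(ep, "dropLog"), "MRCP epoch dropped", all = FALSE)
})

test_that("default synthetic sessions with wide gaps keep every trial", {
  cfg <- synthConfig(nTrials = 10, idleRange = c(4.6, 7), seed = 3)
  s <- generateSession(cfg)
  ep <- segmentSession(s)
  expect_identical(length(ep), 20L)
  expect_identical(sum(epochLabels(ep) == "MRCP"), 10L)
})

test_that("z-normalization matches the population-SD closed form", {
  z <- zNormalize(c(1, 2, 3))
  expect_equal(z, c(-1.2247, 0, 1.2247), tolerance = 1e-4)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean(z^2)), 1, tolerance = 1e-12)
  # idempotent
  expect_equal(zNormalize(z), z, tolerance = 1e-12)
  # constant channel errors
  expect_error(zNormalize(rep(2, 10)), "constant")
  # per-channel on a matrix
  m <- rbind(1:4, c(5, 1, 3, 2))
  zm <- zNormalize(m)
  expect_equal(rowMeans(zm), c(0, 0), tolerance = 1e-12)
  expect_equal(rowMeans(zm^2), c(1, 1), tolerance = 1e-12)
})

test_that("degenerate epochs are dropped with a logged reason", {
  mats <- list(matrix(rnorm(20), 2), rbind(rnorm(10), rep(1, 10)))
  ep <- epochsFromMats(mats, c("MRCP", "NON_MRCP"))
  out <- zNormalizeEpochs(ep)
  expect_identical(length(out), 1L)
  expect_match(attr(out, "dropLog"), "epoch 2", all = FALSE)
})

test_that("stratified split reproduces the per-class floor rule", {
  # pooled class totals 184 MRCP / 163 non-MRCP -> 122/108 train, 62/55 test
  mats <- lapply(seq_len(184 + 163), function(i) matrix(rnorm(8), 1))
  ep <- epochsFromMats(mats, rep(c("MRCP", "NON_MRCP"), c(184, 163)))
  sp <- stratifiedSplit(ep, seed = 4)
  expect_equal(unname(table(epochLabels(sp@train))), c(122, 108),
               ignore_attr = TRUE)
  expect_equal(unname(table(epochLabels(sp@test))), c(62, 55),
               ignore_attr = TRUE)
  # 3 + 3 -> 2/2 train, 1/1 test
  ep2 <- epochsFromMats(lapply(1:6, function(i) matrix(rnorm(8), 1)),
                        rep(c("MRCP", "NON_MRCP"), 3))
  sp2 <- stratifiedSplit(ep2, seed = 1)
  expect_equal(unname(table(epochLabels(sp2@train))), c(2, 2),
               ignore_attr = TRUE)
})

test_that("split is a seed-deterministic partition", {
  mats <- lapply(1:30, function(i) matrix(rnorm(8), 1))
  ep <- epochsFromMats(mats, rep(c("MRCP", "NON_MRCP"), 15))
  ids <- function(e) apply(epochData(e), 3, function(m) paste(m, collapse = ","))
  sp1 <- stratifiedSplit(ep, seed = 8)
  sp2 <- stratifiedSplit(ep, seed = 8)
  expect_identical(epochData(sp1@train), epochData(sp2@train))
  # partition: union is the input, intersection empty
  all1 <- c(ids(sp1@train), ids(sp1@test))
  expect_setequal(all1, ids(ep))
  expect_identical(anyDuplicated(all1), 0L)
  # class absent errors
  epBad <- epochsFromMats(mats[1:4], rep("MRCP", 4))
  expect_error(stratifiedSplit(epBad), "2 epochs per class")
})

test_that("decimation preserves sub-band content and remaps events", {
  fs <- 1024
  cfg <- synthConfig(nTrials = 3, seed = 6)
  s <- generateSession(cfg)
  d <- decimateSession(bandpassSession(s, bandSpec(0.01, 1)), 64)
  expect_equal(samplingRate(d), 64)
  expect_equal(ncol(eegData(d)), ceiling(ncol(eegData(s)) / 16))
  expect_equal(unname(sessionEvents(d)[, 1]),
               as.integer(ceiling(sessionEvents(s)[, 1] / 16)))
  expect_error(decimateSession(s, 60), "divide")
})
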