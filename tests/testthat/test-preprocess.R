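test_that("common-average re-referencing zeroes the channel mean and is idempotent", {
  set.seed(41)
  rec <- eegRecording(matrix(rnorm(19 * 1000), 19), fs = 250)
  out <- rereferenceCommonAverage(rec)
  expect_lt(max(abs(colMeans(samples(out)))), 1e-10)
  expect_identical(reference(out), "common-average")
  again <- rereferenceCommonAverage(out)
  expect_equal(samples(again), samples(out))
  ## common-mode rejection: a constant offset on every channel is invisible
  shifted <- eegRecording(samples(rec) + 42, fs = 250)
  expect_equal(samples(rereferenceCommonAverage(shifted)), samples(out))
  ## two antisymmetric channels are already average-referenced
  x <- rnorm(100)
  anti <- eegRecording(rbind(x, -x), fs = 250)
  expect_equal(samples(rereferenceCommonAverage(anti)), samples(anti),
               ignore_attr = TRUE)
  expect_error(rereferenceCommonAverage(eegRecording(matrix(x, 1), fs = 250)),
               "2 channels")
})

test_that("a 5-minute recording fragments into 150 consecutive 2-s epochs", {
  rec <- eegRecording(matrix(0, 2, 300 * 250), fs = 250)
  ep <- makeEpochs(rec)
  expect_identical(length(keptMask(ep)), 150L)
  expect_true(all(keptMask(ep)))
})

test_that("epoch bookkeeping: kept + rejected = total = floor(duration / 2 s)", {
  for (durS in c(7, 20, 31)) {
    rec <- quickRecording(seed = durS, duration = durS)
    ep <- makeEpochs(rereferenceCommonAverage(rec),
                     amplitudeThreshold = 30, gradientThreshold = 8)
    km <- keptMask(ep)
    expect_identical(length(km), as.integer(durS %/% 2))
    expect_identical(sum(km) + sum(!km), length(km))
    expect_identical(length(rejectionLog(ep)), length(km))
  }
  expect_error(makeEpochs(eegRecording(matrix(0, 2, 100), fs = 250)),
               "shorter")
})

test_that("infinite thresholds keep every epoch of a clean recording", {
  ep <- makeEpochs(rereferenceCommonAverage(quickRecording(seed = 8)),
                   amplitudeThreshold = Inf, gradientThreshold = Inf)
  expect_true(all(keptMask(ep)))
  expect_true(all(rejectionLog(ep) == "ok"))
})

test_that("Welch PSD of a pure sinusoid peaks exactly at its frequency", {
  t <- seq(0, 20 - 1 / 250, by = 1 / 250)
  x <- rbind(sin(2 * pi * 10 * t), cos(2 * pi * 10 * t))
  ep <- makeEpochs(eegRecording(x, fs = 250), amplitudeThreshold = Inf,
                   gradientThreshold = Inf)
  ps <- welchPsd(ep)
  f <- freqs(ps)
  expect_equal(f, seq(2, 45, 0.5))
  expect_equal(f[which.max(spectrumPower(ps)[1, ])], 10)
})

test_that("a native resolution other than 0.5 Hz is rejected, not interpolated", {
  rec <- eegRecording(matrix(rnorm(2 * 1000), 2), fs = 250)
  ep <- makeEpochs(rec, epochLengthS = 1, amplitudeThreshold = Inf,
                   gradientThreshold = Inf)
  expect_error(welchPsd(ep), "0.5 Hz")
})

test_that("Welch estimate variance shrinks as 1/(kept epochs)", {
  noiseRec <- function(durS, seed) generateRecording(
    eegSimConfig(nChannels = 1, duration = durS, alphaPower = 0,
                 thetaPower = 0, aperiodicExponent = 0, seed = seed))
  binScatter <- function(durS, seed) {
    ps <- welchPsd(makeEpochs(noiseRec(durS, seed), amplitudeThreshold = Inf,
                              gradientThreshold = Inf))
    p <- spectrumPower(ps)[1, ]
    stats::var(p / mean(p))
  }
  ## 150 vs 10 epochs: relative bin variance should drop roughly 15-fold
  v10 <- mean(vapply(1:4, function(s) binScatter(20, s), numeric(1)))
  v150 <- mean(vapply(1:4, function(s) binScatter(300, s + 100), numeric(1)))
  expect_gt(v10 / v150, 6)
  expect_lt(v10 / v150, 40)
})

test_that("welchPsd refuses a recording with zero kept epochs", {
  rec <- eegRecording(matrix(1000 * rnorm(2 * 1000), 2), fs = 250)
  ep <- makeEpochs(rec, amplitudeThreshold = 1)
  expect_error(welchPsd(ep), "kept")
})

test_that("collapsing equals the bin-wise channel mean", {
  set.seed(12)
  pw <- matrix(rexp(19 * 87), 19)
  ps <- new("PowerSpectrum", freqs = stdGrid, power = pw,
            channelLabels = TEN_TWENTY_19, nEpochs = 1L)
  cs <- collapseSpectrum(ps)
  ## brute-force oracle: explicit per-bin loop
  oracle <- vapply(seq_len(87), function(j) sum(pw[, j]) / 19, numeric(1))
  expect_equal(spectrumPower(cs), oracle)
  ## identical channels collapse to any single channel
  same <- new("PowerSpectrum", freqs = stdGrid,
              power = matrix(pw[1, ], 3, 87, byrow = TRUE),
              channelLabels = c("a", "b", "c"), nEpochs = 1L)
  expect_equal(spectrumPower(collapseSpectrum(same)), pw[1, ])
  ## powers p and 3p average to 2p
  p3 <- new("PowerSpectrum", freqs = stdGrid,
            power = rbind(pw[1, ], 3 * pw[1, ]),
            channelLabels = c("a", "b"), nEpochs = 1L)
  expect_equal(spectrumPower(collapseSpectrum(p3)), 2 * pw[1, ])
})

test_that("spectrum CSV round-trips per-channel and collapsed power", {
  ps <- welchPsd(makeEpochs(rereferenceCommonAverage(quickRecording(seed = 2,
                                                                    duration = 8))))
  path <- withr::local_tempfile(fileext = ".csv")
  writeSpectrumCsv(ps, path)
  back <- readSpectrumCsv(path)
  expect_equal(freqs(back$spectrum), freqs(ps))
  expect_equal(spectrumPower(back$spectrum), spectrumPower(ps),
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(spectrumPower(back$collapsed),
               spectrumPower(collapseSpectrum(ps)), tolerance = 1e-6)
})

test_that("optional band-pass attenuates out-of-band content without phase shift", {
  t <- seq(0, 8 - 1 / 250, by = 1 / 250)
  x <- sin(2 * pi * 10 * t) + sin(2 * pi * 100 * t)
  rec <- eegRecording(rbind(x, x), fs = 250)
  filt <- bandpassFilter(rec, 0.3, 70)
  ## 100 Hz content gone, 10 Hz retained and in phase
  keep <- 500:1500
  expect_gt(cor(samples(filt)[1, keep], sin(2 * pi * 10 * t)[keep]), 0.99)
})
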