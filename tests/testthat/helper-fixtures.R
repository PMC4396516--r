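## Shared fixture builders; everything is generated in code at test time.

stdGrid <- seq(2, 45, by = 0.5)

## Collapsed spectrum from an arbitrary non-negative curve on the grid.
toySpectrum <- function(power, freqs = stdGrid)
  collapsedSpectrum(freqs, power)

## 1/f trend plus a Gaussian alpha bump; trough location is controlled by
## the bump's lower tail against the decaying trend.
bumpSpectrum <- function(iafHz = 10, bumpAmp = 3, bumpSd = 0.7,
                         trend = 10 / stdGrid)
  toySpectrum(trend + bumpAmp * exp(-(stdGrid - iafHz)^2 / (2 * bumpSd^2)))

## Short synthetic recording for tests that only need plumbing.
quickRecording <- function(seed = 1, duration = 20, ...)
  generateRecording(eegSimConfig(duration = duration, seed = seed, ...))

## Collapsed spectrum of a recording via the standard chain.
recordingSpectrum <- function(rec, ...)
  collapseSpectrum(welchPsd(makeEpochs(rereferenceCommonAverage(rec), ...)))
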