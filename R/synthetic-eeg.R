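## Synthetic resting-state EEG with known spectral ground truth.
##
## Each channel is a sum of three unit-variance processes scaled by the
## config amplitudes: a 1/f^beta aperiodic background, a narrow-band alpha
## oscillation centred at iafTrue, and a narrow-band theta component.
## Oscillations are band-filtered Gaussian noise (spectral-domain Gaussian
## amplitude windows), not pure tones, so peaks have realistic width.

## Evaluate expr with a private, reproducible RNG stream; the caller's
## global .Random.seed is left untouched.
withSeed <- function(seed, expr) {
  hasSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (hasSeed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (hasSeed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

## White Gaussian noise shaped in the frequency domain by ampFun(f) and
## rescaled to unit variance.  ampFun receives folded frequencies in Hz.
shapedNoise <- function(n, fs, ampFun) {
  z <- stats::fft(stats::rnorm(n))
  f <- (seq_len(n) - 1) * fs / n
  fFold <- pmin(f, fs - f)
  a <- ampFun(fFold)
  a[1] <- 0                                   # no DC
  x <- Re(stats::fft(z * a, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s == 0) x else x / s
}

aperiodicAmp <- function(beta) {
  function(f) {
    fc <- pmin(pmax(f, 0.3), 70)              # exponent applied over 0.3-70 Hz
    a <- fc^(-beta / 2)
    a[f > 70 | f < 0.05] <- 0                 # acquisition band edge
    a
  }
}

gaussianBumpAmp <- function(centre, sigma) {
  function(f) exp(-(f - centre)^2 / (2 * sigma^2))
}

#' Generate a synthetic multichannel resting-state EEG recording
#'
#' Simulates an eyes-closed recording as, per channel, the sum of a
#' 1/f^beta aperiodic background, a narrow-band alpha oscillation centred at
#' `iafTrue` and a narrow-band theta component, each an independent (up to
#' the configured inter-channel coherence) band-filtered Gaussian noise
#' process with a random per-channel gain (+/-20\%).  Units are nominal
#' microvolts; the absolute scale is irrelevant downstream because all band
#' powers are relative.
#'
#' With the default amplitudes the collapsed Welch spectrum has its 5-14 Hz
#' maximum within one 0.5 Hz bin of `iafTrue`.  Identical configs (including
#' seed) give bitwise-identical samples.
#'
#' @param config An [eegSimConfig()] object.
#' @return An [eegRecording()] (reference `"linked-mastoid"`).  If
#'   `artifactRate > 0`, artifacts are injected and the event log is attached
#'   as attribute `"artifactLog"`.
#' @examples
#' rec <- generateRecording(eegSimConfig(duration = 10, seed = 42))
#' rec
#' @seealso [injectArtifacts()], [welchPsd()], [detectAnchors()]
#' @export
generateRecording <- function(config) {
  stopifnot(is(config, "EegSimConfig"))
  validObject(config)
  n <- round(config@duration * config@fs)
  nch <- config@nChannels
  alphaSigma <- 0.6    # Hz, spectral half-width of the alpha process
  thetaSigma <- 0.8
  muVScale <- 5        # nominal microvolt scaling of unit-variance components

  rec <- withSeed(config@seed, {
    comp <- function(ampFun, coherent) {
      ## shared + channel-specific realizations mixed by channelCoherence
      rho <- config@channelCoherence
      shared <- if (rho > 0 && coherent) shapedNoise(n, config@fs, ampFun) else NULL
      out <- matrix(0, nch, n)
      for (ch in seq_len(nch)) {
        own <- shapedNoise(n, config@fs, ampFun)
        x <- if (is.null(shared)) own else sqrt(rho) * shared + sqrt(1 - rho) * own
        gain <- stats::runif(1, 0.8, 1.2)     # channel heterogeneity
        out[ch, ] <- gain * x
      }
      out
    }
    bg <- comp(aperiodicAmp(config@aperiodicExponent), coherent = FALSE)
    sig <- config@noiseScale * bg
    if (config@alphaPower > 0)
      sig <- sig + config@alphaPower *
        comp(gaussianBumpAmp(config@iafTrue, alphaSigma), coherent = TRUE)
    if (config@thetaPower > 0)
      sig <- sig + config@thetaPower *
        comp(gaussianBumpAmp(config@thetaFreq, thetaSigma), coherent = TRUE)
    eegRecording(muVScale * sig, fs = config@fs,
                 channelLabels = if (nch == 19) TEN_TWENTY_19 else NULL)
  })
  if (config@artifactRate > 0)
    rec <- injectArtifacts(rec, rate = config@artifactRate,
                           amplitude = 500, seed = config@seed + 1L)
  rec
}

#' Inject high-amplitude transient artifacts into a recording
#'
#' Adds short tapered high-amplitude transients (half-sine pulses of ~120 ms)
#' at Poisson-distributed times, emulating the gross ocular/muscular events
#' that epoch rejection must catch.  Each event hits a random subset of 4-8
#' channels (such events are spatially localized, and a common-mode pulse
#' would mostly cancel under the common average reference).  The event log
#' records each event's onset sample and peak amplitude.
#'
#' @param rec An [eegRecording()].
#' @param rate Expected events per minute (>= 0); `rate = 0` returns the
#'   input unchanged with an empty log.
#' @param amplitude Peak amplitude of each transient in signal units
#'   (must be positive).
#' @param seed Integer seed; fixed seed gives identical event logs.
#' @return The contaminated `EegRecording`, with the event log (a data.frame
#'   with columns `sample`, `time_s`, `amplitude`) attached as attribute
#'   `"artifactLog"`.
#' @export
injectArtifacts <- function(rec, rate, amplitude = 500, seed = 1L) {
  stopifnot(is(rec, "EegRecording"))
  if (rate < 0) stop("rate: must be >= 0")
  if (amplitude <= 0) stop("amplitude: must be positive")
  emptyLog <- data.frame(sample = integer(), time_s = numeric(),
                         amplitude = numeric())
  if (rate == 0) {
    attr(rec, "artifactLog") <- emptyLog
    return(rec)
  }
  x <- rec@samples
  n <- ncol(x)
  fs <- rec@fs
  pulseLen <- max(3L, round(0.12 * fs))
  pulse <- sin(pi * seq_len(pulseLen) / (pulseLen + 1))  # tapered, peak ~1
  out <- withSeed(seed, {
    nEvents <- stats::rpois(1, rate * n / fs / 60)
    if (nEvents > 0) {
      starts <- sort(sample.int(n - pulseLen, nEvents, replace = FALSE))
      for (s in starts) {
        nHit <- sample(4:min(8, nrow(x)), 1)
        hit <- sample.int(nrow(x), nHit)
        gains <- numeric(nrow(x))
        gains[hit] <- stats::runif(nHit, 0.8, 1.2)       # per-channel severity
        idx <- s:(s + pulseLen - 1)
        x[, idx] <- x[, idx] + amplitude * (gains %o% pulse)
      }
      list(x = x, log = data.frame(sample = starts, time_s = (starts - 1) / fs,
                                   amplitude = amplitude))
    } else list(x = x, log = emptyLog)
  })
  res <- eegRecording(out$x, fs = fs, channelLabels = rec@channelLabels,
                      reference = rec@reference)
  attr(res, "artifactLog") <- out$log
  res
}

#' Retrieve the artifact event log of a recording
#'
#' @param rec An [eegRecording()] returned by [injectArtifacts()] or
#'   [generateRecording()].
#' @return A data.frame with columns `sample`, `time_s`, `amplitude`
#'   (zero rows for a clean recording).
#' @export
artifactLog <- function(rec) {
  lg <- attr(rec, "artifactLog")
  if (is.null(lg)) data.frame(sample = integer(), time_s = numeric(),
                              amplitude = numeric())
  else lg
}
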