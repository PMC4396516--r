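#' @import methods
NULL

#' Standard 19-channel 10-20 montage labels
#'
#' Electrode names of the classic 19-site 10-20 scalp montage, in the
#' conventional anterior-to-posterior order.
#'
#' @format Character vector of length 19.
#' @export
TEN_TWENTY_19 <- c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
                   "T3", "C3", "Cz", "C4", "T4",
                   "T5", "P3", "Pz", "P4", "T6", "O1", "O2")

## The analysis grid shared by every spectral object: 0.5 Hz bins, 2-45 Hz.
standardFreqGrid <- function() seq(2, 45, by = 0.5)

## ---------------------------------------------------------------------------
## Simulation configuration
## ---------------------------------------------------------------------------

#' @rdname eegSimConfig
#' @export
setClass("EegSimConfig",
         representation(nChannels = "integer",
                        fs = "numeric",
                        duration = "numeric",
                        iafTrue = "numeric",
                        alphaPower = "numeric",
                        thetaFreq = "numeric",
                        thetaPower = "numeric",
                        aperiodicExponent = "numeric",
                        noiseScale = "numeric",
                        artifactRate = "numeric",
                        channelCoherence = "numeric",
                        seed = "integer"))

setValidity("EegSimConfig", function(object) {
  msgs <- character()
  if (object@nChannels < 1) msgs <- c(msgs, "nChannels: must be >= 1")
  if (object@fs <= 2 * 45) msgs <- c(msgs, "fs: must exceed 90 Hz so the 2-45 Hz range is representable")
  n <- object@duration * object@fs
  if (abs(n - round(n)) > 1e-8) msgs <- c(msgs, "duration: duration * fs must be an integer sample count")
  if (object@duration <= 0) msgs <- c(msgs, "duration: must be positive")
  if (object@iafTrue < 5 || object@iafTrue > 14) msgs <- c(msgs, "iafTrue: must lie in [5, 14] Hz")
  if (object@alphaPower < 0) msgs <- c(msgs, "alphaPower: must be >= 0")
  if (object@thetaPower < 0) msgs <- c(msgs, "thetaPower: must be >= 0")
  if (object@thetaFreq <= 0 || object@thetaFreq >= object@iafTrue)
    msgs <- c(msgs, "thetaFreq: must be positive and below iafTrue")
  if (object@noiseScale < 0) msgs <- c(msgs, "noiseScale: must be >= 0")
  if (object@artifactRate < 0) msgs <- c(msgs, "artifactRate: must be >= 0")
  if (object@channelCoherence < 0 || object@channelCoherence > 1)
    msgs <- c(msgs, "channelCoherence: must lie in [0, 1]")
  if (length(msgs)) msgs else TRUE
})

#' Configuration for the synthetic resting-state EEG generator
#'
#' Bundles all parameters of [generateRecording()]: montage size, sampling
#' rate, duration, the true individual alpha frequency and the relative
#' strengths of the alpha, theta and aperiodic (1/f) components.  Defaults
#' describe a 5-minute, 19-channel, 250 Hz eyes-closed recording with a
#' clear 10 Hz alpha peak over a 1/f background.
#'
#' @param nChannels Number of scalp channels (default 19, the 10-20 montage).
#' @param fs Sampling rate in Hz (default 250).
#' @param duration Recording length in seconds (default 300).
#' @param iafTrue Ground-truth individual alpha frequency in Hz, in [5, 14].
#' @param alphaPower Relative amplitude (component SD) of the alpha
#'   oscillation; 0 removes it.
#' @param thetaFreq Centre frequency of the theta component in Hz.
#' @param thetaPower Relative amplitude of the theta component.
#' @param aperiodicExponent Exponent beta of the 1/f^beta background,
#'   applied over 0.3-70 Hz only; 0 gives band-limited white noise.
#' @param noiseScale Relative amplitude of the aperiodic background.
#' @param artifactRate Transient artifact rate in events/minute applied at
#'   generation time (0 = clean recording; see also [injectArtifacts()]).
#' @param channelCoherence Fraction (0-1) of each oscillatory component
#'   shared across channels. The study montage's true inter-channel
#'   coherence is unknown; this is an explicit knob, defaulting to 0.5.
#' @param seed Integer seed; identical seed + config give bitwise-identical
#'   recordings.
#' @return An `EegSimConfig` object.
#' @seealso [generateRecording()]
#' @export
eegSimConfig <- function(nChannels = 19L, fs = 250, duration = 300,
                         iafTrue = 10, alphaPower = 2, thetaFreq = 6,
                         thetaPower = 0.5, aperiodicExponent = 1,
                         noiseScale = 1, artifactRate = 0,
                         channelCoherence = 0.5, seed = 1L) {
  new("EegSimConfig", nChannels = as.integer(nChannels), fs = fs,
      duration = duration, iafTrue = iafTrue, alphaPower = alphaPower,
      thetaFreq = thetaFreq, thetaPower = thetaPower,
      aperiodicExponent = aperiodicExponent, noiseScale = noiseScale,
      artifactRate = artifactRate, channelCoherence = channelCoherence,
      seed = as.integer(seed))
}

## ---------------------------------------------------------------------------
## Recording and epochs
## ---------------------------------------------------------------------------

#' @rdname eegRecording
#' @export
setClass("EegRecording",
         representation(samples = "matrix",
                        fs = "numeric",
                        channelLabels = "character",
                        reference = "character"))

setValidity("EegRecording", function(object) {
  msgs <- character()
  if (nrow(object@samples) != length(object@channelLabels))
    msgs <- c(msgs, "channel count must match number of labels")
  if (any(!is.finite(object@samples)))
    msgs <- c(msgs, "samples contain non-finite values")
  if (object@fs <= 0) msgs <- c(msgs, "fs must be positive")
  if (!object@reference %in% c("linked-mastoid", "common-average"))
    msgs <- c(msgs, "reference must be 'linked-mastoid' or 'common-average'")
  if (length(msgs)) msgs else TRUE
})

#' Construct a multichannel EEG recording
#'
#' A `EegRecording` holds the raw signal matrix (channels x time, nominal
#' microvolts), the sampling rate and the montage labels, together with the
#' referencing state (`"linked-mastoid"` as acquired, or `"common-average"`
#' after [rereferenceCommonAverage()]).
#'
#' @param samples Numeric matrix, channels in rows, samples in columns.
#' @param fs Sampling rate in Hz.
#' @param channelLabels Character vector, one label per row of `samples`.
#' @param reference Referencing scheme of the data.
#' @return An `EegRecording`.
#' @export
eegRecording <- function(samples, fs, channelLabels = NULL,
                         reference = "linked-mastoid") {
  samples <- as.matrix(samples)
  if (is.null(channelLabels)) {
    channelLabels <- if (nrow(samples) == 19) TEN_TWENTY_19 else
      paste0("ch", seq_len(nrow(samples)))
  }
  new("EegRecording", samples = samples, fs = fs,
      channelLabels = as.character(channelLabels), reference = reference)
}

#' @rdname makeEpochs
#' @export
setClass("EpochSet",
         representation(epochs = "array",       # channels x samples x epochs
                        fs = "numeric",
                        epochLengthS = "numeric",
                        keptMask = "logical",
                        rejectionLog = "character",
                        channelLabels = "character"))

setValidity("EpochSet", function(object) {
  d <- dim(object@epochs)
  msgs <- character()
  if (length(d) != 3) msgs <- c(msgs, "epochs must be a 3-d array (channels x samples x epochs)")
  else {
    if (d[2] != round(object@epochLengthS * object@fs))
      msgs <- c(msgs, "epoch sample count must equal epochLengthS * fs")
    if (d[3] != length(object@keptMask) || d[3] != length(object@rejectionLog))
      msgs <- c(msgs, "keptMask and rejectionLog must have one entry per epoch")
  }
  if (length(msgs)) msgs else TRUE
})

## ---------------------------------------------------------------------------
## Spectra
## ---------------------------------------------------------------------------

#' @rdname welchPsd
#' @export
setClass("PowerSpectrum",
         representation(freqs = "numeric",
                        power = "matrix",        # channels x bins
                        channelLabels = "character",
                        nEpochs = "integer"))

validateGrid <- function(freqs) {
  msgs <- character()
  if (length(freqs) < 2) return("frequency grid needs at least two bins")
  if (max(abs(diff(freqs) - 0.5)) > 1e-9)
    msgs <- c(msgs, "grid spacing must be exactly 0.5 Hz")
  if (freqs[1] < 2 - 1e-9 || freqs[length(freqs)] > 45 + 1e-9)
    msgs <- c(msgs, "frequency range must lie within [2, 45] Hz")
  msgs
}

setValidity("PowerSpectrum", function(object) {
  msgs <- validateGrid(object@freqs)
  if (ncol(object@power) != length(object@freqs))
    msgs <- c(msgs, "power must have one column per frequency bin")
  if (any(object@power < 0)) msgs <- c(msgs, "power must be non-negative")
  if (length(msgs)) msgs else TRUE
})

#' @rdname collapseSpectrum
#' @export
setClass("CollapsedSpectrum",
         representation(freqs = "numeric",
                        power = "numeric"))

setValidity("CollapsedSpectrum", function(object) {
  msgs <- validateGrid(object@freqs)
  if (length(object@power) != length(object@freqs))
    msgs <- c(msgs, "power must have one value per frequency bin")
  if (any(object@power < 0)) msgs <- c(msgs, "power must be non-negative")
  if (length(msgs)) msgs else TRUE
})

#' Build a collapsed spectrum from a frequency grid and power vector
#'
#' Mostly useful for constructing analytic test spectra; pipeline code obtains
#' collapsed spectra from [collapseSpectrum()].
#'
#' @param freqs Frequency grid (must be 0.5 Hz spaced within 2-45 Hz).
#' @param power Non-negative power, one value per bin.
#' @return A `CollapsedSpectrum`.
#' @export
collapsedSpectrum <- function(freqs, power)
  new("CollapsedSpectrum", freqs = freqs, power = power)

## ---------------------------------------------------------------------------
## Anchors, bands, profiles
## ---------------------------------------------------------------------------

#' @rdname detectAnchors
#' @export
setClass("AnchorFrequencies",
         representation(tf = "numeric",
                        iaf = "numeric",
                        qualityFlags = "character"))

setValidity("AnchorFrequencies", function(object) {
  msgs <- character()
  if (object@iaf < 5 || object@iaf > 14) msgs <- c(msgs, "iaf must lie in [5, 14] Hz")
  if (object@tf >= object@iaf) msgs <- c(msgs, "tf must be below iaf")
  ## detected anchors sit on the 0.5 Hz grid; cohort-mean anchors are
  ## averages, so only the printed 0.1 Hz precision is enforced here
  onGrid <- function(x) abs(x * 10 - round(x * 10)) < 1e-6
  if (!onGrid(object@tf) || !onGrid(object@iaf))
    msgs <- c(msgs, "anchors must sit on a 0.1 Hz grid")
  if (length(msgs)) msgs else TRUE
})

#' Construct anchor frequencies directly
#'
#' @param tf Theta/alpha transition frequency in Hz.
#' @param iaf Individual alpha frequency peak in Hz.
#' @param qualityFlags Optional character vector of quality flags.
#' @return An `AnchorFrequencies` object.
#' @export
anchorFrequencies <- function(tf, iaf, qualityFlags = character())
  new("AnchorFrequencies", tf = tf, iaf = iaf, qualityFlags = qualityFlags)

#' @rdname deriveBands
#' @export
setClass("BandScheme",
         representation(bands = "matrix",     # 5 x 2 (low, high), rownames bands
                        mid = "numeric",
                        flags = "character"))

setValidity("BandScheme", function(object) {
  msgs <- character()
  b <- object@bands
  if (!identical(rownames(b), c("delta", "theta", "alpha1", "alpha2", "alpha3")))
    msgs <- c(msgs, "bands must be delta, theta, alpha1, alpha2, alpha3 in order")
  if (any(b[, 2] <= b[, 1])) msgs <- c(msgs, "each band must have positive width")
  ## contiguity (delta may have been truncated at the 2 Hz grid edge)
  if (any(abs(b[-1, 1] - b[-5, 2]) > 1e-9))
    msgs <- c(msgs, "bands must be contiguous")
  if (length(msgs)) msgs else TRUE
})

#' @rdname relativeBandPower
#' @export
setClass("BandPowerProfile",
         representation(relativePower = "numeric",  # named, 5 bands
                        alphaRatio = "numeric",
                        riskLabel = "character"))

setValidity("BandPowerProfile", function(object) {
  msgs <- character()
  if (any(object@relativePower < 0)) msgs <- c(msgs, "relative powers must be >= 0")
  if (length(object@alphaRatio) == 1 && is.finite(object@alphaRatio)) {
    if (object@alphaRatio < 0) msgs <- c(msgs, "alphaRatio must be >= 0")
    if (length(object@riskLabel) == 1 && !is.na(object@riskLabel) &&
        !identical(object@riskLabel, as.character(classifyRisk(object@alphaRatio))))
      msgs <- c(msgs, "riskLabel inconsistent with classifyRisk(alphaRatio)")
  }
  if (length(msgs)) msgs else TRUE
})

## ---------------------------------------------------------------------------
## Perfusion W-scores
## ---------------------------------------------------------------------------

#' @rdname fitControlModel
#' @export
setClass("ControlAgeModel",
         representation(coefficients = "data.frame",  # roi, intercept, slope, residualSd
                        nControls = "integer",
                        degenerate = "character"))

setValidity("ControlAgeModel", function(object) {
  msgs <- character()
  need <- c("roi", "intercept", "slope", "residualSd")
  if (!all(need %in% names(object@coefficients)))
    msgs <- c(msgs, "coefficients must have columns roi, intercept, slope, residualSd")
  else if (any(object@coefficients$residualSd < 0))
    msgs <- c(msgs, "residualSd must be >= 0")
  if (object@nControls < 3) msgs <- c(msgs, "nControls must be >= 3")
  if (length(msgs)) msgs else TRUE
})

## ---------------------------------------------------------------------------
## Radial morphometry
## ---------------------------------------------------------------------------

#' @rdname binaryMask3D
#' @export
setClass("BinaryMask3D",
         representation(voxels = "array",
                        voxelSize = "numeric"))

setValidity("BinaryMask3D", function(object) {
  msgs <- character()
  if (length(dim(object@voxels)) != 3) msgs <- c(msgs, "voxels must be a 3-d array")
  if (!is.logical(object@voxels)) msgs <- c(msgs, "voxels must be logical")
  if (!any(object@voxels)) msgs <- c(msgs, "mask must contain at least one foreground voxel")
  if (length(object@voxelSize) != 3 || any(object@voxelSize <= 0))
    msgs <- c(msgs, "voxelSize must be three positive mm values")
  if (length(msgs)) msgs else TRUE
})

#' Construct a 3D binary segmentation mask
#'
#' Wraps a logical voxel array with its physical voxel size.  Connectivity is
#' checked loosely: a mask whose foreground splits into several 6-connected
#' components is accepted with a warning, since downstream distances are still
#' defined.
#'
#' @param voxels Logical (or 0/1 numeric) 3-d array; `TRUE` = foreground.
#' @param voxelSize Voxel edge lengths in mm, length 1 (isotropic) or 3.
#' @param checkConnectivity Warn when the foreground is not a single
#'   6-connected component (default TRUE).
#' @return A `BinaryMask3D`.
#' @export
binaryMask3D <- function(voxels, voxelSize = c(1, 1, 1),
                         checkConnectivity = TRUE) {
  if (!is.logical(voxels)) {
    v <- array(voxels != 0, dim = dim(voxels))
    voxels <- v
  }
  if (length(voxelSize) == 1) voxelSize <- rep(voxelSize, 3)
  obj <- new("BinaryMask3D", voxels = voxels, voxelSize = as.numeric(voxelSize))
  if (checkConnectivity && countComponents6(voxels) > 1L)
    warning("mask foreground is not a single 6-connected component")
  obj
}

#' @rdname radialProfile
#' @export
setClass("RadialProfile",
         representation(medialCurve = "matrix",      # slices x 3, mm
                        boundaryPoints = "matrix",   # points x 3, mm
                        radialDistances = "numeric", # mm, one per boundary point
                        meanRadialDistance = "numeric",
                        volume = "numeric",          # mm^3
                        flags = "character"))

setValidity("RadialProfile", function(object) {
  msgs <- character()
  if (any(object@radialDistances < 0)) msgs <- c(msgs, "distances must be >= 0")
  if (nrow(object@boundaryPoints) != length(object@radialDistances))
    msgs <- c(msgs, "one distance per boundary point required")
  if (length(msgs)) msgs else TRUE
})

## ---------------------------------------------------------------------------
## Statistics
## ---------------------------------------------------------------------------

#' @rdname statResult
#' @export
setClass("StatResult",
         representation(statisticName = "character",
                        statisticValue = "numeric",
                        df = "numeric",
                        pTwoTailed = "numeric",
                        methodNotes = "character"))

setValidity("StatResult", function(object) {
  msgs <- character()
  if (is.finite(object@pTwoTailed) &&
      (object@pTwoTailed < 0 || object@pTwoTailed > 1))
    msgs <- c(msgs, "p must lie in [0, 1]")
  if (length(object@df) && any(is.finite(object@df) & object@df <= 0))
    msgs <- c(msgs, "df must be positive")
  if (length(msgs)) msgs else TRUE
})

#' Construct a statistical test result
#'
#' Light-weight container used by every test in the package: the named
#' statistic, its degrees of freedom (one or two values), the two-tailed p
#' and free-text method notes.
#'
#' @param statisticName e.g. `"t"`, `"F"`, `"chi-squared"`, `"r"`.
#' @param statisticValue Numeric value of the statistic.
#' @param df Degrees of freedom (length 1 or 2); may be empty.
#' @param pTwoTailed Two-tailed p-value.
#' @param methodNotes Character notes (test variant, degeneracies, ...).
#' @return A `StatResult`.
#' @export
statResult <- function(statisticName, statisticValue, df = numeric(),
                       pTwoTailed = NA_real_, methodNotes = character())
  new("StatResult", statisticName = statisticName,
      statisticValue = statisticValue, df = as.numeric(df),
      pTwoTailed = pTwoTailed, methodNotes = methodNotes)
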