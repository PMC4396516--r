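## Accessor generics and show methods.  Slots are never reached into from
## user code; these are the supported surface.

#' Accessors for eegBands objects
#'
#' Small family of read-only accessors: signal matrix, sampling rate, channel
#' labels and referencing state of a recording; frequency grid and power of a
#' spectrum; anchor frequencies, band table and relative powers; and the
#' pieces of a fitted control-age model or radial profile.
#'
#' @param object An object of the appropriate class.
#' @return The slot value (matrix, numeric vector, character, ...).
#' @name accessors
#' @aliases samples samplingRate channelLabels reference freqs spectrumPower
#'   keptMask rejectionLog tf iaf qualityFlags bandTable bandMid relativePower
#'   riskLabel modelTable nControls medialPoints surfacePoints radialValues
#'   meanRadialDistance maskVolume pValue statistic
NULL

#' @rdname accessors
#' @export
setGeneric("samples", function(object) standardGeneric("samples"))
#' @rdname accessors
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setGeneric("channelLabels", function(object) standardGeneric("channelLabels"))
#' @rdname accessors
#' @export
setGeneric("reference", function(object) standardGeneric("reference"))
#' @rdname accessors
#' @export
setGeneric("freqs", function(object) standardGeneric("freqs"))
#' @rdname accessors
#' @export
setGeneric("spectrumPower", function(object) standardGeneric("spectrumPower"))
#' @rdname accessors
#' @export
setGeneric("keptMask", function(object) standardGeneric("keptMask"))
#' @rdname accessors
#' @export
setGeneric("rejectionLog", function(object) standardGeneric("rejectionLog"))
#' @rdname accessors
#' @export
setGeneric("tf", function(object) standardGeneric("tf"))
#' @rdname accessors
#' @export
setGeneric("iaf", function(object) standardGeneric("iaf"))
#' @rdname accessors
#' @export
setGeneric("qualityFlags", function(object) standardGeneric("qualityFlags"))
#' @rdname accessors
#' @export
setGeneric("bandTable", function(object) standardGeneric("bandTable"))
#' @rdname accessors
#' @export
setGeneric("bandMid", function(object) standardGeneric("bandMid"))
#' @rdname accessors
#' @export
setGeneric("relativePower", function(object) standardGeneric("relativePower"))
#' @rdname accessors
#' @export
setGeneric("riskLabel", function(object) standardGeneric("riskLabel"))
#' @rdname accessors
#' @export
setGeneric("modelTable", function(object) standardGeneric("modelTable"))
#' @rdname accessors
#' @export
setGeneric("nControls", function(object) standardGeneric("nControls"))
#' @rdname accessors
#' @export
setGeneric("medialPoints", function(object) standardGeneric("medialPoints"))
#' @rdname accessors
#' @export
setGeneric("surfacePoints", function(object) standardGeneric("surfacePoints"))
#' @rdname accessors
#' @export
setGeneric("radialValues", function(object) standardGeneric("radialValues"))
#' @rdname accessors
#' @export
setGeneric("meanRadialDistance", function(object) standardGeneric("meanRadialDistance"))
#' @rdname accessors
#' @export
setGeneric("maskVolume", function(object) standardGeneric("maskVolume"))
#' @rdname accessors
#' @export
setGeneric("pValue", function(object) standardGeneric("pValue"))
#' @rdname accessors
#' @export
setGeneric("statistic", function(object) standardGeneric("statistic"))

setMethod("samples", "EegRecording", function(object) object@samples)
setMethod("samplingRate", "EegRecording", function(object) object@fs)
setMethod("channelLabels", "EegRecording", function(object) object@channelLabels)
setMethod("reference", "EegRecording", function(object) object@reference)

setMethod("samplingRate", "EpochSet", function(object) object@fs)
setMethod("keptMask", "EpochSet", function(object) object@keptMask)
setMethod("rejectionLog", "EpochSet", function(object) object@rejectionLog)
setMethod("channelLabels", "EpochSet", function(object) object@channelLabels)

setMethod("freqs", "PowerSpectrum", function(object) object@freqs)
setMethod("spectrumPower", "PowerSpectrum", function(object) object@power)
setMethod("channelLabels", "PowerSpectrum", function(object) object@channelLabels)
setMethod("freqs", "CollapsedSpectrum", function(object) object@freqs)
setMethod("spectrumPower", "CollapsedSpectrum", function(object) object@power)

setMethod("tf", "AnchorFrequencies", function(object) object@tf)
setMethod("iaf", "AnchorFrequencies", function(object) object@iaf)
setMethod("qualityFlags", "AnchorFrequencies", function(object) object@qualityFlags)

setMethod("bandTable", "BandScheme", function(object) object@bands)
setMethod("bandMid", "BandScheme", function(object) object@mid)
setMethod("qualityFlags", "BandScheme", function(object) object@flags)

setMethod("relativePower", "BandPowerProfile", function(object) object@relativePower)
setMethod("riskLabel", "BandPowerProfile", function(object) object@riskLabel)

setMethod("modelTable", "ControlAgeModel", function(object) object@coefficients)
setMethod("nControls", "ControlAgeModel", function(object) object@nControls)
setMethod("qualityFlags", "ControlAgeModel", function(object) object@degenerate)

setMethod("medialPoints", "RadialProfile", function(object) object@medialCurve)
setMethod("surfacePoints", "RadialProfile", function(object) object@boundaryPoints)
setMethod("radialValues", "RadialProfile", function(object) object@radialDistances)
setMethod("meanRadialDistance", "RadialProfile", function(object) object@meanRadialDistance)
setMethod("maskVolume", "RadialProfile", function(object) object@volume)
setMethod("qualityFlags", "RadialProfile", function(object) object@flags)

setMethod("pValue", "StatResult", function(object) object@pTwoTailed)
setMethod("statistic", "StatResult", function(object) object@statisticValue)

## ---------------------------------------------------------------------------
## show methods
## ---------------------------------------------------------------------------

setMethod("show", "EegRecording", function(object) {
  cat(sprintf("EegRecording: %d channels x %d samples (%.1f s @ %g Hz), reference=%s\n",
              nrow(object@samples), ncol(object@samples),
              ncol(object@samples) / object@fs, object@fs, object@reference))
})

setMethod("show", "EpochSet", function(object) {
  cat(sprintf("EpochSet: %d epochs of %g s (%d kept, %d rejected)\n",
              dim(object@epochs)[3], object@epochLengthS,
              sum(object@keptMask), sum(!object@keptMask)))
})

setMethod("show", "PowerSpectrum", function(object) {
  cat(sprintf("PowerSpectrum: %d channels, %d bins (%.1f-%.1f Hz, 0.5 Hz), %d epochs averaged\n",
              nrow(object@power), length(object@freqs),
              min(object@freqs), max(object@freqs), object@nEpochs))
})

setMethod("show", "CollapsedSpectrum", function(object) {
  cat(sprintf("CollapsedSpectrum: %d bins, %.1f-%.1f Hz\n",
              length(object@freqs), min(object@freqs), max(object@freqs)))
})

setMethod("show", "AnchorFrequencies", function(object) {
  cat(sprintf("AnchorFrequencies: TF=%.1f Hz, IAF=%.1f Hz%s\n",
              object@tf, object@iaf,
              if (length(object@qualityFlags))
                paste0(" [", paste(object@qualityFlags, collapse = ", "), "]")
              else ""))
})

setMethod("show", "BandScheme", function(object) {
  cat("BandScheme (Hz):\n")
  b <- object@bands
  for (i in seq_len(nrow(b)))
    cat(sprintf("  %-7s %4.1f - %4.1f\n", rownames(b)[i], b[i, 1], b[i, 2]))
  if (length(object@flags))
    cat("  flags:", paste(object@flags, collapse = ", "), "\n")
})

setMethod("show", "BandPowerProfile", function(object) {
  cat("BandPowerProfile:\n  relative power:",
      paste(sprintf("%s=%.3f", names(object@relativePower), object@relativePower),
            collapse = " "), "\n")
  if (is.finite(object@alphaRatio))
    cat(sprintf("  alpha3/alpha2 = %.3f (%s risk)\n",
                object@alphaRatio, object@riskLabel))
})

setMethod("show", "ControlAgeModel", function(object) {
  cat(sprintf("ControlAgeModel: %d ROIs fitted on %d controls\n",
              nrow(object@coefficients), object@nControls))
  if (length(object@degenerate))
    cat("  degenerate ROIs:", paste(object@degenerate, collapse = ", "), "\n")
})

setMethod("show", "BinaryMask3D", function(object) {
  cat(sprintf("BinaryMask3D: %s grid, voxel %s mm, %d foreground voxels\n",
              paste(dim(object@voxels), collapse = "x"),
              paste(object@voxelSize, collapse = "x"), sum(object@voxels)))
})

setMethod("show", "RadialProfile", function(object) {
  cat(sprintf("RadialProfile: %d surface points, %d medial points\n  mean radial distance %.2f mm, volume %.1f mm^3\n",
              nrow(object@boundaryPoints), nrow(object@medialCurve),
              object@meanRadialDistance, object@volume))
})

setMethod("show", "StatResult", function(object) {
  dfTxt <- if (length(object@df))
    paste0(" (df=", paste(signif(object@df, 4), collapse = ", "), ")") else ""
  cat(sprintf("%s = %.4g%s, two-tailed p = %.4g\n", object@statisticName,
              object@statisticValue, dfTxt, object@pTwoTailed))
  if (length(object@methodNotes))
    cat("  notes:", paste(object@methodNotes, collapse = "; "), "\n")
})
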