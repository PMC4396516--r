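## Individually anchored frequency bands.
##
## Two anchor frequencies are read off the collapsed spectrum: the IAF (the
## frequency of maximum power in the extended alpha range 5-14 Hz) and the
## TF (the theta/alpha transition, the spectral trough below the alpha
## peak).  Five bands follow: delta [TF-4, TF-2), theta [TF-2, TF),
## alpha1 [TF, mid), alpha2 [mid, IAF), alpha3 [IAF, IAF+2], with
## mid = (TF+IAF)/2.

BAND_NAMES <- c("delta", "theta", "alpha1", "alpha2", "alpha3")

#' Detect the TF and IAF anchor frequencies on a collapsed spectrum
#'
#' IAF is the frequency of maximum power within the extended alpha range
#' (5-14 Hz by default).  TF, the theta/alpha transition, is the frequency of
#' minimum power searched in `[tfLower, IAF - 1]` Hz; the search window
#' excludes the delta edge and forces TF < IAF, and among tied minima the
#' highest frequency (closest to the alpha peak) is taken.  Quality flags
#' record when the IAF bin is not a strict local maximum
#' (`"no-local-peak"`), when the trough power equals a neighbour's
#' (`"flat-trough"`), or when TF lands on a search-window edge
#' (`"tf-at-search-edge"`).
#'
#' @param cs A `CollapsedSpectrum` on the standard 0.5 Hz grid.
#' @param iafRange Search interval for the alpha peak, Hz (default c(5, 14)).
#' @param tfLower Lower edge of the TF search window, Hz (default 3).
#' @return An `AnchorFrequencies` object.
#' @examples
#' f <- seq(2, 45, 0.5)
#' p <- 1 / f + dnorm(f, 10, 0.7)            # 1/f trend + alpha bump
#' detectAnchors(collapsedSpectrum(f, p))
#' @export
detectAnchors <- function(cs, iafRange = c(5, 14), tfLower = 3) {
  stopifnot(is(cs, "CollapsedSpectrum"))
  f <- cs@freqs
  p <- cs@power
  flags <- character()

  inAlpha <- which(f >= iafRange[1] - 1e-9 & f <= iafRange[2] + 1e-9)
  if (!length(inAlpha)) stop("spectrum does not cover the IAF search range")
  iafIdx <- inAlpha[which.max(p[inAlpha])]
  iafHz <- f[iafIdx]
  localMax <- iafIdx > 1 && iafIdx < length(f) &&
    p[iafIdx] > p[iafIdx - 1] && p[iafIdx] > p[iafIdx + 1]
  if (!localMax) flags <- c(flags, "no-local-peak")

  tfUpper <- iafHz - 1
  inTf <- which(f >= tfLower - 1e-9 & f <= tfUpper + 1e-9)
  if (!length(inTf)) stop("degenerate anchors: empty TF search window below IAF")
  minP <- min(p[inTf])
  tfIdx <- max(inTf[p[inTf] <= minP + 1e-12])   # tie-break: highest frequency
  tfHz <- f[tfIdx]
  nb <- c(tfIdx - 1, tfIdx + 1)
  nb <- nb[nb >= 1 & nb <= length(f)]
  if (any(abs(p[nb] - p[tfIdx]) < 1e-12)) flags <- c(flags, "flat-trough")
  if (abs(tfHz - tfLower) < 1e-9 || abs(tfHz - tfUpper) < 1e-9)
    flags <- c(flags, "tf-at-search-edge")

  if (iafHz - tfHz < 1 - 1e-9)
    stop("degenerate anchors: IAF - TF < 1 Hz, band widths would collapse")
  anchorFrequencies(tf = tfHz, iaf = iafHz, qualityFlags = flags)
}

#' Derive the five individualized bands from the anchor frequencies
#'
#' Applies the anchoring rule: delta spans TF-4 to TF-2, theta TF-2 to TF,
#' the low alpha band runs from TF to IAF and is split at its midpoint into
#' alpha1 and alpha2, and alpha3 (high alpha) spans IAF to IAF+2.  When
#' TF-4 falls below the 2 Hz edge of the analysis grid, delta is truncated
#' at 2 Hz and the scheme is flagged `"delta-truncated"`.
#'
#' @param anchors An `AnchorFrequencies` object, or the TF value in Hz when
#'   `iaf` is also given.
#' @param iaf IAF in Hz (only when `anchors` is numeric).
#' @return A `BandScheme`.
#' @examples
#' deriveBands(anchorFrequencies(tf = 6.9, iaf = 10.9))
#' @export
deriveBands <- function(anchors, iaf = NULL) {
  if (is.numeric(anchors)) {
    if (is.null(iaf)) stop("give an AnchorFrequencies object or both tf and iaf")
    anchors <- anchorFrequencies(tf = anchors, iaf = iaf)
  }
  stopifnot(is(anchors, "AnchorFrequencies"))
  validObject(anchors)
  tfHz <- anchors@tf
  iafHz <- anchors@iaf
  mid <- (tfHz + iafHz) / 2
  flags <- character()
  deltaLow <- tfHz - 4
  if (deltaLow < 2 - 1e-9) {
    deltaLow <- 2
    flags <- c(flags, "delta-truncated")
    warning("delta band truncated at the 2 Hz grid edge")
  }
  b <- rbind(delta = c(deltaLow, tfHz - 2),
             theta = c(tfHz - 2, tfHz),
             alpha1 = c(tfHz, mid),
             alpha2 = c(mid, iafHz),
             alpha3 = c(iafHz, iafHz + 2))
  colnames(b) <- c("low", "high")
  new("BandScheme", bands = b, mid = mid, flags = flags)
}

## Bin membership: half-open [low, high) for every band except alpha3,
## closed at IAF+2.  A bin belongs to a band iff its centre frequency falls
## in the interval, so shared edges are never double counted (the bin at
## exactly IAF belongs to alpha3).
bandBins <- function(freqs, scheme) {
  b <- scheme@bands
  lapply(stats::setNames(seq_len(nrow(b)), rownames(b)), function(i) {
    closedHigh <- rownames(b)[i] == "alpha3"
    hi <- b[i, 2] + if (closedHigh) 1e-9 else -1e-9
    which(freqs >= b[i, 1] - 1e-9 & freqs <= hi)
  })
}

#' Relative band powers under an individualized band scheme
#'
#' The per-bin relative power is the bin's power divided by the mean power
#' over all bins in 2-45 Hz (so the grand mean of per-bin relative power is
#' exactly 1).  Each band's value is the unweighted mean of the relative
#' powers of its bins.  By default this is computed on the collapsed
#' spectrum, matching the anchor definition; passing a `PowerSpectrum`
#' computes per-channel band powers instead (one row per channel).
#'
#' @param spectrum A `CollapsedSpectrum` (default mode) or `PowerSpectrum`.
#' @param scheme A `BandScheme` from [deriveBands()].
#' @return For a collapsed spectrum, a `BandPowerProfile` with the five band
#'   powers filled in (ratio and label unset; see [bandPowerProfile()]).
#'   For a `PowerSpectrum`, a channels x 5 matrix of band powers.
#' @export
relativeBandPower <- function(spectrum, scheme) {
  stopifnot(is(scheme, "BandScheme"))
  if (is(spectrum, "PowerSpectrum")) {
    bins <- bandBins(spectrum@freqs, scheme)
    checkBins(bins)
    rel <- spectrum@power / rowMeans(spectrum@power)
    out <- vapply(bins, function(ix) rowMeans(rel[, ix, drop = FALSE]),
                  numeric(nrow(rel)))
    if (is.null(dim(out))) out <- matrix(out, nrow = 1,
                                         dimnames = list(NULL, BAND_NAMES))
    rownames(out) <- spectrum@channelLabels
    return(out)
  }
  stopifnot(is(spectrum, "CollapsedSpectrum"))
  bins <- bandBins(spectrum@freqs, scheme)
  checkBins(bins)
  rel <- spectrum@power / mean(spectrum@power)
  vals <- vapply(bins, function(ix) mean(rel[ix]), numeric(1))
  new("BandPowerProfile", relativePower = vals, alphaRatio = NA_real_,
      riskLabel = NA_character_)
}

checkBins <- function(bins) {
  empty <- names(bins)[vapply(bins, length, integer(1)) == 0]
  if (length(empty))
    stop("band(s) with zero assigned bins: ", paste(empty, collapse = ", "))
  invisible(TRUE)
}

#' Alpha3/alpha2 power ratio
#'
#' The study's risk biomarker: relative power in the upper alpha band
#' divided by relative power in the mid alpha band.
#'
#' @param profile A `BandPowerProfile`, or a named numeric vector containing
#'   `alpha2` and `alpha3`.
#' @return The ratio (unitless).
#' @export
alphaRatio <- function(profile) {
  rp <- if (is(profile, "BandPowerProfile")) profile@relativePower else profile
  if (!all(c("alpha2", "alpha3") %in% names(rp)))
    stop("profile must contain alpha2 and alpha3 powers")
  if (rp[["alpha2"]] == 0) stop("undefined ratio: alpha2 power is zero")
  rp[["alpha3"]] / rp[["alpha2"]]
}

#' Classify subjects into risk groups by fixed alpha3/alpha2 cutoffs
#'
#' Fixed-cutoff stratification: `low` for ratio < 1, `middle` for
#' 1 <= ratio < 1.17, `high` for ratio >= 1.17.  The published two-decimal
#' rule leaves (1.16, 1.17) unmapped; the middle class is implemented as the
#' half-open interval [1.00, 1.17) so that every finite non-negative ratio
#' receives exactly one label.
#'
#' @param ratio Numeric vector of alpha3/alpha2 ratios (finite, >= 0).
#' @param cutoffs The two class boundaries (default `c(1, 1.17)`).
#' @return Factor with ordered levels `low`, `middle`, `high`.
#' @examples
#' classifyRisk(c(0.9, 1.08, 1.29))
#' @export
classifyRisk <- function(ratio, cutoffs = c(1, 1.17)) {
  if (any(!is.finite(ratio)) || any(ratio < 0))
    stop("ratio must be finite and >= 0")
  if (length(cutoffs) != 2 || cutoffs[1] >= cutoffs[2])
    stop("cutoffs must be two increasing values")
  factor(ifelse(ratio < cutoffs[1], "low",
                ifelse(ratio < cutoffs[2], "middle", "high")),
         levels = c("low", "middle", "high"))
}

#' Data-driven tertile split of a set of ratios
#'
#' The cohort-level alternative to the fixed cutoffs: boundaries at the 1/3
#' and 2/3 empirical quantiles (linear interpolation of the empirical CDF,
#' R quantile type 7), labels assigned with the same `<` / `>=` convention
#' as [classifyRisk()].
#'
#' @param ratios Numeric vector, length >= 3.
#' @return A list with `boundaries` (the two quantiles) and `labels`
#'   (factor low/middle/high, one per input value, input order preserved).
#' @export
tertileSplit <- function(ratios) {
  if (length(ratios) < 3) stop("need at least 3 values for a tertile split")
  if (length(unique(ratios)) == 1)
    stop("degenerate tertiles: all values identical")
  q <- unname(stats::quantile(ratios, c(1, 2) / 3, type = 7))
  if (q[1] >= q[2]) stop("degenerate tertiles: boundaries coincide")
  list(boundaries = q, labels = classifyRisk(ratios, cutoffs = q))
}

#' Complete band-power profile for one subject
#'
#' Convenience wrapper running [relativeBandPower()], [alphaRatio()] and
#' [classifyRisk()] and returning the filled-in profile.
#'
#' @param spectrum A `CollapsedSpectrum`.
#' @param scheme A `BandScheme`.
#' @return A `BandPowerProfile` with powers, ratio and risk label set.
#' @export
bandPowerProfile <- function(spectrum, scheme) {
  prof <- relativeBandPower(spectrum, scheme)
  r <- alphaRatio(prof)
  new("BandPowerProfile", relativePower = prof@relativePower,
      alphaRatio = r, riskLabel = as.character(classifyRisk(r)))
}
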