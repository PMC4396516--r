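## Plain-text stage contracts: recording CSV, spectrum CSV, control-model
## JSON, and NIfTI masks (via RNifti).  Every writer is paired with a
## reader that round-trips losslessly to printed precision.

#' Write / read a recording as plain CSV
#'
#' One metadata comment line (`# fs=<Hz> reference=<scheme>`), then one row
#' per channel: the channel label followed by the sample values.
#'
#' @param rec An [eegRecording()].
#' @param path Output file path.
#' @return `writeRecordingCsv` returns `path` invisibly;
#'   `readRecordingCsv` returns the `EegRecording`.
#' @export
writeRecordingCsv <- function(rec, path) {
  stopifnot(is(rec, "EegRecording"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs=%.10g reference=%s", rec@fs, rec@reference), con)
  for (ch in seq_len(nrow(rec@samples)))
    writeLines(paste(c(rec@channelLabels[ch],
                       format(rec@samples[ch, ], digits = 10, trim = TRUE,
                              scientific = FALSE)), collapse = ","), con)
  invisible(path)
}

#' @rdname writeRecordingCsv
#' @export
readRecordingCsv <- function(path) {
  lines <- readLines(path)
  if (!grepl("^# fs=", lines[1]))
    stop("missing '# fs=' metadata line; not a recording CSV")
  meta <- strsplit(sub("^# ", "", lines[1]), " ")[[1]]
  kv <- strsplit(meta, "=")
  vals <- stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  fs <- as.numeric(vals[["fs"]])
  ref <- if ("reference" %in% names(vals)) vals[["reference"]] else "linked-mastoid"
  body <- strsplit(lines[-1], ",", fixed = TRUE)
  labels <- vapply(body, `[`, "", 1)
  x <- do.call(rbind, lapply(body, function(v) as.numeric(v[-1])))
  rec <- eegRecording(x, fs = fs, channelLabels = labels, reference = ref)
  unknown <- setdiff(labels, TEN_TWENTY_19)
  if (nrow(x) == 19 && length(unknown))
    warning("channel labels not in the 19-name 10-20 set: ",
            paste(unknown, collapse = ", "))
  rec
}

#' Write / read per-channel and collapsed spectra as CSV
#'
#' Column 1 is the frequency grid, then one column per channel, and a final
#' `collapsed` column with the channel average.
#'
#' @param ps A `PowerSpectrum`.
#' @param path File path.
#' @return `writeSpectrumCsv` returns `path` invisibly; `readSpectrumCsv`
#'   returns `list(spectrum = PowerSpectrum, collapsed = CollapsedSpectrum)`.
#' @export
writeSpectrumCsv <- function(ps, path) {
  stopifnot(is(ps, "PowerSpectrum"))
  cs <- collapseSpectrum(ps)
  df <- data.frame(frequency = ps@freqs, t(ps@power), collapsed = cs@power,
                   check.names = FALSE)
  names(df)[2:(1 + nrow(ps@power))] <- ps@channelLabels
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSpectrumCsv
#' @export
readSpectrumCsv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  f <- df[[1]]
  chCols <- setdiff(names(df), c("frequency", "collapsed"))
  pw <- t(as.matrix(df[, chCols, drop = FALSE]))
  ps <- new("PowerSpectrum", freqs = f, power = pw, channelLabels = chCols,
            nEpochs = NA_integer_)
  list(spectrum = ps,
       collapsed = new("CollapsedSpectrum", freqs = f, power = df$collapsed))
}

#' Serialize / restore a fitted control age model as JSON
#'
#' @param model A `ControlAgeModel`.
#' @param path File path.
#' @return `writeControlModelJson` returns `path` invisibly;
#'   `readControlModelJson` returns the `ControlAgeModel`.
#' @export
writeControlModelJson <- function(model, path) {
  stopifnot(is(model, "ControlAgeModel"))
  jsonlite::write_json(list(coefficients = model@coefficients,
                            nControls = model@nControls,
                            degenerate = model@degenerate),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeControlModelJson
#' @export
readControlModelJson <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  coef <- as.data.frame(obj$coefficients)
  new("ControlAgeModel", coefficients = coef,
      nControls = as.integer(obj$nControls),
      degenerate = as.character(obj$degenerate %||% character()))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a binary mask as NIfTI
#'
#' Foreground is stored as 1, background 0; the voxel size goes into the
#' NIfTI pixdim fields.
#'
#' @param mask A [binaryMask3D()].
#' @param path File path (`.nii` or `.nii.gz`).
#' @param threshold Reader-side foreground threshold (voxels > threshold
#'   become foreground; default 0.5).
#' @return `writeMaskNifti` returns `path` invisibly; `readMaskNifti`
#'   returns the `BinaryMask3D`.
#' @export
writeMaskNifti <- function(mask, path) {
  stopifnot(is(mask, "BinaryMask3D"))
  img <- RNifti::asNifti(array(as.numeric(mask@voxels), dim = dim(mask@voxels)))
  RNifti::pixdim(img) <- mask@voxelSize
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname writeMaskNifti
#' @export
readMaskNifti <- function(path, threshold = 0.5) {
  img <- RNifti::readNifti(path)
  vs <- RNifti::pixdim(img)[1:3]
  binaryMask3D(array(as.array(img) > threshold, dim = dim(img)[1:3]),
               voxelSize = vs)
}
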