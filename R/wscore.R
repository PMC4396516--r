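## ROI perfusion normalization and age-corrected W-scores.
##
## Pipelines upstream of this file (template creation, warping, smoothing)
## are image-space operations out of this package's contract; everything
## here starts from ROI count tables.  The W-score is the standard
## age-residual z-score: W = (observed - (intercept + slope * age)) /
## residual SD, with the regression fitted on controls only.

## Default ROI panel: left/right frontal, parietal and temporal lobes,
## thalamus and hippocampal-amygdalar complex.
DEFAULT_ROIS <- as.vector(outer(
  c("frontal", "parietal", "temporal", "thalamus", "hippocampal_amygdalar"),
  c("l", "r"), paste, sep = "_"))

roiColumns <- function(panel, roiCols = NULL) {
  if (!is.null(roiCols)) return(roiCols)
  cand <- intersect(DEFAULT_ROIS, names(panel))
  if (!length(cand))
    stop("no ROI columns found; pass roiCols explicitly")
  cand
}

#' Normalize ROI counts to whole-cerebellum counts
#'
#' Divides every ROI value by the subject's whole-cerebellum count (the
#' perfusion normalization denominator).  The cerebellum column is dropped
#' from the output and the table is marked normalized, so it cannot be
#' consumed twice.
#'
#' @param panel A data.frame with one row per subject, ROI count columns and
#'   a cerebellum column.
#' @param roiCols ROI column names; default: the standard 10-ROI panel
#'   present in the table.
#' @param cerebellumCol Name of the denominator column (default
#'   `"cerebellum"`).
#' @return The normalized data.frame (attribute `"normalized"` set).
#' @export
normalizeRoi <- function(panel, roiCols = NULL, cerebellumCol = "cerebellum") {
  if (isTRUE(attr(panel, "normalized")))
    stop("panel is already normalized: cerebellum counts were consumed")
  if (!cerebellumCol %in% names(panel))
    stop("cerebellum column '", cerebellumCol, "' not found")
  cb <- panel[[cerebellumCol]]
  if (any(!is.finite(cb)) || any(cb <= 0))
    stop("cerebellum counts must all be positive")
  roiCols <- roiColumns(panel, roiCols)
  for (rc in roiCols) panel[[rc]] <- panel[[rc]] / cb
  panel[[cerebellumCol]] <- NULL
  attr(panel, "normalized") <- TRUE
  panel
}

#' Fit the control age model for W-scores
#'
#' Per ROI, an ordinary least-squares regression of the normalized perfusion
#' value on age, fitted on controls only.  The residual SD uses the n-2
#' denominator; no shrinkage is applied (transparency over sophistication at
#' small control samples).  ROIs whose residual SD is numerically zero are
#' flagged degenerate.
#'
#' @param controls Normalized control table (see [normalizeRoi()]) with an
#'   age column; needs >= 3 controls with non-identical ages.
#' @param roiCols ROI columns to model (default: standard panel).
#' @param ageCol Age column name (default `"age"`).
#' @param sexCol Optional sex column to include as a second covariate; the
#'   default age-only model makes no claim about the published procedure's
#'   exact covariate set.
#' @return A `ControlAgeModel`.
#' @export
fitControlModel <- function(controls, roiCols = NULL, ageCol = "age",
                            sexCol = NULL) {
  roiCols <- roiColumns(controls, roiCols)
  if (!ageCol %in% names(controls)) stop("age column '", ageCol, "' not found")
  age <- controls[[ageCol]]
  if (length(age) < 3) stop("need at least 3 controls")
  if (length(unique(age)) == 1)
    stop("singular fit: all control ages identical")
  degenerate <- character()
  rows <- lapply(roiCols, function(rc) {
    y <- controls[[rc]]
    fit <- if (is.null(sexCol)) stats::lm(y ~ age)
           else stats::lm(y ~ age + controls[[sexCol]])
    s <- summary(fit)$sigma                       # df = n - p residual SD
    if (!is.finite(s) || s < 1e-12) degenerate <<- c(degenerate, rc)
    data.frame(roi = rc, intercept = unname(stats::coef(fit)[1]),
               slope = unname(stats::coef(fit)[2]), residualSd = max(s, 0))
  })
  new("ControlAgeModel", coefficients = do.call(rbind, rows),
      nControls = length(age), degenerate = degenerate)
}

#' Age-corrected perfusion W-scores
#'
#' For each subject and ROI, `W = (observed - (intercept + slope * age)) /
#' residualSd` with coefficients from the control model.  A subject exactly
#' on the control regression line scores 0; one residual SD above it scores
#' 1.  By construction, W-scores of the control set itself have mean ~0 and
#' SD ~1 per ROI.
#'
#' @param subjects Normalized subject table with an age column.
#' @param model A `ControlAgeModel` from [fitControlModel()].
#' @param ageCol Age column name (default `"age"`).
#' @return A data.frame of W-scores, columns `w_<roi>`, rows as in
#'   `subjects` (id columns `subject_id`/`group` carried over when present).
#' @export
wScore <- function(subjects, model, ageCol = "age") {
  stopifnot(is(model, "ControlAgeModel"))
  tab <- model@coefficients
  missing <- setdiff(tab$roi, names(subjects))
  if (length(missing))
    stop("ROI missing from subject table: ", paste(missing, collapse = ", "))
  if (!ageCol %in% names(subjects)) stop("age column '", ageCol, "' not found")
  age <- subjects[[ageCol]]
  out <- lapply(seq_len(nrow(tab)), function(i) {
    pred <- tab$intercept[i] + tab$slope[i] * age
    if (tab$residualSd[i] <= 0)
      stop("degenerate model for ROI ", tab$roi[i], ": zero residual SD")
    (subjects[[tab$roi[i]]] - pred) / tab$residualSd[i]
  })
  names(out) <- paste0("w_", tab$roi)
  res <- as.data.frame(out)
  for (idc in intersect(c("subject_id", "group"), names(subjects)))
    res[[idc]] <- subjects[[idc]]
  res[, c(intersect(c("subject_id", "group"), names(subjects)),
          paste0("w_", tab$roi)), drop = FALSE]
}

## Truncated-normal draw by rejection; bounds may be one-sided (NA).
rtruncn <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(2 * n, mean, sd)
    out <- c(out, x[x >= lower & x < upper])
  }
  out[seq_len(n)]
}

#' Simulate a two-group MCI cohort with controls for W-score analyses
#'
#' Generates a subject table emulating the cohort structure the perfusion
#' analyses operate on: ages; cerebellum-normalized ROI perfusion values
#' with a common negative age slope; relative theta power correlated with
#' the hippocampal-amygdalar perfusion residual at a group-specific target
#' correlation (negative in the low-risk group, positive in the high-risk
#' group, so pooling the groups attenuates the correlation toward zero);
#' alpha3/alpha2 ratios drawn so each subject's fixed-cutoff label matches
#' its group; and group-shifted left/right hippocampal volumes.
#'
#' Defaults reproduce the study conditions: 14 low-risk and 13 high-risk
#' patients, 17 controls, theta-perfusion correlations -0.544 / +0.729, and
#' left hippocampal volumes 2606 +/- 353 vs 2073 +/- 412 mm^3 (right:
#' 2581 +/- 473 vs 2296 +/- 501).
#'
#' @param nLow,nHigh,nControls Group sizes (each >= 2, controls >= 3).
#' @param effectConfig Named list overriding any of the defaults in
#'   `cohortEffectDefaults()`: `rLow`, `rHigh`, `roiBase`, `roiAgeSlope`,
#'   `roiSd`, `ageMean`/`ageSd` (per group), `thetaMean`/`thetaSd`,
#'   `ratioMean`/`ratioSd`, `hippoLeft`/`hippoRight` (mean/sd per group),
#'   `mmse`, `wahlund`, `sexP`.
#' @param seed Integer seed; generation is fully reproducible.
#' @return A data.frame, one row per subject: `subject_id`, `group`
#'   (`low-risk`/`high-risk`/`control`), `age`, `sex`, `mmse`,
#'   `alpha_ratio`, `theta_rel_power`, the ten normalized ROI columns,
#'   `hippo_volume_left`, `hippo_volume_right`, `wahlund_score`.
#' @export
generateCohort <- function(nLow = 14, nHigh = 13, nControls = 17,
                           effectConfig = list(), seed = 1L) {
  if (nLow < 2 || nHigh < 2) stop("patient group sizes must be >= 2")
  if (nControls < 3) stop("need >= 3 controls for the age model")
  cfg <- utils::modifyList(cohortEffectDefaults(), effectConfig)
  for (r in c(cfg$rLow, cfg$rHigh))
    if (!is.finite(r) || abs(r) >= 1)
      stop("target correlations must lie in (-1, 1)")

  withSeed(seed, {
    mkGroup <- function(n, group, rTarget, ageMean, ageSd) {
      age <- stats::rnorm(n, ageMean, ageSd)
      z1 <- stats::rnorm(n)                       # hippocampal perfusion residual
      z2 <- stats::rnorm(n)
      hippResid <- cfg$roiSd * z1
      theta <- cfg$thetaMean[[group]] +
        cfg$thetaSd * (rTarget * z1 + sqrt(1 - rTarget^2) * z2)
      rois <- lapply(stats::setNames(DEFAULT_ROIS, DEFAULT_ROIS), function(rc) {
        resid <- if (rc == "hippocampal_amygdalar_l") hippResid
                 else stats::rnorm(n, 0, cfg$roiSd)
        cfg$roiBase[[rc]] + cfg$roiAgeSlope * age + resid
      })
      ratio <- switch(group,
        "low-risk" = rtruncn(n, cfg$ratioMean[1], cfg$ratioSd[1], upper = 1.17),
        "high-risk" = rtruncn(n, cfg$ratioMean[2], cfg$ratioSd[2], lower = 1.17),
        rtruncn(n, cfg$ratioMean[1], cfg$ratioSd[1], upper = 1.17))
      hv <- switch(group,
        "low-risk" = cbind(stats::rnorm(n, cfg$hippoLeft[1], cfg$hippoLeft[2]),
                           stats::rnorm(n, cfg$hippoRight[1], cfg$hippoRight[2])),
        "high-risk" = cbind(stats::rnorm(n, cfg$hippoLeft[3], cfg$hippoLeft[4]),
                            stats::rnorm(n, cfg$hippoRight[3], cfg$hippoRight[4])),
        cbind(stats::rnorm(n, cfg$hippoLeft[1], cfg$hippoLeft[2]),
              stats::rnorm(n, cfg$hippoRight[1], cfg$hippoRight[2])))
      sexP <- switch(group, "low-risk" = cfg$sexP[1], "high-risk" = cfg$sexP[2],
                     mean(cfg$sexP))
      mm <- switch(group, "low-risk" = cfg$mmse[1:2], "high-risk" = cfg$mmse[3:4],
                   c(28.5, 1.2))
      data.frame(group = group, age = age, sex = ifelse(
                   stats::runif(n) < sexP, "F", "M"),
                 mmse = round(pmin(30, stats::rnorm(n, mm[1], mm[2])), 0),
                 alpha_ratio = ratio, theta_rel_power = theta,
                 as.data.frame(rois),
                 hippo_volume_left = hv[, 1], hippo_volume_right = hv[, 2],
                 wahlund_score = pmax(0, stats::rnorm(
                   n, mean(cfg$wahlund[c(1, 3)]), mean(cfg$wahlund[c(2, 4)]))))
    }
    low <- mkGroup(nLow, "low-risk", cfg$rLow, cfg$age[1], cfg$age[2])
    high <- mkGroup(nHigh, "high-risk", cfg$rHigh, cfg$age[3], cfg$age[4])
    ctrl <- mkGroup(nControls, "control", 0, cfg$age[5], cfg$age[6])
    out <- rbind(low, high, ctrl)
    out <- cbind(subject_id = sprintf("S%03d", seq_len(nrow(out))), out)
    rownames(out) <- NULL
    attr(out, "normalized") <- TRUE               # ROI values are cerebellum ratios
    out
  })
}

#' Default effect configuration of the cohort generator
#'
#' The generator's defaults are the study conditions: group-specific
#' theta-perfusion correlations of -0.544 (low risk) and +0.729 (high
#' risk), left hippocampal volumes 2606/353 vs 2073/412 mm^3 (right
#' 2581/473 vs 2296/501), ages 69.1/7.6 vs 70.6/5.5 (controls 70/6), MMSE
#' 27.9/1.6 vs 27.2/1.9, female fractions 6/14 and 9/13.  Perfusion values
#' are cerebellum ratios near 0.9 with a -0.002/year age slope and 0.01
#' residual SD.
#'
#' @return Named list of generator parameters.
#' @export
cohortEffectDefaults <- function() {
  roiBase <- stats::setNames(
    c(0.92, 0.92, 0.90, 0.90, 0.88, 0.88, 0.95, 0.95, 0.85, 0.85),
    DEFAULT_ROIS)
  list(rLow = -0.544, rHigh = 0.729,
       roiBase = as.list(roiBase), roiAgeSlope = -0.002, roiSd = 0.01,
       age = c(69.1, 7.6, 70.6, 5.5, 70, 6),
       thetaMean = list("low-risk" = 0.08, "high-risk" = 0.12,
                        "control" = 0.07),
       thetaSd = 0.03,
       ratioMean = c(1.03, 1.29), ratioSd = c(0.11, 0.10),
       hippoLeft = c(2606, 353, 2073, 412),
       hippoRight = c(2581, 473, 2296, 501),
       mmse = c(27.9, 1.6, 27.2, 1.9),
       wahlund = c(3.58, 3.29, 3.78, 2.63),
       sexP = c(6 / 14, 9 / 13))
}
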