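## Cohort statistics: Pearson r with its analytic two-tailed p, Student's
## t from raw data or from printed summary cells, 2x2 chi-square without
## continuity correction, one-way ANOVA with Levene-gated post hocs
## (Games-Howell under heteroscedasticity, Bonferroni otherwise).  All
## tests are two-tailed.

#' Two-tailed p-value from a correlation coefficient and sample size
#'
#' The exact transform used throughout the package for Pearson
#' correlations: `t = r * sqrt(n - 2) / sqrt(1 - r^2)` referred to the t
#' distribution with n-2 degrees of freedom.  Also the verification path
#' for printed r/p pairs.  `|r| >= 1` is a boundary case returning p = 0
#' with a note rather than an error.
#'
#' @param r Correlation coefficient.
#' @param n Number of paired observations (>= 3).
#' @return A `StatResult` (statistic t, df n-2).
#' @examples
#' pValue(pFromRN(-0.544, 14))   # ~0.044
#' @export
pFromRN <- function(r, n) {
  if (n < 3) stop("need n >= 3")
  if (!is.finite(r)) stop("r must be finite")
  if (abs(r) >= 1)
    return(statResult("t", sign(r) * Inf, df = n - 2, pTwoTailed = 0,
                      methodNotes = "boundary case |r| >= 1"))
  t <- r * sqrt(n - 2) / sqrt(1 - r^2)
  statResult("t", t, df = n - 2, pTwoTailed = 2 * stats::pt(-abs(t), n - 2),
             methodNotes = sprintf("r = %.4g, n = %d", r, as.integer(n)))
}

#' Pearson correlation with analytic two-tailed p
#'
#' Sample correlation of x and y; the p-value comes from [pFromRN()], i.e.
#' the t transform with n-2 df, so raw-data and summary-r verification use
#' one code path.
#'
#' @param x,y Equal-length numeric vectors (n >= 3, neither constant).
#' @return A `StatResult` with statistic `r` (t and df in the notes).
#' @export
pearsonRP <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3) stop("need n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: constant input")
  r <- stats::cor(x, y)
  pr <- pFromRN(r, n)
  statResult("r", r, df = n - 2, pTwoTailed = pr@pTwoTailed,
             methodNotes = sprintf("t = %.4g", pr@statisticValue))
}

#' Independent two-sample t test on raw data
#'
#' Pooled-variance Student's t by default (df = n1 + n2 - 2); Welch's
#' unequal-variance variant on request.  When both groups have zero
#' variance and equal means the result is flagged degenerate (t = 0,
#' p = 1).
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @param mode `"pooled"` (default) or `"welch"`.
#' @return A `StatResult`.
#' @export
tTestIndependent <- function(a, b, mode = c("pooled", "welch")) {
  mode <- match.arg(mode)
  if (length(a) < 2 || length(b) < 2) stop("each group needs n >= 2")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b))
      return(statResult("t", 0, df = length(a) + length(b) - 2,
                        pTwoTailed = 1, methodNotes = "degenerate: zero variance, equal means"))
    return(statResult("t", Inf * sign(mean(a) - mean(b)),
                      df = length(a) + length(b) - 2, pTwoTailed = 0,
                      methodNotes = "degenerate: zero variance, unequal means"))
  }
  tt <- stats::t.test(a, b, var.equal = (mode == "pooled"))
  statResult("t", unname(tt$statistic), df = unname(tt$parameter),
             pTwoTailed = tt$p.value, methodNotes = mode)
}

#' Independent two-sample t test from summary statistics
#'
#' The same statistic as [tTestIndependent()], computed from group means,
#' SDs and sizes -- e.g. directly from printed table cells.
#'
#' @param mean1,sd1,n1 First group summary (sd >= 0, n >= 2).
#' @param mean2,sd2,n2 Second group summary.
#' @param mode `"pooled"` (default) or `"welch"`.
#' @return A `StatResult`.
#' @examples
#' pValue(tTestFromSummary(2606, 353, 14, 2073, 412, 13))  # ~0.001
#' @export
tTestFromSummary <- function(mean1, sd1, n1, mean2, sd2, n2,
                             mode = c("pooled", "welch")) {
  mode <- match.arg(mode)
  if (n1 < 2 || n2 < 2) stop("each group needs n >= 2")
  if (sd1 < 0 || sd2 < 0) stop("sd must be >= 0")
  if (mode == "pooled") {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    v1 <- sd1^2 / n1
    v2 <- sd2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  if (se == 0)
    return(statResult("t", if (mean1 == mean2) 0 else Inf * sign(mean1 - mean2),
                      df = df, pTwoTailed = as.numeric(mean1 == mean2),
                      methodNotes = "degenerate: zero pooled SD"))
  t <- (mean1 - mean2) / se
  statResult("t", t, df = df, pTwoTailed = 2 * stats::pt(-abs(t), df),
             methodNotes = mode)
}

#' Pearson chi-square test on a 2x2 table
#'
#' No continuity correction, df = 1, two-sided.  All marginals must be
#' positive.
#'
#' @param table 2x2 matrix of counts.
#' @return A `StatResult`.
#' @examples
#' pValue(chi2Test2x2(matrix(c(6, 8, 9, 4), 2, byrow = TRUE)))  # ~0.168
#' @export
chi2Test2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == 2)) stop("need a 2x2 table")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero marginal in the 2x2 table")
  ct <- stats::chisq.test(table, correct = FALSE)
  statResult("chi-squared", unname(ct$statistic), df = 1,
             pTwoTailed = ct$p.value, methodNotes = "no continuity correction")
}

asGroupList <- function(groups) {
  if (is.data.frame(groups)) stop("pass a list of numeric vectors")
  stopifnot(is.list(groups))
  if (length(groups) < 2) stop("need at least 2 groups")
  if (any(vapply(groups, length, integer(1)) < 2))
    stop("every group needs n >= 2")
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  groups
}

#' One-way ANOVA across groups
#'
#' Standard equal-variance one-way F with between/within degrees of
#' freedom.  Fully constant data degenerate to F = 0, p = 1.
#'
#' @param groups Named list of numeric vectors (>= 2 groups, each n >= 2).
#' @return A `StatResult` (df = c(between, within)).
#' @export
anovaOneway <- function(groups) {
  groups <- asGroupList(groups)
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)))
  df <- c(nlevels(g) - 1, length(y) - nlevels(g))
  if (stats::var(y) == 0)
    return(statResult("F", 0, df = df, pTwoTailed = 1,
                      methodNotes = "degenerate: constant data"))
  ow <- stats::oneway.test(y ~ g, var.equal = TRUE)
  statResult("F", unname(ow$statistic), df = unname(ow$parameter),
             pTwoTailed = ow$p.value, methodNotes = "equal-variance one-way ANOVA")
}

#' Levene's test for homogeneity of variance
#'
#' Levene's F on absolute deviations from the group means (center = mean),
#' the gate deciding between Games-Howell and Bonferroni post hocs.
#'
#' @param groups Named list of numeric vectors.
#' @return A `StatResult`.
#' @export
leveneHomogeneity <- function(groups) {
  groups <- asGroupList(groups)
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)))
  dev <- abs(y - stats::ave(y, g))
  if (stats::var(dev) == 0)
    return(statResult("F", 0, df = c(nlevels(g) - 1, length(y) - nlevels(g)),
                      pTwoTailed = 1, methodNotes = "degenerate: identical spreads"))
  lt <- car::leveneTest(y ~ g, center = mean)
  statResult("F", lt[1, "F value"], df = lt[["Df"]],
             pTwoTailed = lt[1, "Pr(>F)"], methodNotes = "Levene, center = mean")
}

#' Pairwise post hoc comparisons after a one-way ANOVA
#'
#' `"games_howell"`: Welch-type pairwise t with Welch-Satterthwaite df,
#' referred to the studentized-range distribution with the total number of
#' groups (`q = |t| * sqrt(2)`), robust to unequal variances.
#' `"bonferroni"`: pairwise pooled-variance t with p multiplied by the
#' number of comparisons (capped at 1).  `"auto"` gates on
#' [leveneHomogeneity()] at `alphaLevene`, mirroring the analysis plan of
#' variance-heterogeneous cohort tables.
#'
#' @param groups Named list of numeric vectors.
#' @param method `"auto"`, `"games_howell"` or `"bonferroni"`.
#' @param alphaLevene Gate level for `"auto"` (default 0.05).
#' @return A data.frame with one row per pair: `group1`, `group2`,
#'   `statistic`, `df`, `p`, `method`.
#' @export
posthocPairwise <- function(groups, method = c("auto", "games_howell",
                                               "bonferroni"),
                            alphaLevene = 0.05) {
  method <- match.arg(method)
  groups <- asGroupList(groups)
  if (method == "auto") {
    lev <- leveneHomogeneity(groups)
    method <- if (is.finite(lev@pTwoTailed) && lev@pTwoTailed < alphaLevene)
      "games_howell" else "bonferroni"
  }
  k <- length(groups)
  pairs <- utils::combn(names(groups), 2)
  m <- ncol(pairs)
  rows <- lapply(seq_len(m), function(i) {
    a <- groups[[pairs[1, i]]]
    b <- groups[[pairs[2, i]]]
    n1 <- length(a); n2 <- length(b)
    if (method == "games_howell") {
      v1 <- stats::var(a) / n1
      v2 <- stats::var(b) / n2
      se <- sqrt(v1 + v2)
      if (se == 0) {
        t <- if (mean(a) == mean(b)) 0 else Inf * sign(mean(a) - mean(b))
        df <- n1 + n2 - 2
        p <- as.numeric(mean(a) == mean(b))
      } else {
        t <- (mean(a) - mean(b)) / se
        df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
        p <- stats::ptukey(abs(t) * sqrt(2), nmeans = k, df = df,
                           lower.tail = FALSE)
      }
    } else {
      tt <- tTestFromSummary(mean(a), stats::sd(a), n1,
                             mean(b), stats::sd(b), n2, mode = "pooled")
      t <- tt@statisticValue
      df <- tt@df
      p <- min(1, tt@pTwoTailed * m)
    }
    data.frame(group1 = pairs[1, i], group2 = pairs[2, i], statistic = t,
               df = df, p = p, method = method)
  })
  do.call(rbind, rows)
}

#' Permutation p-value for a Pearson correlation
#'
#' Monte-Carlo two-tailed permutation test: the fraction of label
#' permutations whose |r| reaches the observed |r|.  This is the slow,
#' assumption-free oracle the analytic p-values are checked against.
#'
#' @param x,y Paired numeric vectors.
#' @param nPerm Number of random permutations.
#' @param seed Integer seed.
#' @return A `StatResult` (statistic r; the Monte-Carlo SE in the notes).
#' @export
permutationPearsonP <- function(x, y, nPerm = 10000, seed = 1L) {
  n <- length(x)
  stopifnot(length(y) == n, n >= 3)
  rObs <- stats::cor(x, y)
  xc <- (x - mean(x)) / sqrt(sum((x - mean(x))^2))
  withSeed(seed, {
    hits <- 0L
    yc <- y - mean(y)
    for (b in seq_len(nPerm)) {
      yp <- yc[sample.int(n)]
      r <- sum(xc * yp) / sqrt(sum(yp^2))
      if (abs(r) >= abs(rObs) - 1e-12) hits <- hits + 1L
    }
    p <- (hits + 1) / (nPerm + 1)
    statResult("r", rObs, df = n - 2, pTwoTailed = p,
               methodNotes = sprintf("permutation, %d draws, MC SE ~ %.4g",
                                     nPerm, sqrt(p * (1 - p) / nPerm)))
  })
}
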