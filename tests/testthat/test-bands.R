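test_that("anchors are found on a 1/f-plus-alpha-bump spectrum", {
  cs <- bumpSpectrum(iafHz = 10, bumpAmp = 3, bumpSd = 0.7)
  an <- detectAnchors(cs)
  ## grid-search oracle straight on the constructed curve
  f <- freqs(cs); p <- spectrumPower(cs)
  inA <- f >= 5 & f <= 14
  oracleIaf <- f[inA][which.max(p[inA])]
  inT <- f >= 3 & f <= oracleIaf - 1
  oracleTf <- max(f[inT][p[inT] == min(p[inT])])
  expect_equal(iaf(an), oracleIaf)
  expect_equal(iaf(an), 10)
  expect_equal(tf(an), oracleTf)
  expect_length(qualityFlags(an), 0)
})

test_that("a monotone decreasing spectrum gives IAF at the range edge, flagged", {
  an <- detectAnchors(toySpectrum(50 / stdGrid))
  expect_equal(iaf(an), 5)
  expect_true("no-local-peak" %in% qualityFlags(an))
})

test_that("flat troughs and window-edge TF raise quality flags", {
  p <- 10 / stdGrid + 3 * exp(-(stdGrid - 10)^2 / 0.8)
  p[stdGrid >= 6 & stdGrid <= 7.5] <- min(p[stdGrid >= 3 & stdGrid <= 9])
  an <- detectAnchors(toySpectrum(p))
  expect_true("flat-trough" %in% qualityFlags(an))
  ## rising spectrum puts the trough at the lower search edge
  an2 <- detectAnchors(toySpectrum(stdGrid^1.5))
  expect_true("tf-at-search-edge" %in% qualityFlags(an2))
})

test_that("anchor validity enforces the grid and ordering invariants", {
  expect_error(anchorFrequencies(tf = 11, iaf = 10), "below")
  expect_error(anchorFrequencies(tf = 6.93, iaf = 10), "grid")
  expect_error(anchorFrequencies(tf = 6, iaf = 17), "5, 14")
})

test_that("the cohort-mean anchors reproduce the published band set", {
  sch <- deriveBands(anchorFrequencies(tf = 6.9, iaf = 10.9))
  b <- bandTable(sch)
  expect_equal(unname(b["delta", ]), c(2.9, 4.9))
  expect_equal(unname(b["theta", ]), c(4.9, 6.9))
  expect_equal(unname(b["alpha1", ]), c(6.9, 8.9))
  expect_equal(unname(b["alpha2", ]), c(8.9, 10.9))
  expect_equal(unname(b["alpha3", ]), c(10.9, 12.9))
  expect_equal(bandMid(sch), 8.9)
})

test_that("band arithmetic: midpoint split and equal alpha1/alpha2 widths", {
  b <- bandTable(deriveBands(6, iaf = 10))
  expect_equal(unname(b["alpha1", ]), c(6, 8))
  expect_equal(unname(b["alpha2", ]), c(8, 10))
  b2 <- bandTable(deriveBands(7, iaf = 9))
  expect_equal(diff(b2["alpha1", ]), diff(b2["alpha2", ]), ignore_attr = TRUE)
  expect_equal(unname(diff(b2["alpha1", ])), 1)
})

test_that("bands are contiguous with equal alpha splits for any valid anchors", {
  set.seed(7)
  for (i in 1:25) {
    tfHz <- sample(seq(6, 8.5, 0.5), 1)
    iafHz <- tfHz + sample(seq(1.5, 5, 0.5), 1)
    iafHz <- min(iafHz, 14)
    sch <- deriveBands(tfHz, iaf = iafHz)
    b <- bandTable(sch)
    expect_equal(unname(b[-1, 1]), unname(b[-5, 2]))   # contiguity
    expect_equal(unname(diff(b["alpha1", ])), unname(diff(b["alpha2", ])))
    expect_equal(unname(b["alpha3", 2] - b["alpha3", 1]), 2)
  }
})

test_that("a TF below 6 Hz truncates delta at the 2 Hz grid edge with a flag", {
  expect_warning(sch <- deriveBands(5, iaf = 10), "truncated")
  expect_equal(unname(bandTable(sch)["delta", 1]), 2)
  expect_true("delta-truncated" %in% qualityFlags(sch))
})

test_that("relative power self-normalizes: flat spectrum gives 1 in every band", {
  prof <- relativeBandPower(toySpectrum(rep(3.7, 87)),
                            deriveBands(7, iaf = 10))
  expect_equal(unname(relativePower(prof)), rep(1, 5))
})

test_that("mean per-bin relative power over 2-45 Hz is 1 for arbitrary spectra", {
  set.seed(31)
  for (i in 1:20) {
    p <- rexp(87, rate = runif(1, 0.1, 10))
    rel <- p / mean(p)
    expect_equal(mean(rel), 1)
    ## and the five band means are consistent with a hand-computed oracle
    sch <- deriveBands(7, iaf = 10.5)
    prof <- relativeBandPower(toySpectrum(p), sch)
    b <- bandTable(sch)
    hand <- vapply(rownames(b), function(nm) {
      lo <- b[nm, 1]; hi <- b[nm, 2]
      sel <- if (nm == "alpha3") stdGrid >= lo & stdGrid <= hi
             else stdGrid >= lo & stdGrid < hi
      mean(rel[sel])
    }, numeric(1))
    expect_equal(relativePower(prof), hand)
  }
})

test_that("shared band edges are counted once: the IAF bin belongs to alpha3", {
  sch <- deriveBands(7, iaf = 10)
  p <- rep(1, 87)
  p[stdGrid == 10] <- 100              # spike exactly at IAF
  prof <- relativeBandPower(toySpectrum(p), sch)
  rp <- relativePower(prof)
  expect_gt(rp[["alpha3"]], rp[["alpha2"]])
  ## total bin count over the five bands has no double counting
  nBins <- sum((stdGrid >= 3 & stdGrid < 12))   # [tf-4, iaf+2] span
  expect_equal(nBins, 18)
})

test_that("alpha ratio follows its definition and rejects a zero denominator", {
  expect_equal(alphaRatio(c(alpha2 = 0.10, alpha3 = 0.13)), 1.3)
  expect_equal(alphaRatio(c(alpha2 = 0.2, alpha3 = 0.2)), 1)
  expect_error(alphaRatio(c(alpha2 = 0, alpha3 = 0.2)), "alpha2")
})

test_that("spectral content above the IAF drives the ratio above 1", {
  ## same seed, alpha peak moved to the top of alpha2 vs into alpha3
  csLow <- recordingSpectrum(generateRecording(
    eegSimConfig(duration = 60, iafTrue = 10, seed = 21)))
  csHigh <- recordingSpectrum(generateRecording(
    eegSimConfig(duration = 60, iafTrue = 12, seed = 21)))
  sch <- deriveBands(7, iaf = 10.5)    # common frame for both subjects
  rLow <- alphaRatio(relativeBandPower(csLow, sch))
  rHigh <- alphaRatio(relativeBandPower(csHigh, sch))
  expect_gt(rHigh, rLow)
  expect_gt(rHigh, 1)
})

test_that("fixed-cutoff classification matches the published rule", {
  expect_identical(as.character(classifyRisk(c(0.9, 1.08, 1.29))),
                   c("low", "middle", "high"))
  expect_identical(as.character(classifyRisk(1.00)), "middle")
  grid <- seq(0.50, 1.50, by = 0.01)
  lab <- classifyRisk(grid)
  expect_equal(min(grid[lab == "high"]), 1.17)
  expect_equal(max(grid[lab == "middle"]), 1.16)
  ## total partition, monotone in the ratio
  expect_false(any(is.na(lab)))
  expect_true(all(diff(as.integer(lab)) >= 0))
  expect_error(classifyRisk(NaN), "finite")
})

test_that("tertile split reproduces the sort-and-split oracle on 1..9", {
  ts <- tertileSplit(1:9)
  expect_equal(ts$boundaries, c(11, 19) / 3, tolerance = 1e-6)
  expect_identical(as.vector(table(ts$labels)), c(3L, 3L, 3L))
  ## order invariance
  perm <- sample(9)
  expect_equal(tertileSplit((1:9)[perm])$boundaries, ts$boundaries)
  expect_error(tertileSplit(rep(1, 5)), "identical")
  expect_error(tertileSplit(c(1, 2)), "3 values")
})

test_that("tertile and fixed-cutoff labels mostly agree on a realistic cohort", {
  ## near-balanced thirds whose empirical tertiles land near 1.0 and 1.17
  set.seed(17)
  ratios <- c(rnorm(25, 0.90, 0.06), runif(25, 1.00, 1.16),
              rnorm(24, 1.29, 0.08))
  agree <- mean(as.character(tertileSplit(ratios)$labels) ==
                  as.character(classifyRisk(ratios)))
  expect_gte(agree, 0.9)
})
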