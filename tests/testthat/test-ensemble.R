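test_that("mean unitary spectrum combines classes by abundance", {
  ms <- brainMeanSpectrum()
  ## calibrated class energies are the class-type targets, so the
  ## abundance-weighted mean is 0.85*0.09 + 0.15*0.02
  expect_equal(sum(classWeights(ms) * classEnergies(ms)), 0.0795,
               tolerance = 1e-9)
  ## single class: the mean is that class's spectrum
  cl1 <- list(patchClasses()[[1]])
  b1 <- patchBank()[1]
  ms1 <- meanUnitarySpectrum(b1, cl1, patchGeometry(), patchLeadField())
  expect_equal(specValues(ms1), specValues(perClassSpectra(ms1)[[1]]))
  ## doubling all kernel amplitudes quadruples the mean spectrum
  b2 <- lapply(b1, function(k)
    UnitaryKernel(2 * kernelWaveform(k), sampleInterval(k),
                  kernelWindow(k), classLabel(k)))
  ms2 <- meanUnitarySpectrum(b2, cl1, patchGeometry(), patchLeadField())
  expect_equal(specValues(ms2), 4 * specValues(ms1), tolerance = 1e-12)
})

test_that("asynchronous spectrum is lambda * N * mean energy density", {
  ms <- brainMeanSpectrum()
  expect_true(all(specValues(asynchronousSpectrum(0, 16e9, ms)) == 0))
  s1 <- asynchronousSpectrum(2, 5, ms)
  s2 <- asynchronousSpectrum(1, 1, ms)
  expect_equal(specValues(s1), 10 * specValues(s2))
  expect_equal(specUnits(s1), "uV^2/Hz")
})

test_that("whole-brain asynchronous firing stays below the noise floor", {
  spec <- asynchronousSpectrum(1, 16e9, brainMeanSpectrum())
  expect_false(detectability(spec, floor = 1e-3)$detectable)
})

test_that("asynchronous theory matches direct time-domain synthesis", {
  set.seed(99)
  geom <- sphereGeometry(50, density = 50 / (4 * pi * 50^2))
  lf <- leadFieldInfinite(c(0, 0, 58))
  pop <- patchPopulation()
  classes <- patchClasses()
  bank <- calibrateKernelBank(makeKernelBank(classes, dt = 0.5), classes,
                              geom, lf)
  placed <- placePopulation(geom, pop, 50, seed = 7)
  lam <- 5; dur <- 2e5; dt <- 0.5; n <- dur / dt
  sig <- numeric(n)
  for (i in 1:50) {
    u <- scalpUnitaryResponse(bank[[placed@classes[i]]],
                              placed@positions[i, ], placed@frames[[i]],
                              lf)
    uv <- tsSamples(u)[, 1] * 1e-6        # uV
    idx <- sort(sample.int(n - length(uv), rpois(1, lam * dur / 1000)))
    for (s in idx)
      sig[s:(s + length(uv) - 1)] <- sig[s:(s + length(uv) - 1)] + uv
  }
  ps <- estimatePsd(TimeSeries(sig, dt))
  f <- freqs(ps); sel <- f >= 20 & f <= 300
  th <- ensembleBruteforce(placed, bank,
                           SynchronyParams(lambda = lam, rmax = 0,
                                           sigmaX = sqrt(3), sigmaT = 11.3),
                           lf, f[sel])
  expect_equal(mean(specValues(ps)[sel]) / mean(specValues(th)), 1,
               tolerance = 0.05)
})

test_that("the exact double sum honours its structural limits", {
  placed <- patchPlaced()
  bank <- patchBank()
  lf <- patchLeadField()
  fg <- patchFreqs()
  ## Rmax = 0: the pair term vanishes, leaving the auto term
  b0 <- ensembleBruteforce(placed, bank, patchSynchrony(rmax = 0), lf, fg)
  expect_true(all(attr(b0, "pairTerm") == 0))
  expect_equal(specValues(b0), attr(b0, "autoTerm"))
  ## N = 1: single auto term
  one <- new("PlacedPopulation", classes = placed@classes[1],
             excitatory = placed@excitatory[1],
             positions = placed@positions[1, , drop = FALSE],
             frames = placed@frames[1])
  b1 <- ensembleBruteforce(one, bank, patchSynchrony(), lf, fg)
  expect_true(all(attr(b1, "pairTerm") == 0))
  ## pair term is non-negative at f = 0+ for positive coupling
  bp <- ensembleBruteforce(placed, bank, patchSynchrony(), lf, fg)
  expect_gt(attr(bp, "pairTerm")[1], 0)
  expect_error(ensembleBruteforce(placed, bank, patchSynchrony(), lf, fg,
                                  maxN = 10), "pairTermMonteCarlo")
})

test_that("jitter limits collapse the ensemble onto the two references", {
  placed <- patchPlaced()
  bank <- patchBank(); lf <- patchLeadField(); fg <- patchFreqs()
  bAsync <- ensembleBruteforce(placed, bank, patchSynchrony(rmax = 0),
                               lf, fg)
  bInf <- ensembleBruteforce(placed, bank, patchSynchrony(sigmaT = 1e7),
                             lf, fg)
  sel <- fg > 0
  expect_equal(specValues(bInf)[sel], specValues(bAsync)[sel],
               tolerance = 1e-9)
  ## sigmaT = 0 and sigmaT = 5 ms agree below the jitter cutoff and
  ## diverge above it: the pair term is filtered by the Gaussian
  ## exp(-2 pi^2 sigmaT^2 f^2), which crosses 50% at ~37.5 Hz for 5 ms
  b0 <- ensembleBruteforce(placed, bank, patchSynchrony(sigmaT = 0), lf, fg)
  b5 <- ensembleBruteforce(placed, bank, patchSynchrony(sigmaT = 5), lf, fg)
  p0 <- attr(b0, "pairTerm"); p5 <- attr(b5, "pairTerm")
  keep <- abs(p0) > 1e-3 * max(abs(p0))
  gauss <- exp(-2 * pi^2 * (5e-3)^2 * fg^2)
  expect_equal(p5[keep] / p0[keep], gauss[keep], tolerance = 1e-9)
  fc <- sqrt(log(2) / 2) / (pi * 5e-3)
  expect_equal(fc, 37.5, tolerance = 0.01)
  expect_lt(max(abs(p5[keep & fg < fc / 4] / p0[keep & fg < fc / 4] - 1)),
            0.05)
  expect_true(all(abs(p5[keep & fg > 4 * fc]) <
                    0.5 * abs(p0[keep & fg > 4 * fc])))
})

test_that("Chebyshev stopping arithmetic gives the canonical draw count", {
  expect_equal(chebyshevRequiredN(1, 0.1, 0.01), 10000)
})

test_that("Monte Carlo pair estimates agree with the exact sum", {
  placed <- patchPlaced()
  bank <- patchBank(); lf <- patchLeadField(); fg <- patchFreqs()
  syn <- patchSynchrony()
  pt <- attr(ensembleBruteforce(placed, bank, syn, lf, fg), "pairTerm")
  delta <- max(abs(pt)) / 10
  for (s in 1:3) {
    mc <- pairTermMonteCarlo(placed, bank, syn, lf, fg,
                             mc = MCConfig(deltaAbs = delta,
                                           batchSize = 2000), seed = s)
    expect_true(mc$converged)
    expect_lt(max(abs(Re(specValues(mc$spectrum)) - pt)), delta)
  }
  ## non-convergence is flagged when the draw budget is exhausted
  tight <- pairTermMonteCarlo(placed, bank, syn, lf, fg,
                              mc = MCConfig(deltaAbs = delta / 1e6,
                                            batchSize = 500,
                                            maxDraws = 1000), seed = 1)
  expect_false(tight$converged)
})

test_that("the Monte Carlo estimator is unbiased", {
  placed <- patchPlaced()
  bank <- patchBank(); lf <- patchLeadField(); fg <- patchFreqs()
  syn <- patchSynchrony()
  pt <- attr(ensembleBruteforce(placed, bank, syn, lf, fg), "pairTerm")
  i <- which.max(abs(pt))
  est <- vapply(1:200, function(s)
    Re(specValues(pairTermMonteCarlo(placed, bank, syn, lf, fg,
                                     mc = MCConfig(deltaAbs = 1e-30,
                                                   batchSize = 400,
                                                   maxDraws = 400),
                                     seed = s)$spectrum))[i], 0)
  z <- (mean(est) - pt[i]) / (sd(est) / sqrt(200))
  expect_lt(abs(z), 2)
})

test_that("continuum sampling reproduces the placement-averaged pair term", {
  geom <- patchGeometry()
  bank <- patchBank(); lf <- patchLeadField(); fg <- patchFreqs()
  syn <- patchSynchrony()
  pts <- vapply(1:20, function(s)
    attr(ensembleBruteforce(placePopulation(geom, patchPopulation(), 50,
                                            seed = s),
                            bank, syn, lf, fg), "pairTerm"),
    numeric(length(fg)))
  bfMean <- rowMeans(pts)
  pd <- pairDistanceDensity(geom, radii = seq(0, 16, length.out = 81))
  mcc <- pairTermMonteCarlo(geom, bank, classes = patchClasses(),
                            pairDensity = pd, synchrony = syn,
                            leadField = lf, freqsHz = fg,
                            mc = MCConfig(deltaAbs = max(abs(bfMean)) / 5,
                                          batchSize = 1000,
                                          maxDraws = 2e4), seed = 3)
  i <- which.max(abs(bfMean))
  expect_equal(Re(specValues(mcc$spectrum))[i] / bfMean[i], 1,
               tolerance = 0.3)
})

test_that("ensemble power grows with rate, correlation and count", {
  placed <- patchPlaced()
  bank <- patchBank(); lf <- patchLeadField(); fg <- patchFreqs()
  at <- function(lam, rmax) specValues(ensembleBruteforce(
    placed, bank, SynchronyParams(lam, rmax, sqrt(3), 11.3), lf, fg))
  expect_true(all(at(2, 0.2) >= at(1, 0.2)))
  expect_true(all(at(1, 0.25) >= at(1, 0.1)))
  ms <- brainMeanSpectrum()
  expect_true(all(specValues(asynchronousSpectrum(1, 2e9, ms)) <=
                    specValues(asynchronousSpectrum(1, 16e9, ms))))
})

test_that("auto and pair terms combine on a shared grid only", {
  ms <- brainMeanSpectrum()
  a <- asynchronousSpectrum(1, 16e9, ms)
  expect_equal(specValues(ensembleSpectrum(a, NULL)), specValues(a))
  zero <- Spectrum(freqs(a), rep(0, length(freqs(a))), kind = "cross")
  expect_equal(specValues(ensembleSpectrum(a, zero)), specValues(a))
  bad <- Spectrum(freqs(a)[-1], rep(0, length(freqs(a)) - 1),
                  kind = "cross")
  expect_error(ensembleSpectrum(a, bad), "grid")
})

test_that("synaptic ensemble splits its timescales by spatial coherence", {
  pd <- pairDistanceDensity(patchGeometry(),
                            radii = seq(0, 16, length.out = 81))
  tp <- TrendParams()
  f <- exp(seq(log(1), log(500), length.out = 100))
  ## both scales zero: N times the single-neuron spectrum
  s00 <- synapticEnsembleSpectrum(tp, 0, 0, pd, N = 50, freqsHz = f)
  expect_equal(specValues(s00), 50 * evalTrend(tp, f), tolerance = 1e-12)
  ## AMPA scale zero: its cross term vanishes
  sg <- synapticEnsembleSpectrum(tp, 1, 0, pd, N = 50, freqsHz = f)
  cmp <- attr(sg, "components")
  expect_equal(cmp$pairWeightE, 0)
  expect_gt(cmp$pairWeightI, 0)
  ## wider GABA coherence boosts the GABA share above its single-neuron
  ## share
  LI <- apEEG:::lorentzianPair(tp@ampI, tp@tauI1, tp@tauI2, f)
  singleShareI <- integrateSpectrum(Spectrum(f, LI)) /
    integrateSpectrum(Spectrum(f, evalTrend(tp, f)))
  ensShareI <- integrateSpectrum(Spectrum(f, cmp$inhibitory)) /
    integrateSpectrum(Spectrum(f, cmp$inhibitory + cmp$excitatory))
  expect_gt(ensShareI, singleShareI)
})
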