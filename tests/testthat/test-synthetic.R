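test_that("class kernels are band-pass, deterministic and scale correctly", {
  cl <- NeuronClassSpec("E", kernelParams = list(peakFreq = 100,
                                                 amplitude = 1,
                                                 ahpAmplitude = 0))
  k <- makeClassKernel(cl, dt = 0.5)
  es <- energySpectrum(k)
  f <- freqs(es); v <- specValues(es)
  fPeak <- f[which.max(v)]
  expect_gt(fPeak, 50); expect_lt(fPeak, 150)
  ## without an AHP, 1 Hz power sits at least 10x below the band-pass peak
  expect_lt(v[which.min(abs(f - 1))] * 10, max(v))
  ## kernels are pure functions of the class parameters
  b1 <- makeKernelBank(list(cl), seed = 1)
  b2 <- makeKernelBank(list(cl), seed = 99)
  expect_identical(kernelWaveform(b1[[1]]), kernelWaveform(b2[[1]]))
  ## doubling the amplitude quadruples the energy
  cl2 <- NeuronClassSpec("E2", kernelParams = list(peakFreq = 100,
                                                   amplitude = 2,
                                                   ahpAmplitude = 0))
  expect_equal(kernelEnergy(makeClassKernel(cl2, dt = 0.5)),
               4 * kernelEnergy(k), tolerance = 1e-12)
  expect_error(makeClassKernel(NeuronClassSpec("bad",
    kernelParams = list(amplitude = -1))), "positive")
})

test_that("AHP tails add low-frequency power", {
  mk <- function(a) {
    cl <- NeuronClassSpec("x", kernelParams = list(ahpAmplitude = a,
                                                   ahpDecay = 80))
    es <- energySpectrum(makeClassKernel(cl, dt = 0.5, window = c(-10, 400)))
    specValues(es)[which.min(abs(freqs(es) - 1))]
  }
  expect_gt(mk(0.1), 10 * mk(0))
})

test_that("population tables hit the requested excitatory fraction", {
  pop <- makePopulation(0.85, 6, seed = 1)
  expect_equal(sum(pop$abundance), 1)
  expect_equal(sum(pop$abundance[pop$excitatory]), 0.85)
  expect_true(all(!makePopulation(0, 4, seed = 1)$excitatory))
  expect_true(all(makePopulation(1, 4, seed = 1)$excitatory))
  expect_error(makePopulation(1.2), "excFraction")
  ## same seed, same table
  expect_identical(pop, makePopulation(0.85, 6, seed = 1))
})

test_that("synthetic morphologies honour their asymmetry target", {
  m0 <- makeMorphology(0, nSegments = 30, seed = 2)
  expect_equal(asymmetryIndex(m0), 0, tolerance = 1e-9)
  expect_identical(segmentMidpoints(makeMorphology(10, 30, seed = 2)),
                   segmentMidpoints(makeMorphology(10, 30, seed = 2)))
  expect_error(makeMorphology(0, nSegments = 1), ">= 2")
})

test_that("active/passive traces embed the kernel exactly", {
  k <- unitKernel()
  ## lambda = 0: active is identical to passive
  tr0 <- makeActivePassiveTraces(k, 0, duration = 5000, seed = 1)
  expect_identical(tsSamples(tr0$active), tsSamples(tr0$passive))
  ## noise off: active - passive is the exact kernel superposition
  tr <- makeActivePassiveTraces(k, 3, duration = 20000, noiseSd = 0, seed = 2)
  d <- tsSamples(tr$active) - tsSamples(tr$passive)
  recon <- matrix(0, nrow(d), 3)
  w <- t(kernelWaveform(k))
  off <- round(kernelWindow(k)[1] / sampleInterval(k))
  for (s in tr$spikes) {
    i <- round(s / sampleInterval(k)) + 1L
    rows <- (i + off):(i + off + nrow(w) - 1L)
    recon[rows, ] <- recon[rows, ] + w
  }
  expect_equal(d, recon, tolerance = 1e-12)
  ## voltage surrogate crosses 0 mV exactly at the spike samples
  spk <- detectSpikes(tr$voltage)
  expect_equal(spk, tr$spikes)
  expect_error(makeActivePassiveTraces(k, 1, duration = 100),
               "too short")
})

test_that("spike counts follow Poisson statistics", {
  k <- unitKernel()
  tr <- makeActivePassiveTraces(k, 10, duration = 1e5, noiseSd = 0,
                                seed = 11)
  n <- length(tr$spikes)
  expect_gt(n, 1000 - 4 * sqrt(1000))
  expect_lt(n, 1000 + 4 * sqrt(1000))
})

test_that("synthetic EEG spectra follow the trend model exactly", {
  tp <- TrendParams()
  f <- exp(seq(log(1), log(500), length.out = 150))
  s <- makeEegSpectrum(tp, floor = 0, freqsHz = f, relNoise = 0)
  expect_equal(specValues(s), (1 + 1 / f^2) * evalTrend(tp, f))
  sf <- makeEegSpectrum(tp, floor = 1e-3, freqsHz = f)
  expect_equal(specValues(sf) - specValues(s), rep(1e-3, length(f)))
  ## multiplicative noise is seed-deterministic and mean-preserving-ish
  n1 <- makeEegSpectrum(tp, floor = 0, freqsHz = f, relNoise = 0.1,
                        seed = 5)
  expect_identical(specValues(n1),
                   specValues(makeEegSpectrum(tp, floor = 0, freqsHz = f,
                                              relNoise = 0.1, seed = 5)))
  expect_equal(mean(specValues(n1) / specValues(s)), 1, tolerance = 0.05)
})

test_that("correlated spike pairs hit their degenerate limits", {
  expect_error(makeCorrelatedSpikePair(1, 1.5, 10), "rmax")
  ## full correlation, no jitter: identical trains
  sp <- makeCorrelatedSpikePair(5, 1, 0, duration = 1e5, seed = 3)
  expect_identical(sp$t1, sp$t2)
  ## no correlation: correlogram flat at 0 within confidence bounds
  sp0 <- makeCorrelatedSpikePair(5, 0, 10, duration = 1e6, seed = 4)
  emp <- empiricalCrossCorrelogram(sp0$t1, sp0$t2, 1e6,
                                   seq(-40, 40, by = 4))
  expect_lt(max(abs(emp$density / emp$se)), 4)
})

test_that("kernel calibration reaches the target scalp energies", {
  bank <- patchBank()
  sc <- attr(bank, "scales")
  expect_true(all(is.finite(sc) & sc > 0))
  ms <- meanUnitarySpectrum(bank, patchClasses(), patchGeometry(),
                            patchLeadField())
  expect_equal(unname(classEnergies(ms)),
               vapply(patchClasses(), function(cl) cl@targetEnergy, 0),
               tolerance = 1e-9)
})
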