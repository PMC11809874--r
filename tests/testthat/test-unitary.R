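test_that("spike detection finds threshold-crossing peaks only", {
  dt <- 0.5
  sub <- TimeSeries(rep(-65, 1000), dt)
  expect_length(detectSpikes(sub), 0)
  v <- rep(-65, 1000)
  v[200:210] <- -65 + 100 * exp(-((200:210) - 205)^2 / 4)
  one <- detectSpikes(TimeSeries(v, dt))
  expect_equal(one, (205 - 1) * dt)
  ## two bumps 50 ms apart, ordered output
  v[500:510] <- v[200:210]
  two <- detectSpikes(TimeSeries(v, dt))
  expect_equal(two, c(204, 504) * dt)
  expect_error(detectSpikes(TimeSeries(matrix(0, 10, 3), dt)),
               "single-channel")
})

test_that("refractory separation keeps the larger of close peaks", {
  v <- rep(-65, 400)
  v[100] <- 10; v[103] <- 20
  spk <- detectSpikes(TimeSeries(v, 1), refractory = 10)
  expect_equal(spk, 102)
})

test_that("noiseless STA recovers the kernel to machine precision", {
  k <- unitKernel()
  tr <- makeActivePassiveTraces(k, 5, duration = 60000, noiseSd = 0,
                                seed = 3)
  spk <- detectSpikes(tr$voltage)
  sta <- spikeTriggeredAverage(tr$active, tr$passive, spk,
                               window = c(-10, 150),
                               excludeOverlaps = TRUE)
  expect_lt(max(abs(kernelWaveform(sta) - kernelWaveform(k))), 1e-12)
  ## active == passive -> zero kernel
  z <- spikeTriggeredAverage(tr$passive, tr$passive, spk,
                             window = c(-10, 150))
  expect_true(all(kernelWaveform(z) == 0))
})

test_that("STA refuses too few usable spikes, counting them", {
  k <- unitKernel()
  tr <- makeActivePassiveTraces(k, 5, duration = 60000, noiseSd = 0,
                                seed = 3)
  expect_error(spikeTriggeredAverage(tr$active, tr$passive,
                                     tr$spikes[1:4], window = c(-10, 150)),
               "only 4 usable")
})

test_that("STA error shrinks as one over the square root of spike count", {
  k <- unitKernel()
  tr <- makeActivePassiveTraces(k, 12, duration = 2e5, noiseSd = 0.3,
                                seed = 9)
  rmse <- vapply(c(10, 40, 160), function(n) {
    sta <- spikeTriggeredAverage(tr$active, tr$passive, tr$spikes[1:n],
                                 window = c(-10, 150))
    sqrt(mean((kernelWaveform(sta) - kernelWaveform(k))^2))
  }, 0)
  expect_true(all(diff(rmse) < 0))
  ## 16x the spikes: ~4x smaller error (loose band for a single draw)
  expect_gt(rmse[1] / rmse[3], 2.0)
  expect_lt(rmse[1] / rmse[3], 8.0)
})

test_that("linear AP model fit is exact on constructed spectra", {
  f <- exp(seq(log(1), log(500), length.out = 120))
  sap <- exp(-(log(f) - log(100))^2)
  ssyn <- 10 / (1 + (f / 30)^2)
  ## beta enters against Sap in value^2*s/Hz; grid values are *ms/Hz
  S <- Spectrum(f, ssyn + 5 * sap * 1e-3)
  fit <- fitLinearApModel(S, Spectrum(f, ssyn),
                          Spectrum(f, sap, kind = "energy"))
  expect_equal(fittedBeta(fit), 5, tolerance = 1e-9)
  expect_equal(fitRSquared(fit), 1, tolerance = 1e-9)
  ## S = Ssyn alone: beta = 0
  fit0 <- fitLinearApModel(Spectrum(f, ssyn), Spectrum(f, ssyn),
                           Spectrum(f, sap, kind = "energy"))
  expect_equal(fittedBeta(fit0), 0)
  ## beta invariant to a common rescaling of all three spectra
  fitC <- fitLinearApModel(Spectrum(f, 7 * (ssyn + 5 * sap * 1e-3)),
                           Spectrum(f, 7 * ssyn),
                           Spectrum(f, 7 * sap, kind = "energy"))
  expect_equal(fittedBeta(fitC), 5, tolerance = 1e-9)
  expect_error(fitLinearApModel(S, Spectrum(f, ssyn),
                                Spectrum(f, rep(0, 120), kind = "energy")),
               "unidentifiable")
  expect_error(fitLinearApModel(S, Spectrum(f[-1], ssyn[-1]),
                                Spectrum(f, sap, kind = "energy")),
               "common frequency grid")
})

test_that("fitted beta tracks the firing rate through the full pipeline", {
  fit <- pipelineBeta(10, seed = 104)
  expect_equal(fittedBeta(fit), 10, tolerance = 0.1)
  expect_gt(fitRSquared(fit), 0.9)
})

test_that("saturating the active trace degrades the linear model fit", {
  k <- unitKernel()
  tr <- makeActivePassiveTraces(k, 10, duration = 60000, noiseSd = 0.05,
                                seed = 4)
  r2 <- vapply(c(Inf, 0.4, 0.12), function(sat) {
    a <- tsSamples(tr$active)
    if (is.finite(sat)) a <- sat * tanh(a / sat)
    S <- estimatePsd(TimeSeries(a, sampleInterval(tr$active)))
    Ssyn <- estimatePsd(tr$passive)
    fitRSquared(fitLinearApModel(S, Ssyn, energySpectrumAt(k, freqs(S))))
  }, 0)
  expect_true(all(diff(r2) < 0))
})
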