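test_that("double-Lorentzian trend evaluates to hand-computed values", {
  tp <- TrendParams()
  expect_equal(evalTrend(tp, 0),
               3.6 * (0.004 - 0.020)^2 + 3.3 * (0.001 - 0.003)^2)
  expect_lt(evalTrend(tp, 1e5), 1e-12)
  ## component isolation: pure inhibitory double Lorentzian
  pI <- TrendParams(ampE = 0)
  knee <- 1 / (2 * pi * 0.020)
  expect_equal(evalTrend(pI, knee),
               3.6 * (0.016)^2 / ((1 + (0.004 / 0.020)^2) * 2))
  expect_error(TrendParams(tauI1 = 0.02, tauI2 = 0.004), "rise")
})

test_that("noise-floor subtraction clips and counts", {
  s <- Spectrum(1:4, c(2e-3, 2e-3, 5e-4, 1e-3))
  out <- suppressWarnings(subtractNoiseFloor(s, 1e-3))
  expect_equal(specValues(out)[1], 1e-3)
  expect_equal(specValues(out)[3], 1e-12)
  expect_equal(attr(out, "nClipped"), 2)
  expect_warning(subtractNoiseFloor(s, 1e-3), "clipped")
  ident <- subtractNoiseFloor(s, 0)
  expect_equal(specValues(ident), specValues(s))
})

test_that("trend fit recovers noiseless parameters exactly", {
  f <- exp(seq(log(1), log(300), length.out = 200))
  tp <- TrendParams()
  fit <- fitTrend(Spectrum(f, evalTrend(tp, f)), seed = 1)
  expect_equal(fit@ampI, 3.6, tolerance = 1e-4)
  expect_equal(fit@ampE, 3.3, tolerance = 1e-4)
  expect_equal(fit@tauI1, 0.004, tolerance = 1e-4)
  expect_equal(fit@tauI2, 0.020, tolerance = 1e-4)
})

test_that("trend fit round-trips random physiological parameter sets", {
  set.seed(7)
  f <- exp(seq(log(1), log(300), length.out = 200))
  for (k in 1:100) {
    tI1 <- runif(1, 0.002, 0.008)
    tI2 <- tI1 * runif(1, 2.5, 8)
    aI <- 10^runif(1, -1, 1)
    aE <- aI * 10^runif(1, -1, 0.5)
    tp <- TrendParams(tauI1 = tI1, tauI2 = tI2, ampI = aI, ampE = aE)
    fit <- fitTrend(Spectrum(f, evalTrend(tp, f)), seed = k)
    rel <- abs(c(fit@ampI / aI, fit@ampE / aE,
                 fit@tauI1 / tI1, fit@tauI2 / tI2) - 1)
    expect_lt(max(rel), 0.01, label = sprintf("round trip %d", k))
  }
})

test_that("trend fit tolerates multiplicative sampling noise", {
  f <- exp(seq(log(1), log(300), length.out = 200))
  errs <- vapply(1:50, function(s) {
    set.seed(1000 + s)
    v <- evalTrend(TrendParams(), f) *
      rlnorm(length(f), 0, sqrt(log(1 + 0.05^2)))
    fit <- fitTrend(Spectrum(f, v), seed = s)
    max(abs(c(fit@ampI / 3.6, fit@ampE / 3.3,
              fit@tauI1 / 0.004, fit@tauI2 / 0.020) - 1))
  }, 0)
  expect_lt(median(errs), 0.10)
})

test_that("trend fit rejects inadequate inputs", {
  expect_error(fitTrend(Spectrum(1:10, rep(1, 10))), "20 frequency bins")
  f <- seq(10, 90, length.out = 30)
  expect_error(fitTrend(Spectrum(f, rep(1, 30))), "2 decades")
  f2 <- exp(seq(log(1), log(300), length.out = 30))
  expect_error(fitTrend(Spectrum(f2, c(rep(1, 29), 0), kind = "cross")),
               "positive")
})

test_that("detectability reports the maximal density above 30 Hz", {
  f <- seq(1, 500, by = 1)
  low <- Spectrum(f, rep(1e-4, length(f)))
  d <- detectability(low, floor = 1e-3)
  expect_false(d$detectable)
  expect_equal(d$maxDensity, 1e-4)
  v <- rep(1e-4, length(f)); v[f == 200] <- 1e-2
  d2 <- detectability(Spectrum(f, v), floor = 1e-3)
  expect_true(d2$detectable)
  expect_equal(d2$maxDensity, 1e-2)
  expect_equal(d2$fAtMax, 200)
  expect_error(detectability(Spectrum(1:10, rep(1, 10)), fMin = 30),
               "past fMin")
})

test_that("peak amplitudes relative to the trend behave", {
  tp <- TrendParams()
  f <- seq(1, 100, by = 1)
  s <- Spectrum(f, evalTrend(tp, f))
  expect_equal(peakRelativeAmplitude(s, tp, 10), 1)
  expect_equal(peakRelativeAmplitude(Spectrum(f, rep(0, length(f)),
                                              kind = "cross"), tp, 10), 0)
})

test_that("peak translation preserves trend-relative amplitude", {
  tp <- TrendParams()
  alpha <- list(center = 10, amplitude = 5, width = 1.5)
  tr <- translatePeak(alpha, tp, 40)
  expect_equal(tr$center, 40)
  expect_equal(tr$amplitude, 5)
  expect_equal(tr$absolutePower / (5 * evalTrend(tp, 40)), 1)
  ## absolute power scales by trend(target)/trend(center)
  expect_equal(tr$absolutePower / (alpha$amplitude * evalTrend(tp, 10)),
               evalTrend(tp, 40) / evalTrend(tp, 10))
  ident <- translatePeak(alpha, tp, 10)
  expect_equal(ident$absolutePower, 5 * evalTrend(tp, 10))
})

test_that("AP fraction of rhythm peaks is a guarded ratio", {
  expect_equal(apFraction(3, 1)$fraction, 0.75)
  expect_equal(apFraction(0, 1)$fraction, 0)
  z <- apFraction(0, 0)
  expect_false(z$defined)
  expect_equal(z$fraction, 0)
  ## synaptic peak below floor, AP peak above: all-AP and detectable
  r <- apFraction(5e-3, 0, floor = 1e-3)
  expect_equal(r$fraction, 1)
  expect_true(r$detectable)
  ## monotone in both arguments
  expect_gt(apFraction(4, 1)$fraction, apFraction(3, 1)$fraction)
  expect_lt(apFraction(3, 2)$fraction, apFraction(3, 1)$fraction)
})

test_that("toy spectrum assembles its caption equation", {
  f <- exp(seq(log(1), log(500), length.out = 300))
  bare <- ToyModelParams(peaks = data.frame(center = numeric(0),
                                            width = numeric(0),
                                            amplitude = numeric(0)),
                         noise = 0)
  s <- toySpectrum(bare, f)
  expect_equal(specValues(s), (1 + 1 / f^2) * evalTrend(bare@trend, f))
  ## a peak at 10 Hz of amplitude a satisfies
  ## P(10)/trend(10) - (1 + 1/100) = a on a noiseless grid
  pk <- ToyModelParams(peaks = data.frame(center = 10, width = 1.5,
                                          amplitude = 5), noise = 0)
  s10 <- toySpectrum(pk, 10)
  expect_equal(specValues(s10) / evalTrend(pk@trend, 10) - (1 + 1 / 100),
               5)
  ## halving the additive noise halves the >200 Hz plateau
  a <- ToyModelParams(); b <- ToyModelParams(noise = a@noise / 2)
  expect_equal(noisePlateau(toySpectrum(b, f)) /
                 noisePlateau(toySpectrum(a, f)), 0.5, tolerance = 1e-9)
  ## additive HFO creates a local maximum at its centre
  h <- toySpectrum(ToyModelParams(hfoCenter = 250), f)
  i <- which.min(abs(f - 250))
  v <- specValues(h)
  expect_true(v[i] > v[i - 10] && v[i] > v[i + 10])
})

test_that("detrending strategies differ exactly as designed", {
  f <- exp(seq(log(1), log(500), length.out = 400))
  base <- ToyModelParams()
  modT <- base@trend
  modT@ampE <- modT@ampE / 2.5
  mod <- ToyModelParams(peaks = base@peaks, trend = modT,
                        noise = base@noise / 2)
  sA <- toySpectrum(base, f); sB <- toySpectrum(mod, f)
  i10 <- which.min(abs(f - 10)); i40 <- which.min(abs(f - 40))
  ## mixed: subtract the additive noise, divide the synaptic trend ->
  ## rhythm power unchanged between the two conditions
  mA <- specValues(detrendSpectrum(sA, base@trend, base@noise, "mixed"))
  mB <- specValues(detrendSpectrum(sB, modT, mod@noise, "mixed"))
  expect_lt(max(abs(mB / mA - 1)[c(i10, i40)]), 1e-9)
  ## divisive-only inflates the 40 Hz peak artifactually
  dA <- specValues(detrendSpectrum(sA, base@trend, base@noise, "divisive"))
  dB <- specValues(detrendSpectrum(sB, modT, mod@noise, "divisive"))
  expect_gt((dB / dA)[i40], 1)
  ## subtractive with zero floor is the identity
  expect_equal(specValues(detrendSpectrum(sA, base@trend, 0,
                                          "subtractive")),
               specValues(sA))
})
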