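# apEEG

Do action potentials (APs) contribute measurably to scalp EEG? Synaptic
currents are the textbook source of EEG, but spiking activity shapes the
broadband spectrum of invasive recordings, and whether any of that
survives at the scalp decides how EEG spectra should be detrended and
how high-frequency oscillations should be read. **apEEG** is an R
package for researchers modelling EEG generation: it quantifies the
scalp signal produced by spiking ("apEEG") under explicit biophysical
and statistical assumptions, and compares it to synaptic EEG and to the
noise floor of a recording system.

## The model

A spike adds a stereotyped transient to its neuron's current dipole — a
*unitary AP response* `q_ap(t)`, extracted by spike-triggered averaging
of active-minus-passive simulations. The single-neuron spectrum then
obeys the linear model

    S(f) = Ssyn(f) + beta * Sap(f)

with `Sap` the energy spectrum of the unitary response and `beta` an
estimate of the firing rate. Summing over the brain through a lead field
`nu(x)` gives the ensemble apEEG spectrum

    P_ap(f) = sum_{i,j} Rspike_ij(f) * nu(x_i)' Rap_ij(f) nu(x_j)

whose diagonal is the asynchronous term `lambda * N * Sbar_AP(f)` and
whose off-diagonal (pair) term is driven by spike synchrony, modelled as
a distance-damped, Gaussian-jittered, optionally rhythmic
cross-correlogram with closed-form spectrum

    R(f) = lambda * Rmax * exp(-d^2 / 2 sigmaX^2) * exp(-2 pi^2 sigmaT^2 f^2)

(shifted to `±f0` for rhythmic synchrony). Pair sums at brain scale are
estimated by Monte Carlo with a Chebyshev-inequality stopping rule. On
the analysis side, the aperiodic spectral trend is modelled as two
Lorentzian pairs from inhibitory and excitatory synaptic time constants,
fitted after noise-floor subtraction, and three detrending strategies
(divisive, subtractive, mixed) are provided and compared. A
synthetic-data module generates every input the analysis expects —
kernels, populations, morphologies, correlated spike trains, trend-shaped
spectra — as pure functions of parameters and a seed.

## Worked example

Whole-brain asynchronous firing at 1 Hz, with class scalp energies
calibrated to 0.09 pV²·ms (excitatory) and 0.02 pV²·ms (inhibitory):

```r
library(apEEG)

geom <- sphereGeometry(radius = 50, density = 16e9 / (4 * pi * 50^2))
lf   <- leadFieldInfinite(c(0, 0, 58))          # electrode 8 mm above cortex
pop  <- makePopulation(excFraction = 0.85, nClasses = 6, seed = 1)
classes <- populationClasses(pop)
bank <- calibrateKernelBank(makeKernelBank(classes), classes, geom, lf)

ms <- meanUnitarySpectrum(bank, classes, geom, lf)
ms
#> MeanUnitarySpectrum: 6 classes, weighted mean energy 0.0795 pV^2*ms

spec <- asynchronousSpectrum(lambda = 1, N = 16e9, ms)
detectability(spec, floor = 1e-3)
#> $maxDensity
#> [1] 1.215218e-08
#> $detectable
#> [1] FALSE
#> $fAtMax
#> [1] 82.13907
```

The abundance-weighted mean unitary scalp energy is
`0.85 * 0.09 + 0.15 * 0.02 = 0.0795` pV²·ms (~0.08), and the
asynchronous whole-brain spectrum peaks near 82 Hz at ~1.2e-8 µV²/Hz —
five orders of magnitude below a 1e-3 µV²/Hz amplifier floor, hence
undetectable: asynchronous spiking cannot produce scalp EEG.

Fitting the double-Lorentzian trend recovers its generating parameters,
and the rhythmic synchrony spectrum peaks at the rhythm frequency:

```r
f <- exp(seq(log(1), log(300), length.out = 200))
fitTrend(Spectrum(f, evalTrend(TrendParams(), f)), seed = 1)
#> TrendParams: tauI = (4, 20) ms, tauE = (1, 3) ms, AI = 3.6, AE = 3.3, ...

p <- synchronyPreset("mt-cotuned", f0 = 40)     # Rmax = 0.2, sigmaT = 11.3 ms
fGrid <- seq(0, 500, by = 0.1)
fGrid[which.max(crossSpectrumAnalytic(p, d = 0, f = fGrid))]
#> [1] 40
```

See `vignettes/apeeg-methods.Rmd` for the model assumptions, parameter
defaults and their rationale, and known limitations.

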