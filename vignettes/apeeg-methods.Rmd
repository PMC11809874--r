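---
title: "Modelling action-potential contributions to scalp EEG spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling action-potential contributions to scalp EEG spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apEEG)
```

## The scientific problem

Scalp EEG power spectra combine a smooth broadband ("aperiodic") trend,
narrowband rhythm peaks, and contamination from muscle (EMG) and
amplifier noise. Whether neuronal action potentials (APs) — as opposed to
synaptic currents — contribute measurably to any of these components
matters for how spectra should be detrended and how high-frequency
oscillations should be interpreted. apEEG implements a quantitative
framework for this question: it models the scalp signal produced by every
spike in the brain as a linear superposition of *unitary AP responses*
and asks, under parameterized models of spike synchrony, how large the
resulting "apEEG" spectrum can get relative to synaptic EEG and to the
noise floor of a recording system.

## The linear model of AP contributions

The starting point is the observation that the AP component of a single
neuron's current dipole behaves like a linear impulse response: each
spike adds a stereotyped transient `q_ap(t)` (a 3-component dipole
waveform, the `UnitaryKernel`). The power spectrum of a spiking neuron's
dipole then decomposes as

```
S(f) = Ssyn(f) + beta * Sap(f)
```

where `Ssyn` is the synaptic (passive) spectrum, `Sap` the energy
spectrum of the unitary response, and `beta` an estimate of the firing
rate. `spikeTriggeredAverage()` extracts the kernel from paired
active/passive traces, and `fitLinearApModel()` estimates `beta` by
weighted least squares over 1–500 Hz with log-spaced frequency weighting
(each decade contributes equally — the estimator's band and weighting are
package choices, exposed as arguments). `beta` is constrained
non-negative by default because it estimates a rate; an unconstrained
fit is available via `nonNegative = FALSE`.

At the population level, the apEEG spectrum is a double sum over neuron
pairs of spike cross-spectra times lead-field-projected kernel
cross-spectra. With uncorrelated Poisson firing only the diagonal
survives:

```
P_async(f) = lambda * N * Sbar_AP(f)
```

with `Sbar_AP` the abundance- and location-averaged unitary scalp energy
spectrum (`meanUnitarySpectrum()`). Spike synchrony adds an off-diagonal
pair term, computed exactly for small populations
(`ensembleBruteforce()`) or by Monte Carlo integration over the
pair-distance density (`pairTermMonteCarlo()`).

## The synchrony model

Pairwise spike synchrony is modelled by a cross-correlogram that decays
with cortical distance (Gaussian, scale `sigmaX`), is smeared in time by
spike jitter (Gaussian, scale `sigmaT`), and optionally oscillates at a
rhythm frequency `f0`:

```
R(tau) = lambda * Rmax / sqrt(2 pi sigmaT^2)
         * exp(-d^2 / 2 sigmaX^2) * exp(-tau^2 / 2 sigmaT^2)
         * cos(2 pi f0 tau)
```

Its Fourier transform is closed-form (`crossSpectrumAnalytic()`): a
Gaussian low-pass in frequency for the aperiodic model, the half-sum of
Gaussians centred at `±f0` for the rhythmic model, and a flat spectrum
in the zero-jitter limit. Defaults encode measured physiology:
`Rmax = 0.2` and `sigmaT = 11.3` ms (co-tuned sensory neurons, the
`"mt-cotuned"` preset), `sigmaX = sqrt(3)` mm (spatial correlation scale
of a few square millimetres), with surveyed ranges `Rmax` 0.05–0.25,
`sigmaT` 10–100 ms, `lambda` 0.1–2 Hz. One deliberate naming decision:
the spatial scale appears under two symbols in the source literature for
the correlogram and its transform; the package uses the single parameter
`sigmaX` for both.

### A known factor-of-two subtlety

The exact transform of the rhythmic correlogram has peak density
`lambda * Rmax * (1 + exp(-8 pi^2 sigmaT^2 f0^2)) / 2` at `f0` — i.e.
*half* the zero-jitter aperiodic level whenever `sigmaT * f0` is not
small, because the cosine splits the correlated mass between `+f0` and
`-f0`. The often-quoted qualitative picture that rhythmic peak heights
"trace out" the zero-jitter spectrum is therefore exact only up to this
factor; on a log-scaled spectrum spanning many decades the discrepancy
is invisible, but quantitatively the rhythmic peak equals the
zero-jitter level times `(A + g*P) / (A + P)` where `A` and `P` are the
auto and pair terms and `g` is the half-sum factor. On the package's
50-neuron test fixture the measured peak ratios are 0.92–0.95; in a
pair-term-dominated (brain-scale) regime the ratio approaches 0.5. The
package implements the exact transform — verified against numerical
quadrature of the correlogram to 1e-6 — rather than renormalizing the
rhythmic kernel to hide the factor.

## Geometry and lead fields

All positions are in mm, dipole moments in nA·µm, potentials in µV; the
single SI conversion lives in `leadFieldInfinite()`. The default lead
field is the analytic infinite-homogeneous-medium dipole potential
(`sigma = 0.33` S/m), which preserves the `1/r^2` falloff and
orientation selectivity that drive the ensemble statistics; lead fields
exported from realistic head models can be loaded with
`leadFieldFromTable()` behind the same interface. A multi-shell
analytic sphere model is not implemented. The electrode convention is a
single electrode at a configurable position.

Source geometry is either an analytic sphere or a triangle mesh.
`pairDistanceDensity()` computes dN(r) — the expected number of
neighbours per mm of separation — by intersecting *Euclidean* balls with
the cortical surface (triangle clipping by recursive subdivision on
meshes; the exact cap-area identity `A = pi r^2` on spheres) and
differentiating the neighbour count by central differences on the radii
grid. A geodesic-ball variant would differ at large `r/R` (on a sphere,
`2 pi rho R sin(r/R)` versus the Euclidean `2 pi rho r`); at the scales
tested (r up to R/5) the two agree within ~1%.

## Monte Carlo pair term and stopping rule

Brain-scale pair sums (~10^19 pairs) are intractable, so the pair term
is estimated by sampling: a class pair proportional to abundance, a
uniform cortical location, a displacement distance drawn from dN(r),
with the Gaussian distance damping applied as a weight. The
frequency shape of the spike cross-spectrum factors out of the spatial
sampling, so each draw contributes a full frequency-resolved vector.
Sampling stops when Chebyshev's inequality bounds the probability of an
absolute error exceeding `deltaAbs` by `confidence` at every frequency:
`var / (n * deltaAbs^2) <= confidence`, checked batch-wise on running
(Welford/Chan) statistics. Runs that exhaust `maxDraws` first are
flagged `converged = FALSE` rather than silently returned.

Two samplers share this machinery. The continuum sampler above is the
full-scale path (sphere geometries). The discrete sampler draws ordered
pairs from an explicitly placed population — importance-sampled
proportional to the distance-damping factor, which keeps the per-draw
variance insensitive to its huge dynamic range — and estimates exactly
the quantity `ensembleBruteforce()` computes, which is what makes the
oracle-equivalence test in the suite a sharp check: across 100 seeded
runs the estimate must fall within the quoted Chebyshev bound of the
exact double sum at least 99 times.

## Spectral trend, noise floor, and detrending

The aperiodic trend is modelled as two Lorentzian pairs from inhibitory
(GABAR) and excitatory (AMPAR) synaptic kinetics (`evalTrend()`), with
reference parameters `tauI = 4/20` ms, `tauE = 1/3` ms, `AI = 3.6`,
`AE = 3.3`. `fitTrend()` fits in log-power space with equal per-bin
weight on a log-spaced grid (the loss is a package choice), by
Levenberg–Marquardt from deterministic multi-starts; rise < decay is
enforced by parameterization. The excitatory time constants are fixed at
1 and 3 ms by default — they have little leverage provided they are
faster than the inhibitory ones — and can be freed. Measured spectra are
noise-floor corrected first (`subtractNoiseFloor()`, clipping to 1e-12
µV²/Hz with a reported clip count); the reference floor is 1e-3 µV²/Hz.

`detrendSpectrum()` implements three strategies whose difference is the
package's central practical message: *divisive* detrending by
trend-plus-floor artifactually inflates high-frequency rhythm power when
the additive plateau changes between conditions; *subtractive*
correction alone leaves the synaptic filtering in place; the *mixed*
strategy — subtract the additive floor, then divide by the synaptic
trend — leaves rhythm power exactly invariant when only the floor and
trend amplitudes change. The toy model (`toySpectrum()`) demonstrates
this on the spectrum
`P(f) = (1 + alpha(f) + gamma(f) + 1/f^2) Psyn(f) + HFO(f) + noise`.

## The synthetic-data module

Real inputs to this analysis come from compartmental neuron simulations,
a head model, and published EEG; the synthetic module generates
statistical stand-ins with the structure the analysis assumes. Choices
and what they emulate:

* **Kernels** (`makeClassKernel()`): two opposed-polarity Gaussians
  separated by half the period of the class peak frequency (band-pass
  energy spectrum peaking near ~100 Hz, the AP up/downstroke) plus an
  optional slow exponential after-hyperpolarization tail that adds
  low-frequency power. Kernels are deterministic functions of their
  class parameters. What they do *not* emulate: morphology-specific
  waveform detail, channel kinetics, or forward-propagating axonal
  spikes.
* **Populations** (`makePopulation()`): 85% excitatory abundance by
  default; class-type target scalp energies of 0.09 (excitatory) and
  0.02 (inhibitory) pV²·ms, imposed by an explicit calibration step
  (`calibrateKernelBank()`) that rescales kernel amplitudes so
  location-averaged scalp energies hit the targets under the chosen
  geometry and lead field. Energies are defined as `integral |u|^2 dt`
  with time in ms.
* **Traces** (`makeActivePassiveTraces()`): the passive synaptic
  surrogate is coloured noise shaped by the two-timescale trend spectrum
  (the surrogate's spectrum is a package choice, exposed via
  `noiseTrend`); the active trace adds the kernel at Poisson spike
  times, and a voltage surrogate crosses 0 mV exactly at the spike
  peaks so threshold detection recovers ground truth.
* **Spike pairs** (`makeCorrelatedSpikePair()`): a shared mother train
  of rate `lambda * Rmax` copied into both trains with independent
  jitter of sd `sigmaT / sqrt(2)` each — so the *relative* jitter has sd
  `sigmaT`, matching the correlogram's semantics — plus independent
  complements. With `f0 > 0` the shared events are drawn from a
  sinusoidally modulated rate, which approximates (not exactly
  reproduces) the damped-cosine correlogram.
* **Toy spectra** (`ToyModelParams()`): rhythm peaks at 10 Hz
  (amplitude 5, width 1.5 Hz) and 40 Hz (amplitude 2, width 5 Hz); the
  additive plateau defaults to 1e-5 µV²/Hz, chosen so that both rhythm
  peaks ride visibly above the plateau while the plateau still dominates
  the spectrum above 200 Hz — the regime the detrending comparison is
  about; the optional HFO peak sits at 250 Hz. The
  ~2.5-fold excitation:inhibition reduction in the comparison condition
  is applied directly as `AE -> AE / 2.5` (no mechanistic E:I knob is
  modelled).

Because every generator is a pure function of parameters and a seed,
passing tests demonstrate internal consistency of the framework — that
the estimators recover what the generators put in, and that simulation
and closed forms agree — not that real cortical neurons have these
kernels or rates.

## Problem sizes and numerical choices

The test suite runs on deliberately small problems: a 50-neuron
spherical patch (radius 8 mm, dense enough that neighbours fall within
`sigmaX`) for ensemble checks; 60-second synthetic recordings at 0.5 ms
sampling for the firing-rate regression; 200-bin log-spaced grids for
trend fits; Fibonacci lattices of 64 locations × 4 azimuths for
location averaging (deterministic, so calibration and evaluation agree
exactly). Brain-scale constants (`N = 16e9` neurons, noise floor 1e-3
µV²/Hz) enter only through closed-form scalings, never through
brute-force enumeration. Degenerate inputs are handled explicitly:
zero-jitter synchrony is treated spectrally (the correlogram is a
delta), coordinates with zero spread contribute nothing to the
asymmetry index (0/0 -> 0), sub-floor spectral bins are clipped and
counted, and Monte Carlo runs that hit their draw cap are flagged.

## Morphometry

The dendrite asymmetry index summarizes how far a volume-weighted
dendritic centroid lies from the soma, normalized coordinate-wise by the
midpoint spread (`asymmetryIndex()`; SWC files load via
`readSwcMorphology()`, soma-centred, with truncated-cone segment
volumes). The index is unitless up to an arbitrary overall scale; no
normalization beyond the coordinate spread is applied. The synthetic
link between morphology and signal strength —
`morphologyDipoleAmplitude()`, kernel amplitude proportional to the
volume-weighted centroid offset — is the mechanism by which the package
reproduces the positive rank correlation between asymmetry and unitary
scalp energy; it is a surrogate for, not a model of, dendritic return
currents.

## Known limitations

* The AP–synaptic cross-spectrum is assumed null; only back-propagating
  (somatodendritic) AP currents are represented.
* The default lead field ignores skull/scalp conductivity layering;
  absolute scalp magnitudes should be read as order-of-magnitude under
  the analytic surrogate, which is why the calibration targets are
  imposed rather than derived.
* `pairDistanceDensity()` uses Euclidean (not geodesic) balls.
* The rhythmic spike-pair generator approximates the damped-cosine
  correlogram by rate modulation; its bridge to the closed form is
  quantitative only in the aperiodic case.
* Multitaper estimation and time-frequency analysis are out of scope;
  the PSD estimator is Welch with a Hann window and 50% overlap, with
  the segment length as the main user-facing resolution knob (default
  2 s).
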