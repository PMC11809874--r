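#' @import methods
NULL

## Unit tags used throughout the package. Positions are mm, dipole moments
## nA.um, scalp potentials uV (1 uV = 1e6 pV), time in ms, frequency in Hz.
UNIT_POWER_UV2 <- "uV^2/Hz"
UNIT_ENERGY_PV2MS <- "pV^2*ms/Hz"
UNIT_ENERGY_DIPOLE <- "(nA*um)^2*ms/Hz"

## Energy densities are stored in unit^2*ms/Hz; spike-train spectra are in Hz
## (1/s). Their product needs ms -> s at exactly one site: this constant.
MS_TO_S <- 1e-3
## pV^2*ms -> uV^2*s for ensemble assembly (pV^2 -> uV^2 is 1e-12).
PV2MS_TO_UV2S <- 1e-15

#' Spectrum: a density on a frequency grid
#'
#' The shared spectral container. A `Spectrum` couples a strictly increasing,
#' non-negative frequency grid (Hz) to density values, together with a unit
#' string and a `kind` declaring how the values must be interpreted:
#' \describe{
#'   \item{`"power"`}{one-sided power spectral density, real and non-negative
#'     (e.g. uV^2/Hz).}
#'   \item{`"energy"`}{one-sided energy spectral density of a finite-duration
#'     kernel; integrating over frequency returns the kernel energy
#'     `sum(|u(t)|^2 dt)` with `dt` in ms.}
#'   \item{`"cross"`}{a cross-spectral density, possibly complex.}
#' }
#'
#' @slot freqs numeric, strictly increasing, >= 0 (Hz).
#' @slot values numeric or complex densities, same length as `freqs`.
#' @slot units character unit tag.
#' @slot kind one of `"power"`, `"energy"`, `"cross"`.
#' @export
setClass("Spectrum",
  representation(freqs = "numeric", values = "ANY",
                 units = "character", kind = "character"))

setValidity("Spectrum", function(object) {
  msg <- character()
  f <- object@freqs
  v <- object@values
  if (length(f) != length(v))
    msg <- c(msg, "freqs and values must have equal length")
  if (length(f) > 0 && any(f < 0))
    msg <- c(msg, "frequencies must be non-negative")
  if (length(f) > 1 && any(diff(f) <= 0))
    msg <- c(msg, "frequency grid must be strictly increasing")
  if (!object@kind %in% c("power", "energy", "cross"))
    msg <- c(msg, "kind must be one of 'power', 'energy', 'cross'")
  if (object@kind %in% c("power", "energy")) {
    if (is.complex(v))
      msg <- c(msg, "power/energy spectra must be real-valued")
    else if (length(v) > 0 && any(v < -1e-12 * max(abs(v), 1)))
      msg <- c(msg, "power/energy spectra must be non-negative")
  }
  if (length(msg)) msg else TRUE
})

#' @param freqs,values,units,kind see the class slots.
#' @rdname Spectrum-class
#' @export
Spectrum <- function(freqs, values, units = UNIT_POWER_UV2, kind = "power") {
  new("Spectrum", freqs = as.numeric(freqs), values = values,
      units = units, kind = kind)
}

#' TimeSeries: uniformly sampled signal, possibly multi-channel
#'
#' Samples are stored as a T x C matrix (one column per channel; a dipole
#' trace uses columns x, y, z). `dt` is the sampling interval in ms.
#'
#' @slot dt sampling interval (ms), > 0.
#' @slot samples numeric matrix, T rows x C channels.
#' @export
setClass("TimeSeries",
  representation(dt = "numeric", samples = "matrix"))

setValidity("TimeSeries", function(object) {
  msg <- character()
  if (length(object@dt) != 1 || !is.finite(object@dt) || object@dt <= 0)
    msg <- c(msg, "dt must be a single positive number (ms)")
  if (!is.numeric(object@samples))
    msg <- c(msg, "samples must be numeric")
  if (length(msg)) msg else TRUE
})

#' @param samples numeric vector or T x C matrix.
#' @param dt sampling interval in ms.
#' @rdname TimeSeries-class
#' @export
TimeSeries <- function(samples, dt) {
  if (is.null(dim(samples))) samples <- matrix(samples, ncol = 1)
  new("TimeSeries", dt = dt, samples = samples)
}

#' UnitaryKernel: the dipole impulse response of one action potential
#'
#' A 3 x T matrix holding the x, y, z components of the transient added to a
#' neuron's current dipole by a single spike (nA.um), sampled at `dt` ms, on
#' a window `(pre, post)` ms around the spike peak.
#'
#' @slot dt sampling interval (ms).
#' @slot waveform 3 x T numeric matrix (nA.um).
#' @slot window numeric length 2, (pre, post) in ms, pre <= 0 <= post.
#' @slot classLabel character neuron-class label.
#' @slot units character, dipole units.
#' @export
setClass("UnitaryKernel",
  representation(dt = "numeric", waveform = "matrix", window = "numeric",
                 classLabel = "character", units = "character"))

setValidity("UnitaryKernel", function(object) {
  msg <- character()
  if (object@dt <= 0) msg <- c(msg, "dt must be positive")
  if (nrow(object@waveform) != 3)
    msg <- c(msg, "waveform must have 3 rows (dipole x,y,z)")
  if (ncol(object@waveform) < 1) msg <- c(msg, "waveform must be non-empty")
  if (length(object@window) != 2 || object@window[1] > object@window[2])
    msg <- c(msg, "window must be (pre, post) with pre <= post")
  span <- (ncol(object@waveform) - 1) * object@dt
  if (diff(object@window) - span > object@dt + 1e-9)
    msg <- c(msg, "window must cover the waveform support")
  if (length(msg)) msg else TRUE
})

#' @param waveform 3 x T matrix; @param dt ms; @param window (pre, post) ms;
#' @param classLabel label; @param units dipole unit string.
#' @rdname UnitaryKernel-class
#' @export
UnitaryKernel <- function(waveform, dt, window = NULL,
                          classLabel = "unlabelled", units = "nA*um") {
  if (is.null(dim(waveform))) waveform <- matrix(waveform, nrow = 3,
                                                 ncol = length(waveform) / 3)
  if (is.null(window)) window <- c(0, (ncol(waveform) - 1) * dt)
  new("UnitaryKernel", dt = dt, waveform = waveform, window = window,
      classLabel = classLabel, units = units)
}

#' SynchronyParams: the pairwise spike cross-correlogram model
#'
#' Parameterizes the distance-dependent, Gaussian-jittered (optionally
#' rhythmic) spike-train cross-correlogram used for ensemble apEEG
#' assembly. The correlogram between neurons separated by `d` mm is
#' `lambda * Rmax / sqrt(2 pi sigmaT^2) * exp(-d^2 / 2 sigmaX^2) *
#' exp(-tau^2 / 2 sigmaT^2) * cos(2 pi f0 tau)`; `f0 = 0` gives the
#' aperiodic model.
#'
#' @slot lambda mean firing rate (Hz).
#' @slot rmax maximal pairwise correlation, in [0, 1].
#' @slot sigmaX spatial decay scale of synchrony (mm), > 0.
#' @slot sigmaT spike-time jitter scale (ms), >= 0.
#' @slot f0 rhythm frequency (Hz); 0 means aperiodic.
#' @export
setClass("SynchronyParams",
  representation(lambda = "numeric", rmax = "numeric", sigmaX = "numeric",
                 sigmaT = "numeric", f0 = "numeric"))

setValidity("SynchronyParams", function(object) {
  msg <- character()
  if (object@lambda < 0) msg <- c(msg, "lambda must be >= 0")
  if (object@rmax < 0 || object@rmax > 1)
    msg <- c(msg, "rmax must lie in [0, 1]")
  if (object@sigmaX <= 0) msg <- c(msg, "sigmaX must be > 0")
  if (object@sigmaT < 0) msg <- c(msg, "sigmaT must be >= 0")
  if (object@f0 < 0) msg <- c(msg, "f0 must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @param lambda,rmax,sigmaX,sigmaT,f0 see slots.
#' @rdname SynchronyParams-class
#' @export
SynchronyParams <- function(lambda = 1, rmax = 0.2, sigmaX = sqrt(3),
                            sigmaT = 11.3, f0 = 0) {
  new("SynchronyParams", lambda = lambda, rmax = rmax, sigmaX = sigmaX,
      sigmaT = sigmaT, f0 = f0)
}

#' TrendParams: double-Lorentzian aperiodic spectral trend
#'
#' The aperiodic EEG trend is modelled as the sum of two Lorentzian pairs,
#' one from inhibitory (GABAR) and one from excitatory (AMPAR) synaptic
#' kinetics, each with a rise and a decay time constant (seconds):
#' `S(f) = AI (tI1 - tI2)^2 / [(1 + (2 pi f tI1)^2)(1 + (2 pi f tI2)^2)] +
#'  AE (tE1 - tE2)^2 / [(1 + (2 pi f tE1)^2)(1 + (2 pi f tE2)^2)]`.
#' A frequency-independent instrument/EMG noise floor (uV^2/Hz) rides on
#' top of the trend in measured spectra.
#'
#' @slot tauI1,tauI2 inhibitory rise/decay time constants (s), rise < decay.
#' @slot tauE1,tauE2 excitatory rise/decay time constants (s), rise < decay.
#' @slot ampI,ampE unitless amplitude scales, >= 0.
#' @slot floor noise-floor density (uV^2/Hz), >= 0.
#' @export
setClass("TrendParams",
  representation(tauI1 = "numeric", tauI2 = "numeric",
                 tauE1 = "numeric", tauE2 = "numeric",
                 ampI = "numeric", ampE = "numeric", floor = "numeric"))

setValidity("TrendParams", function(object) {
  msg <- character()
  taus <- c(object@tauI1, object@tauI2, object@tauE1, object@tauE2)
  if (any(taus <= 0)) msg <- c(msg, "all time constants must be > 0")
  if (object@tauI1 >= object@tauI2)
    msg <- c(msg, "inhibitory rise must be faster than decay (tauI1 < tauI2)")
  if (object@tauE1 >= object@tauE2)
    msg <- c(msg, "excitatory rise must be faster than decay (tauE1 < tauE2)")
  if (object@ampI < 0 || object@ampE < 0)
    msg <- c(msg, "amplitudes must be >= 0")
  if (object@floor < 0) msg <- c(msg, "floor must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @param tauI1,tauI2,tauE1,tauE2 time constants in seconds.
#' @param ampI,ampE amplitude scales.
#' @param floor noise floor (uV^2/Hz).
#' @rdname TrendParams-class
#' @export
TrendParams <- function(tauI1 = 0.004, tauI2 = 0.020,
                        tauE1 = 0.001, tauE2 = 0.003,
                        ampI = 3.6, ampE = 3.3, floor = 0) {
  new("TrendParams", tauI1 = tauI1, tauI2 = tauI2, tauE1 = tauE1,
      tauE2 = tauE2, ampI = ampI, ampE = ampE, floor = floor)
}

#' Morphology: cone-segment representation of a dendritic arbour
#'
#' Each dendritic segment is a truncated cone summarized by its midpoint
#' (um, relative to the soma at the origin) and its volume
#' `V = (1/3) pi L (r1^2 + r1 r2 + r2^2)` (um^3).
#'
#' @slot midpoints N x 3 numeric matrix (um).
#' @slot volumes numeric length N (um^3), >= 0.
#' @export
setClass("Morphology",
  representation(midpoints = "matrix", volumes = "numeric"))

setValidity("Morphology", function(object) {
  msg <- character()
  if (ncol(object@midpoints) != 3)
    msg <- c(msg, "midpoints must be an N x 3 matrix")
  if (nrow(object@midpoints) != length(object@volumes))
    msg <- c(msg, "midpoints and volumes must agree in length")
  if (any(object@volumes < 0)) msg <- c(msg, "volumes must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @param midpoints N x 3 matrix (um); @param volumes length-N vector (um^3).
#' @rdname Morphology-class
#' @export
Morphology <- function(midpoints, volumes) {
  new("Morphology", midpoints = as.matrix(midpoints),
      volumes = as.numeric(volumes))
}

#' LeadField: map from a dipole source to a scalp potential
#'
#' Wraps an evaluator `function(position)` returning the 3-vector nu (uV per
#' nA.um) such that a dipole moment p (nA.um) at `position` (mm) produces
#' the potential `sum(nu * p)` uV at the electrode.
#'
#' @slot evaluator function(position) -> numeric(3).
#' @slot provenance one of "analytic-infinite-medium", "analytic-sphere",
#'   "file".
#' @export
setClass("LeadField",
  representation(evaluator = "function", provenance = "character"))

#' @param evaluator,provenance see slots.
#' @rdname LeadField-class
#' @export
LeadField <- function(evaluator, provenance = "analytic-infinite-medium") {
  new("LeadField", evaluator = evaluator, provenance = provenance)
}

#' CortexGeometry: the source surface neurons live on
#'
#' Either an analytic sphere (radius mm) or a triangle mesh (vertices mm,
#' 1-based faces). Carries the areal neuron density and the implied total
#' neuron count `nNeurons = density * area`.
#'
#' @slot type "sphere" or "mesh".
#' @slot radius sphere radius (mm); NA for meshes.
#' @slot vertices V x 3 matrix (mm); empty for spheres.
#' @slot faces F x 3 integer matrix; empty for spheres.
#' @slot density areal neuron density (neurons/mm^2).
#' @slot nNeurons total neuron count.
#' @export
setClass("CortexGeometry",
  representation(type = "character", radius = "numeric",
                 vertices = "matrix", faces = "matrix",
                 density = "numeric", nNeurons = "numeric"))

setValidity("CortexGeometry", function(object) {
  msg <- character()
  if (!object@type %in% c("sphere", "mesh"))
    msg <- c(msg, "type must be 'sphere' or 'mesh'")
  if (object@density < 0) msg <- c(msg, "density must be >= 0")
  if (object@type == "sphere" && (is.na(object@radius) || object@radius <= 0))
    msg <- c(msg, "sphere radius must be positive")
  if (object@type == "mesh" && nrow(object@vertices) < 3)
    msg <- c(msg, "mesh must have at least 3 vertices")
  if (length(msg)) msg else TRUE
})

#' PairDensity: density of neuron pairs over separation distance
#'
#' `values[k]` is dN(r_k): the expected number of neighbours per unit
#' distance (1/mm) at Euclidean separation `radii[k]` from a source,
#' i.e. the derivative of areal-density times ball-restricted surface
#' area. Integrates to (nNeurons - 1) per source.
#'
#' @slot radii increasing grid of separations (mm), starting at 0.
#' @slot values dN(r) (1/mm), >= 0.
#' @export
setClass("PairDensity",
  representation(radii = "numeric", values = "numeric"))

setValidity("PairDensity", function(object) {
  msg <- character()
  if (length(object@radii) != length(object@values))
    msg <- c(msg, "radii and values must agree in length")
  if (length(object@radii) > 1 && any(diff(object@radii) <= 0))
    msg <- c(msg, "radii must be strictly increasing")
  if (any(object@values < 0)) msg <- c(msg, "dN(r) must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @param radii,values see slots.
#' @rdname PairDensity-class
#' @export
PairDensity <- function(radii, values) {
  new("PairDensity", radii = as.numeric(radii), values = as.numeric(values))
}

#' MCConfig: Monte Carlo error target and stopping rule
#'
#' The pair-term integrator stops, per Chebyshev's inequality, once the
#' running sample variance satisfies `var / (n * deltaAbs^2) <= confidence`,
#' guaranteeing the estimate is within `deltaAbs` of the mean with
#' probability at least `1 - confidence`.
#'
#' @slot deltaAbs absolute error target (uV^2/Hz), > 0.
#' @slot confidence tail probability bound, in (0, 1).
#' @slot batchSize draws between stopping checks.
#' @slot maxDraws hard cap on draws.
#' @export
setClass("MCConfig",
  representation(deltaAbs = "numeric", confidence = "numeric",
                 batchSize = "numeric", maxDraws = "numeric"))

setValidity("MCConfig", function(object) {
  msg <- character()
  if (object@deltaAbs <= 0) msg <- c(msg, "deltaAbs must be > 0")
  if (object@confidence <= 0 || object@confidence >= 1)
    msg <- c(msg, "confidence must lie in (0, 1)")
  if (object@batchSize < 1) msg <- c(msg, "batchSize must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @param deltaAbs,confidence,batchSize,maxDraws see slots.
#' @rdname MCConfig-class
#' @export
MCConfig <- function(deltaAbs, confidence = 0.01, batchSize = 1e4,
                     maxDraws = 1e7) {
  new("MCConfig", deltaAbs = deltaAbs, confidence = confidence,
      batchSize = batchSize, maxDraws = maxDraws)
}

#' NeuronClassSpec: synthetic stand-in for one neuron morphology class
#'
#' Describes the unitary-kernel generator for a class: band-pass peak
#' frequency, dipole amplitude, after-hyperpolarization (AHP) tail, and
#' the class's relative abundance in the population.
#'
#' @slot name class label.
#' @slot excitatory logical flag.
#' @slot abundance population weight, >= 0.
#' @slot kernelParams list with elements `peakFreq` (Hz), `amplitude`
#'   (nA.um), `shapeRatio` (down/upstroke amplitude ratio), `ahpAmplitude`
#'   (nA.um), `ahpDecay` (ms, > 0), `orientation` (3-vector mixing the
#'   dipole components; normalized on use).
#' @slot targetEnergy target location-averaged scalp energy (pV^2*ms);
#'   NA disables calibration for the class.
#' @export
setClass("NeuronClassSpec",
  representation(name = "character", excitatory = "logical",
                 abundance = "numeric", kernelParams = "list",
                 targetEnergy = "numeric"))

setValidity("NeuronClassSpec", function(object) {
  msg <- character()
  if (object@abundance < 0) msg <- c(msg, "abundance must be >= 0")
  kp <- object@kernelParams
  if (!is.null(kp$amplitude) && kp$amplitude <= 0)
    msg <- c(msg, "kernel amplitude must be positive")
  if (!is.null(kp$ahpDecay) && kp$ahpDecay <= 0)
    msg <- c(msg, "AHP decay must be > 0")
  if (length(msg)) msg else TRUE
})

#' @param name,excitatory,abundance,kernelParams,targetEnergy see slots.
#' @rdname NeuronClassSpec-class
#' @export
NeuronClassSpec <- function(name, excitatory = TRUE, abundance = 1,
                            kernelParams = list(), targetEnergy = NA_real_) {
  kp <- utils::modifyList(list(peakFreq = 100, amplitude = 1,
                               shapeRatio = 0.8, ahpAmplitude = 0,
                               ahpDecay = 80,
                               orientation = c(0.25, 0.25, 1)),
                          kernelParams)
  new("NeuronClassSpec", name = name, excitatory = excitatory,
      abundance = abundance, kernelParams = kp,
      targetEnergy = targetEnergy)
}

#' ToyModelParams: parameters of the detrending toy spectrum
#'
#' The toy EEG spectrum is
#' `P(f) = (1 + sum of Gaussian peaks + 1/f^2) * Psyn(f) + HFO(f) + noise`
#' where `Psyn` is a double-Lorentzian trend, the Gaussian peaks model
#' rhythms multiplicative in the synaptic filter, the optional additive
#' HFO peak models an AP-generated high-frequency oscillation, and
#' `noise` is a constant EMG/amplifier plateau.
#'
#' @slot peaks data.frame with columns center (Hz), width (Hz),
#'   amplitude (x trend).
#' @slot trend [TrendParams-class] for Psyn.
#' @slot noise additive plateau (uV^2/Hz), >= 0.
#' @slot hfoCenter,hfoWidth,hfoAmplitude additive HFO Gaussian
#'   (uV^2/Hz peak amplitude); `hfoCenter = NA` disables it.
#' @export
setClass("ToyModelParams",
  representation(peaks = "data.frame", trend = "TrendParams",
                 noise = "numeric", hfoCenter = "numeric",
                 hfoWidth = "numeric", hfoAmplitude = "numeric"))

setValidity("ToyModelParams", function(object) {
  msg <- character()
  p <- object@peaks
  if (nrow(p) > 0) {
    if (any(p$center <= 0)) msg <- c(msg, "peak centers must be > 0")
    if (any(p$amplitude < 0)) msg <- c(msg, "peak amplitudes must be >= 0")
  }
  if (object@noise < 0) msg <- c(msg, "noise must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @param peaks,trend,noise,hfoCenter,hfoWidth,hfoAmplitude see slots.
#' @rdname ToyModelParams-class
#' @export
ToyModelParams <- function(peaks = data.frame(center = c(10, 40),
                                              width = c(1.5, 5),
                                              amplitude = c(5, 2)),
                           trend = TrendParams(),
                           noise = 1e-5,
                           hfoCenter = NA_real_, hfoWidth = 10,
                           hfoAmplitude = 5e-5) {
  new("ToyModelParams", peaks = peaks, trend = trend, noise = noise,
      hfoCenter = hfoCenter, hfoWidth = hfoWidth,
      hfoAmplitude = hfoAmplitude)
}

#' MeanUnitarySpectrum: population-averaged unitary scalp energy spectrum
#'
#' A [Spectrum-class] (energy kind, pV^2*ms/Hz) averaged over neuron
#' classes and cortical locations with abundance weights, plus the
#' per-class breakdown and per-class integrated energies.
#'
#' @slot perClass named list of per-class [Spectrum-class] objects.
#' @slot weights abundance weights (sum to 1).
#' @slot classEnergies integrated scalp energies per class (pV^2*ms).
#' @export
setClass("MeanUnitarySpectrum", contains = "Spectrum",
  representation(perClass = "list", weights = "numeric",
                 classEnergies = "numeric"))

#' LinearFitResult: fitted linear AP spectral model
#'
#' @slot beta fitted scaling factor (spikes/s).
#' @slot rSquared goodness of fit, <= 1.
#' @slot residual residual [Spectrum-class] over the fit band.
#' @export
setClass("LinearFitResult",
  representation(beta = "numeric", rSquared = "numeric",
                 residual = "Spectrum"))

setValidity("LinearFitResult", function(object) {
  msg <- character()
  if (!is.finite(object@beta)) msg <- c(msg, "beta must be finite")
  if (is.finite(object@rSquared) && object@rSquared > 1 + 1e-12)
    msg <- c(msg, "rSquared must be <= 1")
  if (length(msg)) msg else TRUE
})

## ---- show methods -------------------------------------------------------

setMethod("show", "Spectrum", function(object) {
  f <- object@freqs
  cat(sprintf("Spectrum (%s): %d bins, %.4g-%.4g Hz [%s]\n",
              object@kind, length(f),
              if (length(f)) min(f) else NA, if (length(f)) max(f) else NA,
              object@units))
})

setMethod("show", "TimeSeries", function(object) {
  cat(sprintf("TimeSeries: %d samples x %d channel(s), dt = %g ms (%.3g s)\n",
              nrow(object@samples), ncol(object@samples), object@dt,
              nrow(object@samples) * object@dt / 1000))
})

setMethod("show", "UnitaryKernel", function(object) {
  cat(sprintf(
    "UnitaryKernel '%s': 3 x %d @ dt = %g ms, window (%g, %g) ms [%s]\n",
    object@classLabel, ncol(object@waveform), object@dt,
    object@window[1], object@window[2], object@units))
})

setMethod("show", "SynchronyParams", function(object) {
  cat(sprintf(
    "SynchronyParams: lambda = %g Hz, Rmax = %g, sigmaX = %g mm, sigmaT = %g ms, f0 = %g Hz\n",
    object@lambda, object@rmax, object@sigmaX, object@sigmaT, object@f0))
})

setMethod("show", "TrendParams", function(object) {
  cat(sprintf(
    "TrendParams: tauI = (%g, %g) ms, tauE = (%g, %g) ms, AI = %g, AE = %g, floor = %g uV^2/Hz\n",
    1e3 * object@tauI1, 1e3 * object@tauI2, 1e3 * object@tauE1,
    1e3 * object@tauE2, object@ampI, object@ampE, object@floor))
})

setMethod("show", "Morphology", function(object) {
  cat(sprintf("Morphology: %d cone segments, total volume %.4g um^3\n",
              length(object@volumes), sum(object@volumes)))
})

setMethod("show", "CortexGeometry", function(object) {
  if (object@type == "sphere")
    cat(sprintf("CortexGeometry: sphere R = %g mm, %.3g neurons (%.3g /mm^2)\n",
                object@radius, object@nNeurons, object@density))
  else
    cat(sprintf("CortexGeometry: mesh, %d vertices / %d faces, %.3g neurons\n",
                nrow(object@vertices), nrow(object@faces), object@nNeurons))
})

setMethod("show", "MeanUnitarySpectrum", function(object) {
  cat(sprintf(
    "MeanUnitarySpectrum: %d classes, weighted mean energy %.4g pV^2*ms\n",
    length(object@perClass), sum(object@weights * object@classEnergies)))
})

setMethod("show", "LinearFitResult", function(object) {
  cat(sprintf("LinearFitResult: beta = %.4g spikes/s, R^2 = %.4f\n",
              object@beta, object@rSquared))
})
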