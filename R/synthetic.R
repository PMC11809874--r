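## Synthetic stand-ins for the inputs the real analysis takes from
## compartmental simulation, head models and published EEG: unitary AP
## kernels, excitatory/inhibitory populations, cone-segment morphologies,
## active/passive dipole traces, correlated spike pairs, and trend-shaped
## EEG spectra. Every generator is a pure function of (parameters, seed).

#' Generate a unitary AP kernel for one neuron class
#'
#' The dipole impulse response is modelled, per component, as two
#' opposed-polarity Gaussians (the AP up- and downstroke, separated by
#' half the period of the class peak frequency, giving a band-pass energy
#' spectrum peaked near `peakFreq`) plus an optional slow negative
#' exponential tail (after-hyperpolarization, AHP) that adds
#' low-frequency power. The 3 components share the temporal shape and are
#' mixed by the class orientation vector (apical-basal axis along z).
#'
#' @param class a [NeuronClassSpec-class].
#' @param dt sampling interval (ms).
#' @param window (pre, post) support in ms.
#' @return a [UnitaryKernel-class] (dipole units nA.um).
#' @export
makeClassKernel <- function(class, dt = 0.1, window = c(-10, 150)) {
  stopifnot(is(class, "NeuronClassSpec"))
  kp <- class@kernelParams
  if (kp$amplitude <= 0) stop("kernel amplitude must be positive")
  tms <- seq(window[1], window[2], by = dt)
  delta <- 500 / kp$peakFreq            # ms between up and downstroke
  s <- delta / 5
  up <- exp(-(tms + delta / 2)^2 / (2 * s^2))
  down <- exp(-(tms - delta / 2)^2 / (2 * s^2))
  shape <- kp$amplitude * (up - kp$shapeRatio * down)
  if (kp$ahpAmplitude > 0) {
    tail <- ifelse(tms > 0,
                   (1 - exp(-tms / 2)) * exp(-tms / kp$ahpDecay), 0)
    shape <- shape - kp$ahpAmplitude * tail
  }
  o <- kp$orientation / sqrt(sum(kp$orientation^2))
  UnitaryKernel(waveform = o %o% shape, dt = dt, window = window,
                classLabel = class@name)
}

#' Generate a kernel bank for a population
#'
#' One [UnitaryKernel-class] per class. Kernels are deterministic
#' functions of the class specifications; the seed argument is accepted
#' for interface uniformity with the other generators but has no effect.
#'
#' @param classes list of [NeuronClassSpec-class] objects (>= 1).
#' @param seed unused (kernels are parameter-deterministic).
#' @param dt,window forwarded to [makeClassKernel()].
#' @return named list of [UnitaryKernel-class] objects.
#' @export
makeKernelBank <- function(classes, seed = 1, dt = 0.1,
                           window = c(-10, 150)) {
  if (length(classes) < 1) stop("at least one neuron class is required")
  bank <- lapply(classes, makeClassKernel, dt = dt, window = window)
  names(bank) <- vapply(classes, function(cl) cl@name, "")
  bank
}

#' Generate an excitatory/inhibitory population table
#'
#' Class abundances are drawn (seeded) and normalized so that the
#' excitatory classes sum exactly to `excFraction` (cortical default
#' 0.85) and the inhibitory classes to the remainder. Excitatory classes
#' default to larger dipole amplitudes and occasional AHP tails;
#' per-class target scalp energies default to the class-type means
#' (0.09 pV^2*ms excitatory, 0.02 inhibitory).
#'
#' @param excFraction excitatory abundance fraction, in [0, 1].
#' @param nClasses number of classes.
#' @param seed RNG seed.
#' @return data.frame with columns name, excitatory, abundance, peakFreq,
#'   amplitude, shapeRatio, ahpAmplitude, ahpDecay, targetEnergy.
#' @export
makePopulation <- function(excFraction = 0.85, nClasses = 6, seed = 1) {
  if (excFraction < 0 || excFraction > 1)
    stop("excFraction must lie in [0, 1]")
  set.seed(seed)
  nExc <- if (excFraction == 0) 0L
  else if (excFraction == 1) nClasses
  else max(1L, min(nClasses - 1L, round(nClasses * 0.6)))
  exc <- c(rep(TRUE, nExc), rep(FALSE, nClasses - nExc))
  w <- stats::runif(nClasses, 0.5, 1.5)
  ab <- numeric(nClasses)
  if (any(exc)) ab[exc] <- excFraction * w[exc] / sum(w[exc])
  if (any(!exc)) ab[!exc] <- (1 - excFraction) * w[!exc] / sum(w[!exc])
  data.frame(
    name = sprintf("%s%02d", ifelse(exc, "E", "I"), seq_len(nClasses)),
    excitatory = exc,
    abundance = ab,
    peakFreq = stats::runif(nClasses, 80, 120),
    amplitude = ifelse(exc, stats::runif(nClasses, 0.8, 1.2),
                       stats::runif(nClasses, 0.4, 0.6)),
    shapeRatio = stats::runif(nClasses, 0.7, 0.9),
    ahpAmplitude = ifelse(stats::runif(nClasses) < 0.3, 0.05, 0),
    ahpDecay = stats::runif(nClasses, 50, 150),
    targetEnergy = ifelse(exc, 0.09, 0.02))
}

#' Turn a population table into NeuronClassSpec objects
#' @param population a data.frame from [makePopulation()].
#' @return list of [NeuronClassSpec-class].
#' @export
populationClasses <- function(population) {
  lapply(seq_len(nrow(population)), function(i) {
    r <- population[i, ]
    NeuronClassSpec(
      name = as.character(r$name), excitatory = r$excitatory,
      abundance = r$abundance,
      kernelParams = list(peakFreq = r$peakFreq, amplitude = r$amplitude,
                          shapeRatio = r$shapeRatio,
                          ahpAmplitude = r$ahpAmplitude,
                          ahpDecay = r$ahpDecay),
      targetEnergy = r$targetEnergy)
  })
}

#' Generate a cone-segment morphology with controlled asymmetry
#'
#' Builds a point-symmetric set of equal-volume segments (asymmetry index
#' exactly 0) and then translates all midpoints by `asymmetry` um along
#' z, so the index grows strictly with the requested offset.
#'
#' @param asymmetry centroid offset along z (um), >= 0.
#' @param nSegments number of segments, >= 2.
#' @param seed RNG seed.
#' @param spread isotropic midpoint scale (um).
#' @return a [Morphology-class].
#' @export
makeMorphology <- function(asymmetry = 0, nSegments = 40, seed = 1,
                           spread = 50) {
  if (nSegments < 2)
    stop("nSegments must be >= 2 (the asymmetry index needs N >= 2)")
  set.seed(seed)
  half <- floor(nSegments / 2)
  pts <- matrix(stats::rnorm(3 * half, sd = spread), ncol = 3)
  mid <- rbind(pts, -pts)
  if (nSegments %% 2 == 1) mid <- rbind(mid, c(0, 0, 0))
  mid[, 3] <- mid[, 3] + asymmetry
  Morphology(midpoints = mid, volumes = rep(10, nrow(mid)))
}

## Two-timescale coloured noise surrogate for the synaptic dipole: white
## noise shaped in the frequency domain by the square root of a
## double-Lorentzian spectrum.
colouredNoise <- function(n, dt, sd, trend) {
  if (sd <= 0) return(numeric(n))
  fs <- 1000 / dt
  j <- 0:(n - 1)
  fmir <- pmin(j, n - j) * fs / n       # mirrored grid keeps FFT Hermitian
  shape <- evalTrend(trend, fmir)
  shape <- shape / max(shape)
  w <- stats::fft(stats::rnorm(n))
  x <- Re(stats::fft(w * sqrt(shape), inverse = TRUE)) / n
  sd * x / stats::sd(x)
}

#' Paired active/passive dipole traces with a known spike train
#'
#' Emulates the active/passive protocol used to isolate AP dipole
#' currents: the passive trace is a coloured-noise synaptic surrogate
#' (two-timescale spectrum); the active trace adds the unitary kernel at
#' Poisson spike times; a somatic-voltage surrogate crosses 0 mV exactly
#' at the spike peaks so that threshold-based spike detection recovers
#' the ground-truth times.
#'
#' @param kernel a [UnitaryKernel-class].
#' @param lambda firing rate (Hz), >= 0.
#' @param duration record length (ms).
#' @param noiseSd synaptic surrogate standard deviation per component
#'   (nA.um); 0 disables noise.
#' @param noiseTrend [TrendParams-class] shaping the surrogate spectrum.
#' @param seed RNG seed.
#' @return list with `active`, `passive` (3-channel [TimeSeries-class]),
#'   `spikes` (ms), `voltage` (1-channel [TimeSeries-class], mV).
#' @export
makeActivePassiveTraces <- function(kernel, lambda, duration,
                                    noiseSd = 0.05,
                                    noiseTrend = TrendParams(),
                                    seed = 1) {
  stopifnot(is(kernel, "UnitaryKernel"), lambda >= 0)
  dt <- kernel@dt
  win <- kernel@window
  if (duration < diff(win) + dt)
    stop(sprintf("duration (%g ms) too short for one kernel window (%g ms)",
                 duration, diff(win)))
  n <- floor(duration / dt)
  set.seed(seed)
  passive <- sapply(1:3, function(k)
    colouredNoise(n, dt, noiseSd, noiseTrend))

  ## admissible spike window keeps every kernel fully inside the record
  lo <- -win[1]; hi <- duration - win[2] - dt
  nspk <- stats::rpois(1, lambda * (duration * MS_TO_S))
  spikes <- sort(stats::runif(nspk, lo, hi))
  spikeIdx <- round(spikes / dt) + 1L
  spikes <- (spikeIdx - 1L) * dt       # snap to the sample grid

  active <- passive
  w <- t(kernel@waveform)              # T x 3
  off <- round(win[1] / dt)
  for (i in spikeIdx) {
    rows <- (i + off):(i + off + nrow(w) - 1L)
    active[rows, ] <- active[rows, ] + w
  }

  volt <- rep(-65, n)
  tgrid <- (seq_len(n) - 1L) * dt
  for (s in spikes) {
    b <- 95 * exp(-(tgrid - s)^2 / (2 * 0.25^2))
    volt <- volt + b
  }
  list(active = TimeSeries(active, dt), passive = TimeSeries(passive, dt),
       spikes = spikes, voltage = TimeSeries(volt, dt))
}

#' Synthetic EEG power spectrum with trend, peaks and noise floor
#'
#' `P(f) = (1 + sum of Gaussian peaks + 1/f^2) * trend(f) + floor`, with
#' optional multiplicative sampling noise (log-normal, coefficient of
#' variation `relNoise`) emulating periodogram scatter.
#'
#' @param trend a [TrendParams-class].
#' @param peaks data.frame(center, width, amplitude); may be empty.
#' @param floor additive noise floor (uV^2/Hz).
#' @param freqsHz frequency grid (Hz), > 0.
#' @param relNoise multiplicative noise CV (0 = noiseless).
#' @param seed RNG seed.
#' @return a [Spectrum-class] (power, uV^2/Hz).
#' @export
makeEegSpectrum <- function(trend, peaks = data.frame(center = numeric(0),
                                                      width = numeric(0),
                                                      amplitude = numeric(0)),
                            floor = 1e-3,
                            freqsHz = exp(seq(log(1), log(500),
                                              length.out = 200)),
                            relNoise = 0, seed = 1) {
  stopifnot(is(trend, "TrendParams"), floor >= 0, all(freqsHz > 0))
  tm <- ToyModelParams(peaks = peaks, trend = trend, noise = floor)
  s <- toySpectrum(tm, freqsHz)
  v <- Re(specValues(s))
  if (relNoise > 0) {
    set.seed(seed)
    sdl <- sqrt(log(1 + relNoise^2))
    v <- v * stats::rlnorm(length(v), -sdl^2 / 2, sdl)
  }
  out <- Spectrum(freqsHz, v, units = UNIT_POWER_UV2, kind = "power")
  attr(out, "components") <- attr(s, "components")
  out
}

#' Pair of Poisson spike trains with controlled synchrony
#'
#' Each train is marginally Poisson(`lambda`): a shared mother train of
#' rate `lambda * rmax` is copied into both trains with independent
#' Gaussian jitter of sd `sigmaT / sqrt(2)` each (so the relative jitter
#' has sd `sigmaT`), and each train adds an independent Poisson
#' complement of rate `lambda * (1 - rmax)`. With `f0 > 0` the shared
#' events are drawn from a sinusoidally modulated rate, which makes the
#' cross-correlogram oscillatory (approximating the damped-cosine model).
#'
#' @param lambda mean rate (Hz).
#' @param rmax shared fraction, in [0, 1].
#' @param sigmaT relative jitter sd (ms).
#' @param f0 rhythm frequency (Hz), 0 for aperiodic.
#' @param duration record length (ms).
#' @param seed RNG seed.
#' @return list(t1, t2): sorted spike times (ms).
#' @export
makeCorrelatedSpikePair <- function(lambda, rmax, sigmaT, f0 = 0,
                                    duration = 1e5, seed = 1) {
  if (rmax < 0 || rmax > 1) stop("rmax must lie in [0, 1]")
  stopifnot(lambda >= 0, duration > 0)
  set.seed(seed)
  Tsec <- duration * MS_TO_S
  nShared <- stats::rpois(1, lambda * rmax * Tsec)
  shared <- stats::runif(nShared, 0, duration)
  if (f0 > 0 && nShared > 0) {
    ## thin a rate 1 + cos(2 pi f0 t) profile (max 2) for phase locking
    keep <- stats::runif(nShared) <
      (1 + cos(2 * pi * f0 * shared * MS_TO_S)) / 2
    extra <- stats::runif(round(1.0 * nShared), 0, duration)
    keepE <- stats::runif(length(extra)) <
      (1 + cos(2 * pi * f0 * extra * MS_TO_S)) / 2
    shared <- c(shared[keep], extra[keepE])
  }
  jit <- sigmaT / sqrt(2)
  t1 <- shared + stats::rnorm(length(shared), sd = jit)
  t2 <- shared + stats::rnorm(length(shared), sd = jit)
  n1 <- stats::rpois(1, lambda * (1 - rmax) * Tsec)
  n2 <- stats::rpois(1, lambda * (1 - rmax) * Tsec)
  t1 <- c(t1, stats::runif(n1, 0, duration))
  t2 <- c(t2, stats::runif(n2, 0, duration))
  list(t1 = sort(t1[t1 >= 0 & t1 <= duration]),
       t2 = sort(t2[t2 >= 0 & t2 <= duration]))
}

#' Surrogate dipole amplitude of a morphology
#'
#' The net dipole generated by an AP scales with the displacement between
#' the somatic current sink and the return currents spread over the
#' dendrites; the surrogate uses the volume-weighted centroid offset of
#' the arbour (um) times a fixed moment per um. Links the morphology
#' generator to the kernel generator, so that more asymmetric synthetic
#' arbours yield stronger unitary responses (as the asymmetry index
#' predicts for real cells).
#'
#' @param m a [Morphology-class].
#' @param momentPerUm dipole moment per um of centroid offset
#'   (nA.um / um).
#' @return kernel amplitude (nA.um).
#' @export
morphologyDipoleAmplitude <- function(m, momentPerUm = 0.02) {
  off <- sqrt(sum(colSums(m@midpoints * m@volumes)^2)) / sum(m@volumes)
  momentPerUm * off
}

#' Calibrate kernel amplitudes to target scalp energies
#'
#' Rescales each class kernel so that its location-averaged scalp energy
#' (over a deterministic Fibonacci lattice of source locations and a
#' fixed azimuth grid) matches the class's `targetEnergy` (pV^2*ms).
#' Calibration is explicit: the returned bank carries the scale factors
#' as an attribute.
#'
#' @param bank named list of [UnitaryKernel-class] (from
#'   [makeKernelBank()]).
#' @param classes list of [NeuronClassSpec-class] with target energies.
#' @param geometry a [CortexGeometry-class].
#' @param leadField a [LeadField-class].
#' @param nLocations locations averaged per class.
#' @param nAzimuths tangent-plane orientations averaged per location.
#' @return calibrated bank; `attr(, "scales")` holds per-class factors.
#' @export
calibrateKernelBank <- function(bank, classes, geometry, leadField,
                                nLocations = 64, nAzimuths = 4) {
  sp <- surfacePoints(geometry, nLocations, method = "fibonacci")
  az <- seq(0, pi, length.out = nAzimuths + 1)[seq_len(nAzimuths)]
  scales <- numeric(length(bank)); names(scales) <- names(bank)
  out <- bank
  for (ci in seq_along(bank)) {
    target <- classes[[ci]]@targetEnergy
    if (!is.finite(target)) { scales[ci] <- 1; next }
    e <- 0
    for (i in seq_len(nLocations))
      for (a in az) {
        fr <- orientationFrame(sp$normals[i, ], a)
        u <- scalpUnitaryResponse(bank[[ci]], sp$points[i, ], fr, leadField)
        e <- e + sum(u@samples^2) * u@dt
      }
    e <- e / (nLocations * nAzimuths)
    if (e <= 0) stop("class '", names(bank)[ci],
                     "' produces zero scalp energy; cannot calibrate")
    scales[ci] <- sqrt(target / e)
    k <- bank[[ci]]
    out[[ci]] <- UnitaryKernel(k@waveform * scales[ci], k@dt, k@window,
                               k@classLabel, k@units)
  }
  attr(out, "scales") <- scales
  out
}
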