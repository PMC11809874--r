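## Ensemble apEEG assembly. The AP contribution to the scalp power
## spectrum decomposes into a diagonal (auto) term, lambda * N * mean
## unitary scalp energy spectrum, and an off-diagonal (pair) term driven
## by the spike-synchrony cross-spectrum. The pair term is computed
## either exactly (double sum over a placed population) or by Monte Carlo
## integration over the pair-distance density with Chebyshev stopping.
##
## Unit flow: kernels nA.um -> lead field uV -> scalp transfer u_hat in
## uV*s; spike spectra in Hz; products are uV^2/Hz. One-sided spectra
## (factor 2 at f > 0) throughout, matching the spectra module.

#' Scalp response of one unitary kernel at one cortical site
#'
#' Rotates the kernel into the head frame and projects it through the
#' lead field: `u(t) = nu(x)^T B w(t)`, reported in pV.
#'
#' @param kernel a [UnitaryKernel-class] (nA.um).
#' @param position source position (mm).
#' @param frame 3 x 3 orientation frame (columns t1, t2, normal).
#' @param leadField a [LeadField-class].
#' @return single-channel [TimeSeries-class] in pV.
#' @export
scalpUnitaryResponse <- function(kernel, position, frame, leadField) {
  nu <- leadField@evaluator(position)
  a <- as.vector(t(frame) %*% nu)       # uV per nA.um, in kernel coords
  u <- as.vector(a %*% kernel@waveform) * 1e6   # pV
  TimeSeries(u, kernel@dt)
}

## Complex scalp transfer s_hat_i(f) (uV*s) for every placed neuron.
scalpTransferMatrix <- function(placed, bank, leadField, freqsHz) {
  n <- length(placed@classes)
  ut <- lapply(bank, kernelTransfer, freqsHz = freqsHz)  # nA.um*ms
  s <- matrix(0i, n, length(freqsHz))
  for (i in seq_len(n)) {
    nu <- leadField@evaluator(placed@positions[i, ])
    a <- as.vector(t(placed@frames[[i]]) %*% nu)
    s[i, ] <- (ut[[placed@classes[i]]] %*% a) * MS_TO_S   # uV*s
  }
  s
}

onesidedFactor <- function(f) ifelse(f > 0, 2, 1)

#' Population-mean unitary scalp energy spectrum
#'
#' Averages the scalp energy spectrum of each class kernel over cortical
#' locations (deterministic Fibonacci lattice) and tangent-plane
#' azimuths, then combines classes with abundance weights. Per-class
#' integrated scalp energies (pV^2*ms) are computed in the time domain on
#' the same lattice, so they match the calibration targets exactly when
#' the bank was calibrated with the same geometry and lead field.
#'
#' @param bank named list of [UnitaryKernel-class].
#' @param classes list of [NeuronClassSpec-class] carrying abundances.
#' @param geometry a [CortexGeometry-class].
#' @param leadField a [LeadField-class].
#' @param freqsHz output frequency grid (Hz); default log-spaced
#'   1-1000 Hz, 200 points.
#' @param nLocations,nAzimuths averaging resolution.
#' @return a [MeanUnitarySpectrum-class] (energy kind, pV^2*ms/Hz).
#' @export
meanUnitarySpectrum <- function(bank, classes, geometry, leadField,
                                freqsHz = exp(seq(log(1), log(1000),
                                                  length.out = 200)),
                                nLocations = 64, nAzimuths = 4) {
  if (length(bank) < 1) stop("kernel bank is empty")
  if (surfaceArea(geometry) <= 0) stop("geometry has no surface area")
  wts <- vapply(classes, function(cl) cl@abundance, 0)
  if (sum(wts) <= 0) stop("class abundances sum to zero")
  wts <- wts / sum(wts)
  sp <- surfacePoints(geometry, nLocations, method = "fibonacci")
  az <- seq(0, pi, length.out = nAzimuths + 1)[seq_len(nAzimuths)]
  osf <- onesidedFactor(freqsHz)

  perClass <- vector("list", length(bank))
  energies <- numeric(length(bank))
  for (ci in seq_along(bank)) {
    k <- bank[[ci]]
    ut <- kernelTransfer(k, freqsHz) * 1e6        # pV*ms
    acc <- numeric(length(freqsHz)); e <- 0
    for (i in seq_len(nLocations)) {
      nu <- leadField@evaluator(sp$points[i, ])
      for (az1 in az) {
        a <- as.vector(t(orientationFrame(sp$normals[i, ], az1)) %*% nu)
        acc <- acc + osf * Mod(ut %*% a)^2 * MS_TO_S  # pV^2*ms/Hz
        e <- e + sum((as.vector(a %*% k@waveform) * 1e6)^2) * k@dt
      }
    }
    m <- nLocations * nAzimuths
    perClass[[ci]] <- Spectrum(freqsHz, acc / m, units = UNIT_ENERGY_PV2MS,
                               kind = "energy")
    energies[ci] <- e / m
  }
  names(perClass) <- names(bank)
  mean <- Reduce(`+`, Map(function(s, w) w * s@values, perClass, wts))
  new("MeanUnitarySpectrum",
      Spectrum(freqsHz, mean, units = UNIT_ENERGY_PV2MS, kind = "energy"),
      perClass = perClass, weights = wts, classEnergies = energies)
}

#' Asynchronous ensemble apEEG spectrum
#'
#' With uncorrelated Poisson firing the pair term vanishes and the
#' ensemble spectrum is `lambda * N * Sbar_AP(f)`.
#'
#' @param lambda mean firing rate (Hz), >= 0.
#' @param N number of neurons, >= 0 (cortical default 16e9).
#' @param meanSpec a [MeanUnitarySpectrum-class] (pV^2*ms/Hz).
#' @return a power [Spectrum-class] in uV^2/Hz.
#' @export
asynchronousSpectrum <- function(lambda, N, meanSpec) {
  stopifnot(lambda >= 0, N >= 0, is(meanSpec, "MeanUnitarySpectrum"))
  Spectrum(meanSpec@freqs,
           lambda * N * Re(meanSpec@values) * PV2MS_TO_UV2S,
           units = UNIT_POWER_UV2, kind = "power")
}

#' Exact ensemble apEEG spectrum by double sum
#'
#' Evaluates the full pairwise sum
#' `sum_{i,j} Rspike_hat_{ij}(f) nu^T(x_i) Rap_hat_{ij}(f) nu(x_j)` over a
#' placed population: the diagonal gives the auto (asynchronous) term,
#' the off-diagonal the synchrony-driven pair term. Intended as the exact
#' reference for populations of up to a few hundred neurons.
#'
#' @param placed a [PlacedPopulation-class].
#' @param bank named list of [UnitaryKernel-class] covering the placed
#'   classes.
#' @param synchrony a [SynchronyParams-class].
#' @param leadField a [LeadField-class].
#' @param freqsHz frequency grid (Hz).
#' @param maxN refuse larger populations (use the Monte Carlo path).
#' @return a power [Spectrum-class] (uV^2/Hz) with attributes `autoTerm`
#'   and `pairTerm` (numeric vectors on the same grid).
#' @export
ensembleBruteforce <- function(placed, bank, synchrony, leadField,
                               freqsHz = exp(seq(log(1), log(1000),
                                                 length.out = 100)),
                               maxN = 200) {
  stopifnot(is(placed, "PlacedPopulation"), is(synchrony, "SynchronyParams"))
  n <- length(placed@classes)
  if (n > maxN)
    stop(sprintf(paste0("population of %d exceeds the exact-sum limit ",
                        "(%d); use pairTermMonteCarlo"), n, maxN))
  s <- scalpTransferMatrix(placed, bank, leadField, freqsHz)
  osf <- onesidedFactor(freqsHz)
  autoTerm <- synchrony@lambda * colSums(Mod(s)^2) * osf
  ## distance-damped coupling, frequency part factored out
  D <- as.matrix(stats::dist(placed@positions))
  C <- synchrony@lambda * synchrony@rmax *
    exp(-D^2 / (2 * synchrony@sigmaX^2))
  diag(C) <- 0
  base <- vapply(seq_along(freqsHz), function(j)
    Re(Conj(s[, j]) %*% C %*% s[, j])[1], 0)
  fshape <- crossSpectrumAnalytic(
    SynchronyParams(1, 1, synchrony@sigmaX, synchrony@sigmaT,
                    synchrony@f0), 0, freqsHz)
  pairTerm <- base * fshape * osf
  out <- Spectrum(freqsHz, pmax(autoTerm + pairTerm, 0),
                  units = UNIT_POWER_UV2, kind = "power")
  attr(out, "autoTerm") <- autoTerm
  attr(out, "pairTerm") <- pairTerm
  out
}

#' Draws required by Chebyshev's inequality
#'
#' Smallest n with `variance / (n * delta^2) <= confidence`, i.e. the
#' sample size after which a sample-mean estimate is within `delta` of
#' the mean with probability at least `1 - confidence`.
#'
#' @param variance per-draw variance.
#' @param delta absolute error target.
#' @param confidence tail probability bound.
#' @return integer draw count.
#' @export
chebyshevRequiredN <- function(variance, delta, confidence = 0.01) {
  ceiling(variance / (confidence * delta^2))
}

## Running mean / M2 per frequency, merged batch-wise (Chan's parallel
## variance update), so stopping checks cost O(1) per batch.
welfordUpdate <- function(state, X) {
  b <- nrow(X)
  bm <- colMeans(X)
  bM2 <- colSums(sweep(X, 2, bm)^2)
  if (state$n == 0)
    return(list(n = b, mean = bm, M2 = bM2))
  d <- bm - state$mean
  nT <- state$n + b
  state$M2 <- state$M2 + bM2 + d^2 * state$n * b / nT
  state$mean <- state$mean + d * b / nT
  state$n <- nT
  state
}

## Chebyshev stopping: the sample variance of the frequency-resolved
## estimate (spatial draws times the factored frequency shape) must give
## every frequency bin an error bound of deltaAbs at the configured
## confidence. Returns TRUE when satisfied.
mcConverged <- function(state, sc, mc) {
  if (state$n < 2) return(FALSE)
  s2 <- state$M2 / (state$n - 1)
  max(s2 * sc^2) / (state$n * mc@deltaAbs^2) <= mc@confidence
}

mcFinish <- function(state, freqsHz, sc, mc, converged) {
  est <- state$mean * sc
  s2 <- state$M2 / max(state$n - 1, 1)
  bound <- sqrt(max(s2 * sc^2) / (state$n * mc@confidence))
  out <- Spectrum(freqsHz, est, units = UNIT_POWER_UV2, kind = "cross")
  list(spectrum = out, errorBound = bound, nDraws = state$n,
       converged = converged, deltaAbs = mc@deltaAbs)
}

#' Monte Carlo estimate of the ensemble pair term
#'
#' Estimates the off-diagonal synchrony term of the ensemble spectrum by
#' random sampling, stopping when Chebyshev's inequality bounds the
#' probability of an absolute error exceeding `deltaAbs` by
#' `confidence`. Two samplers are provided:
#' \describe{
#'   \item{`PlacedPopulation`}{draws ordered neuron pairs uniformly from
#'     an explicitly placed population; the estimand is then exactly the
#'     [ensembleBruteforce()] pair term, making this the validation
#'     path.}
#'   \item{`CortexGeometry`}{the full-scale sampler: draws a class pair
#'     proportional to abundance, a uniform cortical location, and a
#'     displacement distance from the pair-distance density dN(r),
#'     weighting each draw by the spatial synchrony decay
#'     `exp(-r^2 / 2 sigmaX^2)`.}
#' }
#' The frequency shape of the spike cross-spectrum factors out of the
#' spatial sampling; the stopping rule is applied to the
#' frequency-resolved estimate (worst frequency governs).
#'
#' @param x a [PlacedPopulation-class] or [CortexGeometry-class].
#' @param bank named list of [UnitaryKernel-class].
#' @param synchrony a [SynchronyParams-class].
#' @param leadField a [LeadField-class].
#' @param freqsHz frequency grid (Hz).
#' @param mc an [MCConfig-class].
#' @param seed RNG seed.
#' @param classes (geometry method) list of [NeuronClassSpec-class].
#' @param pairDensity (geometry method) a [PairDensity-class].
#' @param ... passed through.
#' @return list(spectrum, errorBound, nDraws, converged, deltaAbs); the
#'   spectrum is a [Spectrum-class] (uV^2/Hz; kind `"cross"` since small
#'   negative excursions are legitimate), `converged = FALSE` flags
#'   stopping at `maxDraws` before the Chebyshev criterion.
#' @export
setGeneric("pairTermMonteCarlo", function(x, ...)
  standardGeneric("pairTermMonteCarlo"))

#' @rdname pairTermMonteCarlo
#' @export
setMethod("pairTermMonteCarlo", "PlacedPopulation",
  function(x, bank, synchrony, leadField,
           freqsHz = exp(seq(log(1), log(1000), length.out = 100)),
           mc = MCConfig(deltaAbs = 1e-3), seed = 1, ...) {
    set.seed(seed)
    n <- length(x@classes)
    if (n < 2) stop("need at least two placed neurons")
    s <- scalpTransferMatrix(x, bank, leadField, freqsHz)
    D <- as.matrix(stats::dist(x@positions))
    C <- synchrony@lambda * synchrony@rmax *
      exp(-D^2 / (2 * synchrony@sigmaX^2))
    diag(C) <- 0
    sc <- crossSpectrumAnalytic(
      SynchronyParams(1, 1, synchrony@sigmaX, synchrony@sigmaT,
                      synchrony@f0), 0, freqsHz) * onesidedFactor(freqsHz)
    ## importance-sample ordered pairs by their spatial coupling; each
    ## draw is then weighted by the total coupling mass, which keeps the
    ## per-draw variance insensitive to the (huge) dynamic range of the
    ## distance damping
    pmass <- as.vector(C)
    Ctot <- sum(pmass)
    if (Ctot <= 0) {
      state <- list(n = 2, mean = numeric(length(freqsHz)),
                    M2 = numeric(length(freqsHz)))
      return(mcFinish(state, freqsHz, sc, mc, TRUE))
    }
    state <- list(n = 0, mean = numeric(length(freqsHz)),
                  M2 = numeric(length(freqsHz)))
    repeat {
      b <- min(mc@batchSize, mc@maxDraws - state$n)
      if (b <= 0) return(mcFinish(state, freqsHz, sc, mc, FALSE))
      flat <- sample.int(length(pmass), b, replace = TRUE, prob = pmass)
      i <- ((flat - 1L) %% n) + 1L
      j <- ((flat - 1L) %/% n) + 1L
      X <- Re(s[i, , drop = FALSE] * Conj(s[j, , drop = FALSE])) * Ctot
      state <- welfordUpdate(state, X)
      if (mcConverged(state, sc, mc))
        return(mcFinish(state, freqsHz, sc, mc, TRUE))
    }
  })

#' @rdname pairTermMonteCarlo
#' @export
setMethod("pairTermMonteCarlo", "CortexGeometry",
  function(x, bank, classes, pairDensity, synchrony, leadField,
           freqsHz = exp(seq(log(1), log(1000), length.out = 100)),
           mc = MCConfig(deltaAbs = 1e-3), seed = 1, ...) {
    set.seed(seed)
    stopifnot(is(pairDensity, "PairDensity"))
    wts <- vapply(classes, function(cl) cl@abundance, 0)
    wts <- wts / sum(wts)
    ut <- lapply(bank, function(k) kernelTransfer(k, freqsHz) * MS_TO_S)
    sc <- crossSpectrumAnalytic(
      SynchronyParams(1, 1, synchrony@sigmaX, synchrony@sigmaT,
                      synchrony@f0), 0, freqsHz) * onesidedFactor(freqsHz)
    ## discretize dN(r) for displacement sampling
    r <- pairDensity@radii; dn <- pairDensity@values
    dr <- diff(r)
    mass <- dr * (utils::head(dn, -1) + utils::tail(dn, -1)) / 2
    Itot <- sum(mass)                  # ~ N - 1 neighbours per source
    N <- x@nNeurons
    amp <- synchrony@lambda * synchrony@rmax
    state <- list(n = 0, mean = numeric(length(freqsHz)),
                  M2 = numeric(length(freqsHz)))
    repeat {
      b <- min(mc@batchSize, mc@maxDraws - state$n)
      if (b <= 0) return(mcFinish(state, freqsHz, sc, mc, FALSE))
      ki <- sample.int(length(wts), b, replace = TRUE, prob = wts)
      kj <- sample.int(length(wts), b, replace = TRUE, prob = wts)
      ctr <- surfacePoints(x, b, method = "random",
                           seed = sample.int(2^31 - 1, 1))
      bin <- sample.int(length(mass), b, replace = TRUE, prob = mass)
      rr <- r[bin] + stats::runif(b) * dr[bin]
      X <- matrix(0, b, length(freqsHz))
      for (k in seq_len(b)) {
        fr1 <- orientationFrame(ctr$normals[k, ], stats::runif(1, 0, 2 * pi))
        p2 <- displaceOnSurface(x, ctr$points[k, ], rr[k])
        fr2 <- orientationFrame(p2$normal, stats::runif(1, 0, 2 * pi))
        a1 <- as.vector(t(fr1) %*% leadField@evaluator(ctr$points[k, ]))
        a2 <- as.vector(t(fr2) %*% leadField@evaluator(p2$point))
        s1 <- ut[[ki[k]]] %*% a1
        s2c <- ut[[kj[k]]] %*% a2
        X[k, ] <- Re(s1 * Conj(s2c)) *
          (N * Itot * amp * exp(-rr[k]^2 / (2 * synchrony@sigmaX^2)))
      }
      state <- welfordUpdate(state, X)
      if (mcConverged(state, sc, mc))
        return(mcFinish(state, freqsHz, sc, mc, TRUE))
    }
  })

#' Combine auto and pair terms into the ensemble spectrum
#'
#' @param autoTerm a power [Spectrum-class] (e.g. from
#'   [asynchronousSpectrum()]).
#' @param pairTerm a [Spectrum-class] on the same grid (e.g.
#'   `pairTermMonteCarlo(...)$spectrum`), or NULL for none.
#' @return a power [Spectrum-class]; negative totals (Monte Carlo noise)
#'   are clipped at 0.
#' @export
ensembleSpectrum <- function(autoTerm, pairTerm = NULL) {
  stopifnot(is(autoTerm, "Spectrum"))
  if (is.null(pairTerm)) return(autoTerm)
  if (length(autoTerm@freqs) != length(pairTerm@freqs) ||
      any(abs(autoTerm@freqs - pairTerm@freqs) > 1e-9))
    stop("auto and pair terms must share a frequency grid")
  Spectrum(autoTerm@freqs,
           pmax(Re(autoTerm@values) + Re(pairTerm@values), 0),
           units = autoTerm@units, kind = "power")
}

#' Ensemble spectrum of correlated synaptic currents
#'
#' Phenomenological two-timescale model: the single-neuron synaptic EEG
#' spectrum is a sum of an inhibitory (GABAR) and an excitatory (AMPAR)
#' Lorentzian pair, and pairwise coherence decays spatially with separate
#' Gaussian scales per component. The ensemble spectrum is
#' `N * (L_I + L_E) + N * (W_I L_I + W_E L_E)` with
#' `W_c = integral exp(-r^2 / 2 sigma_c^2) dN(r) dr` the effective number
#' of coherent neighbours per source for component c (`sigma_c = 0`
#' removes that cross term).
#'
#' @param trend a [TrendParams-class] giving the component Lorentzians.
#' @param sigmaGabar,sigmaAmpar spatial coherence scales (mm), >= 0.
#' @param pairDensity a [PairDensity-class].
#' @param N number of neurons.
#' @param freqsHz frequency grid (Hz).
#' @return a power [Spectrum-class] with attribute `components`
#'   (inhibitory and excitatory ensemble parts and the pair weights).
#' @export
synapticEnsembleSpectrum <- function(trend, sigmaGabar, sigmaAmpar,
                                     pairDensity, N,
                                     freqsHz = exp(seq(log(1), log(500),
                                                       length.out = 150))) {
  stopifnot(is(trend, "TrendParams"), sigmaGabar >= 0, sigmaAmpar >= 0,
            is(pairDensity, "PairDensity"))
  LI <- lorentzianPair(trend@ampI, trend@tauI1, trend@tauI2, freqsHz)
  LE <- lorentzianPair(trend@ampE, trend@tauE1, trend@tauE2, freqsHz)
  pw <- function(sig) {
    if (sig <= 0) return(0)
    r <- pairDensity@radii
    w <- exp(-r^2 / (2 * sig^2)) * pairDensity@values
    sum(diff(r) * (utils::head(w, -1) + utils::tail(w, -1)) / 2)
  }
  WI <- pw(sigmaGabar); WE <- pw(sigmaAmpar)
  vI <- N * LI * (1 + WI); vE <- N * LE * (1 + WE)
  out <- Spectrum(freqsHz, vI + vE, units = UNIT_POWER_UV2, kind = "power")
  attr(out, "components") <- list(inhibitory = vI, excitatory = vE,
                                  pairWeightI = WI, pairWeightE = WE)
  out
}
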