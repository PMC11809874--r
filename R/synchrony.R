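## Spike-train second-order statistics. The pairwise cross-correlogram is a
## distance-damped, Gaussian-jittered (optionally cosine-modulated) density;
## its Fourier transform (convention int h(tau) e^{-2 pi i f tau} d tau) has
## a closed form used throughout the ensemble assembly.

#' Spike-train cross-correlogram model
#'
#' Evaluates the model cross-correlogram between two neurons separated by
#' `d` mm at lags `tau` ms:
#' `lambda Rmax / sqrt(2 pi sigmaT^2) * exp(-d^2/2 sigmaX^2) *
#'  exp(-tau^2/2 sigmaT^2) * cos(2 pi f0 tau)`.
#' This is a covariance density (the flat `lambda^2` chance level is
#' excluded); with `f0 = 0` it is the aperiodic model; it is even in `tau`.
#' Units: Hz per ms of lag (rate density), with `tau` and `sigmaT` in ms.
#'
#' @param p a [SynchronyParams-class].
#' @param d pairwise distance (mm).
#' @param tau lag(s), ms. `sigmaT` must be > 0 for pointwise evaluation
#'   (the `sigmaT = 0` delta limit is handled spectrally by
#'   [crossSpectrumAnalytic()]).
#' @return numeric vector of correlogram values.
#' @export
crossCorrelogram <- function(p, d, tau) {
  stopifnot(is(p, "SynchronyParams"))
  if (p@sigmaT <= 0)
    stop("pointwise correlogram evaluation requires sigmaT > 0; ",
         "the zero-jitter limit is a delta and is handled spectrally")
  env <- exp(-d^2 / (2 * p@sigmaX^2)) *
    exp(-tau^2 / (2 * p@sigmaT^2)) / sqrt(2 * pi * p@sigmaT^2)
  osc <- if (p@f0 > 0) cos(2 * pi * p@f0 * tau * MS_TO_S) else 1
  p@lambda * p@rmax * env * osc
}

#' Closed-form spike-train cross-spectrum
#'
#' Fourier transform of [crossCorrelogram()]. For the aperiodic model
#' (`f0 = 0`):
#' `lambda Rmax exp(-d^2/2 sigmaX^2) exp(-2 pi^2 sigmaT^2 f^2)`;
#' for the rhythmic model the Gaussian splits into the half-sum of copies
#' centred at `+f0` and `-f0`. `sigmaT = 0` gives the flat zero-jitter
#' limit `lambda Rmax exp(-d^2/2 sigmaX^2)`. Values are real (the model
#' correlogram is even) and in Hz.
#'
#' @inheritParams crossCorrelogram
#' @param f frequencies (Hz), >= 0.
#' @return numeric vector of spectral densities (Hz).
#' @export
crossSpectrumAnalytic <- function(p, d, f) {
  stopifnot(is(p, "SynchronyParams"), all(f >= 0))
  amp <- p@lambda * p@rmax * exp(-d^2 / (2 * p@sigmaX^2))
  st <- p@sigmaT * MS_TO_S                  # seconds
  if (st == 0) return(rep(amp, length(f)))
  if (p@f0 > 0) {
    amp * 0.5 * (exp(-2 * pi^2 * st^2 * (f - p@f0)^2) +
                 exp(-2 * pi^2 * st^2 * (f + p@f0)^2))
  } else {
    amp * exp(-2 * pi^2 * st^2 * f^2)
  }
}

#' Spike-train auto-spectrum
#'
#' For a Poisson train the (unnormalized) auto-correlation beyond the
#' delta at zero lag carries no structure, so the spectrum is flat at the
#' firing rate `lambda`.
#'
#' @inheritParams crossSpectrumAnalytic
#' @return numeric vector, `lambda` at every frequency.
#' @export
autoSpectrum <- function(p, f) {
  stopifnot(is(p, "SynchronyParams"))
  rep(p@lambda, length(f))
}

#' Named physiological synchrony presets
#'
#' `"mt-cotuned"`: co-tuned sensory neurons (Rmax = 0.2, sigmaT = 11.3 ms);
#' `"v4-slow"`: slower correlation timescales (Rmax = 0.2, sigmaT = 100 ms).
#' Surveyed physiological ranges are Rmax in [0.05, 0.25], sigmaT in
#' [10, 100] ms, lambda in [0.1, 2] Hz.
#'
#' @param name preset name.
#' @param lambda firing rate override (Hz).
#' @param f0 rhythm frequency override (Hz).
#' @return a [SynchronyParams-class].
#' @export
synchronyPreset <- function(name = c("mt-cotuned", "v4-slow"), lambda = 1,
                            f0 = 0) {
  name <- match.arg(name)
  switch(name,
    "mt-cotuned" = SynchronyParams(lambda = lambda, rmax = 0.2,
                                   sigmaX = sqrt(3), sigmaT = 11.3, f0 = f0),
    "v4-slow" = SynchronyParams(lambda = lambda, rmax = 0.2,
                                sigmaX = sqrt(3), sigmaT = 100, f0 = f0))
}

#' Empirical cross-correlogram of two spike trains
#'
#' Histogram estimate of the covariance density between two spike trains:
#' pair counts per lag bin, normalized by duration and bin width, with the
#' chance level `lambda1 * lambda2` subtracted. Comparable directly to
#' [crossCorrelogram()].
#'
#' @param t1,t2 spike times (ms).
#' @param duration record length (ms).
#' @param lags bin centres (ms).
#' @param binWidth bin width (ms).
#' @return data.frame with columns `lag`, `density` (Hz/ms), and `se`, a
#'   Poisson standard error on the density.
#' @export
empiricalCrossCorrelogram <- function(t1, t2, duration, lags,
                                      binWidth = diff(lags[1:2])) {
  maxLag <- max(abs(lags)) + binWidth
  counts <- numeric(length(lags))
  ## count spike pairs falling in each lag bin; t2 sorted for windowing
  t2 <- sort(t2)
  for (s in t1) {
    lo <- findInterval(s - maxLag, t2) + 1L
    hi <- findInterval(s + maxLag, t2)
    if (hi < lo) next
    dl <- t2[lo:hi] - s
    idx <- round((dl - lags[1]) / binWidth) + 1L
    ok <- idx >= 1L & idx <= length(lags)
    if (any(ok)) {
      tab <- tabulate(idx[ok], nbins = length(lags))
      counts <- counts + tab
    }
  }
  Tsec <- duration * MS_TO_S
  r1 <- length(t1) / Tsec; r2 <- length(t2) / Tsec
  ## density in Hz per ms of lag; chance level r1*r2 (Hz^2) * 1e-3
  dens <- counts / (Tsec * binWidth) - r1 * r2 * MS_TO_S
  se <- sqrt(pmax(counts, 1)) / (Tsec * binWidth)
  data.frame(lag = lags, density = dens, se = se)
}
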