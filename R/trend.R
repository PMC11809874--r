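## Aperiodic spectral-trend modelling: noise-floor correction, the
## double-Lorentzian synaptic-timescale trend, detectability against the
## amplifier floor, rhythm-peak bookkeeping, and detrending strategies.

lorentzianPair <- function(amp, tau1, tau2, f) {
  amp * (tau1 - tau2)^2 /
    ((1 + (2 * pi * f * tau1)^2) * (1 + (2 * pi * f * tau2)^2))
}

#' Evaluate the double-Lorentzian spectral trend
#'
#' `S(f) = AI (tI1-tI2)^2 / [(1+(2 pi f tI1)^2)(1+(2 pi f tI2)^2)]
#'       + AE (tE1-tE2)^2 / [(1+(2 pi f tE1)^2)(1+(2 pi f tE2)^2)]`,
#' time constants in seconds, `f` in Hz. The noise floor stored in `p` is
#' not included; it is additive on measured spectra only.
#'
#' @param p a [TrendParams-class].
#' @param f frequencies (Hz), >= 0.
#' @return densities (uV^2/Hz).
#' @export
evalTrend <- function(p, f) {
  stopifnot(is(p, "TrendParams"), all(f >= 0))
  lorentzianPair(p@ampI, p@tauI1, p@tauI2, f) +
    lorentzianPair(p@ampE, p@tauE1, p@tauE2, f)
}

#' Subtract a constant noise floor from a spectrum
#'
#' Densities falling at or below the floor are clipped to a tiny positive
#' epsilon (1e-12 uV^2/Hz) so that later log-space fits stay defined; the
#' number of clipped bins is reported as an attribute and a warning.
#'
#' @param s a [Spectrum-class] of kind `"power"`.
#' @param floor non-negative density to subtract (uV^2/Hz).
#' @param eps clip value for bins below the floor.
#' @return a [Spectrum-class]; `attr(, "nClipped")` counts clipped bins.
#' @export
subtractNoiseFloor <- function(s, floor, eps = 1e-12) {
  stopifnot(is(s, "Spectrum"), floor >= 0)
  v <- Re(s@values) - floor
  nclip <- sum(v < eps)
  out <- Spectrum(s@freqs, pmax(v, eps), units = s@units, kind = s@kind)
  attr(out, "nClipped") <- nclip
  if (nclip > 0 && floor > 0)
    warning(sprintf("%d bin(s) at or below the noise floor were clipped",
                    nclip))
  out
}

## log-space residuals of the trend model; par is
## (log tauI1, log dI, log ampI, log ampE [, log tauE1, log dE]) with
## tauI2 = tauI1 * (1 + dI), guaranteeing rise < decay.
trendResiduals <- function(par, f, logS, fixedTauE) {
  tauI1 <- exp(par[1]); tauI2 <- tauI1 * (1 + exp(par[2]))
  ampI <- exp(par[3]); ampE <- exp(par[4])
  if (is.null(fixedTauE)) {
    tauE1 <- exp(par[5]); tauE2 <- tauE1 * (1 + exp(par[6]))
  } else {
    tauE1 <- fixedTauE[1]; tauE2 <- fixedTauE[2]
  }
  m <- lorentzianPair(ampI, tauI1, tauI2, f) +
    lorentzianPair(ampE, tauE1, tauE2, f)
  log(pmax(m, 1e-300)) - logS
}

#' Fit the double-Lorentzian trend to a spectrum
#'
#' Least squares in log-power space (equal weight per bin; intended for
#' log-spaced grids) via Levenberg-Marquardt with deterministic
#' multi-start. The spectrum should already be noise-floor corrected. The
#' inhibitory time constants and both amplitudes are always fitted; the
#' excitatory time constants are fixed at 1 and 3 ms by default (their
#' exact values have little leverage provided they are faster than the
#' inhibitory ones) and can be freed with `fixTauE = FALSE`.
#'
#' @param s a [Spectrum-class], >= 20 bins spanning >= 2 decades.
#' @param fixTauE keep tauE at `tauEInit` (default) or fit them.
#' @param tauEInit excitatory (rise, decay) in seconds.
#' @param nStarts number of multi-start initializations.
#' @param seed integer seed for the (deterministic) start jitter.
#' @param excludeDC drop the f = 0 bin before fitting (default).
#' @return a [TrendParams-class]; attributes `rss` (log-space residual sum
#'   of squares) and `rSquared` (in log space) record goodness of fit.
#' @export
fitTrend <- function(s, fixTauE = TRUE, tauEInit = c(0.001, 0.003),
                     nStarts = 8, seed = 1, excludeDC = TRUE) {
  stopifnot(is(s, "Spectrum"))
  f <- s@freqs; v <- Re(s@values)
  if (excludeDC) { keep <- f > 0; f <- f[keep]; v <- v[keep] }
  if (length(f) < 20)
    stop("trend fitting requires at least 20 frequency bins")
  if (log10(max(f) / min(f)) < 2)
    stop("trend fitting requires a grid spanning at least 2 decades")
  if (any(v <= 0))
    stop("trend fitting requires positive densities; ",
         "noise-floor correct the spectrum first")
  logS <- log(v)
  fixedTauE <- if (fixTauE) tauEInit else NULL
  nPar <- if (fixTauE) 4L else 6L

  ## crude moment-based initial guesses, then jittered multi-starts
  s0 <- stats::approx(log(f), logS, xout = log(min(f) * 10))$y
  a0 <- exp(s0) / (0.004 - 0.020)^2 / 2
  base <- c(log(0.004), log(4), log(max(a0, 1e-6)), log(max(a0 / 10, 1e-8)))
  if (!fixTauE) base <- c(base, log(0.001), log(2))

  rng <- withr_seed_draws(seed, nStarts - 1, nPar)
  starts <- rbind(base, sweep(rng, 2, base, "+"))

  best <- NULL
  for (k in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = starts[k, ], fn = trendResiduals, f = f,
                         logS = logS, fixedTauE = fixedTauE,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-14, ptol = 1e-14)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss)
      best <- list(par = fit$par, rss = rss)
  }
  if (is.null(best))
    stop("trend fit failed to converge from any start; residuals could ",
         "not be evaluated")
  par <- best$par
  tauI1 <- exp(par[1]); tauI2 <- tauI1 * (1 + exp(par[2]))
  if (fixTauE) { tauE1 <- tauEInit[1]; tauE2 <- tauEInit[2] }
  else { tauE1 <- exp(par[5]); tauE2 <- tauE1 * (1 + exp(par[6])) }
  out <- TrendParams(tauI1 = tauI1, tauI2 = tauI2, tauE1 = tauE1,
                     tauE2 = tauE2, ampI = exp(par[3]), ampE = exp(par[4]))
  attr(out, "rss") <- best$rss
  attr(out, "rSquared") <- 1 - best$rss / sum((logS - mean(logS))^2)
  out
}

## deterministic N(0, 0.5) draws for multi-start jitter, isolated from the
## caller's RNG stream
withr_seed_draws <- function(seed, n, k) {
  if (n <= 0) return(matrix(numeric(0), ncol = k))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  matrix(stats::rnorm(n * k, sd = 0.5), ncol = k)
}

#' Maximal high-frequency density and detectability
#'
#' The largest spectral density above `fMin` (default 30 Hz) and whether
#' it exceeds the amplifier noise floor.
#'
#' @param s a [Spectrum-class].
#' @param floor noise-floor density (uV^2/Hz).
#' @param fMin lower frequency bound (Hz).
#' @return list(maxDensity, detectable, fAtMax).
#' @export
detectability <- function(s, floor = 1e-3, fMin = 30) {
  stopifnot(is(s, "Spectrum"))
  sel <- s@freqs > fMin
  if (!any(sel)) stop("frequency grid does not extend past fMin")
  v <- Re(s@values)[sel]
  i <- which.max(v)
  list(maxDensity = v[i], detectable = v[i] > floor,
       fAtMax = s@freqs[sel][i])
}

#' Rhythm-peak amplitude relative to the spectral trend
#'
#' Peak density of an AP-generated spectrum at the rhythm frequency,
#' divided by the fitted trend density there.
#'
#' @param apSpectrum a [Spectrum-class].
#' @param trend a [TrendParams-class].
#' @param f0 rhythm frequency (Hz); must lie on the grid (nearest bin
#'   within half a grid step is used).
#' @return scalar ratio.
#' @export
peakRelativeAmplitude <- function(apSpectrum, trend, f0) {
  stopifnot(is(apSpectrum, "Spectrum"), is(trend, "TrendParams"))
  i <- which.min(abs(apSpectrum@freqs - f0))
  if (abs(apSpectrum@freqs[i] - f0) > max(diff(apSpectrum@freqs)))
    stop("f0 is not on the frequency grid")
  Re(apSpectrum@values[i]) / evalTrend(trend, f0)
}

#' Translate a spectral peak along the trend
#'
#' Moves a peak (e.g. the alpha rhythm, assumed purely synaptic) to a new
#' centre frequency while holding its amplitude fixed relative to the
#' spectral trend: the absolute peak power scales by
#' `trend(target) / trend(center)`. Used to bound synaptic contributions
#' to high-frequency rhythms.
#'
#' @param peak list or data.frame row with `center` (Hz), `amplitude`
#'   (x trend), `width` (Hz).
#' @param trend a [TrendParams-class].
#' @param target new centre frequency (Hz).
#' @return list with the translated `center`, `amplitude` (unchanged,
#'   relative to trend), `width`, and `absolutePower`
#'   (amplitude * trend(target), uV^2/Hz).
#' @export
translatePeak <- function(peak, trend, target) {
  stopifnot(is(trend, "TrendParams"))
  list(center = target, amplitude = peak$amplitude, width = peak$width,
       absolutePower = peak$amplitude * evalTrend(trend, target))
}

#' Fraction of a rhythm peak contributed by APs
#'
#' `ap / (ap + syn)` for peak powers at a common rhythm frequency; the
#' peak counts as detectable when the combined peak-plus-trend density
#' exceeds the noise floor.
#'
#' @param apPeakPower,synPeakPower peak densities (uV^2/Hz), >= 0.
#' @param floor noise-floor density (uV^2/Hz).
#' @param trendAtF0 trend density at the rhythm frequency (uV^2/Hz).
#' @return list(fraction, detectable, defined); `fraction` is 0 with
#'   `defined = FALSE` when both powers are 0.
#' @export
apFraction <- function(apPeakPower, synPeakPower, floor = 1e-3,
                       trendAtF0 = 0) {
  stopifnot(apPeakPower >= 0, synPeakPower >= 0)
  tot <- apPeakPower + synPeakPower
  if (tot == 0)
    return(list(fraction = 0, detectable = trendAtF0 > floor,
                defined = FALSE))
  list(fraction = apPeakPower / tot,
       detectable = (tot + trendAtF0) > floor, defined = TRUE)
}

gaussPeak <- function(f, center, width, amplitude)
  amplitude * exp(-(f - center)^2 / (2 * width^2))

#' Toy EEG spectrum for detrending comparisons
#'
#' `P(f) = (1 + sum_k peak_k(f) + 1/f^2) * Psyn(f) + HFO(f) + noise`,
#' with Gaussian rhythm peaks multiplicative in the synaptic trend, an
#' optional additive (AP-generated) high-frequency-oscillation Gaussian,
#' and a constant additive EMG/amplifier plateau.
#'
#' @param p a [ToyModelParams-class].
#' @param f frequencies (Hz), > 0 (the 1/f^2 term diverges at DC).
#' @return a [Spectrum-class] with attribute `components`, a list of the
#'   `synaptic` (trend-filtered), `hfo` and `noise` parts.
#' @export
toySpectrum <- function(p, f) {
  stopifnot(is(p, "ToyModelParams"), all(f > 0))
  mult <- rep(1, length(f)) + 1 / f^2
  if (nrow(p@peaks) > 0)
    for (k in seq_len(nrow(p@peaks)))
      mult <- mult + gaussPeak(f, p@peaks$center[k], p@peaks$width[k],
                               p@peaks$amplitude[k])
  syn <- mult * evalTrend(p@trend, f)
  hfo <- if (is.finite(p@hfoCenter))
    gaussPeak(f, p@hfoCenter, p@hfoWidth, p@hfoAmplitude)
  else rep(0, length(f))
  total <- syn + hfo + p@noise
  out <- Spectrum(f, total, units = UNIT_POWER_UV2, kind = "power")
  attr(out, "components") <- list(synaptic = syn, hfo = hfo,
                                  noise = rep(p@noise, length(f)))
  out
}

#' Estimate the additive noise plateau of a toy spectrum
#'
#' Mean spectral density above `fMin` (default 200 Hz) after removing the
#' synaptic component: at these frequencies the Lorentzian trend has
#' decayed by orders of magnitude, so what remains estimates the additive
#' EMG/amplifier plateau.
#'
#' @param s a [Spectrum-class] produced by [toySpectrum()] (its synaptic
#'   component attribute is used), or any spectrum if `trend` is given.
#' @param trend optional [TrendParams-class]; when supplied the synaptic
#'   part is recomputed as `(1 + 1/f^2) * evalTrend(trend, f)`.
#' @param fMin averaging band lower edge (Hz).
#' @return scalar plateau estimate (uV^2/Hz).
#' @export
noisePlateau <- function(s, trend = NULL, fMin = 200) {
  stopifnot(is(s, "Spectrum"))
  sel <- s@freqs > fMin
  if (!any(sel)) stop("frequency grid does not extend past fMin")
  f <- s@freqs[sel]
  syn <- if (!is.null(trend)) (1 + 1 / f^2) * evalTrend(trend, f)
  else {
    comp <- attr(s, "components")
    if (is.null(comp)) stop("supply `trend` for spectra without components")
    comp$synaptic[sel]
  }
  mean(Re(s@values)[sel] - syn)
}

#' Detrend a spectrum
#'
#' Three strategies for removing the aperiodic structure of an EEG
#' spectrum:
#' \describe{
#'   \item{divisive}{`s / (trend + floor)` — divides out the whole trend
#'     including the additive plateau; inflates high-frequency peaks when
#'     the plateau differs between conditions.}
#'   \item{subtractive}{`s - floor` — removes only the additive plateau.}
#'   \item{mixed}{`(s - floor) / trend` — subtract the additive noise
#'     first, then divide by the synaptic trend; leaves rhythm power
#'     invariant to changes in floor and trend scale.}
#' }
#'
#' @param s a [Spectrum-class].
#' @param trend a [TrendParams-class] or numeric vector of trend densities
#'   on the grid of `s` (must be positive).
#' @param floor additive plateau density (uV^2/Hz).
#' @param mode one of `"divisive"`, `"subtractive"`, `"mixed"`.
#' @return a [Spectrum-class]; detrended values are unitless for the
#'   divisive modes.
#' @export
detrendSpectrum <- function(s, trend, floor = 0,
                            mode = c("mixed", "divisive", "subtractive")) {
  stopifnot(is(s, "Spectrum"))
  mode <- match.arg(mode)
  tv <- if (is(trend, "TrendParams")) evalTrend(trend, s@freqs)
  else as.numeric(trend)
  if (mode != "subtractive" && any(tv <= 0))
    stop("divisive detrending requires a positive trend on the grid")
  v <- Re(s@values)
  out <- switch(mode,
    divisive = v / (tv + floor),
    subtractive = v - floor,
    mixed = (v - floor) / tv)
  units <- if (mode == "subtractive") s@units else "unitless"
  Spectrum(s@freqs, pmax(out, 0), units = units, kind = "power")
}
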