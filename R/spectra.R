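## Spectral primitives shared by all stages. All estimators are one-sided
## and Parseval-consistent: integrating a PSD over Hz returns the signal
## variance; integrating an energy spectrum returns sum(u^2)*dt (ms).

hannWindow <- function(n) 0.5 * (1 - cos(2 * pi * seq_len(n) / (n + 1)))

welchPlan <- function(n, dt, segmentLength, overlap) {
  L <- max(2L, round(segmentLength / dt))
  step <- max(1L, floor(L * (1 - overlap)))
  if (n < L + step)
    stop(sprintf(paste0("series too short for Welch estimation: ",
                        "%d samples given, at least %d required ",
                        "(two %d-sample segments at %.0f%% overlap)"),
         n, L + step, L, 100 * overlap))
  starts <- seq(1L, n - L + 1L, by = step)
  list(L = L, starts = starts)
}

## Average cross-periodogram over Welch segments; x, y are T x C matrices.
## Returns list(freqs, values) one-sided; values complex unless x is y.
welchCross <- function(x, y, dt, segmentLength, overlap) {
  n <- nrow(x)
  plan <- welchPlan(n, dt, segmentLength, overlap)
  L <- plan$L
  w <- hannWindow(L)
  fs <- 1000 / dt                      # Hz
  scale <- 1 / (fs * sum(w^2))
  nf <- floor(L / 2) + 1L
  acc <- complex(nf)
  for (s in plan$starts) {
    seg <- s:(s + L - 1L)
    for (ch in seq_len(ncol(x))) {
      xs <- x[seg, ch]; ys <- y[seg, ch]
      xs <- xs - mean(xs); ys <- ys - mean(ys)
      fx <- stats::fft(w * xs); fy <- stats::fft(w * ys)
      acc <- acc + (Conj(fx) * fy)[seq_len(nf)]
    }
  }
  vals <- acc * scale / length(plan$starts)
  ## one-sided: double all interior bins
  dbl <- rep(2, nf); dbl[1] <- 1
  if (L %% 2 == 0) dbl[nf] <- 1
  vals <- vals * dbl
  list(freqs = (seq_len(nf) - 1L) * fs / L, values = vals)
}

#' Welch power spectral density
#'
#' Averaged-periodogram (Welch) estimate with a Hann window and 50%
#' overlap. Segments are mean-detrended. Multi-channel series return the
#' summed density across channels. One-sided, so the integral over the
#' frequency grid approximates the (detrended) signal variance.
#'
#' @param series a [TimeSeries-class].
#' @param segmentLength segment duration in ms (default 2000 ms).
#' @param overlap fractional segment overlap (default 0.5).
#' @param units unit tag for the returned density.
#' @return a [Spectrum-class] of kind `"power"`.
#' @examples
#' x <- TimeSeries(rnorm(2^14), dt = 1)
#' s <- estimatePsd(x)
#' sum(specValues(s)) * diff(freqs(s))[1]   # ~ var(x) = 1
#' @export
estimatePsd <- function(series, segmentLength = 2000, overlap = 0.5,
                        units = UNIT_POWER_UV2) {
  stopifnot(is(series, "TimeSeries"))
  x <- series@samples
  est <- welchCross(x, x, series@dt, segmentLength, overlap)
  Spectrum(est$freqs, pmax(Re(est$values), 0), units = units, kind = "power")
}

#' Welch cross-spectral density
#'
#' Cross-spectrum between two equally sampled series, averaged over Welch
#' segments (Hann, 50% overlap); `estimateCsd(a, b)` is the complex
#' conjugate of `estimateCsd(b, a)`, and `estimateCsd(a, a)` reduces to
#' [estimatePsd()]. Channels are summed.
#'
#' @param a,b [TimeSeries-class] objects with equal length and `dt`.
#' @inheritParams estimatePsd
#' @return a [Spectrum-class] of kind `"cross"` with complex values.
#' @export
estimateCsd <- function(a, b, segmentLength = 2000, overlap = 0.5,
                        units = UNIT_POWER_UV2) {
  stopifnot(is(a, "TimeSeries"), is(b, "TimeSeries"))
  if (abs(a@dt - b@dt) > 1e-12)
    stop("cross-spectral estimation requires equal sampling intervals")
  if (nrow(a@samples) != nrow(b@samples) ||
      ncol(a@samples) != ncol(b@samples))
    stop("cross-spectral estimation requires equally sized series")
  est <- welchCross(a@samples, b@samples, a@dt, segmentLength, overlap)
  Spectrum(est$freqs, est$values, units = units, kind = "cross")
}

energySpectrumMatrix <- function(x, dt, units) {
  n <- nrow(x)
  if (n < 1) stop("cannot compute the energy spectrum of an empty kernel")
  ft <- stats::mvfft(x) * dt                       # unit * ms
  nf <- floor(n / 2) + 1L
  e <- rowSums(Mod(ft[seq_len(nf), , drop = FALSE])^2) * MS_TO_S
  dbl <- rep(2, nf); dbl[1] <- 1
  if (n %% 2 == 0) dbl[nf] <- 1
  fs <- 1000 / dt
  Spectrum((seq_len(nf) - 1L) * fs / n, e * dbl, units = units,
           kind = "energy")
}

#' @rdname energySpectrum
#' @export
setMethod("energySpectrum", "TimeSeries", function(kernel, ...) {
  energySpectrumMatrix(kernel@samples, kernel@dt, UNIT_ENERGY_DIPOLE)
})

#' @rdname energySpectrum
#' @export
setMethod("energySpectrum", "UnitaryKernel", function(kernel, ...) {
  energySpectrumMatrix(t(kernel@waveform), kernel@dt, UNIT_ENERGY_DIPOLE)
})

#' Kernel Fourier transform on an arbitrary frequency grid
#'
#' Continuous-frequency transform `u_hat(f) = sum_t u(t) e^{-2 pi i f t} dt`
#' of a finite kernel, evaluated at arbitrary frequencies (Hz). Times are
#' taken from the kernel window so that t = 0 is the spike peak. Used by
#' the ensemble assembly, which needs kernel cross-spectra on shared
#' log-spaced grids rather than FFT grids.
#'
#' @param kernel a [UnitaryKernel-class].
#' @param freqsHz numeric frequency grid (Hz).
#' @return complex matrix, `length(freqsHz)` x 3 (units value * ms).
#' @export
kernelTransfer <- function(kernel, freqsHz) {
  w <- kernel@waveform                  # 3 x T
  tms <- seq(kernel@window[1], by = kernel@dt, length.out = ncol(w))
  ## phase uses seconds since f is in Hz
  ph <- exp(-2i * pi * outer(freqsHz, tms * MS_TO_S))
  (ph %*% t(w)) * kernel@dt
}

#' Energy spectrum on an arbitrary frequency grid
#'
#' One-sided energy spectral density `2 |u_hat(f)|^2` (factor 1 at f = 0)
#' evaluated at arbitrary frequencies via [kernelTransfer()], e.g. to put
#' a kernel's energy spectrum on a Welch PSD grid for the linear AP model
#' fit. Channels are summed; units value^2*ms/Hz as for
#' [energySpectrum()].
#'
#' @param kernel a [UnitaryKernel-class].
#' @param freqsHz frequency grid (Hz).
#' @return a [Spectrum-class] of kind `"energy"`.
#' @export
energySpectrumAt <- function(kernel, freqsHz) {
  ut <- kernelTransfer(kernel, freqsHz)
  v <- rowSums(Mod(ut)^2) * MS_TO_S * ifelse(freqsHz > 0, 2, 1)
  Spectrum(freqsHz, v, units = UNIT_ENERGY_DIPOLE, kind = "energy")
}

#' Total energy of a kernel
#'
#' `sum over channels of sum(u(t)^2) * dt`, dt in ms.
#' @param kernel a [UnitaryKernel-class].
#' @return scalar energy in value^2*ms.
#' @export
kernelEnergy <- function(kernel) sum(kernel@waveform^2) * kernel@dt

#' Restrict a spectrum to a frequency band
#'
#' @param s a [Spectrum-class].
#' @param band numeric length 2, inclusive (Hz).
#' @return the restricted [Spectrum-class].
#' @export
bandSubset <- function(s, band) {
  keep <- s@freqs >= band[1] & s@freqs <= band[2]
  if (!any(keep)) stop("band contains no frequency bins")
  Spectrum(s@freqs[keep], s@values[keep], units = s@units, kind = s@kind)
}

#' Trapezoidal integral of a spectrum over frequency
#'
#' @param s a [Spectrum-class].
#' @return scalar; units are `units(s) * Hz`.
#' @export
integrateSpectrum <- function(s) {
  f <- s@freqs; v <- Re(s@values)
  if (length(f) < 2) return(0)
  sum(diff(f) * (utils::head(v, -1) + utils::tail(v, -1)) / 2)
}
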